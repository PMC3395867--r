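#' Proportionality fit between plate and lumen resistance
#'
#' Fits the proportionality `R_P = k R_L` across species. Because the data
#' span several decades, the primary convention is least squares in log
#' space: the model `log R_P = log k + log R_L` gives
#' \deqn{\hat{k} = \exp\left( \overline{\log R_P - \log R_L} \right),}
#' i.e. `k` is the geometric mean of the per-species ratios, so no single
#' large species dominates the fit. The uncertainty is the standard error of
#' the mean log ratio mapped through the exponential,
#' `k * sd(log residuals) / sqrt(n)`, and the correlation is the Pearson
#' correlation of `log R_L` versus `log R_P`. For comparison the linear-space
#' proportionality fit (`k = sum(R_P R_L) / sum(R_L^2)`) and the linear-space
#' Pearson correlation are also reported.
#'
#' Under the log-space convention, rescaling every `R_L` by a factor `c`
#' divides `k` by exactly `c` and leaves the correlation unchanged, so a
#' lumen blockage factor `b` maps `k` to `k / b^4`.
#'
#' @param R_lumen,R_plate Equal-length vectors of positive resistances
#'   (Pa s/m^3), `n >= 2`.
#' @return An object of class `"prop_fit"` with elements `k`, `k_se`,
#'   `r_corr`, `n`, `k_linear`, `r_corr_linear`, `log_residuals` and the
#'   input `data`.
#' @examples
#' RL <- 10^stats::runif(19, 12, 16)
#' fit <- fit_proportionality(RL, 2.5 * RL)
#' coef(fit)
#' @export
fit_proportionality <- function(R_lumen, R_plate) {
  if (length(R_lumen) != length(R_plate))
    stop("R_lumen and R_plate must have the same length", call. = FALSE)
  n <- length(R_lumen)
  if (n < 2) stop("need at least two species to fit", call. = FALSE)
  if (any(!is.finite(R_lumen)) || any(!is.finite(R_plate)) ||
      any(R_lumen <= 0) || any(R_plate <= 0))
    stop("all resistances must be positive (log-space fit)", call. = FALSE)
  log_ratio <- log(R_plate) - log(R_lumen)
  k <- exp(mean(log_ratio))
  resid <- log_ratio - mean(log_ratio)
  s <- stats::sd(log_ratio)
  structure(list(k = k,
                 k_se = k * s / sqrt(n),
                 r_corr = stats::cor(log(R_lumen), log(R_plate)),
                 n = n,
                 k_linear = sum(R_plate * R_lumen) / sum(R_lumen^2),
                 r_corr_linear = stats::cor(R_lumen, R_plate),
                 log_residuals = resid,
                 data = data.frame(R_lumen = R_lumen, R_plate = R_plate)),
            class = "prop_fit")
}

#' @export
print.prop_fit <- function(x, digits = 3, ...) {
  cat("Proportionality fit R_plate = k * R_lumen (log-space least squares)\n")
  cat(sprintf("  k = %.*g +/- %.*g   (r_corr = %.*g, n = %d)\n",
              digits, x$k, digits, x$k_se, digits, x$r_corr, x$n))
  invisible(x)
}

#' @export
summary.prop_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.prop_fit")
}

#' @export
print.summary.prop_fit <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  linear-space comparison: k = %.*g (Pearson r = %.*g)\n",
              digits, f$k_linear, digits, f$r_corr_linear))
  cat(sprintf("  log-residual sd = %.*g over %d species\n",
              digits, stats::sd(f$log_residuals), f$n))
  cat(sprintf("  total-resistance amplification 1 + k = %.*g\n",
              digits, 1 + f$k))
  invisible(x)
}

#' @export
coef.prop_fit <- function(object, ...) {
  c(k = object$k)
}

#' @export
predict.prop_fit <- function(object, newdata = NULL, ...) {
  RL <- if (is.null(newdata)) object$data$R_lumen
        else if (is.data.frame(newdata)) newdata$R_lumen
        else as.numeric(newdata)
  object$k * RL
}

#' @export
residuals.prop_fit <- function(object, ...) {
  object$log_residuals
}

#' @export
plot.prop_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$R_lumen, d$R_plate, log = "xy",
                 xlab = "R_lumen (Pa s/m^3)", ylab = "R_plate (Pa s/m^3)",
                 main = sprintf("R_plate = %.2g R_lumen (r = %.2f)",
                                x$k, x$r_corr), ...)
  rng <- range(d$R_lumen)
  graphics::lines(rng, x$k * rng, lwd = 2)
  graphics::lines(rng, (x$k + 2 * x$k_se) * rng, lty = 2)
  graphics::lines(rng, max(x$k - 2 * x$k_se, .Machine$double.xmin) * rng,
                  lty = 2)
  invisible(x)
}
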