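#' Parameter sweep over the dimensionless geometry groups
#'
#' Crosses the supplied values of the dimensionless groups (`alpha`, `beta`,
#' `gamma`, `delta`, `phi`) and, for each combination and replicate,
#' generates a sieve-plate realization and computes the total sieve-tube
#' resistance with each estimator: explicit-pore parallel sum (`eq10`, on the
#' sampled realization), pore-size-distribution integral (`eq11`), and the
#' Poiseuille-only and mean-radius legacy estimators. Ratios against `eq11`
#' are included for estimator comparison.
#'
#' The physical scale is set by `mean_radius` (default 1 um); all resistances
#' scale as `eta / length^3` so the ratios are scale-free. The pore count per
#' plate is `round(phi / (delta^2 (1 + beta^2)))`. Combinations whose pores
#' cannot be packed at the requested covering fraction (random sequential
#' addition jams near phi ~ 0.55) are recorded as failed rows rather than
#' aborting the sweep.
#'
#' @param alpha,beta,gamma,delta,phi Numeric vectors of group values. They
#'   must lie within the ranges the model was assessed over:
#'   alpha 0.4--1.2, beta 0.2--0.4, gamma 10--100, delta 0.05--0.2,
#'   phi 0.1--0.6.
#' @param reps Replicates (fresh realization) per combination.
#' @param seed Master seed; each row derives its own sub-seed, so identical
#'   arguments give an identical table.
#' @param fluid A [fluid_properties()].
#' @param mean_radius Dimensional mean pore radius in m (scale only).
#' @return A data frame with one row per combination and replicate: the five
#'   groups, `rep`, `n_pores`, `status` (`"ok"` or `"packing_failed"`), the
#'   four resistances (Pa s/m^3, `NA` for failed rows) and the three ratios.
#' @examples
#' sw <- parameter_sweep(alpha = c(0.4, 1.2), beta = 0.25, gamma = 10,
#'                       delta = 0.1, phi = c(0.2, 0.5), reps = 1, seed = 1)
#' @export
parameter_sweep <- function(alpha, beta, gamma, delta, phi, reps = 1,
                            seed = 1, fluid = fluid_properties(),
                            mean_radius = 1e-6) {
  check_range <- function(x, lo, hi, nm) {
    if (any(x < lo) || any(x > hi))
      stop(sprintf("%s values must lie within [%g, %g]", nm, lo, hi),
           call. = FALSE)
  }
  check_range(alpha, 0.4, 1.2, "alpha")
  check_range(beta, 0.2, 0.4, "beta")
  check_range(gamma, 10, 100, "gamma")
  check_range(delta, 0.05, 0.2, "delta")
  check_range(phi, 0.1, 0.6, "phi")
  stopifnot(reps >= 1, reps == round(reps))

  grid <- expand.grid(alpha = alpha, beta = beta, gamma = gamma,
                      delta = delta, phi = phi, rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  res <- data.frame(grid,
                    n_pores = NA_integer_, status = "ok",
                    R_eq10 = NA_real_, R_eq11 = NA_real_,
                    R_mullendore = NA_real_, R_thompson_holbrook = NA_real_,
                    ratio_eq10_eq11 = NA_real_,
                    ratio_mullendore_eq11 = NA_real_,
                    ratio_thompson_holbrook_eq11 = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- grid[i, ]
    row_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    r_tube <- mean_radius / g$delta
    sd_radius <- g$beta * mean_radius
    lp <- g$alpha * mean_radius
    l_tube <- g$gamma * r_tube
    N <- max(1L, as.integer(round(g$phi / (g$delta^2 * (1 + g$beta^2)))))
    res$n_pores[i] <- N
    tube <- tube_geometry(l_tube, r_tube)
    radii <- sample_pore_radii(mean_radius, sd_radius, N, seed = row_seed)
    realization <- tryCatch(
      place_pores(radii, r_tube, lp, seed = row_seed),
      error = function(e) e)
    if (inherits(realization, "error")) {
      res$status[i] <- "packing_failed"
      next
    }
    plate_d <- plate_spec(lp, pore_radii = realization$pores$radius)
    plate_n <- plate_spec(lp, mean_radius = mean_radius,
                          sd_radius = sd_radius, n_pores = N)
    res$R_eq10[i] <- total_resistance(tube, plate_d, fluid, "eq10")
    res$R_eq11[i] <- total_resistance(tube, plate_n, fluid, "eq11")
    res$R_mullendore[i] <- total_resistance(tube, plate_n, fluid, "mullendore")
    res$R_thompson_holbrook[i] <-
      total_resistance(tube, plate_n, fluid, "thompson_holbrook")
    res$ratio_eq10_eq11[i] <- res$R_eq10[i] / res$R_eq11[i]
    res$ratio_mullendore_eq11[i] <- res$R_mullendore[i] / res$R_eq11[i]
    res$ratio_thompson_holbrook_eq11[i] <-
      res$R_thompson_holbrook[i] / res$R_eq11[i]
  }
  attr(res, "seed") <- seed
  res
}

#' Write a sweep table to CSV
#'
#' @param sweep A data frame from [parameter_sweep()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
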