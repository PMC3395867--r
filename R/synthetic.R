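#' Sample pore radii from a truncated normal law
#'
#' Draws `n` pore radii from Normal(`mean_radius`, `sd_radius`) and rejects
#' non-positive draws (redrawing until `n` positive radii are obtained).
#' Rejection, rather than clipping, preserves the shape of the distribution;
#' for relative spreads `sd_radius/mean_radius <= 0.4` the rejected mass is at
#' most about 0.6%, so sample moments remain essentially those of the
#' untruncated law.
#'
#' @param mean_radius Mean pore radius in m.
#' @param sd_radius Standard deviation in m, `>= 0`.
#' @param n Number of radii, `>= 1`.
#' @param seed Integer seed; the same seed always returns the same radii.
#' @return Numeric vector of `n` positive radii in m.
#' @examples
#' r <- sample_pore_radii(1e-6, 0.25e-6, 100, seed = 1)
#' @export
sample_pore_radii <- function(mean_radius, sd_radius, n, seed) {
  stopifnot(mean_radius > 0, sd_radius >= 0, n >= 1, n == round(n))
  if (sd_radius >= mean_radius)
    warning("sd_radius >= mean_radius: heavy truncation at zero will ",
            "distort the sample moments", call. = FALSE)
  if (sd_radius == 0) return(rep(mean_radius, n))
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(n - length(out), mean_radius, sd_radius)
      out <- c(out, draw[draw > 0])
    }
    out
  })
}

#' Generate an idealized sieve-plate realization
#'
#' Places circular pores of the given radii at random non-overlapping
#' positions inside the tube cross-section, by random sequential addition:
#' pores are placed largest first, each by proposing uniform centers in the
#' disk of feasible centers (radius `r - pore_radius`) until the pore neither
#' leaves the cross-section nor overlaps an already-placed pore. Random
#' sequential addition jams well below a covering fraction of about 0.55, so
#' requests near or above that may legitimately fail; failure raises a packing
#' error reporting the achieved versus requested covering fraction.
#'
#' @param radii Pore radii in m (e.g. from [sample_pore_radii()]).
#' @param radius Tube (plate) radius in m.
#' @param thickness Plate thickness in m (carried as metadata).
#' @param seed Integer seed; placement is reproducible.
#' @param min_gap Minimum surface-to-surface distance between pores in m
#'   (default 0: pores may touch but not overlap).
#' @param max_attempts Maximum center proposals per pore (default `1e5`).
#' @return An object of class `"plate_realization"`: a list with `radius`,
#'   `thickness`, `seed` and a data frame `pores` with columns `x`, `y`,
#'   `radius` (m).
#' @examples
#' radii <- sample_pore_radii(1e-6, 0.25e-6, 30, seed = 2)
#' pl <- place_pores(radii, radius = 10e-6, thickness = 1e-6, seed = 2)
#' @export
place_pores <- function(radii, radius, thickness = NA_real_, seed,
                        min_gap = 0, max_attempts = 1e5) {
  stopifnot(length(radii) >= 1L, all(radii > 0), radius > 0, min_gap >= 0,
            max_attempts >= 1)
  phi_req <- sum(radii^2) / radius^2
  if (phi_req > 1)
    stop(sprintf(
      "packing error: requested covering fraction %.3f exceeds 1 by area",
      phi_req), call. = FALSE)
  if (any(radii >= radius))
    stop("every pore radius must be smaller than the tube radius",
         call. = FALSE)
  ord <- order(radii, decreasing = TRUE)
  radii <- radii[ord]
  n <- length(radii)
  x <- numeric(n); y <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      rp <- radii[i]
      rmax <- radius - rp          # strict containment of the pore disk
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        # uniform point in the disk of feasible centers
        rho <- rmax * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        cx <- rho * cos(th); cy <- rho * sin(th)
        if (i > 1L) {
          d2 <- (x[seq_len(i - 1L)] - cx)^2 + (y[seq_len(i - 1L)] - cy)^2
          if (any(d2 < (radii[seq_len(i - 1L)] + rp + min_gap)^2)) next
        }
        x[i] <- cx; y[i] <- cy
        placed <- TRUE
        break
      }
      if (!placed) {
        phi_done <- sum(radii[seq_len(i - 1L)]^2) / radius^2
        stop(sprintf(paste0(
          "packing error: placed %d/%d pores (covering fraction %.3f of ",
          "requested %.3f) before exhausting %d attempts"),
          i - 1L, n, phi_done, phi_req, as.integer(max_attempts)),
          call. = FALSE)
      }
    }
  })
  structure(list(radius = radius, thickness = thickness, seed = seed,
                 pores = data.frame(x = x, y = y, radius = radii)),
            class = "plate_realization")
}

#' @export
print.plate_realization <- function(x, ...) {
  phi <- sum(x$pores$radius^2) / x$radius^2
  cat(sprintf(
    "Sieve-plate realization: r = %g um, %d pores, phi = %.3f (seed %s)\n",
    x$radius * 1e6, nrow(x$pores), phi, format(x$seed)))
  invisible(x)
}

#' @export
plot.plate_realization <- function(x, ...) {
  r_um <- x$radius * 1e6
  graphics::plot(NA, xlim = c(-r_um, r_um), ylim = c(-r_um, r_um), asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = "Sieve-plate realization", ...)
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(r_um * cos(th), r_um * sin(th), lwd = 2)
  for (i in seq_len(nrow(x$pores))) {
    graphics::polygon(x$pores$x[i] * 1e6 + x$pores$radius[i] * 1e6 * cos(th),
                      x$pores$y[i] * 1e6 + x$pores$radius[i] * 1e6 * sin(th),
                      col = "grey80")
  }
  invisible(x)
}

#' Check the geometric invariants of a plate realization
#'
#' Brute-force oracle over all pore pairs: verifies strict containment of
#' every pore disk in the cross-section and the absence of overlaps
#' (surface-to-surface distance `>= min_gap`). Intended for testing and
#' validation of generated realizations.
#'
#' @param realization A `"plate_realization"`.
#' @param min_gap Minimum allowed gap in m.
#' @return `TRUE` if all checks pass, otherwise `FALSE` (with attribute
#'   `"why"` describing the first violation).
#' @examples
#' pl <- place_pores(sample_pore_radii(1e-6, 0.25e-6, 20, 3), 10e-6, 1e-6, 3)
#' check_realization(pl)
#' @export
check_realization <- function(realization, min_gap = 0) {
  stopifnot(inherits(realization, "plate_realization"))
  p <- realization$pores
  r <- realization$radius
  if (any(p$radius <= 0))
    return(structure(FALSE, why = "non-positive pore radius"))
  cont <- sqrt(p$x^2 + p$y^2) + p$radius
  if (any(cont >= r * (1 + 1e-12)))
    return(structure(FALSE, why = "pore not strictly inside cross-section"))
  n <- nrow(p)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        d <- sqrt((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2)
        if (d < p$radius[i] + p$radius[j] + min_gap - 1e-15 * r)
          return(structure(FALSE,
                           why = sprintf("pores %d and %d overlap", i, j)))
      }
    }
  }
  TRUE
}

#' Fit a normal distribution to measured pore radii
#'
#' Sample mean and sample standard deviation (unbiased, n-1 denominator) of a
#' set of pore radii; the moment analogue of fitting a normal curve to a
#' pore-radius histogram. In well-cleared sieve plates the ratio sd/mean is
#' found empirically to be about 0.25.
#'
#' @param radii Numeric vector of at least two positive radii in m.
#' @return A list of class `"distribution_fit"` with elements `mean`, `sd`,
#'   `n` and `rel_spread` (= sd/mean).
#' @examples
#' fit_pore_distribution(sample_pore_radii(1e-6, 0.25e-6, 5000, 4))
#' @export
fit_pore_distribution <- function(radii) {
  if (length(radii) < 2L)
    stop("need at least two radii to fit a distribution", call. = FALSE)
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("radii must be positive and finite", call. = FALSE)
  m <- mean(radii)
  s <- stats::sd(radii)
  structure(list(mean = m, sd = s, n = length(radii), rel_spread = s / m),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf(
    "Pore-radius fit: mean = %.4g um, sd = %.4g um (sd/mean = %.3f, n = %d)\n",
    x$mean * 1e6, x$sd * 1e6, x$rel_spread, x$n))
  invisible(x)
}

#' Write / read a plate realization as plain text
#'
#' The realization is stored as a CSV of pore centers and radii in
#' micrometers, preceded by `#`-prefixed header lines recording the tube
#' radius, plate thickness and seed.
#'
#' @param realization A `"plate_realization"`.
#' @param path File path.
#' @return `write_realization()` returns `path` invisibly;
#'   `read_realization()` returns a `"plate_realization"`.
#' @examples
#' pl <- place_pores(sample_pore_radii(1e-6, 0.25e-6, 10, 5), 10e-6, 1e-6, 5)
#' f <- tempfile(fileext = ".csv")
#' write_realization(pl, f)
#' pl2 <- read_realization(f)
#' @export
write_realization <- function(realization, path) {
  stopifnot(inherits(realization, "plate_realization"))
  hdr <- c(sprintf("# r_um: %.12g", realization$radius * 1e6),
           sprintf("# lp_um: %.12g", realization$thickness * 1e6),
           sprintf("# seed: %s", format(realization$seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("x_um,y_um,radius_um", con)
  p <- realization$pores
  writeLines(sprintf("%.12g,%.12g,%.12g", p$x * 1e6, p$y * 1e6,
                     p$radius * 1e6), con)
  invisible(path)
}

#' @rdname write_realization
#' @export
read_realization <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) != 1L) stop("missing header line for ", key, call. = FALSE)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", ln))
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  structure(list(radius = get_num("r_um") * 1e-6,
                 thickness = get_num("lp_um") * 1e-6,
                 seed = as.integer(get_num("seed")),
                 pores = data.frame(x = df$x_um * 1e-6, y = df$y_um * 1e-6,
                                    radius = df$radius_um * 1e-6)),
            class = "plate_realization")
}
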