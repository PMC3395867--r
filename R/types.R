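#' Sap fluid properties
#'
#' Dynamic viscosity and density of the phloem sap. Sugar solutions in the
#' 0.1--1 M range have roughly twice the viscosity of water, so the default is
#' 2 mPa s; the density is essentially that of water.
#'
#' @param viscosity Dynamic viscosity in Pa s (default `2e-3`).
#' @param density Density in kg/m^3 (default `1000`).
#' @return An object of class `"fluid_properties"`.
#' @examples
#' fluid_properties()
#' fluid_properties(viscosity = 1.5e-3)
#' @export
fluid_properties <- function(viscosity = 2e-3, density = 1000) {
  stopifnot(is.numeric(viscosity), length(viscosity) == 1L, is.finite(viscosity),
            is.numeric(density), length(density) == 1L, is.finite(density))
  if (viscosity <= 0) stop("viscosity must be positive", call. = FALSE)
  if (density <= 0) stop("density must be positive", call. = FALSE)
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Sap: eta = %g mPa s, rho = %g kg/m^3\n",
              x$viscosity * 1e3, x$density))
  invisible(x)
}

#' Sieve tube lumen geometry
#'
#' A sieve tube element is modelled as a straight cylinder of length `length`
#' and radius `radius`. `blockage_factor` rescales the radius open to flow
#' (effective radius `blockage_factor * radius`), representing partial
#' occlusion of the lumen by parietal organelles; it affects only the lumen
#' resistance, never the sieve-plate pores.
#'
#' @param length Tube (cell) length in m.
#' @param radius Tube radius in m.
#' @param blockage_factor Fraction of the radius open to flow, in (0, 1].
#' @return An object of class `"tube_geometry"`.
#' @examples
#' tube_geometry(length = 100e-6, radius = 10e-6)
#' tube_geometry(100e-6, 10e-6, blockage_factor = 0.8)
#' @export
tube_geometry <- function(length, radius, blockage_factor = 1) {
  stopifnot(is.numeric(length), length(length) == 1L, is.finite(length),
            is.numeric(radius), length(radius) == 1L, is.finite(radius),
            is.numeric(blockage_factor), length(blockage_factor) == 1L,
            is.finite(blockage_factor))
  if (length <= 0) stop("tube length must be positive", call. = FALSE)
  if (radius <= 0) stop("tube radius must be positive", call. = FALSE)
  if (blockage_factor <= 0 || blockage_factor > 1)
    stop("blockage_factor must lie in (0, 1]", call. = FALSE)
  structure(list(length = length, radius = radius,
                 blockage_factor = blockage_factor),
            class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("Sieve tube lumen: l = %g um, r = %g um", x$length * 1e6,
              x$radius * 1e6))
  if (x$blockage_factor < 1)
    cat(sprintf(" (effective open radius %g um, blockage factor %g)",
                x$blockage_factor * x$radius * 1e6, x$blockage_factor))
  cat("\n")
  invisible(x)
}

#' Sieve plate specification
#'
#' Describes a sieve plate of thickness `thickness` either by the explicit
#' list of its pore radii (`mode = "discrete"`) or by the parameters of a
#' normal pore-radius distribution (`mode = "distributional"`): mean radius,
#' standard deviation and pore count.
#'
#' @param thickness Plate thickness in m.
#' @param pore_radii Numeric vector of pore radii in m (discrete mode).
#' @param mean_radius Mean pore radius in m (distributional mode).
#' @param sd_radius Pore-radius standard deviation in m, `>= 0`.
#' @param n_pores Number of pores (distributional mode), positive integer.
#' @return An object of class `"plate_spec"` with element `mode` set to
#'   `"discrete"` or `"distributional"`.
#' @examples
#' plate_spec(1e-6, pore_radii = c(0.8, 1.0, 1.2) * 1e-6)
#' plate_spec(1e-6, mean_radius = 1e-6, sd_radius = 0.25e-6, n_pores = 100)
#' @export
plate_spec <- function(thickness, pore_radii = NULL, mean_radius = NULL,
                       sd_radius = NULL, n_pores = NULL) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L, is.finite(thickness))
  if (thickness <= 0) stop("plate thickness must be positive", call. = FALSE)
  if (!is.null(pore_radii)) {
    if (!is.null(mean_radius) || !is.null(sd_radius) || !is.null(n_pores))
      stop("give either pore_radii or (mean_radius, sd_radius, n_pores), not both",
           call. = FALSE)
    if (length(pore_radii) == 0L || any(!is.finite(pore_radii)) ||
        any(pore_radii <= 0))
      stop("pore_radii must be a non-empty vector of positive radii",
           call. = FALSE)
    out <- list(thickness = thickness, mode = "discrete",
                pore_radii = as.numeric(pore_radii),
                n_pores = length(pore_radii))
  } else {
    if (is.null(mean_radius) || is.null(n_pores))
      stop("distributional mode requires mean_radius and n_pores", call. = FALSE)
    if (is.null(sd_radius)) sd_radius <- 0
    stopifnot(is.numeric(mean_radius), length(mean_radius) == 1L,
              is.numeric(sd_radius), length(sd_radius) == 1L,
              is.numeric(n_pores), length(n_pores) == 1L)
    if (mean_radius <= 0) stop("mean_radius must be positive", call. = FALSE)
    if (sd_radius < 0) stop("sd_radius must be non-negative", call. = FALSE)
    if (sd_radius >= mean_radius)
      stop("sd_radius must be smaller than mean_radius (normal mass below ",
           "zero would not be negligible)", call. = FALSE)
    if (n_pores < 1 || n_pores != round(n_pores))
      stop("n_pores must be a positive integer", call. = FALSE)
    out <- list(thickness = thickness, mode = "distributional",
                mean_radius = mean_radius, sd_radius = sd_radius,
                n_pores = as.integer(n_pores))
  }
  structure(out, class = "plate_spec")
}

#' @export
print.plate_spec <- function(x, ...) {
  if (x$mode == "discrete") {
    cat(sprintf(
      "Sieve plate: lp = %g um, %d explicit pores (mean radius %.3g um)\n",
      x$thickness * 1e6, x$n_pores, mean(x$pore_radii) * 1e6))
  } else {
    cat(sprintf(
      "Sieve plate: lp = %g um, N = %d pores ~ Normal(%.3g um, sd %.3g um)\n",
      x$thickness * 1e6, x$n_pores, x$mean_radius * 1e6, x$sd_radius * 1e6))
  }
  invisible(x)
}

# mean and sd of the pore-radius law implied by a plate_spec (sample moments
# in discrete mode)
plate_moments <- function(plate) {
  if (plate$mode == "discrete") {
    list(mean = mean(plate$pore_radii),
         sd = if (plate$n_pores > 1L) stats::sd(plate$pore_radii) else 0)
  } else {
    list(mean = plate$mean_radius, sd = plate$sd_radius)
  }
}
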