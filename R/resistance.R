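#' Hydraulic resistance of the sieve tube lumen
#'
#' Hagen-Poiseuille resistance of a straight cylindrical lumen,
#' \deqn{R_L = \frac{8 \eta \ell}{\pi (b r)^4},}
#' where \eqn{b} is the blockage factor of the tube (effective radius open to
#' flow \eqn{b r}).
#'
#' @param tube A [tube_geometry()].
#' @param fluid A [fluid_properties()].
#' @return Resistance in Pa s/m^3.
#' @examples
#' lumen_resistance(tube_geometry(100e-6, 10e-6), fluid_properties())
#' @export
lumen_resistance <- function(tube, fluid = fluid_properties()) {
  stopifnot(inherits(tube, "tube_geometry"), inherits(fluid, "fluid_properties"))
  r_eff <- tube$blockage_factor * tube$radius
  8 * fluid$viscosity * tube$length / (pi * r_eff^4)
}

#' Hydraulic resistance of a single sieve pore
#'
#' Series combination of the Hagen-Poiseuille resistance of a cylindrical pore
#' of length `lp` and the Sampson resistance of a circular orifice in a plate
#' of vanishing thickness:
#' \deqn{R^{*} = \frac{8 \eta \ell_p}{\pi r_p^4} + \frac{3 \eta}{r_p^3}.}
#' For `lp = 0` this reduces exactly to the Sampson term. The approximation is
#' worst when the pore length is comparable to its diameter
#' (\eqn{\ell_p \simeq 2 r_p}), where the model error is still only about 1%.
#'
#' @param pore_radius Pore radius in m (vectorised).
#' @param thickness Plate (pore) thickness in m, `>= 0`.
#' @param fluid A [fluid_properties()].
#' @return Resistance in Pa s/m^3.
#' @examples
#' single_pore_resistance(1e-6, 1e-6, fluid_properties())
#' single_pore_resistance(1e-6, 0)  # pure Sampson orifice
#' @export
single_pore_resistance <- function(pore_radius, thickness,
                                   fluid = fluid_properties()) {
  stopifnot(is.numeric(pore_radius), is.numeric(thickness),
            length(thickness) == 1L, inherits(fluid, "fluid_properties"))
  if (any(!is.finite(pore_radius)) || any(pore_radius <= 0))
    stop("pore_radius must be positive", call. = FALSE)
  if (!is.finite(thickness) || thickness < 0)
    stop("thickness must be non-negative", call. = FALSE)
  eta <- fluid$viscosity
  8 * eta * thickness / (pi * pore_radius^4) + 3 * eta / pore_radius^3
}

#' Sieve-plate resistance from explicit pore radii
#'
#' Pores act as hydraulic resistors in parallel: the plate resistance is the
#' harmonic composition
#' \deqn{R_P = \left( \sum_{i=1}^{N} R_{p,i}^{-1} \right)^{-1}}
#' with the per-pore resistance of [single_pore_resistance()].
#'
#' @param pore_radii Non-empty numeric vector of pore radii in m.
#' @param thickness Plate thickness in m.
#' @param fluid A [fluid_properties()].
#' @return Resistance in Pa s/m^3.
#' @examples
#' plate_resistance_discrete(c(0.8, 1.0, 1.2) * 1e-6, 1e-6)
#' @export
plate_resistance_discrete <- function(pore_radii, thickness,
                                      fluid = fluid_properties()) {
  if (length(pore_radii) == 0L)
    stop("pore_radii must be non-empty", call. = FALSE)
  1 / sum(1 / single_pore_resistance(pore_radii, thickness, fluid))
}

# Eq-11-style integral over the re-scaled pore radius xi = r_p / mean_radius:
# E_normal(1,beta)[ (8 alpha / (pi xi^4) + 3 / xi^3)^(-1) ], taken over
# (0, Inf) with the untruncated normal density (mass below zero is <= 0.6%
# for beta <= 0.4 and the integrand vanishes like xi^4 near 0).
pore_admittance_integral <- function(alpha, beta, rel_tol = 1e-10) {
  f <- function(xi) {
    stats::dnorm(xi, mean = 1, sd = beta) /
      (8 * alpha / (pi * xi^4) + 3 / xi^3)
  }
  # integrate a window centred on the density peak (all the mass lies within
  # ~8 beta of xi = 1, and for narrow densities a blind (0, Inf) pass would
  # miss the spike), then add the residual tails
  lo <- max(0, 1 - 10 * beta)
  hi <- 1 + 10 * beta
  res <- tryCatch({
    core <- stats::integrate(f, lo, hi, rel.tol = rel_tol, abs.tol = 0,
                             subdivisions = 400L)
    left <- if (lo > 0)
      stats::integrate(f, 0, lo, rel.tol = rel_tol, subdivisions = 400L)
    else list(value = 0, abs.error = 0)
    tail <- stats::integrate(f, hi, Inf, rel.tol = rel_tol,
                             subdivisions = 400L)
    list(value = core$value + left$value + tail$value,
         abs.error = core$abs.error + left$abs.error + tail$abs.error)
  }, error = function(e) {
    stop("quadrature of the pore-size-distribution integral failed (alpha = ",
         signif(alpha, 4), ", beta = ", signif(beta, 4), "): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.finite(res$value) || res$value <= 0)
    stop("quadrature returned a non-positive value (alpha = ",
         signif(alpha, 4), ", beta = ", signif(beta, 4), ")", call. = FALSE)
  res$value
}

#' Sieve-plate resistance from a normal pore-size distribution
#'
#' When only the mean pore radius, its standard deviation and the pore count
#' are known, the parallel sum over pores is replaced by an expectation over
#' the normal pore-radius law. With the re-scaled radius
#' \eqn{\xi = r_p/\bar{r}_p}, the aspect ratio \eqn{\alpha = \ell_p/\bar{r}_p}
#' and the relative spread \eqn{\beta = \sigma_p/\bar{r}_p},
#' \deqn{R_P = \frac{\eta}{N \bar{r}_p^3}
#'   \left[ \int_0^\infty \frac{e^{-(1-\xi)^2/(2\beta^2)}}{\sqrt{2\pi\beta^2}}
#'   \left( \frac{8\alpha}{\pi \xi^4} + \frac{3}{\xi^3} \right)^{-1}
#'   d\xi \right]^{-1}.}
#' The integral is evaluated by adaptive quadrature to a relative tolerance of
#' about 1e-10; the degenerate case `sd_radius = 0` is handled analytically
#' and equals [plate_resistance_thompson_holbrook()].
#'
#' Because wide distributions put more conductance in the large-pore tail,
#' the resistance decreases as `sd_radius` grows at fixed `mean_radius`.
#'
#' @param mean_radius Mean pore radius in m.
#' @param sd_radius Pore-radius standard deviation in m, `>= 0`.
#' @param n_pores Number of pores.
#' @param thickness Plate thickness in m.
#' @param fluid A [fluid_properties()].
#' @return Resistance in Pa s/m^3.
#' @examples
#' plate_resistance_distributional(1e-6, 0.25e-6, 100, 1e-6)
#' @export
plate_resistance_distributional <- function(mean_radius, sd_radius, n_pores,
                                            thickness,
                                            fluid = fluid_properties()) {
  stopifnot(is.numeric(mean_radius), mean_radius > 0,
            is.numeric(sd_radius), sd_radius >= 0,
            is.numeric(n_pores), n_pores >= 1,
            is.numeric(thickness), thickness >= 0,
            inherits(fluid, "fluid_properties"))
  if (sd_radius == 0)
    return(plate_resistance_thompson_holbrook(mean_radius, n_pores, thickness,
                                              fluid))
  alpha <- thickness / mean_radius
  beta <- sd_radius / mean_radius
  I <- pore_admittance_integral(alpha, beta)
  fluid$viscosity / (n_pores * mean_radius^3 * I)
}

#' Sieve-plate resistance, Poiseuille-only legacy estimator
#'
#' Legacy estimator that keeps only the Hagen-Poiseuille term
#' \eqn{8\eta\ell_p/(\pi r_{p,i}^4)} per pore, dropping the Sampson orifice
#' term; adequate only when \eqn{r_p/\ell_p \ll 1}. In distributional form the
#' parallel sum becomes \eqn{R_P = 8\eta\ell_p / (\pi N E[r_p^4])} with the
#' normal-law moment \eqn{E[r_p^4] = \bar{r}_p^4 + 6\bar{r}_p^2\sigma_p^2 +
#' 3\sigma_p^4}.
#'
#' @param pore_radii Explicit pore radii in m, or `NULL` to use the
#'   distributional form.
#' @param mean_radius,sd_radius,n_pores Normal-law parameters
#'   (distributional form).
#' @param thickness Plate thickness in m.
#' @param fluid A [fluid_properties()].
#' @return Resistance in Pa s/m^3. Never exceeds
#'   [plate_resistance_discrete()] on the same pores, since it omits a
#'   positive series term.
#' @examples
#' plate_resistance_mullendore(pore_radii = c(1e-6), thickness = 1e-6)
#' plate_resistance_mullendore(mean_radius = 1e-6, sd_radius = 0.25e-6,
#'                             n_pores = 100, thickness = 1e-6)
#' @export
plate_resistance_mullendore <- function(pore_radii = NULL, mean_radius = NULL,
                                        sd_radius = 0, n_pores = NULL,
                                        thickness, fluid = fluid_properties()) {
  stopifnot(is.numeric(thickness), thickness > 0,
            inherits(fluid, "fluid_properties"))
  eta <- fluid$viscosity
  if (!is.null(pore_radii)) {
    if (length(pore_radii) == 0L || any(pore_radii <= 0))
      stop("pore_radii must be non-empty and positive", call. = FALSE)
    return(8 * eta * thickness / (pi * sum(pore_radii^4)))
  }
  stopifnot(is.numeric(mean_radius), mean_radius > 0, sd_radius >= 0,
            is.numeric(n_pores), n_pores >= 1)
  m4 <- mean_radius^4 + 6 * mean_radius^2 * sd_radius^2 + 3 * sd_radius^4
  8 * eta * thickness / (pi * n_pores * m4)
}

#' Sieve-plate resistance, mean-radius legacy estimator
#'
#' Legacy estimator that ignores pore-size variation: every pore is assigned
#' the arithmetic mean radius, keeping both the Poiseuille and Sampson terms,
#' \deqn{R_P = \frac{1}{N}\left( \frac{8\eta\ell_p}{\pi\bar{r}_p^4} +
#'   \frac{3\eta}{\bar{r}_p^3} \right).}
#'
#' @param mean_radius Arithmetic mean pore radius in m.
#' @param n_pores Number of pores.
#' @param thickness Plate thickness in m.
#' @param fluid A [fluid_properties()].
#' @return Resistance in Pa s/m^3.
#' @examples
#' plate_resistance_thompson_holbrook(1e-6, 100, 1e-6)
#' @export
plate_resistance_thompson_holbrook <- function(mean_radius, n_pores, thickness,
                                               fluid = fluid_properties()) {
  stopifnot(is.numeric(mean_radius), mean_radius > 0,
            is.numeric(n_pores), n_pores >= 1)
  single_pore_resistance(mean_radius, thickness, fluid) / n_pores
}

#' Total resistance of a sieve tube element
#'
#' The lumen and the sieve plate act in series: `R = R_L + R_P`. The plate
#' term is computed by the chosen estimator:
#' \describe{
#'   \item{`"eq10"`}{parallel sum over explicit pore radii
#'     ([plate_resistance_discrete()]); requires a discrete [plate_spec()].}
#'   \item{`"eq11"`}{pore-size-distribution integral
#'     ([plate_resistance_distributional()]); requires a distributional
#'     [plate_spec()].}
#'   \item{`"mullendore"`}{Poiseuille-only legacy estimator (either mode).}
#'   \item{`"thompson_holbrook"`}{mean-radius legacy estimator (either mode;
#'     in discrete mode the arithmetic mean of the supplied radii is used).}
#' }
#'
#' @param tube A [tube_geometry()].
#' @param plate A [plate_spec()].
#' @param fluid A [fluid_properties()].
#' @param method Plate estimator, see Details.
#' @return Total resistance in Pa s/m^3.
#' @examples
#' tube <- tube_geometry(100e-6, 10e-6)
#' plate <- plate_spec(1e-6, mean_radius = 1e-6, sd_radius = 0.25e-6,
#'                     n_pores = 100)
#' total_resistance(tube, plate, method = "eq11")
#' @export
total_resistance <- function(tube, plate, fluid = fluid_properties(),
                             method = c("eq10", "eq11", "mullendore",
                                        "thompson_holbrook")) {
  stopifnot(inherits(tube, "tube_geometry"), inherits(plate, "plate_spec"))
  method <- match.arg(method)
  lumen_resistance(tube, fluid) + plate_term(plate, fluid, method)
}

# dispatch of the plate estimator over plate_spec modes
plate_term <- function(plate, fluid, method) {
  switch(method,
    eq10 = {
      if (plate$mode != "discrete")
        stop("method 'eq10' needs explicit pore radii (discrete plate_spec)",
             call. = FALSE)
      plate_resistance_discrete(plate$pore_radii, plate$thickness, fluid)
    },
    eq11 = {
      if (plate$mode != "distributional")
        stop("method 'eq11' needs a distributional plate_spec ",
             "(mean_radius, sd_radius, n_pores)", call. = FALSE)
      plate_resistance_distributional(plate$mean_radius, plate$sd_radius,
                                      plate$n_pores, plate$thickness, fluid)
    },
    mullendore = {
      if (plate$mode == "discrete")
        plate_resistance_mullendore(pore_radii = plate$pore_radii,
                                    thickness = plate$thickness, fluid = fluid)
      else
        plate_resistance_mullendore(mean_radius = plate$mean_radius,
                                    sd_radius = plate$sd_radius,
                                    n_pores = plate$n_pores,
                                    thickness = plate$thickness, fluid = fluid)
    },
    thompson_holbrook = {
      m <- plate_moments(plate)
      plate_resistance_thompson_holbrook(m$mean, plate$n_pores,
                                         plate$thickness, fluid)
    })
}

#' Dimensionless groups of the sieve-tube/sieve-plate geometry
#'
#' Returns the five groups that control the problem: the pore-plate aspect
#' ratio `alpha = lp / mean_radius`, the relative pore spread
#' `beta = sd_radius / mean_radius`, the cell aspect ratio
#' `gamma = l / r`, the pore-cell ratio `delta = mean_radius / r`, and the
#' covering fraction `phi`. `phi` is computed from explicit radii as
#' \eqn{\sum_i r_{p,i}^2 / r^2} when the plate is discrete, and as its
#' expectation \eqn{N (\bar{r}_p^2 + \sigma_p^2)/r^2} in distributional mode.
#'
#' @param tube A [tube_geometry()].
#' @param plate A [plate_spec()].
#' @return A list of class `"dimensionless_groups"` with elements `alpha`,
#'   `beta`, `gamma`, `delta`, `phi`.
#' @examples
#' dimensionless_groups(tube_geometry(100e-6, 10e-6),
#'                      plate_spec(0.5e-6, mean_radius = 1e-6,
#'                                 sd_radius = 0.25e-6, n_pores = 50))
#' @export
dimensionless_groups <- function(tube, plate) {
  stopifnot(inherits(tube, "tube_geometry"), inherits(plate, "plate_spec"))
  m <- plate_moments(plate)
  phi <- if (plate$mode == "discrete") {
    sum(plate$pore_radii^2) / tube$radius^2
  } else {
    plate$n_pores * (plate$mean_radius^2 + plate$sd_radius^2) / tube$radius^2
  }
  structure(list(alpha = plate$thickness / m$mean,
                 beta = m$sd / m$mean,
                 gamma = tube$length / tube$radius,
                 delta = m$mean / tube$radius,
                 phi = phi),
            class = "dimensionless_groups")
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat(sprintf(
    "alpha = %.4g, beta = %.4g, gamma = %.4g, delta = %.4g, phi = %.4g\n",
    x$alpha, x$beta, x$gamma, x$delta, x$phi))
  invisible(x)
}

#' Pore count implied by a covering fraction
#'
#' Anatomy tables often report the covering fraction `phi` rather than the
#' pore count. Inverting the expectation of the covering fraction of a
#' normal pore-radius law gives
#' `N = round(phi * r^2 / (mean_radius^2 + sd_radius^2))`.
#'
#' @param phi Covering fraction in (0, 1).
#' @param radius Tube radius in m.
#' @param mean_radius Mean pore radius in m.
#' @param sd_radius Pore-radius standard deviation in m.
#' @return Integer pore count (at least 1).
#' @examples
#' pore_count_from_phi(0.5, 10e-6, 1e-6, 0.25e-6)
#' @export
pore_count_from_phi <- function(phi, radius, mean_radius, sd_radius = 0) {
  stopifnot(phi > 0, phi < 1, radius > 0, mean_radius > 0, sd_radius >= 0)
  max(1L, as.integer(round(phi * radius^2 / (mean_radius^2 + sd_radius^2))))
}

#' Flow diagnostics for a sieve tube element
#'
#' Given a pressure drop `delta_p` or a mean lumen velocity `u` (exactly one),
#' computes the other via `u = delta_p / (A R)` with `A = pi r^2`, the mean
#' pore velocity `u_p = u / phi` (volume-flux conservation through the
#' covering fraction `phi`), and the Reynolds numbers
#' `Re_L = rho u r / eta` and `Re_P = rho u_p mean_radius / eta`. In the
#' phloem both are far below one, which is what justifies the creeping-flow
#' resistor model.
#'
#' @param tube A [tube_geometry()].
#' @param plate A [plate_spec()].
#' @param fluid A [fluid_properties()].
#' @param delta_p Pressure drop in Pa (give this or `u`).
#' @param u Mean lumen flow velocity in m/s (give this or `delta_p`).
#' @param method Plate estimator passed to [total_resistance()]; defaults to
#'   `"eq10"` for discrete plates and `"eq11"` otherwise.
#' @return A list of class `"flow_diagnostics"` with elements `u`, `u_pore`,
#'   `Re_lumen`, `Re_pore`, `delta_p`, `area`, `phi`, `resistance`.
#' @examples
#' tube <- tube_geometry(100e-6, 10e-6)
#' plate <- plate_spec(1e-6, mean_radius = 1e-6, sd_radius = 0.25e-6,
#'                     n_pores = 50)
#' flow_diagnostics(tube, plate, u = 280e-6)
#' @export
flow_diagnostics <- function(tube, plate, fluid = fluid_properties(),
                             delta_p = NULL, u = NULL, method = NULL) {
  stopifnot(inherits(tube, "tube_geometry"), inherits(plate, "plate_spec"))
  if (is.null(delta_p) == is.null(u))
    stop("supply exactly one of delta_p or u", call. = FALSE)
  if (is.null(method))
    method <- if (plate$mode == "discrete") "eq10" else "eq11"
  groups <- dimensionless_groups(tube, plate)
  if (groups$phi <= 0) stop("covering fraction phi must be positive",
                            call. = FALSE)
  A <- pi * tube$radius^2
  R <- total_resistance(tube, plate, fluid, method)
  if (is.null(u)) u <- delta_p / (A * R) else delta_p <- u * A * R
  u_pore <- u / groups$phi
  m <- plate_moments(plate)
  structure(list(u = u,
                 u_pore = u_pore,
                 Re_lumen = fluid$density * u * tube$radius / fluid$viscosity,
                 Re_pore = fluid$density * u_pore * m$mean / fluid$viscosity,
                 delta_p = delta_p, area = A, phi = groups$phi,
                 resistance = R),
            class = "flow_diagnostics")
}

#' @export
print.flow_diagnostics <- function(x, ...) {
  cat(sprintf("u = %.4g um/s, u_pore = %.4g um/s (phi = %.3g)\n",
              x$u * 1e6, x$u_pore * 1e6, x$phi))
  cat(sprintf("Re_lumen = %.3g, Re_pore = %.3g\n", x$Re_lumen, x$Re_pore))
  cat(sprintf("delta_p = %.4g Pa over R = %.4g Pa s/m^3\n",
              x$delta_p, x$resistance))
  invisible(x)
}
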