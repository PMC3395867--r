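#' Axisymmetric single-pore geometry
#'
#' Computational domain for the creeping-flow validation solver: a
#' cylindrical tube of radius `radius` with a plate of thickness `thickness`
#' spanning the cross-section except for a single coaxial circular pore of
#' radius `pore_radius`. The lumen extends `lumen_length` upstream and
#' downstream of the plate; the default (and minimum) of four tube radii is
#' conservative, since the flow disturbance of a pore decays within about one
#' pore diameter.
#'
#' @param radius Tube radius in m.
#' @param pore_radius Pore radius in m, `<= radius`. `pore_radius == radius`
#'   means no plate (open tube).
#' @param thickness Plate thickness in m (`0` allowed only for the open
#'   tube; the discrete plate is always at least one grid cell thick).
#' @param lumen_length Upstream and downstream lumen length in m,
#'   `>= 4 * radius`.
#' @return An object of class `"axisym_geometry"`.
#' @examples
#' axisym_geometry(10e-6, 1e-6, 2e-6)
#' @export
axisym_geometry <- function(radius, pore_radius, thickness,
                            lumen_length = 4 * radius) {
  stopifnot(radius > 0, pore_radius > 0, thickness >= 0, lumen_length > 0)
  if (pore_radius > radius)
    stop("pore_radius must not exceed the tube radius", call. = FALSE)
  if (lumen_length < 4 * radius)
    stop("lumen_length must be at least 4 tube radii so that the far field ",
         "is fully developed", call. = FALSE)
  structure(list(radius = radius, pore_radius = pore_radius,
                 thickness = thickness, lumen_length = lumen_length),
            class = "axisym_geometry")
}

#' @export
print.axisym_geometry <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric domain: r = %g um, rp = %g um, lp = %g um, lumen 2 x %g um\n",
    x$radius * 1e6, x$pore_radius * 1e6, x$thickness * 1e6,
    x$lumen_length * 1e6))
  invisible(x)
}

# node type codes for the grid classification
.ST_FLUID <- 0L; .ST_AXIS <- 1L; .ST_WALL <- 2L; .ST_INOUT <- 3L
.ST_SOLID <- 4L

#' Steady Stokes flow through a single coaxial sieve pore
#'
#' Solves the axisymmetric Stokes equations (creeping flow,
#' `grad p = eta laplace u`, `div u = 0`) in the geometry of
#' [axisym_geometry()] with an imposed volume flux, using the Stokes
#' streamfunction formulation `E^4 psi = 0` on a uniform grid:
#' second-order centered differences for the operator
#' `E^2 = d_zz + d_ss - (1/s) d_s`, applied twice, with no-slip walls
#' (`psi` constant and mirror ghosts for `d psi/d n = 0`), symmetry on the
#' axis, and fully developed Poiseuille profiles imposed at inlet and
#' outlet. The sparse linear system is solved directly.
#'
#' The grid spacing is `pore_radius / resolution`; the tube radius, plate
#' thickness and lumen length are snapped to whole cells (the snapped values
#' are reported in the returned object). The hydraulic resistance is
#' extracted through the dissipation identity `dp * Q = 2 eta int(e:e) dV`,
#' which is exact for Stokes flow between fully developed end sections and,
#' being an integral of the solution, is far less sensitive to pointwise
#' discretization error than differentiated pressure profiles; the axial
#' pressure profile is also returned as a diagnostic. See
#' [numeric_resistance()] for the decomposition and
#' [richardson_resistance()] for grid-converged estimates.
#'
#' @param geometry An [axisym_geometry()].
#' @param resolution Grid cells across the pore radius (minimum 16 for
#'   production use; smaller values are refused).
#' @param flux Imposed volume flux in m^3/s.
#' @param fluid A [fluid_properties()]; only the viscosity enters.
#' @param symmetric Exploit the mirror symmetry of the domain about the
#'   plate mid-plane, solving half the system (default). Set `FALSE` to
#'   solve the full domain, e.g. to verify the up/downstream symmetry of
#'   the computed fields.
#' @return An object of class `"stokes_solution"`: grid vectors `z`, `s`
#'   (m), matrices `psi`, `u_z` (streamfunction, axial velocity), the axial
#'   pressure profile `p_axis`, the flux `Q`, the snapped geometry, and the
#'   resistance decomposition of [numeric_resistance()] (`R_total`,
#'   `R_plate`, `R_excess`), plus the mass-conservation diagnostic
#'   `flux_variation`.
#' @examples
#' \donttest{
#' geo <- axisym_geometry(10e-6, 2.5e-6, 5e-6)
#' sol <- solve_single_pore(geo, resolution = 16)
#' sol$R_total
#' }
#' @export
solve_single_pore <- function(geometry, resolution = 16, flux = 1e-15,
                              fluid = fluid_properties(), symmetric = TRUE) {
  stopifnot(inherits(geometry, "axisym_geometry"))
  if (resolution < 16)
    stop("resolution must give at least 16 cells across the pore radius",
         call. = FALSE)
  if (flux <= 0) stop("flux must be positive", call. = FALSE)

  r <- geometry$radius
  open_tube <- geometry$pore_radius >= r
  # non-dimensional grid: lengths in units of r, viscosity 1, flux 1
  delta <- geometry$pore_radius / r
  h <- delta / resolution
  J <- as.integer(round(1 / h)); h <- 1 / J      # snap tube radius
  Jp <- if (open_tube) J else as.integer(round(delta / h))
  nL <- as.integer(round(geometry$lumen_length / r / h))
  mP <- if (open_tube) 0L else max(1L, as.integer(round(
    geometry$thickness / r / h)))
  if (symmetric && mP %% 2L == 1L) mP <- mP + 1L  # mirror plane on gridline
  i1 <- nL; i2 <- nL + mP                        # plate face gridline indices
  I <- 2L * nL + mP
  # the domain is mirror-symmetric about the plate mid-plane; when
  # `symmetric`, unknowns beyond the mid-plane are folded onto their mirror
  # image, halving the linear system
  mid <- if (symmetric) nL + mP %/% 2L else I
  mi <- function(i) ifelse(i > mid, 2L * mid - i, i)
  snapped <- list(radius = r, pore_radius = Jp * h * r,
                  thickness = mP * h * r, lumen_length = nL * h * r)

  psiw <- 1 / (2 * pi)                           # psi on walls for Q = 1
  # node types: rows i = 0..I (z), cols j = 0..J (s)
  type <- matrix(.ST_FLUID, I + 1L, J + 1L)
  type[1L, ] <- .ST_INOUT
  type[I + 1L, ] <- .ST_INOUT
  type[, J + 1L] <- .ST_WALL
  if (!open_tube) {
    for (i in i1:i2) {
      for (j in Jp:J) {
        type[i + 1L, j + 1L] <-
          if (i == i1 || i == i2 || j == Jp) .ST_WALL else .ST_SOLID
      }
    }
  }
  type[, 1L] <- .ST_AXIS

  s <- (0:J) * h
  pois <- psiw * (2 * s^2 - s^4)                 # Poiseuille streamfunction
  known <- matrix(NA_real_, I + 1L, J + 1L)
  known[type == .ST_WALL] <- psiw
  known[type == .ST_AXIS] <- 0
  inout_rows <- which(type == .ST_INOUT, arr.ind = TRUE)
  known[inout_rows] <- pois[inout_rows[, 2L]]

  in_half <- row(type) - 1L <= mid
  unk <- matrix(0L, I + 1L, J + 1L)
  fluid_nodes <- which(type == .ST_FLUID & in_half, arr.ind = TRUE)
  unk[fluid_nodes] <- seq_len(nrow(fluid_nodes))
  n_unk <- nrow(fluid_nodes)
  chi <- matrix(0L, I + 1L, J + 1L)
  chi_nodes <- which((type == .ST_FLUID | type == .ST_WALL |
                        type == .ST_INOUT) & in_half, arr.ind = TRUE)
  chi[chi_nodes] <- seq_len(nrow(chi_nodes))
  n_chi <- nrow(chi_nodes)
  if (mid < I) {                                # fold the mirrored half
    for (i in (mid + 1L):I) {
      unk[i + 1L, ] <- unk[2L * mid - i + 1L, ]
      chi[i + 1L, ] <- chi[2L * mid - i + 1L, ]
    }
  }

  # ---- chi = E^2 psi at all fluid/wall/inout nodes (axis: chi = 0) ----
  # triplets into Cu (coefficients on unknown psi) and c0 (known part)
  ti <- vector("list", 16L); tj <- vector("list", 16L); tx <- vector("list", 16L)
  nt <- 0L
  c0 <- numeric(n_chi)
  add_entry <- function(row, i, j, coef) {
    # reference psi at node (i, j) (0-based indices), known or unknown
    u <- unk[i + 1L, j + 1L]
    if (u > 0L) {
      nt <<- nt + 1L
      ti[[nt]] <<- row; tj[[nt]] <<- u; tx[[nt]] <<- coef
    } else {
      c0[row] <<- c0[row] + coef * known[i + 1L, j + 1L]
    }
  }

  # vectorized block: chi at fluid nodes (all four neighbours exist and are
  # not solid)
  fi <- fluid_nodes[, 1L] - 1L; fj <- fluid_nodes[, 2L] - 1L
  sF <- fj * h
  rows <- chi[fluid_nodes]
  cC <- -4 / h^2
  cE <- rep(1 / h^2, n_unk); cW <- cE
  cN <- 1 / h^2 - 1 / (2 * h * sF)
  cS <- 1 / h^2 + 1 / (2 * h * sF)
  push_vec <- function(row, i, j, coef) {
    u <- unk[cbind(i + 1L, j + 1L)]
    kn <- known[cbind(i + 1L, j + 1L)]
    isu <- u > 0L
    if (any(isu)) {
      nt <<- nt + 1L
      ti[[nt]] <<- row[isu]; tj[[nt]] <<- u[isu]; tx[[nt]] <<- coef[isu]
    }
    if (any(!isu)) {
      idx <- row[!isu]
      add <- coef[!isu] * kn[!isu]
      agg <- rowsum(add, idx)
      c0[as.integer(rownames(agg))] <<- c0[as.integer(rownames(agg))] + agg[, 1L]
    }
  }
  push_vec(rows, fi, fj, rep(cC, n_unk))
  push_vec(rows, fi + 1L, fj, cE)
  push_vec(rows, fi - 1L, fj, cW)
  push_vec(rows, fi, fj + 1L, cN)
  push_vec(rows, fi, fj - 1L, cS)

  # boundary chi rows (wall and inlet/outlet nodes): neighbours outside the
  # grid or inside the solid are mirrored across the node (d psi/d n = 0)
  bn <- which((type == .ST_WALL | type == .ST_INOUT) & in_half,
              arr.ind = TRUE)
  for (kk in seq_len(nrow(bn))) {
    i <- bn[kk, 1L] - 1L; j <- bn[kk, 2L] - 1L
    row <- chi[i + 1L, j + 1L]
    sj <- j * h
    coefs <- c(E = 1 / h^2, W = 1 / h^2,
               N = 1 / h^2 - 1 / (2 * h * sj),
               S = 1 / h^2 + 1 / (2 * h * sj))
    add_entry(row, i, j, -4 / h^2)
    di <- c(1L, -1L, 0L, 0L); dj <- c(0L, 0L, 1L, -1L)
    for (d in 1:4) {
      ni <- i + di[d]; nj <- j + dj[d]
      bad <- ni < 0L || ni > I || nj > J ||
        type[ni + 1L, nj + 1L] == .ST_SOLID
      if (bad) { ni <- i - di[d]; nj <- j - dj[d] }   # mirror ghost
      add_entry(row, ni, nj, coefs[d])
    }
  }
  Cu <- Matrix::sparseMatrix(i = unlist(ti[seq_len(nt)]),
                             j = unlist(tj[seq_len(nt)]),
                             x = unlist(tx[seq_len(nt)]),
                             dims = c(n_chi, n_unk))

  # ---- outer operator: E^2 chi = 0 at every fluid node ----
  oi <- vector("list", 5L); oj <- vector("list", 5L); ox <- vector("list", 5L)
  grab <- function(i, j) chi[cbind(i + 1L, j + 1L)]   # 0 when chi fixed at 0
  neigh <- list(c(0L, 0L), c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  ncoef <- list(rep(cC, n_unk), cE, cW, cN, cS)
  for (d in 1:5) {
    cols <- grab(fi + neigh[[d]][1L], fj + neigh[[d]][2L])
    keep <- cols > 0L
    oi[[d]] <- seq_len(n_unk)[keep]
    oj[[d]] <- cols[keep]
    ox[[d]] <- ncoef[[d]][keep]
  }
  O <- Matrix::sparseMatrix(i = unlist(oi), j = unlist(oj), x = unlist(ox),
                            dims = c(n_unk, n_chi))

  A <- O %*% Cu
  bq <- as.numeric(-O %*% c0)
  x <- tryCatch(
    as.numeric(Matrix::solve(A, bq)),
    error = function(e) stop("sparse Stokes solve failed: ",
                             conditionMessage(e), call. = FALSE))
  if (any(!is.finite(x)))
    stop("sparse Stokes solve returned non-finite values", call. = FALSE)

  psi <- known
  fluid_all <- which(type == .ST_FLUID, arr.ind = TRUE)
  psi[fluid_all] <- x[unk[fluid_all]]
  psi[type == .ST_SOLID] <- NA_real_

  # ---- fields and resistance (still non-dimensional, Q = 1) ----
  z <- (0:I) * h
  u_z <- matrix(NA_real_, I + 1L, J + 1L)
  for (j in 1:(J - 1L)) {
    u_z[, j + 1L] <- (psi[, j + 2L] - psi[, j]) / (2 * h * s[j + 1L])
  }
  # near the axis u_z(s) ~ u0 + c2 s^2 + c4 s^4, i.e.
  # psi(s) = u0 s^2/2 + c2 s^4/4 + c4 s^6/6; fit (u0, c2) through the first
  # three off-axis nodes (exact for fully developed flow)
  xs <- (1:3)^2 * h^2
  V <- cbind(xs / 2, xs^2 / 4, xs^3 / 6)
  coefs <- psi[, 2:4] %*% t(solve(V))
  u0 <- coefs[, 1L]; c2 <- coefs[, 2L]
  u_z[, 1L] <- u0
  u_z[type == .ST_WALL] <- 0
  u_z[type == .ST_SOLID] <- NA_real_

  # axial pressure gradient on the axis: dp/dz = u0'' + 4 c2 (the axis limit
  # of the axisymmetric Laplacian contributes 2 c2 from u_ss and 2 c2 from
  # u_s/s)
  d2u0 <- c(NA_real_, diff(diff(u0)) / h^2, NA_real_)
  d2u0[1L] <- d2u0[2L]; d2u0[I + 1L] <- d2u0[I]
  dpdz <- d2u0 + 4 * c2
  p_axis <- c(0, cumsum((dpdz[-1L] + dpdz[-(I + 1L)]) / 2 * h))

  # radial velocity u_s = -(1/s) d psi / d z (zero on axis, walls, in/out)
  u_s <- matrix(0, I + 1L, J + 1L)
  if (I >= 2L) {
    for (j in 1:J) {
      u_s[2:I, j + 1L] <- -(psi[3:(I + 1L), j + 1L] -
                              psi[1:(I - 1L), j + 1L]) / (2 * h * s[j + 1L])
    }
  }
  u_s[type == .ST_WALL] <- 0
  u_s[type == .ST_SOLID] <- NA_real_

  # total resistance from the dissipation identity dp * Q = 2 eta int(e:e):
  # strain rates at cell centers from the corner velocities; cells touching
  # the solid plate interior are excluded (the fluid region is exactly tiled
  # because all walls lie on gridlines)
  iA <- 1:I; jA <- 1:J
  corner <- function(M, di, dj) M[iA + di, jA + dj, drop = FALSE]
  solid <- type == .ST_SOLID
  bad <- corner(solid, 0L, 0L) | corner(solid, 1L, 0L) |
    corner(solid, 0L, 1L) | corner(solid, 1L, 1L)
  duz_dz <- (corner(u_z, 1L, 0L) + corner(u_z, 1L, 1L) -
               corner(u_z, 0L, 0L) - corner(u_z, 0L, 1L)) / (2 * h)
  duz_ds <- (corner(u_z, 0L, 1L) + corner(u_z, 1L, 1L) -
               corner(u_z, 0L, 0L) - corner(u_z, 1L, 0L)) / (2 * h)
  dus_ds <- (corner(u_s, 0L, 1L) + corner(u_s, 1L, 1L) -
               corner(u_s, 0L, 0L) - corner(u_s, 1L, 0L)) / (2 * h)
  dus_dz <- (corner(u_s, 1L, 0L) + corner(u_s, 1L, 1L) -
               corner(u_s, 0L, 0L) - corner(u_s, 0L, 1L)) / (2 * h)
  us_c <- (corner(u_s, 0L, 0L) + corner(u_s, 1L, 0L) +
             corner(u_s, 0L, 1L) + corner(u_s, 1L, 1L)) / 4
  s_c <- matrix((jA - 0.5) * h, I, J, byrow = TRUE)
  ee <- duz_dz^2 + dus_ds^2 + (us_c / s_c)^2 + 0.5 * (duz_ds + dus_dz)^2
  ee[bad] <- 0
  dissipation <- 2 * sum(ee * 2 * pi * s_c * h^2, na.rm = TRUE)

  res <- stokes_decompose(dissipation, nL, h, mP, Jp, open_tube)

  # lumen-section flux (mass conservation diagnostic)
  lum_i <- c(seq(2L, i1), seq(i2 + 2L, I))      # strictly inside the lumen
  Qsec <- vapply(lum_i, function(ii) {
    f <- 2 * pi * s * u_z[ii, ]
    sum((f[-1L] + f[-(J + 1L)]) / 2 * h)
  }, numeric(1))
  flux_variation <- max(abs(Qsec - 1))

  scale_R <- fluid$viscosity / r^3              # back to SI
  structure(list(z = z * r, s = s * r,
                 psi = psi * flux, u_z = u_z * flux / r^2,
                 u_s = u_s * flux / r^2,
                 p_axis = p_axis * flux * scale_R,
                 dpdz_axis = dpdz * flux * scale_R / r,
                 Q = flux, h = h * r,
                 geometry = snapped, resolution = resolution,
                 type = type,
                 R_total = res$total * scale_R,
                 R_plate = res$plate * scale_R,
                 R_excess = res$excess * scale_R,
                 R_lumen_theory = res$lumen_theory * scale_R,
                 flux_variation = flux_variation),
            class = "stokes_solution")
}

# resistance decomposition from the dissipation integral
# (non-dimensional units, Q = 1, eta = 1, r = 1): R = dissipation / Q^2
stokes_decompose <- function(dissipation, nL, h, mP, Jp, open_tube) {
  L <- nL * h
  lumen_theory <- 8 * (2 * L) / pi              # radius 1, eta 1
  total <- dissipation
  plate <- if (open_tube) total - 8 * (2 * L + mP * h) / pi
           else total - lumen_theory
  pore_pois <- if (open_tube) 0 else 8 * (mP * h) / (pi * (Jp * h)^4)
  list(total = total, plate = plate, excess = plate - pore_pois,
       lumen_theory = lumen_theory)
}

#' @export
print.stokes_solution <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(
    "Stokes solution: r = %g um, rp = %g um, lp = %g um (h = %g um)\n",
    g$radius * 1e6, g$pore_radius * 1e6, g$thickness * 1e6, x$h * 1e6))
  cat(sprintf("  R_total = %.4g Pa s/m^3 (plate %.4g, excess %.4g)\n",
              x$R_total, x$R_plate, x$R_excess))
  cat(sprintf("  cross-section flux variation: %.3g%%\n",
              100 * x$flux_variation))
  invisible(x)
}

#' @export
plot.stokes_solution <- function(x, ...) {
  graphics::image(x$z * 1e6, x$s * 1e6, abs(x$u_z),
                  xlab = "z (um)", ylab = "s (um)",
                  main = "|u_z| (m/s)", useRaster = TRUE, ...)
  invisible(x)
}

#' Resistance decomposition of a Stokes solution
#'
#' Returns the hydraulic resistance of a [solve_single_pore()] solution,
#' decomposed into the analytic Hagen-Poiseuille contribution of the lumen
#' segments, the plate contribution (total minus lumen), and the
#' Sampson-like excess (plate contribution minus the Poiseuille resistance
#' of the pore channel itself). The total is the far-field axial pressure
#' drop, obtained by linear extrapolation of the fully developed upstream
#' and downstream pressure profiles to the domain ends, divided by the flux.
#'
#' @param solution A `"stokes_solution"`.
#' @return A list with elements `total`, `lumen_theory`, `plate`, `excess`
#'   (Pa s/m^3).
#' @export
numeric_resistance <- function(solution) {
  stopifnot(inherits(solution, "stokes_solution"))
  list(total = solution$R_total,
       lumen_theory = solution$R_lumen_theory,
       plate = solution$R_plate,
       excess = solution$R_excess)
}

#' Grid-converged resistance by Richardson extrapolation
#'
#' Solves the same geometry on a sequence of grids and extrapolates the
#' resistance to zero grid spacing. The pore-rim corner of the plate makes
#' the resistance converge at a reduced, geometry-dependent rate, so the
#' convergence order `p` is estimated from the last three grids (Aitken's
#' procedure) and the power-law `R(h) = R_inf + C h^p` is extrapolated from
#' the two finest. A non-monotone sequence (no resolvable power law) raises
#' a convergence warning and returns the finest-grid value unextrapolated.
#'
#' @param geometry An [axisym_geometry()].
#' @param resolutions Increasing vector of at least three resolutions
#'   (cells across the pore radius).
#' @param what Which resistance component to extrapolate: the Sampson-like
#'   `"excess"`, the `"plate"` contribution, or the `"total"`.
#' @param fluid A [fluid_properties()].
#' @param symmetric Passed to [solve_single_pore()].
#' @return A list with `value` (extrapolated resistance, Pa s/m^3),
#'   `values` (per-grid), `resolutions`, `order` (estimated `p`, `NA` if
#'   extrapolation was abandoned) and `extrapolated`.
#' @examples
#' \donttest{
#' geo <- axisym_geometry(10e-6, 2.5e-6, 1.25e-6)
#' richardson_resistance(geo, resolutions = c(16, 20, 24), what = "excess")
#' }
#' @export
richardson_resistance <- function(geometry, resolutions = c(16, 20, 24),
                                  what = c("excess", "plate", "total"),
                                  fluid = fluid_properties(),
                                  symmetric = TRUE) {
  what <- match.arg(what)
  stopifnot(length(resolutions) >= 3, !is.unsorted(resolutions))
  field <- switch(what, excess = "R_excess", plate = "R_plate",
                  total = "R_total")
  vals <- vapply(resolutions, function(res) {
    solve_single_pore(geometry, resolution = res, fluid = fluid,
                      symmetric = symmetric)[[field]]
  }, numeric(1))
  n <- length(vals)
  R1 <- vals[n - 2L]; R2 <- vals[n - 1L]; R3 <- vals[n]
  h1 <- 1 / resolutions[n - 2L]; h2 <- 1 / resolutions[n - 1L]
  h3 <- 1 / resolutions[n]
  ratio <- (R1 - R2) / (R2 - R3)
  p <- NA_real_
  if (is.finite(ratio) && ratio > 1) {
    f <- function(p) (h1^p - h2^p) / (h2^p - h3^p) - ratio
    p <- tryCatch(stats::uniroot(f, c(0.3, 4))$root, error = function(e) NA_real_)
  }
  if (is.na(p)) {
    warning("non-monotone grid-convergence sequence; returning the ",
            "finest-grid value without extrapolation", call. = FALSE)
    return(list(value = R3, values = vals, resolutions = resolutions,
                order = NA_real_, extrapolated = FALSE))
  }
  value <- R3 + (R3 - R2) / ((h2 / h3)^p - 1)
  list(value = value, values = vals, resolutions = resolutions,
       order = p, extrapolated = TRUE)
}

#' Validate the resistor formulas against the Stokes solver
#'
#' Runs the canonical single-pore validation cases and compares the numeric
#' resistance with the closed forms: an open tube against Hagen-Poiseuille;
#' the thickness-independent end-correction (excess) of a pore of length
#' half its radius against the Sampson orifice term `3 eta / rp^3`; and the
#' plate contribution of a pore of length `2 * pore_radius` (the worst case
#' for the series approximation) against the combined pore formula. The
#' plate cases use Richardson extrapolation over `resolutions`
#' ([richardson_resistance()]) because of the reduced convergence rate at
#' the pore rim; the open tube is smooth and uses a single fine grid.
#' Failures are reported as rows, never raised.
#'
#' @param radius Tube radius in m.
#' @param delta Pore-to-tube radius ratio for the plate cases.
#' @param resolutions Grid sequence (cells across the pore radius) for the
#'   plate cases.
#' @param tolerances Named relative tolerances for cases `poiseuille`,
#'   `sampson`, `eq5`.
#' @param fluid A [fluid_properties()].
#' @return Data frame with one row per case: `case`, `R_num`, `R_ref`,
#'   `rel_err`, `tol`, `pass`.
#' @examples
#' \donttest{
#' validate_stokes(delta = 0.25, resolutions = c(16, 20, 24))
#' }
#' @export
validate_stokes <- function(radius = 10e-6, delta = 0.1,
                            resolutions = c(16, 20, 24),
                            tolerances = c(poiseuille = 0.02, sampson = 0.05,
                                           eq5 = 0.05),
                            fluid = fluid_properties()) {
  rp <- delta * radius
  eta <- fluid$viscosity
  out <- data.frame(case = c("poiseuille", "sampson", "eq5"),
                    R_num = NA_real_, R_ref = NA_real_, rel_err = NA_real_,
                    tol = as.numeric(tolerances[c("poiseuille", "sampson",
                                                  "eq5")]),
                    pass = NA, stringsAsFactors = FALSE)

  sol <- solve_single_pore(axisym_geometry(radius, radius, 0),
                           resolution = 2 * max(resolutions), fluid = fluid)
  out$R_num[1] <- sol$R_total
  out$R_ref[1] <- 8 * eta * (2 * sol$geometry$lumen_length) / (pi * radius^4)

  geo_s <- axisym_geometry(radius, rp, rp / 2)
  rs <- richardson_resistance(geo_s, resolutions, "excess", fluid)
  out$R_num[2] <- rs$value
  out$R_ref[2] <- 3 * eta / rp^3

  geo_5 <- axisym_geometry(radius, rp, 2 * rp)
  r5 <- richardson_resistance(geo_5, resolutions, "plate", fluid)
  out$R_num[3] <- r5$value
  out$R_ref[3] <- single_pore_resistance(rp, 2 * rp, fluid)

  out$rel_err <- abs(out$R_num - out$R_ref) / out$R_ref
  out$pass <- out$rel_err <= out$tol
  out
}
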