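# moderate-cost geometry for the unit tests: pore a quarter of the tube
# radius, 16 cells across the pore radius
stokes_geo <- function(lp_factor = 2) {
  axisym_geometry(10e-6, 2.5e-6, lp_factor * 2.5e-6)
}

test_that("geometry preconditions are enforced", {
  expect_error(axisym_geometry(10e-6, 11e-6, 1e-6), "exceed")
  expect_error(axisym_geometry(10e-6, 1e-6, 1e-6, lumen_length = 10e-6),
               "4 tube radii")
  expect_error(solve_single_pore(stokes_geo(), resolution = 8), "16 cells")
})

test_that("half-domain and full-domain solves agree", {
  a <- solve_single_pore(stokes_geo(), 16, symmetric = FALSE)
  b <- solve_single_pore(stokes_geo(), 16, symmetric = TRUE)
  expect_equal(b$R_total, a$R_total, tolerance = 1e-10)
  expect_equal(b$psi, a$psi, tolerance = 1e-9)
})

test_that("creeping flow is up/downstream symmetric", {
  sol <- solve_single_pore(stokes_geo(), 16, symmetric = FALSE)
  n <- length(sol$z)
  speed <- sqrt(sol$u_z^2 + sol$u_s^2)
  mirrored <- speed[n:1, ]
  scale <- max(speed, na.rm = TRUE)
  expect_lt(max(abs(speed - mirrored), na.rm = TRUE) / scale, 1e-8)
})

test_that("the solve is linear in the imposed flux", {
  s1 <- solve_single_pore(stokes_geo(), 16, flux = 1e-15)
  s3 <- solve_single_pore(stokes_geo(), 16, flux = 3e-15)
  expect_equal(s3$R_total, s1$R_total, tolerance = 1e-6)
  expect_equal(s3$p_axis, 3 * s1$p_axis, tolerance = 1e-6)
  expect_lt(max(abs(s3$u_z - 3 * s1$u_z), na.rm = TRUE),
            1e-12 * max(abs(s1$u_z), na.rm = TRUE))
})

test_that("mass is conserved across lumen sections", {
  sol <- solve_single_pore(stokes_geo(), 16)
  expect_lt(sol$flux_variation, 0.005)
})

test_that("an open tube reproduces Poiseuille flow", {
  sol <- solve_single_pore(axisym_geometry(10e-6, 10e-6, 0), resolution = 16)
  ref <- 8 * sap$viscosity * 2 * sol$geometry$lumen_length /
    (pi * (10e-6)^4)
  expect_equal(sol$R_total, ref, tolerance = 0.02)
  # no plate: the plate contribution vanishes within tolerance
  dec <- numeric_resistance(sol)
  expect_lt(abs(dec$plate) / dec$total, 0.02)
  # parabolic centerline velocity
  u_centre <- 2 * sol$Q / (pi * (10e-6)^2)
  expect_equal(max(sol$u_z[, 1]), u_centre, tolerance = 0.01)
})

test_that("the pore disturbance is confined to the plate neighbourhood", {
  # the centerline jet of a single pore relaxes on the slowest tube
  # eigenmode scale (~1.5 tube radii); far from the plate the profile is
  # indistinguishable from Poiseuille
  sol <- solve_single_pore(stokes_geo(), 16)
  r <- sol$geometry$radius
  u_centre <- 2 * sol$Q / (pi * r^2)
  far <- sol$z <= sol$geometry$lumen_length - 2 * r
  dev <- abs(sol$u_z[far, 1] - u_centre) / u_centre
  expect_lt(max(dev), 0.05)
  # while within one pore diameter of the face the flow is strongly
  # disturbed (the jet accelerates toward the pore)
  near <- sol$z >= sol$geometry$lumen_length - 2 * sol$geometry$pore_radius &
    sol$z <= sol$geometry$lumen_length
  expect_gt(max(abs(sol$u_z[near, 1] - u_centre) / u_centre), 0.5)
})

test_that("grid refinement converges and extrapolates monotonically", {
  rr <- richardson_resistance(stokes_geo(), resolutions = c(16, 20, 24),
                              what = "plate")
  expect_true(rr$extrapolated)
  expect_true(all(diff(rr$values) > 0))           # monotone toward the limit
  expect_gt(rr$order, 0.3)
  expect_lt(rr$order, 4)
  # the extrapolation continues the monotone sequence and stays a modest
  # correction on the finest grid
  expect_gt(rr$value, rr$values[3])
  expect_lt(abs(rr$value - rr$values[3]) / rr$values[3], 0.15)
})

test_that("validation reports failures as rows instead of raising", {
  rep <- validate_stokes(delta = 0.25, resolutions = c(16, 20, 24),
                         tolerances = c(poiseuille = 1e-4, sampson = 1e-5,
                                        eq5 = 1e-5))
  expect_s3_class(rep, "data.frame")
  expect_equal(rep$case, c("poiseuille", "sampson", "eq5"))
  expect_false(any(rep$pass))
  expect_true(all(is.finite(rep$rel_err)))
})
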