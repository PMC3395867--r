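test_that("lumen resistance matches Hagen-Poiseuille and the blockage law", {
  # constants chosen so 8 eta l / (pi r^4) = 1
  unit <- fluid_properties(viscosity = pi / 8)
  expect_equal(lumen_resistance(tube_geometry(1, 1), unit), 1)

  # hand evaluation: 8 * 2e-3 * 1e-4 / (pi * (1e-5)^4)
  expect_equal(lumen_resistance(tube_geometry(1e-4, 1e-5), sap),
               5.092958e13, tolerance = 1e-6)

  # r^-4 scaling of the blocked lumen
  open <- lumen_resistance(tube_geometry(1e-4, 1e-5), sap)
  blocked <- lumen_resistance(tube_geometry(1e-4, 1e-5, 0.8), sap)
  expect_equal(blocked / open, 1 / 0.8^4)

  expect_error(tube_geometry(-1, 1), "positive")
  expect_error(tube_geometry(1, 1, 1.2), "blockage")
})

test_that("single-pore resistance is Poiseuille plus Sampson", {
  one <- fluid_properties(viscosity = 1)
  # zero thickness: pure Sampson orifice 3 eta / r^3
  expect_equal(single_pore_resistance(1, 0, one), 3)

  # hand sum 5.093e15 + 6.0e15 at rp = lp = 1 um, eta = 2 mPa s
  expect_equal(single_pore_resistance(1e-6, 1e-6, sap),
               8 * 2e-3 * 1e-6 / (pi * 1e-24) + 3 * 2e-3 / 1e-18)
  expect_equal(single_pore_resistance(1e-6, 1e-6, sap), 1.1093e16,
               tolerance = 1e-4)

  # doubling the radius reduces resistance by a factor between 8 and 16
  ratio <- single_pore_resistance(1e-6, 1e-6, sap) /
    single_pore_resistance(2e-6, 1e-6, sap)
  expect_gt(ratio, 8)
  expect_lt(ratio, 16)

  expect_error(single_pore_resistance(-1e-6, 1e-6, sap), "positive")
})

test_that("discrete plate resistance is the parallel (harmonic) composition", {
  # 100 identical pores: R*/100
  expect_equal(plate_resistance_discrete(rep(1e-6, 100), 1e-6, sap),
               single_pore_resistance(1e-6, 1e-6, sap) / 100)
  # a single pore equals the per-pore formula
  expect_equal(plate_resistance_discrete(0.7e-6, 1e-6, sap),
               single_pore_resistance(0.7e-6, 1e-6, sap))
  # three-term brute-force sum
  radii <- c(0.8, 1.0, 1.2) * 1e-6
  byhand <- 1 / sum(1 / (8 * 2e-3 * 1e-6 / (pi * radii^4) +
                           3 * 2e-3 / radii^3))
  expect_equal(plate_resistance_discrete(radii, 1e-6, sap), byhand)
  # permutation invariance and monotone growth of conductance
  expect_equal(plate_resistance_discrete(rev(radii), 1e-6, sap), byhand)
  expect_lt(plate_resistance_discrete(c(radii, 0.5e-6), 1e-6, sap), byhand)
  expect_error(plate_resistance_discrete(numeric(0), 1e-6, sap), "non-empty")
})

test_that("legacy estimators behave as stated", {
  # Poiseuille-only estimator, single pore
  expect_equal(plate_resistance_mullendore(pore_radii = 1e-6,
                                           thickness = 1e-6, fluid = sap),
               5.092958e15, tolerance = 1e-6)
  # always below the full estimator (a positive series term is omitted)
  radii <- c(0.6, 1.0, 1.5) * 1e-6
  expect_lt(plate_resistance_mullendore(pore_radii = radii, thickness = 1e-6,
                                        fluid = sap),
            plate_resistance_discrete(radii, 1e-6, sap))
  # sd = 0 distributional equals N identical discrete pores
  expect_equal(
    plate_resistance_mullendore(mean_radius = 1e-6, sd_radius = 0,
                                n_pores = 50, thickness = 1e-6, fluid = sap),
    plate_resistance_mullendore(pore_radii = rep(1e-6, 50),
                                thickness = 1e-6, fluid = sap))

  # mean-radius estimator: N = 1 equals the per-pore formula; hand value
  expect_equal(plate_resistance_thompson_holbrook(1e-6, 1, 1e-6, sap),
               single_pore_resistance(1e-6, 1e-6, sap))
  expect_equal(plate_resistance_thompson_holbrook(1e-6, 100, 1e-6, sap),
               1.1093e14, tolerance = 1e-4)
  # harmonic-mean inequality: unequal radii with the same arithmetic mean
  # conduct better than the mean-radius approximation predicts
  spread <- c(0.5e-6, 1.5e-6)
  expect_gt(plate_resistance_thompson_holbrook(mean(spread), 2, 1e-6, sap),
            plate_resistance_discrete(spread, 1e-6, sap))
})

test_that("total resistance composes lumen and plate in series", {
  tube <- typical_tube()
  plate_d <- plate_spec(1e-6, pore_radii = rep(1e-6, 100))
  plate_n <- plate_spec(1e-6, mean_radius = 1e-6, sd_radius = 0,
                        n_pores = 100)
  # identical pores: explicit sum equals the sd = 0 distributional form
  expect_equal(total_resistance(tube, plate_d, sap, "eq10"),
               total_resistance(tube, plate_n, sap, "eq11"))
  # strictly greater than either addend
  R <- total_resistance(tube, plate_d, sap, "eq10")
  expect_gt(R, lumen_resistance(tube, sap))
  expect_gt(R, plate_resistance_discrete(plate_d$pore_radii, 1e-6, sap))
  # a vast, sparse plate term vanishes against the lumen
  huge <- plate_spec(1e-6, mean_radius = 5e-6, sd_radius = 0, n_pores = 1e6)
  expect_equal(total_resistance(tube, huge, sap, "eq11"),
               lumen_resistance(tube, sap), tolerance = 1e-4)
  # method/mode mismatches are configuration errors
  expect_error(total_resistance(tube, plate_n, sap, "eq10"), "explicit")
  expect_error(total_resistance(tube, plate_d, sap, "eq11"), "distributional")
})

test_that("dimensionless groups and phi inversion", {
  tube <- tube_geometry(100e-6, 10e-6)
  plate <- plate_spec(0.5e-6, pore_radii = rep(1e-6, 50))
  g <- dimensionless_groups(tube, plate)
  expect_equal(g$alpha, 0.5)
  expect_equal(g$beta, 0)
  expect_equal(g$gamma, 10)
  expect_equal(g$delta, 0.1)
  expect_equal(g$phi, 0.5)

  # distributional phi: expectation grows by N sd^2 / r^2
  p0 <- dimensionless_groups(tube, plate_spec(0.5e-6, mean_radius = 1e-6,
                                              sd_radius = 0, n_pores = 50))
  p1 <- dimensionless_groups(tube, plate_spec(0.5e-6, mean_radius = 1e-6,
                                              sd_radius = 0.25e-6,
                                              n_pores = 50))
  expect_equal(p0$phi, 50 * (1e-6)^2 / (10e-6)^2)
  expect_equal(p1$phi - p0$phi, 50 * (0.25e-6)^2 / (10e-6)^2)

  expect_equal(pore_count_from_phi(0.5, 10e-6, 1e-6, 0), 50L)
})

test_that("flow diagnostics reproduce the phloem Reynolds numbers", {
  tube <- tube_geometry(100e-6, 10e-6)
  plate <- plate_spec(1e-6, mean_radius = 1e-6, sd_radius = 0, n_pores = 50)
  d <- flow_diagnostics(tube, plate, sap, u = 280e-6)
  expect_equal(d$Re_lumen, 1.4e-3)
  expect_equal(d$phi, 0.5)
  expect_equal(d$u_pore, 2 * 280e-6)
  expect_equal(d$Re_pore, 2.8e-4)

  # u = dp / (A R) round trip
  d2 <- flow_diagnostics(tube, plate, sap, delta_p = d$delta_p)
  expect_equal(d2$u, 280e-6)

  expect_error(flow_diagnostics(tube, plate, sap), "exactly one")
  expect_error(flow_diagnostics(tube, plate, sap, u = 1, delta_p = 1),
               "exactly one")
})

test_that("all resistances scale linearly in eta and as length^-3", {
  s <- 3.7
  eta2 <- fluid_properties(viscosity = 2e-3 * s)
  radii <- c(0.7, 1.1, 1.4) * 1e-6
  funs <- list(
    function(f, sc) lumen_resistance(tube_geometry(1e-4 * sc, 1e-5 * sc), f),
    function(f, sc) single_pore_resistance(1e-6 * sc, 1e-6 * sc, f),
    function(f, sc) plate_resistance_discrete(radii * sc, 1e-6 * sc, f),
    function(f, sc) plate_resistance_distributional(1e-6 * sc, 0.25e-6 * sc,
                                                    40, 1e-6 * sc, f),
    function(f, sc) plate_resistance_mullendore(mean_radius = 1e-6 * sc,
                                                sd_radius = 0.2e-6 * sc,
                                                n_pores = 40,
                                                thickness = 1e-6 * sc,
                                                fluid = f),
    function(f, sc) plate_resistance_thompson_holbrook(1e-6 * sc, 40,
                                                       1e-6 * sc, f))
  for (fn in funs) {
    expect_equal(fn(eta2, 1) / fn(sap, 1), s, tolerance = 1e-9)
    expect_equal(fn(sap, s) / fn(sap, 1), s^-3, tolerance = 1e-7)
  }
})
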