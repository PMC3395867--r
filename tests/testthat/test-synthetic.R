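test_that("pore-radius sampling is truncated, seeded and moment-faithful", {
  expect_equal(sample_pore_radii(1e-6, 0, 10, seed = 1), rep(1e-6, 10))
  # reproducibility contract
  expect_identical(sample_pore_radii(1e-6, 0.25e-6, 500, seed = 7),
                   sample_pore_radii(1e-6, 0.25e-6, 500, seed = 7))
  # moment recovery at n = 5000
  r <- sample_pore_radii(1e-6, 0.25e-6, 5000, seed = 11)
  expect_true(all(r > 0))
  expect_equal(mean(r), 1e-6, tolerance = 0.01)
  expect_equal(sd(r), 0.25e-6, tolerance = 0.03)
  expect_warning(sample_pore_radii(1e-6, 1.5e-6, 10, seed = 1), "truncation")
})

test_that("pore placement respects containment and non-overlap", {
  # a single pore smaller than the plate always fits
  pl <- place_pores(5e-6, radius = 10e-6, thickness = 1e-6, seed = 1)
  expect_s3_class(pl, "plate_realization")
  expect_true(overlap_oracle(pl))

  # area alone forbids phi > 1
  expect_error(place_pores(rep(2e-6, 100), 10e-6, 1e-6, seed = 1),
               "packing error")

  # dense 50-pore plate near the jamming regime: brute-force oracle over all
  # pairs, and agreement with the packaged checker
  radii <- sample_pore_radii(1e-6, 0.25e-6, 50, seed = 3)
  radii <- radii * sqrt(0.53 / (sum(radii^2) / (10e-6)^2))  # phi = 0.53
  pl2 <- place_pores(radii, 10e-6, 1e-6, seed = 3, max_attempts = 1e6)
  expect_true(overlap_oracle(pl2))
  expect_true(isTRUE(check_realization(pl2)))
  expect_equal(sum(pl2$pores$radius^2) / (10e-6)^2, 0.53, tolerance = 1e-9)

  # placement is seed-reproducible
  pl3 <- place_pores(radii, 10e-6, 1e-6, seed = 3, max_attempts = 1e6)
  expect_identical(pl2$pores, pl3$pores)

  # min_gap is honoured
  gap <- 0.2e-6
  pl4 <- place_pores(sample_pore_radii(1e-6, 0.2e-6, 20, 9), 10e-6, 1e-6,
                     seed = 9, min_gap = gap)
  expect_true(overlap_oracle(pl4, min_gap = gap * (1 - 1e-9)))
})

test_that("impossible packings fail with a packing error, not a hang", {
  radii <- rep(1.2e-6, 120)  # phi = 0.17 but crowded at max_attempts = 50
  expect_error(place_pores(rep(2.8e-6, 12), 10e-6, 1e-6, seed = 2,
                           max_attempts = 200),
               "packing error")
  expect_error(place_pores(radii, 10e-6, 1e-6, seed = 2, max_attempts = 1),
               "packing error")
})

test_that("distribution fitting returns unbiased sample moments", {
  expect_error(fit_pore_distribution(1e-6), "at least two")
  f <- fit_pore_distribution(c(1, 3))
  expect_equal(f$mean, 2)
  expect_equal(f$sd, sqrt(2))
  expect_equal(fit_pore_distribution(rep(2e-6, 5))$sd, 0)
  # recovery of the ~0.25 relative spread on generated data
  f2 <- fit_pore_distribution(sample_pore_radii(1e-6, 0.25e-6, 5000, 21))
  expect_gt(f2$rel_spread, 0.24)
  expect_lt(f2$rel_spread, 0.26)
})

test_that("fitted relative spread is unbiased across seeds", {
  spreads <- vapply(1:20, function(s)
    fit_pore_distribution(sample_pore_radii(1e-6, 0.25e-6, 5000, s))$rel_spread,
    numeric(1))
  expect_equal(mean(spreads), 0.25, tolerance = 0.04)  # +/- 0.01 absolute
  expect_lt(abs(mean(spreads) - 0.25), 0.01)
})

test_that("realizations round-trip through the CSV writer", {
  pl <- place_pores(sample_pore_radii(1e-6, 0.25e-6, 15, 4), 10e-6, 1e-6,
                    seed = 4)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_realization(pl, f)
  pl2 <- read_realization(f)
  expect_equal(pl2$radius, pl$radius)
  expect_equal(pl2$thickness, pl$thickness)
  expect_equal(pl2$pores, pl$pores, tolerance = 1e-10)
})
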