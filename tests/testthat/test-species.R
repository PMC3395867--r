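test_that("the bundled synthetic anatomy table loads and validates", {
  rec <- load_species_table(species_fixture_path())
  expect_equal(nrow(rec), 19)
  expect_true(all(rec$length > 0 & rec$radius > 0 & rec$mean_radius > 0))
  # records without a measured spread are imputed at 0.25 * mean radius
  expect_true(any(rec$sigma_imputed))
  imput <- rec[rec$sigma_imputed, ]
  expect_equal(imput$sd_radius, 0.25 * imput$mean_radius)
  # pore counts derived from the covering fraction are flagged
  expect_true(all(rec$n_from_phi))
  expect_true(all(rec$n_pores >= 1))
  # the table equals the generator output at its recorded seed
  regen <- synthetic_species_table(19, seed = 42)
  disk <- read.csv(species_fixture_path())
  expect_equal(disk$l_um, regen$l_um, tolerance = 1e-9)
  expect_equal(disk$phi, regen$phi, tolerance = 1e-9)
})

test_that("malformed species tables are rejected with the offending row", {
  base <- read.csv(species_fixture_path())
  write_tmp <- function(df) {
    f <- tempfile(fileext = ".csv")
    write.csv(df, f, row.names = FALSE, na = "")
    f
  }
  bad_r <- base; bad_r$r_um[3] <- 0
  expect_error(load_species_table(write_tmp(bad_r)), "row 3")
  bad_n <- base; bad_n$phi[5] <- NA; bad_n$n_pores[5] <- NA
  expect_error(load_species_table(write_tmp(bad_n)), "row 5")
  bad_c <- base; bad_c$rp_mean_um <- NULL
  expect_error(load_species_table(write_tmp(bad_c)), "rp_mean_um")
})

test_that("per-species resistances follow the closed forms", {
  rec <- data.frame(species = "synthetic_case", length = 100e-6,
                    radius = 10e-6, thickness = 1e-6, mean_radius = 1e-6,
                    sd_radius = 0.25e-6, n_pores = 100, phi = 0.5,
                    sigma_imputed = FALSE, n_from_phi = FALSE,
                    stringsAsFactors = FALSE)
  out <- compute_species_resistances(rec, sap)
  expect_equal(out$R_lumen, 5.092958e13, tolerance = 1e-6)
  expect_equal(out$R_total, out$R_lumen + out$R_plate)
  # plate term against a Monte-Carlo oracle
  set.seed(77)
  radii <- rnorm(2e5, 1e-6, 0.25e-6); radii <- radii[radii > 0]
  mc <- 1 / (100 * mean(1 / single_pore_resistance(radii, 1e-6, sap)))
  expect_equal(out$R_plate, mc, tolerance = 0.01)

  # blockage affects the lumen only, by exactly 0.8^-4
  blocked <- compute_species_resistances(rec, sap, blockage_factor = 0.8)
  expect_equal(blocked$R_plate, out$R_plate)
  expect_equal(blocked$R_lumen / out$R_lumen, 1 / 0.8^4)
})

test_that("the full analysis emits both variants and scatter data", {
  an <- run_analysis()
  expect_s3_class(an, "sieve_plate_analysis")
  expect_equal(an$fit_open$n, 19)
  expect_equal(an$amplification, 1 + an$fit_open$k)
  sc <- analysis_scatter(an)
  expect_equal(nrow(sc), 2 * 19)
  expect_true(all(sc$R_plate > 0))
  expect_output(print(an), "open lumen")
})
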