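# shared fixtures: sap at the default viscosity, a typical tube and plate
sap <- fluid_properties(viscosity = 2e-3, density = 1000)

typical_tube <- function(blockage = 1) {
  tube_geometry(length = 100e-6, radius = 10e-6, blockage_factor = blockage)
}

typical_plate <- function(sd = 0.25e-6, n = 100) {
  plate_spec(1e-6, mean_radius = 1e-6, sd_radius = sd, n_pores = n)
}

# independent brute-force overlap/containment oracle (O(N^2) literal loops,
# kept separate from check_realization on purpose)
overlap_oracle <- function(realization, min_gap = 0) {
  p <- realization$pores
  for (i in seq_len(nrow(p))) {
    if (sqrt(p$x[i]^2 + p$y[i]^2) + p$radius[i] >= realization$radius)
      return(FALSE)
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        d <- sqrt((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2)
        if (d < p$radius[i] + p$radius[j] + min_gap) return(FALSE)
      }
    }
  }
  TRUE
}

species_fixture_path <- function() {
  system.file("extdata", "species_anatomy_synthetic.csv",
              package = "sieveplate", mustWork = TRUE)
}
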