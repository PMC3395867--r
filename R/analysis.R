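#' Species-level lumen-versus-plate resistance analysis
#'
#' Runs the full species pipeline: loads (or accepts) an anatomy table,
#' computes the lumen and plate resistance of every species with the
#' pore-size-distribution estimator, and fits the proportionality
#' `R_plate = k R_lumen` for the fully open lumen and for a blocked-lumen
#' variant in which only a fraction `blocked_factor` of the lumen radius is
#' open to flow. The factor `1 + k` measures how much the sieve plates
#' amplify the total resistance of the translocation pathway relative to a
#' plate-less tube.
#'
#' @param species_table Path to an anatomy CSV, a data frame already loaded
#'   by [load_species_table()], or `NULL` for the synthetic table bundled
#'   with the package.
#' @param fluid A [fluid_properties()]; the default sap viscosity of
#'   2 mPa s is applied to every species.
#' @param blocked_factor Blockage factor of the blocked-lumen variant
#'   (default 0.8: 20% of the lumen radius occluded by organelles).
#' @return An object of class `"sieve_plate_analysis"`: the records, the
#'   per-species resistance tables for both variants, the two `"prop_fit"`
#'   objects (`fit_open`, `fit_blocked`), and the open-lumen amplification
#'   factor `1 + k`.
#' @examples
#' an <- run_analysis()
#' an
#' @export
run_analysis <- function(species_table = NULL, fluid = fluid_properties(),
                         blocked_factor = 0.8) {
  records <- if (is.null(species_table)) {
    load_species_table(system.file("extdata", "species_anatomy_synthetic.csv",
                                   package = "sieveplate", mustWork = TRUE))
  } else if (is.character(species_table)) {
    load_species_table(species_table)
  } else if (is.data.frame(species_table)) {
    species_table
  } else {
    stop("species_table must be a path, a data frame, or NULL", call. = FALSE)
  }
  open <- compute_species_resistances(records, fluid, blockage_factor = 1)
  blocked <- compute_species_resistances(records, fluid,
                                         blockage_factor = blocked_factor)
  fit_open <- fit_proportionality(open$R_lumen, open$R_plate)
  fit_blocked <- fit_proportionality(blocked$R_lumen, blocked$R_plate)
  structure(list(records = records,
                 resistances_open = open,
                 resistances_blocked = blocked,
                 fit_open = fit_open,
                 fit_blocked = fit_blocked,
                 amplification = 1 + fit_open$k,
                 blocked_factor = blocked_factor,
                 viscosity = fluid$viscosity),
            class = "sieve_plate_analysis")
}

#' @export
print.sieve_plate_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("Lumen vs plate resistance across %d species (eta = %g mPa s)\n",
              nrow(x$records), x$viscosity * 1e3))
  cat(sprintf("  open lumen:    k = %.*g +/- %.*g (r_corr = %.*g)\n",
              digits, x$fit_open$k, digits, x$fit_open$k_se,
              digits, x$fit_open$r_corr))
  cat(sprintf("  blocked (b = %g): k = %.*g +/- %.*g (r_corr = %.*g)\n",
              x$blocked_factor, digits, x$fit_blocked$k, digits,
              x$fit_blocked$k_se, digits, x$fit_blocked$r_corr))
  cat(sprintf("  plates amplify total resistance by 1 + k = %.*g\n",
              digits, x$amplification))
  invisible(x)
}

#' @export
plot.sieve_plate_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$fit_open, sub = "open lumen", ...)
  plot(x$fit_blocked, sub = sprintf("blocked lumen (b = %g)",
                                    x$blocked_factor), ...)
  invisible(x)
}

#' Scatter data of a species analysis
#'
#' Long-format table of the log-log scatter underlying the fits, convenient
#' for export or custom plotting.
#'
#' @param analysis A `"sieve_plate_analysis"`.
#' @return Data frame with columns `species`, `variant`, `R_lumen`,
#'   `R_plate`.
#' @export
analysis_scatter <- function(analysis) {
  stopifnot(inherits(analysis, "sieve_plate_analysis"))
  rbind(
    data.frame(species = analysis$resistances_open$species, variant = "open",
               R_lumen = analysis$resistances_open$R_lumen,
               R_plate = analysis$resistances_open$R_plate,
               stringsAsFactors = FALSE),
    data.frame(species = analysis$resistances_blocked$species,
               variant = "blocked",
               R_lumen = analysis$resistances_blocked$R_lumen,
               R_plate = analysis$resistances_blocked$R_plate,
               stringsAsFactors = FALSE))
}
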