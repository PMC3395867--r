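#' Load a species anatomy table
#'
#' Reads a CSV of per-species sieve-tube anatomy with header
#' `species,l_um,r_um,lp_um,rp_mean_um,rp_sd_um,n_pores,phi` (lengths in
#' micrometers). `rp_sd_um` may be blank, in which case the pore-radius
#' standard deviation is imputed as `0.25 * rp_mean_um` (the empirical
#' relative spread of sieve-pore radii) and the record is flagged. Each row
#' must carry at least one of `n_pores` and `phi`; a missing pore count is
#' derived from the covering fraction with [pore_count_from_phi()].
#'
#' @param path Path to the CSV file.
#' @return A data frame with one row per species and SI columns: `species`,
#'   `length`, `radius`, `thickness`, `mean_radius`, `sd_radius` (m),
#'   `n_pores`, `phi`, plus logical flags `sigma_imputed` and `n_from_phi`.
#' @examples
#' path <- system.file("extdata", "species_anatomy_synthetic.csv",
#'                     package = "sieveplate")
#' head(load_species_table(path))
#' @export
load_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "l_um", "r_um", "lp_um", "rp_mean_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("species table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!("n_pores" %in% names(df))) df$n_pores <- NA_real_
  if (!("phi" %in% names(df))) df$phi <- NA_real_
  if (!("rp_sd_um" %in% names(df))) df$rp_sd_um <- NA_real_

  n <- nrow(df)
  out <- data.frame(species = as.character(df$species),
                    length = df$l_um * 1e-6,
                    radius = df$r_um * 1e-6,
                    thickness = df$lp_um * 1e-6,
                    mean_radius = df$rp_mean_um * 1e-6,
                    sd_radius = df$rp_sd_um * 1e-6,
                    n_pores = as.numeric(df$n_pores),
                    phi = as.numeric(df$phi),
                    sigma_imputed = FALSE, n_from_phi = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    row_id <- sprintf("row %d (%s)", i, out$species[i])
    for (col in c("length", "radius", "thickness", "mean_radius")) {
      v <- out[[col]][i]
      if (!is.finite(v) || v <= 0)
        stop("validation error in ", row_id, ": ", col,
             " must be a positive length", call. = FALSE)
    }
    if (is.na(out$sd_radius[i])) {
      out$sd_radius[i] <- 0.25 * out$mean_radius[i]
      out$sigma_imputed[i] <- TRUE
    } else if (out$sd_radius[i] < 0) {
      stop("validation error in ", row_id, ": rp_sd_um must be >= 0",
           call. = FALSE)
    }
    if (is.na(out$n_pores[i]) && is.na(out$phi[i]))
      stop("validation error in ", row_id,
           ": at least one of n_pores and phi is required", call. = FALSE)
    if (is.na(out$n_pores[i])) {
      out$n_pores[i] <- pore_count_from_phi(out$phi[i], out$radius[i],
                                            out$mean_radius[i],
                                            out$sd_radius[i])
      out$n_from_phi[i] <- TRUE
    } else if (out$n_pores[i] < 1 || out$n_pores[i] != round(out$n_pores[i])) {
      stop("validation error in ", row_id,
           ": n_pores must be a positive integer", call. = FALSE)
    }
    if (is.na(out$phi[i])) {
      out$phi[i] <- out$n_pores[i] *
        (out$mean_radius[i]^2 + out$sd_radius[i]^2) / out$radius[i]^2
    }
  }
  out
}

#' Generate a synthetic species anatomy table
#'
#' Builds an anatomy table of `n` synthetic "species" whose dimensionless
#' geometry is drawn from ranges typical of published sieve-tube anatomy:
#' tube radius log-uniform over 5--25 um, cell aspect ratio `l/r` log-uniform
#' over 10--60, pore-cell ratio `rp/r` log-uniform over 0.07--0.18,
#' pore-plate aspect ratio `lp/rp` uniform over 0.4--1.2 and covering
#' fraction log-uniform over 0.15--0.55. The first `n_measured` records carry
#' a "measured" relative pore-radius spread drawn near 0.25; the rest leave
#' `rp_sd_um` blank so that loading imputes `0.25 * rp_mean_um`, mirroring
#' the common situation where only the mean pore radius is published.
#'
#' This is a synthetic stand-in for a measured multi-species anatomy table;
#' it emulates realistic ranges, not any particular set of plants.
#'
#' @param n Number of synthetic species.
#' @param seed Integer seed.
#' @param n_measured Records with an explicit `rp_sd_um` value.
#' @return A data frame in the CSV schema of [load_species_table()]
#'   (micrometer units).
#' @examples
#' tab <- synthetic_species_table(19, seed = 42)
#' @export
synthetic_species_table <- function(n = 19, seed = 42, n_measured = 5) {
  stopifnot(n >= 2, n_measured >= 0, n_measured <= n)
  with_seed(seed, {
    runif_log <- function(m, lo, hi) exp(stats::runif(m, log(lo), log(hi)))
    r_um <- runif_log(n, 5, 25)
    gamma <- runif_log(n, 10, 60)
    delta <- runif_log(n, 0.07, 0.18)
    alpha <- stats::runif(n, 0.4, 1.2)
    phi <- runif_log(n, 0.15, 0.55)
    beta <- rep(NA_real_, n)
    if (n_measured > 0)
      beta[seq_len(n_measured)] <- stats::rnorm(n_measured, 0.25, 0.02)
    rp_mean_um <- delta * r_um
    data.frame(species = sprintf("synthetic_sp_%02d", seq_len(n)),
               l_um = round(gamma * r_um, 1),
               r_um = round(r_um, 2),
               lp_um = round(alpha * rp_mean_um, 3),
               rp_mean_um = round(rp_mean_um, 3),
               rp_sd_um = ifelse(is.na(beta), NA_real_,
                                 round(beta * rp_mean_um, 3)),
               n_pores = NA_real_,
               phi = round(phi, 3),
               stringsAsFactors = FALSE)
  })
}

#' Per-species lumen, plate and total resistance
#'
#' For every record of a loaded species table, computes the lumen resistance
#' (Hagen-Poiseuille with the given blockage factor), the sieve-plate
#' resistance from the pore-size-distribution integral
#' ([plate_resistance_distributional()]), and their series total.
#'
#' @param records Data frame from [load_species_table()].
#' @param fluid A [fluid_properties()] (default: sap, eta = 2 mPa s).
#' @param blockage_factor Fraction of the lumen radius open to flow; applies
#'   to the lumen only, never to the plate pores.
#' @return A data frame: `species`, `R_lumen`, `R_plate`, `R_total`
#'   (Pa s/m^3).
#' @examples
#' path <- system.file("extdata", "species_anatomy_synthetic.csv",
#'                     package = "sieveplate")
#' compute_species_resistances(load_species_table(path))
#' @export
compute_species_resistances <- function(records, fluid = fluid_properties(),
                                        blockage_factor = 1) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  n <- nrow(records)
  R_lumen <- R_plate <- numeric(n)
  for (i in seq_len(n)) {
    tube <- tube_geometry(records$length[i], records$radius[i],
                          blockage_factor)
    R_lumen[i] <- lumen_resistance(tube, fluid)
    R_plate[i] <- tryCatch(
      plate_resistance_distributional(records$mean_radius[i],
                                      records$sd_radius[i],
                                      records$n_pores[i],
                                      records$thickness[i], fluid),
      error = function(e) {
        stop("plate resistance failed for species '", records$species[i],
             "': ", conditionMessage(e), call. = FALSE)
      })
  }
  data.frame(species = records$species, R_lumen = R_lumen,
             R_plate = R_plate, R_total = R_lumen + R_plate,
             stringsAsFactors = FALSE)
}
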