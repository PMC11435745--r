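# Seeded synthetic-data generator mirroring the monitoring study design:
# 15 species x 20 samples screened for 24 analytes, spike-recovery
# experiments at three levels x five replicates, and paired
# solvent/matrix-matched calibration series on the printed level grids.

#' Specification for the synthetic-data generator
#'
#' Bundles every ground-truth parameter the generator needs.  The
#' defaults reproduce the monitoring study's structure and outcome: 15
#' species x 20 samples screened for the 24-analyte panel, detection
#' probability 0 everywhere except a single lufenuron residue planted
#' deterministically at 10 ng/g in one eel sample; spike recovery 90%
#' with 5% coefficient of variation (mid-range of the validated method);
#' solvent calibration slope 1000 response units per ng/g with a matrix
#' slope factor of 1.2 (a +20% matrix effect, the edge of the minimal
#' band) and additive response noise SD 50.
#'
#' Detected concentrations are drawn from a log-normal (median
#' `conc_median` ng/g, geometric SD `conc_gsd`) left-truncated at the
#' LOQ, mirroring the censoring rule: residues are positive and
#' right-skewed, and anything below the LOQ would have been recorded as
#' censored.  Recovery noise is multiplicative (CV is relative);
#' calibration noise is additive (instrument noise).
#'
#' @param seed Integer seed; a fixed seed gives identical output across
#'   runs and platforms.
#' @param species Character vector of species.
#' @param pesticides Character vector of analytes.
#' @param n_samples Samples per species (survey design 20).
#' @param detection_prob Baseline per-record detection probability.
#' @param conc_median,conc_gsd Log-normal concentration model for
#'   detections (ng/g; geometric SD > 1 unless degenerate).
#' @param loq Default LOQ (ng/g) for censoring/truncation; per-record
#'   limits beyond the default are resolved downstream.
#' @param plant Optional deterministic planted detection:
#'   `list(pesticide=, species=, concentration=, n=)`; `NULL` for none.
#' @param recovery_true True spike recovery, %.
#' @param recovery_cv True replicate coefficient of variation, %.
#' @param spike_levels Named spike multipliers of the LOQ.
#' @param n_replicates Replicates per spike level.
#' @param solvent_slope,matrix_factor,response_noise_sd Calibration
#'   model: solvent slope (response per ng/g), matrix/solvent slope
#'   ratio, additive response noise SD.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 20240633,
                           species = species_vocabulary(),
                           pesticides = pesticide_vocabulary(),
                           n_samples = 20,
                           detection_prob = 0,
                           conc_median = 10, conc_gsd = 1.5,
                           loq = 5,
                           plant = list(pesticide = "Lufenuron",
                                        species = "Eel",
                                        concentration = 10, n = 1),
                           recovery_true = 90, recovery_cv = 5,
                           spike_levels = c(LOQ = 1, `10xLOQ` = 10,
                                            `50xLOQ` = 50),
                           n_replicates = 5,
                           solvent_slope = 1000, matrix_factor = 1.2,
                           response_noise_sd = 50) {
  stopifnot(detection_prob >= 0, detection_prob <= 1, n_samples >= 1,
            conc_median > 0, conc_gsd >= 1, loq > 0, recovery_true > 0,
            recovery_cv >= 0, solvent_slope != 0, matrix_factor > 0,
            response_noise_sd >= 0)
  structure(list(seed = as.integer(seed), species = species,
                 pesticides = pesticides, n_samples = n_samples,
                 detection_prob = detection_prob,
                 conc_median = conc_median, conc_gsd = conc_gsd,
                 loq = loq, plant = plant,
                 recovery_true = recovery_true, recovery_cv = recovery_cv,
                 spike_levels = spike_levels, n_replicates = n_replicates,
                 solvent_slope = solvent_slope,
                 matrix_factor = matrix_factor,
                 response_noise_sd = response_noise_sd),
            class = "generator_spec")
}

# Left-truncated log-normal draw via inverse-CDF so every draw costs one
# uniform (no rejection loop, and determinism is independent of the
# truncation point).
.rlnorm_trunc <- function(n, median, gsd, lower) {
  mu <- log(median)
  sigma <- log(gsd)
  if (sigma == 0) {
    if (median < lower) stop("degenerate concentration below truncation")
    return(rep(median, n))
  }
  p_lo <- stats::plnorm(lower, mu, sigma)
  u <- stats::runif(n, p_lo, 1)
  stats::qlnorm(u, mu, sigma)
}

#' Generate a synthetic monitoring-survey table
#'
#' One record per species x sample x pesticide: detected with
#' `detection_prob` (concentration from the truncated log-normal), else
#' censored.  Any planted detection is then overwritten
#' deterministically into the first `plant$n` samples of the target
#' species.  Output is valid under the `"residues"` schema and
#' byte-identical for a fixed seed.
#'
#' @param spec A [generator_spec()].
#' @return Residue records data frame.
#' @export
generate_monitoring <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  grid <- expand.grid(sample = seq_len(spec$n_samples),
                      species = spec$species,
                      pesticide = spec$pesticides,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  detected <- stats::runif(n) < spec$detection_prob
  conc <- rep(NA_real_, n)
  if (any(detected)) {
    conc[detected] <- .rlnorm_trunc(sum(detected), spec$conc_median,
                                    spec$conc_gsd, spec$loq)
  }
  df <- data.frame(
    sample_id = sprintf("SYN-%02d-%02d", match(grid$species, spec$species),
                        grid$sample),
    species = grid$species, region = "synthetic",
    pesticide = grid$pesticide, concentration = conc, censored = !detected)
  if (!is.null(spec$plant)) {
    idx <- which(df$species == spec$plant$species &
                 df$pesticide == spec$plant$pesticide)[seq_len(spec$plant$n)]
    df$concentration[idx] <- spec$plant$concentration
    df$censored[idx] <- FALSE
  }
  validate_table(df, "residues")
  df
}

#' Generate synthetic spike-recovery experiments
#'
#' For each pesticide x spike level, `n_replicates` measurements
#' `spike * (recovery_true/100) * (1 + e)`, `e ~ N(0, (recovery_cv/100)^2)`
#' (multiplicative noise: the CV is relative).  Negative draws are
#' truncated at 0; the truncation count is attached as
#' `attr(, "n_truncated")`.  With `recovery_cv = 0`,
#' [compute_recovery()] returns exactly `recovery_true`.
#'
#' @param spec A [generator_spec()].
#' @param matrix Matrix label for the runs.
#' @return Long-form validation data frame (schema `"validation"`).
#' @export
generate_validation <- function(spec, matrix = "Eel") {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed + 1L)
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      level_class = names(spec$spike_levels),
                      pesticide = spec$pesticides,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  spike <- spec$loq * spec$spike_levels[grid$level_class]
  noise <- stats::rnorm(nrow(grid), 0, spec$recovery_cv / 100)
  measured <- spike * (spec$recovery_true / 100) * (1 + noise)
  n_trunc <- sum(measured < 0)
  measured[measured < 0] <- 0
  df <- data.frame(pesticide = grid$pesticide, matrix = matrix,
                   spike_level = unname(spike),
                   level_class = grid$level_class,
                   replicate = as.integer(grid$replicate),
                   measured = measured)
  validate_table(df, "validation")
  attr(df, "n_truncated") <- n_trunc
  df
}

#' Calibration level grid for an LOQ class
#'
#' The concentration grids used for matrix-matched calibration, keyed by
#' the analyte's LOQ (ng/g): 3 -> 0.25–15; 4 -> 0.3–20; 5 -> 0.4–25;
#' 7 -> 0.6–35; 10 -> 0.8–50.
#'
#' @param loq One of 3, 4, 5, 7, 10.
#' @return Numeric vector of levels, ng/g.
#' @export
calibration_level_grid <- function(loq) {
  grids <- list(
    `3`  = c(0.25, 0.75, 1.5, 3.75, 7.5, 12, 15),
    `4`  = c(0.3, 1, 1.6, 2, 5, 10, 16, 20),
    `5`  = c(0.4, 1.25, 2, 2.5, 6.25, 12.5, 20, 25),
    `7`  = c(0.6, 1.75, 2.8, 3.5, 8.75, 17.5, 28, 35),
    `10` = c(0.8, 2.5, 4, 5, 12.5, 25, 40, 50))
  key <- as.character(loq)
  if (!key %in% names(grids)) {
    stop("no calibration grid for LOQ ", loq,
         " ng/g (known: 3, 4, 5, 7, 10)", call. = FALSE)
  }
  grids[[key]]
}

#' Generate paired solvent / matrix-matched calibration series
#'
#' Solvent responses are `solvent_slope * level + e`; matrix responses
#' are `solvent_slope * matrix_factor * level + e`, with additive
#' Gaussian noise `e ~ N(0, response_noise_sd^2)`.  With zero noise the
#' fitted matrix effect equals `(matrix_factor - 1) * 100` exactly and
#' both fits have R² = 1.
#'
#' @param spec A [generator_spec()].
#' @param matrix Matrix name used in the `matrix:<name>` label.
#' @return Long-form calibration data frame (schema `"calibration"`)
#'   with one solvent and one matrix series per pesticide, on the level
#'   grid of `spec$loq`.
#' @export
generate_calibration <- function(spec, matrix = "Eel") {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed + 2L)
  levels <- calibration_level_grid(spec$loq)
  grid <- expand.grid(level = levels,
                      matrix_label = c("solvent",
                                       paste0("matrix:", matrix)),
                      pesticide = spec$pesticides,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  slope <- ifelse(grid$matrix_label == "solvent", spec$solvent_slope,
                  spec$solvent_slope * spec$matrix_factor)
  response <- slope * grid$level +
    stats::rnorm(nrow(grid), 0, spec$response_noise_sd)
  df <- data.frame(pesticide = grid$pesticide,
                   matrix_label = grid$matrix_label,
                   level = grid$level, response = response)
  validate_table(df, "calibration")
  df
}

#' Ground-truth manifest for a generator specification
#'
#' @param spec A [generator_spec()].
#' @return One-row data frame of the true parameters, suitable for
#'   writing alongside generated datasets.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  data.frame(seed = spec$seed, n_species = length(spec$species),
             n_pesticides = length(spec$pesticides),
             n_samples = spec$n_samples,
             detection_prob = spec$detection_prob,
             conc_median = spec$conc_median, conc_gsd = spec$conc_gsd,
             loq = spec$loq,
             plant_pesticide = if (is.null(spec$plant)) NA_character_
                               else spec$plant$pesticide,
             plant_species = if (is.null(spec$plant)) NA_character_
                             else spec$plant$species,
             plant_concentration = if (is.null(spec$plant)) NA_real_
                                   else spec$plant$concentration,
             recovery_true = spec$recovery_true,
             recovery_cv = spec$recovery_cv,
             solvent_slope = spec$solvent_slope,
             matrix_factor = spec$matrix_factor,
             response_noise_sd = spec$response_noise_sd)
}
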