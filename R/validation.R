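# Method-validation statistics: spike recovery and precision, calibration
# linearity, matrix effect, and S/N-scaled detection limits, graded against
# Codex acceptance windows for multiresidue analysis.

#' Spike-recovery accuracy and precision
#'
#' Summarises one spike experiment (a known concentration fortified into a
#' blank matrix, measured in replicate).  Accuracy is the mean recovery,
#' `mean(measured) / spike_level * 100` (%); precision is the relative
#' standard deviation of the replicates, `sd / mean * 100` (%).  The
#' sample (n-1) standard deviation is used throughout, the convention for
#' reported %RSD.  Both statistics are scale-invariant: rescaling the
#' spike and all replicates by the same factor leaves them unchanged.
#'
#' @param spike_level Spiked concentration, ng/g; > 0.
#' @param replicates Numeric vector of measured concentrations (ng/g),
#'   length >= 2, all >= 0.
#' @param pesticide,matrix,level_class Optional labels carried into the
#'   result (`level_class` typically `"LOQ"`, `"10xLOQ"` or `"50xLOQ"`).
#' @return One-row `data.frame`: labels, `n`, `recovery_mean`,
#'   `recovery_sd` (both % of spike), `rsd` (%).
#' @export
#' @examples
#' compute_recovery(10, c(8.8, 9.0, 9.2))  # recovery 90%, RSD 2.2%
compute_recovery <- function(spike_level, replicates, pesticide = NA_character_,
                             matrix = NA_character_,
                             level_class = NA_character_) {
  stopifnot(is.numeric(spike_level), length(spike_level) == 1,
            spike_level > 0, is.numeric(replicates),
            length(replicates) >= 2, all(replicates >= 0))
  m <- mean(replicates)
  s <- stats::sd(replicates)
  if (m == 0) {
    stop("mean of replicates is zero: %RSD undefined", call. = FALSE)
  }
  data.frame(pesticide = pesticide, matrix = matrix,
             level_class = level_class, spike_level = spike_level,
             n = length(replicates),
             recovery_mean = m / spike_level * 100,
             recovery_sd = s / spike_level * 100,
             rsd = s / m * 100)
}

#' Fit a calibration line
#'
#' Ordinary least squares of detector response on concentration level
#' (unweighted, as is usual when calibration spans less than two orders of
#' magnitude).  `r_squared = 1 - SS_res/SS_tot`; a zero-variance response
#' has no explainable variation and its R² is defined as 0, with a
#' warning.
#'
#' @param level Concentration levels, ng/g; >= 3 distinct values.
#' @param response Detector responses (arbitrary units), same length.
#' @param pesticide,matrix_label Optional labels (`matrix_label` is
#'   `"solvent"` or `"matrix:<name>"`).
#' @return One-row `data.frame`: labels, `n`, `slope` (response per ng/g),
#'   `intercept`, `r_squared`.
#' @export
fit_calibration <- function(level, response, pesticide = NA_character_,
                            matrix_label = NA_character_) {
  stopifnot(is.numeric(level), is.numeric(response),
            length(level) == length(response), length(level) >= 3)
  if (length(unique(level)) < 3) {
    stop("degenerate calibration design: need >= 3 distinct levels",
         call. = FALSE)
  }
  fit <- stats::lm(response ~ level)
  ss_tot <- sum((response - mean(response))^2)
  if (ss_tot == 0) {
    warning("zero-variance response: R² defined as 0")
    r2 <- 0
  } else {
    r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  cf <- stats::coef(fit)
  data.frame(pesticide = pesticide, matrix_label = matrix_label,
             n = length(level), slope = unname(cf["level"]),
             intercept = unname(cf["(Intercept)"]), r_squared = r2)
}

#' Matrix effect from paired calibration slopes
#'
#' Signed percentage change of the matrix-matched calibration slope
#' relative to the solvent slope,
#' `ME = (slope_matrix / slope_solvent - 1) * 100` (the Matuszewski-style
#' slope-ratio formulation).  Interpretation bands: |ME| <= 20% minimal
#' ionization interference, |ME| > 50% strong (significant suppression or
#' enhancement), in between medium.
#'
#' @param matrix_fit,solvent_fit One-row fits from [fit_calibration()]
#'   for the same pesticide, in matrix and in solvent.
#' @return One-row `data.frame`: `pesticide`, `matrix`, `me` (%),
#'   `category`.
#' @export
matrix_effect <- function(matrix_fit, solvent_fit) {
  if (!is.na(matrix_fit$pesticide) && !is.na(solvent_fit$pesticide) &&
      matrix_fit$pesticide != solvent_fit$pesticide) {
    stop("matrix and solvent fits are for different pesticides",
         call. = FALSE)
  }
  if (solvent_fit$slope == 0) {
    stop("solvent slope is zero: matrix effect undefined", call. = FALSE)
  }
  me <- (matrix_fit$slope / solvent_fit$slope - 1) * 100
  data.frame(pesticide = matrix_fit$pesticide,
             matrix = sub("^matrix:", "", matrix_fit$matrix_label),
             me = me, category = classify_matrix_effect(me))
}

#' @rdname matrix_effect
#' @param me Numeric vector of matrix-effect percentages.
#' @export
classify_matrix_effect <- function(me) {
  ifelse(abs(me) <= 20, "minimal", ifelse(abs(me) > 50, "strong", "medium"))
}

#' Scale a measured signal-to-noise ratio to LOD and LOQ
#'
#' LOD is the concentration at S/N = 3, LOQ at S/N = 10.  Given one
#' measured concentration and its observed S/N, both limits follow under
#' the approximation that S/N is linear in concentration near the LOQ:
#' `lod = conc * 3 / sn`, `loq = conc * 10 / sn`.
#'
#' @param conc Measured concentration, ng/g; > 0.
#' @param sn_observed Observed signal-to-noise ratio; > 0.
#' @return Named list with `lod` and `loq` (ng/g).
#' @export
lod_loq_from_sn <- function(conc, sn_observed) {
  stopifnot(is.numeric(conc), is.numeric(sn_observed))
  if (any(conc <= 0) || any(sn_observed <= 0)) {
    stop("conc and sn_observed must be > 0", call. = FALSE)
  }
  list(lod = conc * 3 / sn_observed, loq = conc * 10 / sn_observed)
}

#' Grade validation statistics against Codex acceptance windows
#'
#' Multiresidue acceptance windows: mean recovery within 70–120%
#' (inclusive), %RSD at most 20%, calibration R² strictly above 0.98.
#'
#' @param recovery_mean Mean recovery, %.
#' @param rsd Relative standard deviation, %.
#' @param r_squared Calibration coefficient of determination (optional;
#'   `NA` leaves the linearity flag `NA`).
#' @return One-row `data.frame` of logicals: `recovery_pass`, `rsd_pass`,
#'   `linearity_pass`, and `all_pass` (ignoring `NA` flags).
#' @export
codex_flags <- function(recovery_mean, rsd, r_squared = NA_real_) {
  f <- data.frame(recovery_pass = recovery_mean >= 70 & recovery_mean <= 120,
                  rsd_pass = rsd <= 20,
                  linearity_pass = ifelse(is.na(r_squared), NA,
                                          r_squared > 0.98))
  f$all_pass <- apply(f, 1, function(r) all(as.logical(r), na.rm = TRUE))
  f
}

#' Count pesticides with mean recovery below a threshold, per method
#'
#' Used to compare extraction/clean-up candidates: for each method, how
#' many pesticides fall strictly below a recovery threshold (e.g. the
#' count below 60% that disqualified an extraction buffer).
#'
#' @param comparison Long-form data frame with columns `pesticide`,
#'   `method`, `recovery_mean` (one row per pesticide x method; defaults
#'   to [method_comparison_table()]).
#' @param thresholds Numeric vector of recovery thresholds, %.
#' @return Data frame `method` x `threshold` with `n_below`, the count of
#'   pesticides with `recovery_mean < threshold`.
#' @export
method_comparison_summary <- function(comparison = method_comparison_table(),
                                      thresholds = c(60, 70)) {
  key <- paste(comparison$pesticide, comparison$method, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate pesticide x method rows in comparison table",
         call. = FALSE)
  }
  out <- expand.grid(method = unique(comparison$method),
                     threshold = thresholds, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$n_below <- mapply(function(m, th) {
    sum(comparison$recovery_mean[comparison$method == m] < th)
  }, out$method, out$threshold)
  out
}
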