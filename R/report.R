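# Stage orchestration and report rendering.  Each runner returns its
# tabular report plus an integer status following the convention
# 0 = all acceptance flags pass, 1 = at least one flag fails; malformed
# input raises an error (the status-2 path for script drivers).

#' Run the method-validation stage
#'
#' Computes recovery/precision per pesticide x matrix x spike level from
#' long-form validation data, fits solvent and matrix-matched calibration
#' lines, derives the matrix effect, and grades everything against the
#' Codex windows (recovery 70–120%, %RSD <= 20, R² > 0.98).
#'
#' @param validation Long-form validation table (schema `"validation"`).
#' @param calibration Long-form calibration table (schema
#'   `"calibration"`) with a `"solvent"` and one `"matrix:<name>"` series
#'   per pesticide; optional.
#' @return List: `report` (one row per pesticide x matrix x level with
#'   metrics and flags), `linearity` (per-series fits), `matrix_effects`,
#'   `status` (0 if every flag passes, 1 otherwise).
#' @export
validation_report <- function(validation, calibration = NULL) {
  if (nrow(validation) == 0) {
    stop("validation table is empty", call. = FALSE)
  }
  validate_table(validation, "validation")
  runs <- split(validation,
                list(validation$pesticide, validation$matrix,
                     validation$level_class), drop = TRUE)
  rec <- do.call(rbind, lapply(runs, function(g) {
    compute_recovery(g$spike_level[1], g$measured, pesticide = g$pesticide[1],
                     matrix = g$matrix[1], level_class = g$level_class[1])
  }))
  lin <- NULL
  mes <- NULL
  if (!is.null(calibration) && nrow(calibration)) {
    validate_table(calibration, "calibration")
    series <- split(calibration,
                    list(calibration$pesticide, calibration$matrix_label),
                    drop = TRUE)
    lin <- do.call(rbind, lapply(series, function(g) {
      fit_calibration(g$level, g$response, pesticide = g$pesticide[1],
                      matrix_label = g$matrix_label[1])
    }))
    rownames(lin) <- NULL
    mes <- do.call(rbind, lapply(split(lin, lin$pesticide), function(d) {
      solvent <- d[d$matrix_label == "solvent", , drop = FALSE]
      matrixf <- d[d$matrix_label != "solvent", , drop = FALSE]
      if (nrow(solvent) != 1 || nrow(matrixf) == 0) return(NULL)
      do.call(rbind, lapply(seq_len(nrow(matrixf)), function(i) {
        matrix_effect(matrixf[i, ], solvent)
      }))
    }))
    if (!is.null(mes)) rownames(mes) <- NULL
    # grade each recovery row against the matrix-matched fit's linearity
    key <- paste(lin$pesticide, sub("^matrix:", "", lin$matrix_label))
    r2 <- stats::setNames(lin$r_squared, key)[paste(rec$pesticide,
                                                    rec$matrix)]
  } else {
    r2 <- rep(NA_real_, nrow(rec))
  }
  flags <- codex_flags(rec$recovery_mean, rec$rsd, unname(r2))
  report <- cbind(rec, r_squared = unname(r2), flags)
  rownames(report) <- NULL
  report <- report[order(report$pesticide, report$matrix,
                         report$level_class), , drop = FALSE]
  list(report = report, linearity = lin, matrix_effects = mes,
       status = if (all(report$all_pass)) 0L else 1L)
}

#' Run the monitoring + risk-assessment stage
#'
#' Summarises residue records into per pesticide x species detection
#' summaries and runs the nine exposure scenarios for every summary with
#' at least one detection.  Pesticide x species combinations with no
#' detections are skipped (listed in `skipped`); a detected pesticide
#' without an ADI reference is an input error.
#'
#' @param records Residue records (schema `"residues"`).
#' @param limits Limits table (schema `"limits"`).
#' @param consumption Consumption table (schema `"consumption"`).
#' @param tox Toxref table (schema `"toxref"`).
#' @param config Configuration list from [load_config()].
#' @return List: `report` (9 rows per assessed pesticide x species),
#'   `skipped` (combinations with no detections), `headline` (one-line
#'   maximum-%ADI summary), `status` (0; scenario risk is reported, not
#'   an error condition).
#' @export
risk_report <- function(records, limits, consumption, tox,
                        config = load_config()) {
  validate_table(records, "residues")
  validate_table(limits, "limits")
  validate_table(consumption, "consumption")
  validate_table(tox, "toxref")
  summaries <- detection_table(records, limits)
  has_det <- vapply(summaries, function(s) length(s$detections) > 0, NA)
  detected_pests <- unique(vapply(summaries[has_det],
                                  function(s) s$pesticide, ""))
  missing_tox <- setdiff(detected_pests, tox$pesticide)
  if (length(missing_tox)) {
    stop("no ADI reference for detected pesticide: ",
         paste(missing_tox, collapse = ", "), call. = FALSE)
  }
  report <- do.call(rbind, lapply(summaries[has_det], function(s) {
    run_scenarios(s, consumption, tox, config)
  }))
  if (is.null(report)) {
    report <- run_scenarios_empty()
    headline <- "No evaluable detections: all records censored below the LOQ."
  } else {
    rownames(report) <- NULL
    mx <- report[which.max(report$percent_adi), ]
    headline <- sprintf(
      "Maximum %%ADI %s%% (%s in %s, scenario %d, tier %d option %s): %s risk.",
      format_percent_adi(mx$percent_adi), mx$pesticide, mx$species,
      mx$scenario_id, mx$tier, mx$dpc_option, mx$classification)
  }
  list(report = report, skipped = names(summaries)[!has_det],
       headline = headline, status = 0L)
}

run_scenarios_empty <- function() {
  data.frame(pesticide = character(), species = character(),
             scenario_id = integer(), tier = integer(),
             dpc_option = character(), dfi = double(), dpc = double(),
             edi = double(), percent_adi = double(), status = character(),
             classification = character())
}

#' Format a %ADI value for display
#'
#' Hazard indices are reported rounded to 4 decimal places (the
#' convention for values far below the 10% threshold); computation keeps
#' full precision.
#'
#' @param x Numeric vector of %ADI values.
#' @return Character vector.
#' @export
format_percent_adi <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.4f", round(x, 4)))
}

#' Render a risk report as deterministic plain text
#'
#' Same inputs produce byte-identical text; %ADI is shown to 4 decimals.
#'
#' @param risk Result of [risk_report()].
#' @return Character vector of lines.
#' @export
render_report <- function(risk) {
  lines <- c("Dietary risk assessment: nine-scenario %ADI report",
             strrep("=", 50))
  rep_df <- risk$report
  if (nrow(rep_df) == 0) {
    return(c(lines, risk$headline))
  }
  lines <- c(lines, risk$headline, "")
  for (grp in split(rep_df, paste(rep_df$pesticide, rep_df$species))) {
    lines <- c(lines,
               sprintf("%s in %s (LOQ-censored survey):",
                       grp$pesticide[1], grp$species[1]),
               sprintf("  %-9s %-5s %-7s %10s %8s %12s %10s %s",
                       "scenario", "tier", "option", "DFI(g/d)", "DPC(ng/g)",
                       "EDI(ng/d)", "%ADI", "class"))
    for (i in seq_len(nrow(grp))) {
      r <- grp[i, ]
      lines <- c(lines, sprintf(
        "  %-9d %-5d %-7s %10s %8s %12s %10s %s",
        r$scenario_id, r$tier, r$dpc_option,
        ifelse(is.na(r$dfi), "-", sprintf("%.2f", r$dfi)),
        ifelse(is.na(r$dpc), "-", sprintf("%.2f", r$dpc)),
        ifelse(is.na(r$edi), "-", sprintf("%.2f", r$edi)),
        format_percent_adi(r$percent_adi),
        ifelse(r$status == "ok", r$classification, r$status)))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Write a JSON run manifest alongside an output set
#'
#' Records what produced a set of result files: stage name, input paths,
#' configuration, seed, timestamp and package version.
#'
#' @param path Output path for the manifest (JSON).
#' @param stage Stage name (e.g. `"simulate"`, `"risk"`).
#' @param inputs Character vector of input paths.
#' @param config Configuration list.
#' @param seed Integer seed, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, inputs = character(),
                           config = load_config(), seed = NULL) {
  manifest <- list(
    stage = stage, inputs = as.list(inputs), config = config,
    seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("residuerisk")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
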