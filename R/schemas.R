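# CSV schemas and validated readers.  All tables are plain UTF-8 CSV with a
# mandatory header and dot decimal separator; units are fixed by the schema
# (ng/g wet weight for concentrations and limits, g/person/day for intake,
# mg/kg bw/day for ADI) and never auto-converted.

.schemas <- list(
  residues = list(
    columns = c(sample_id = "character", species = "character",
                region = "character", pesticide = "character",
                concentration = "numeric", censored = "logical")
  ),
  limits = list(
    columns = c(pesticide = "character", matrix = "character",
                lod = "numeric", loq = "numeric")
  ),
  consumption = list(
    columns = c(species = "character", mean_intake = "numeric",
                extreme_intake = "numeric", imputed = "logical")
  ),
  toxref = list(
    columns = c(pesticide = "character", adi = "numeric",
                body_weight = "numeric")
  ),
  validation = list(
    # long form: one row per replicate measurement of a spike experiment
    columns = c(pesticide = "character", matrix = "character",
                spike_level = "numeric", level_class = "character",
                replicate = "integer", measured = "numeric")
  ),
  calibration = list(
    columns = c(pesticide = "character", matrix_label = "character",
                level = "numeric", response = "numeric")
  )
)

#' Names of the CSV schemas understood by [read_table()]
#' @return Character vector of schema names.
#' @export
schema_names <- function() names(.schemas)

.schema_error <- function(schema, row, field, msg) {
  stop(sprintf("schema '%s'%s%s: %s", schema,
               if (is.null(row)) "" else sprintf(", row %d", row),
               if (is.null(field)) "" else sprintf(", field '%s'", field),
               msg), call. = FALSE)
}

.check_vocab <- function(x, vocab, schema, field) {
  bad <- which(!is.na(x) & !(x %in% vocab))
  if (length(bad)) {
    .schema_error(schema, bad[1], field,
                  sprintf("unknown value '%s'", x[bad[1]]))
  }
}

#' Read and validate a typed CSV table
#'
#' Reads one of the pipeline's tabular inputs and validates every row
#' against the schema's type and domain invariants.  Violations raise an
#' error naming the schema, the offending row (1-based, excluding the
#' header) and the field, so malformed monitoring submissions are rejected
#' at the door.
#'
#' Schema-specific invariants:
#' \describe{
#'   \item{residues}{`censored` XOR a present `concentration`; species and
#'     pesticide must be in the controlled vocabularies; present
#'     concentrations must be > 0.  (The "at or above the applicable LOQ"
#'     invariant needs a limits table and is enforced by
#'     [detection_table()].)}
#'   \item{limits}{`0 < lod < loq`.}
#'   \item{consumption}{`0 <= mean_intake <= extreme_intake`.}
#'   \item{toxref}{`adi > 0`, `body_weight > 0`.}
#'   \item{validation}{`spike_level > 0`, `measured >= 0`, `level_class`
#'     one of `LOQ`, `10xLOQ`, `50xLOQ`.}
#'   \item{calibration}{`level > 0`.}
#' }
#'
#' @param path Path to a CSV file.
#' @param schema_name One of [schema_names()].
#' @return A validated `data.frame`; row order preserved.
#' @export
#' @examples
#' p <- system.file("extdata", "consumption_knhanes.csv",
#'                  package = "residuerisk")
#' head(read_table(p, "consumption"))
read_table <- function(path, schema_name) {
  schema_name <- match.arg(schema_name, schema_names())
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  spec <- .schemas[[schema_name]]
  cols <- spec$columns
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  missing <- setdiff(names(cols), names(df))
  if (length(missing)) {
    .schema_error(schema_name, NULL, missing[1], "missing column")
  }
  df <- df[names(cols)]
  if (nrow(df) == 0) return(df)
  for (nm in names(cols)) {
    df[[nm]] <- switch(cols[[nm]],
      character = as.character(df[[nm]]),
      numeric   = as.numeric(df[[nm]]),
      integer   = as.integer(df[[nm]]),
      logical   = as.logical(df[[nm]]))
  }
  validate_table(df, schema_name)
  df
}

#' @rdname read_table
#' @param df A data frame already holding the schema's columns.
#' @export
validate_table <- function(df, schema_name) {
  schema_name <- match.arg(schema_name, schema_names())
  err <- function(row, field, msg) .schema_error(schema_name, row, field, msg)
  first <- function(i) if (any(i, na.rm = TRUE)) which(i)[1] else NULL
  switch(schema_name,
    residues = {
      .check_vocab(df$species, species_vocabulary(), schema_name, "species")
      .check_vocab(df$pesticide, pesticide_vocabulary(), schema_name,
                   "pesticide")
      if (!is.null(i <- first(is.na(df$censored))))
        err(i, "censored", "must be TRUE or FALSE")
      if (!is.null(i <- first(df$censored & !is.na(df$concentration))))
        err(i, "concentration",
            "censored record must not carry a concentration")
      if (!is.null(i <- first(!df$censored & is.na(df$concentration))))
        err(i, "concentration", "detected record must carry a concentration")
      if (!is.null(i <- first(!is.na(df$concentration) &
                              df$concentration <= 0)))
        err(i, "concentration", "must be > 0 when present")
    },
    limits = {
      .check_vocab(df$pesticide, pesticide_vocabulary(), schema_name,
                   "pesticide")
      if (!is.null(i <- first(is.na(df$lod) | df$lod <= 0)))
        err(i, "lod", "must be > 0")
      if (!is.null(i <- first(is.na(df$loq) | df$loq <= df$lod)))
        err(i, "loq", "must satisfy 0 < lod < loq")
    },
    consumption = {
      .check_vocab(df$species, species_vocabulary(), schema_name, "species")
      if (!is.null(i <- first(is.na(df$mean_intake) | df$mean_intake < 0)))
        err(i, "mean_intake", "must be >= 0")
      if (!is.null(i <- first(is.na(df$extreme_intake) |
                              df$extreme_intake < df$mean_intake)))
        err(i, "extreme_intake", "must be >= mean_intake")
    },
    toxref = {
      .check_vocab(df$pesticide, pesticide_vocabulary(), schema_name,
                   "pesticide")
      if (!is.null(i <- first(is.na(df$adi) | df$adi <= 0)))
        err(i, "adi", "must be > 0")
      if (!is.null(i <- first(is.na(df$body_weight) | df$body_weight <= 0)))
        err(i, "body_weight", "must be > 0")
    },
    validation = {
      .check_vocab(df$pesticide, pesticide_vocabulary(), schema_name,
                   "pesticide")
      if (!is.null(i <- first(is.na(df$spike_level) | df$spike_level <= 0)))
        err(i, "spike_level", "must be > 0")
      if (!is.null(i <- first(!(df$level_class %in%
                                c("LOQ", "10xLOQ", "50xLOQ")))))
        err(i, "level_class", "must be LOQ, 10xLOQ or 50xLOQ")
      if (!is.null(i <- first(is.na(df$measured) | df$measured < 0)))
        err(i, "measured", "must be >= 0")
    },
    calibration = {
      .check_vocab(df$pesticide, pesticide_vocabulary(), schema_name,
                   "pesticide")
      if (!is.null(i <- first(is.na(df$level) | df$level <= 0)))
        err(i, "level", "must be > 0")
      if (!is.null(i <- first(is.na(df$response))))
        err(i, "response", "must be numeric")
    })
  invisible(df)
}

#' Write a table previously validated against a schema
#'
#' Writing then reading any valid collection is the identity on all
#' fields (round-trip property).
#'
#' @inheritParams read_table
#' @param df Data frame conforming to the schema.
#' @export
write_table <- function(df, path, schema_name) {
  schema_name <- match.arg(schema_name, schema_names())
  validate_table(df, schema_name)
  utils::write.csv(df[names(.schemas[[schema_name]]$columns)], path,
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Load run configuration
#'
#' Configuration is a flat YAML key/value document.  Every key has a
#' default reflecting the study design; unknown keys and non-positive
#' numerics are rejected.
#'
#' Defaults: `body_weight` 60 kg (assumed average adult body weight),
#' `n_tests_per_species` 20 (survey design), `risk_threshold` 10 (%ADI
#' below which risk is conventionally "minimal", FAO/WHO),
#' `tier1_rule` `"detected"` (tier-1 intake = mean intake of the detected
#' species) and `tier3_rule` `"sum"` (tier-3 intake = sum of per-species
#' 99th-percentile intakes).  Alternatives: `tier1_rule = "sum"` (sum of
#' species means) and `tier3_rule = "detected"` or `"max"`.
#'
#' @param path Optional path to a YAML file; `NULL` means all defaults.
#' @return Named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- list(body_weight = 60, n_tests_per_species = 20,
              risk_threshold = 10, tier1_rule = "detected",
              tier3_rule = "sum")
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config key: %s", unknown[1]), call. = FALSE)
  }
  for (key in names(user)) {
    val <- user[[key]]
    if (key %in% c("body_weight", "n_tests_per_species", "risk_threshold")) {
      if (!is.numeric(val) || length(val) != 1 || is.na(val) || val <= 0) {
        stop(sprintf("config key '%s' must be a positive number", key),
             call. = FALSE)
      }
    }
    if (key == "tier1_rule") val <- match.arg(val, c("detected", "sum"))
    if (key == "tier3_rule") val <- match.arg(val, c("sum", "detected", "max"))
    cfg[[key]] <- val
  }
  cfg
}
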