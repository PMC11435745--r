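#' Packaged reference tables
#'
#' Plain-text reference tables shipped with the package:
#'
#' * `consumption_table()` — Korean per-capita consumption of the 15
#'   monitored fishery species (KNHANES 2017–2021), mean and extreme
#'   (99th percentile) intake in g/person/day.  Species without survey
#'   data carry intakes imputed as half the minimum mean and extreme of
#'   similar species (`imputed = TRUE`).
#' * `method_validation_table()` — per pesticide x control matrix (eel,
#'   flatfish, abalone, shrimp) method performance: calibration R²,
#'   matrix effect (%), LOD and LOQ (ng/g wet weight), relative recovery
#'   (%) and %RSD at the LOQ, 10xLOQ and 50xLOQ spike levels.
#' * `method_comparison_table()` — mean spike recovery (± SD, %) of each
#'   of the 24 pesticides under two extraction methods (EN15662, AOAC)
#'   and two clean-up sorbents (C18 alone, PSA + C18), long form.
#' * `monitoring_table()` — a synthetic reconstruction of the national
#'   monitoring survey outcome: 300 residue records (15 species x 20
#'   samples) screened for lufenuron, all censored below the LOQ except
#'   one eel sample detected at 10 ng/g.  The raw survey data are not
#'   public; this fixture reproduces the published summary exactly.
#' * `toxref_table()` — acceptable daily intake (mg/kg bw/day) and the
#'   60 kg default body weight for the detected analyte.
#'
#' @return A validated `data.frame` (see [read_table()]).
#' @name fixtures
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "residuerisk")
  if (!nzchar(path)) stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

#' @rdname fixtures
#' @export
consumption_table <- function() {
  read_table(.extdata("consumption_knhanes.csv"), "consumption")
}

#' @rdname fixtures
#' @export
method_validation_table <- function() {
  df <- utils::read.csv(.extdata("method_validation.csv"),
                        stringsAsFactors = FALSE)
  stopifnot(all(df$r_squared >= 0 & df$r_squared <= 1),
            all(df$lod > 0), all(df$loq > df$lod))
  df
}

#' @rdname fixtures
#' @export
method_comparison_table <- function() {
  utils::read.csv(.extdata("method_comparison.csv"), stringsAsFactors = FALSE)
}

#' @rdname fixtures
#' @export
monitoring_table <- function() {
  read_table(.extdata("monitoring_survey.csv"), "residues")
}

#' @rdname fixtures
#' @export
toxref_table <- function() {
  read_table(.extdata("toxref.csv"), "toxref")
}

#' Derive a limits table from a method-performance table
#'
#' Builds the pesticide x matrix LOD/LOQ lookup used by
#' [detection_table()] from per-matrix method performance, adding one
#' `"default"` row per pesticide that carries the most conservative
#' (largest) LOQ across the validated matrices, so species outside the
#' four validated matrix classes resolve to a defensible limit.
#'
#' @param validation Data frame with columns `pesticide`, `matrix`,
#'   `lod`, `loq`; defaults to [method_validation_table()].
#' @return Limits table (schema `"limits"`).
#' @export
limits_from_validation <- function(validation = method_validation_table()) {
  base <- validation[, c("pesticide", "matrix", "lod", "loq")]
  defaults <- do.call(rbind, lapply(split(base, base$pesticide), function(d) {
    i <- which.max(d$loq)
    data.frame(pesticide = d$pesticide[1], matrix = "default",
               lod = d$lod[i], loq = d$loq[i])
  }))
  out <- rbind(base, defaults)
  rownames(out) <- NULL
  validate_table(out, "limits")
  out
}

#' Resolve the LOQ (and LOD) applicable to a pesticide in a species
#'
#' Lookup order: an exact `matrix == species` row, then the species'
#' matrix class (see [matrix_class()]), then the `"default"` row.
#'
#' @param limits Limits table (schema `"limits"`).
#' @param pesticide,species Scalars.
#' @return Named list with `lod` and `loq` (ng/g wet weight).
#' @export
lookup_limit <- function(limits, pesticide, species) {
  rows <- limits[limits$pesticide == pesticide, , drop = FALSE]
  for (key in unique(c(species, matrix_class(species), "default"))) {
    hit <- rows[rows$matrix == key, , drop = FALSE]
    if (nrow(hit)) return(list(lod = hit$lod[1], loq = hit$loq[1]))
  }
  stop(sprintf("no limit entry for %s in %s (or its matrix class/default)",
               pesticide, species), call. = FALSE)
}
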