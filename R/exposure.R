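# Nine-scenario dietary exposure assessment.  EDI (ng/person/day) =
# DFI (g/person/day) x DPC (ng/g), crossing three intake tiers with three
# censoring-aware residue-concentration estimators; the hazard index %ADI
# expresses EDI as a percentage of the per-person acceptable daily intake.

#' Construct a per-pesticide, per-species detection summary
#'
#' Holds what the risk scenarios consume: how many samples were tested,
#' which concentrations were detected (at or above the LOQ), and the LOQ
#' that applies to the censored remainder.
#'
#' @param pesticide,species Labels.
#' @param n_tests Number of samples tested (survey design default 20).
#' @param detections Numeric vector of detected concentrations, ng/g;
#'   possibly empty, each >= `loq`.
#' @param loq Limit of quantification, ng/g; > 0.
#' @return A `detection_summary` list.
#' @export
detection_summary <- function(pesticide, species, n_tests = 20,
                              detections = numeric(0), loq) {
  stopifnot(n_tests >= 1, length(detections) <= n_tests,
            is.numeric(loq), loq > 0)
  if (length(detections) && any(detections < loq)) {
    stop("detected concentrations must be >= the LOQ", call. = FALSE)
  }
  structure(list(pesticide = pesticide, species = species,
                 n_tests = as.integer(n_tests),
                 detections = as.numeric(detections), loq = loq),
            class = "detection_summary")
}

#' Residue-concentration estimators for censored monitoring data
#'
#' Three estimators of the detected pesticide concentration (DPC, ng/g)
#' from a survey in which most samples fall below the LOQ:
#'
#' * **Option A** — middle-bound substitution: censored samples enter at
#'   the LOQ, `(sum(detections) + loq * n_censored) / n_tests`.
#' * **Option B** — mean of the detected concentrations only.
#' * **Option C** — maximum detected concentration (worst case).
#'
#' Options B and C are defined only when at least one detection exists;
#' with none they error, and [run_scenarios()] reports those scenarios as
#' not evaluable rather than substituting the LOQ.
#'
#' @param s A [detection_summary()].
#' @return Scalar concentration, ng/g.
#' @export
dpc_option_a <- function(s) {
  n_cens <- s$n_tests - length(s$detections)
  (sum(s$detections) + s$loq * n_cens) / s$n_tests
}

#' @rdname dpc_option_a
#' @export
dpc_option_b <- function(s) {
  if (!length(s$detections)) {
    stop("option B undefined with zero detections", call. = FALSE)
  }
  mean(s$detections)
}

#' @rdname dpc_option_a
#' @export
dpc_option_c <- function(s) {
  if (!length(s$detections)) {
    stop("option C undefined with zero detections", call. = FALSE)
  }
  max(s$detections)
}

#' Daily food intake for an exposure tier
#'
#' Tier semantics: 1 — average consumer (mean intake); 2 — extreme
#' consumer of the species in which the residue was detected (its 99th
#' percentile intake); 3 — extreme consumer across fishery species.
#' Tier 2 is fixed by definition; the aggregation behind tiers 1 and 3 is
#' configurable because national summaries rarely state it:
#' `tier1_rule` `"detected"` (default; mean intake of the detected
#' species) or `"sum"` (sum of species means); `tier3_rule` `"sum"`
#' (default; sum of per-species extremes), `"detected"` or `"max"`.
#'
#' @param tier 1, 2 or 3.
#' @param species Detected species (must be present in `consumption`).
#' @param consumption Consumption table (schema `"consumption"`).
#' @param tier1_rule,tier3_rule Aggregation rules, see above.
#' @return Intake, g/person/day.
#' @export
intake_for_tier <- function(tier, species, consumption,
                            tier1_rule = c("detected", "sum"),
                            tier3_rule = c("sum", "detected", "max")) {
  tier1_rule <- match.arg(tier1_rule)
  tier3_rule <- match.arg(tier3_rule)
  stopifnot(tier %in% 1:3)
  row <- consumption[consumption$species == species, , drop = FALSE]
  if (tier != 3 || tier3_rule == "detected") {
    if (nrow(row) != 1) {
      stop(sprintf("species '%s' not in consumption table", species),
           call. = FALSE)
    }
  }
  if (tier == 1) {
    if (tier1_rule == "detected") row$mean_intake
    else sum(consumption$mean_intake)
  } else if (tier == 2) {
    row$extreme_intake
  } else {
    switch(tier3_rule,
           sum = sum(consumption$extreme_intake),
           detected = row$extreme_intake,
           max = max(consumption$extreme_intake))
  }
}

#' Estimated daily intake
#'
#' `EDI = DFI x DPC`: g/person/day times ng/g gives ng/person/day.
#'
#' @param dfi Daily food intake, g/person/day; >= 0.
#' @param dpc Residue concentration, ng/g; >= 0.
#' @return EDI, ng/person/day.
#' @export
compute_edi <- function(dfi, dpc) {
  stopifnot(all(dfi >= 0), all(dpc >= 0))
  dfi * dpc
}

#' Hazard index: EDI as a percentage of the acceptable daily intake
#'
#' The per-person ADI budget is `adi` (mg/kg bw/day) x `body_weight` (kg)
#' x 1e6 (ng per mg), in ng/person/day; %ADI = EDI / budget x 100.  This
#' is the only unit conversion in the exposure chain.
#'
#' @param edi EDI, ng/person/day.
#' @param adi Acceptable daily intake, mg/kg bw/day; > 0.
#' @param body_weight Body weight, kg; > 0 (default 60, assumed average
#'   adult).
#' @return %ADI (percent).
#' @export
percent_adi <- function(edi, adi, body_weight = 60) {
  stopifnot(all(adi > 0), all(body_weight > 0), all(edi >= 0))
  edi / (adi * body_weight * 1e6) * 100
}

#' Run the nine exposure scenarios for one detected pesticide
#'
#' Crosses the three intake tiers with the three DPC estimators, in
#' tier-major order (1A, 1B, 1C, 2A, ..., 3C), assigning
#' `scenario_id = 3 * (tier - 1) + option_index`.  Scenarios using
#' options B or C with zero detections are emitted with status
#' `"not_evaluable"` and `NA` results.  Each evaluable scenario is
#' classified `"minimal"` when %ADI is strictly below the risk threshold
#' (default 10%, the conventional level below which dietary risk is
#' considered negligible), else `"concern"`.
#'
#' @param s A [detection_summary()].
#' @param consumption Consumption table (schema `"consumption"`).
#' @param tox One-row slice of a toxref table for the pesticide, or a
#'   full toxref table (the pesticide's row is selected).
#' @param config Configuration list from [load_config()].
#' @return Data frame of 9 rows: `pesticide`, `species`, `scenario_id`,
#'   `tier`, `dpc_option`, `dfi` (g/person/day), `dpc` (ng/g), `edi`
#'   (ng/person/day), `percent_adi` (%), `status`, `classification`.
#' @export
run_scenarios <- function(s, consumption, tox, config = load_config()) {
  stopifnot(inherits(s, "detection_summary"))
  if (nrow(tox) > 1) tox <- tox[tox$pesticide == s$pesticide, , drop = FALSE]
  if (nrow(tox) != 1) {
    stop(sprintf("no ADI reference for %s", s$pesticide), call. = FALSE)
  }
  bw <- if (!is.null(config$body_weight)) config$body_weight else
    tox$body_weight
  grid <- expand.grid(dpc_option = c("A", "B", "C"), tier = 1:3,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tier <- grid$tier[i]
    opt <- grid$dpc_option[i]
    id <- 3L * (tier - 1L) + match(opt, c("A", "B", "C"))
    evaluable <- opt == "A" || length(s$detections) > 0
    if (!evaluable) {
      return(data.frame(pesticide = s$pesticide, species = s$species,
                        scenario_id = id, tier = tier, dpc_option = opt,
                        dfi = NA_real_, dpc = NA_real_, edi = NA_real_,
                        percent_adi = NA_real_, status = "not_evaluable",
                        classification = NA_character_))
    }
    dpc <- switch(opt, A = dpc_option_a(s), B = dpc_option_b(s),
                  C = dpc_option_c(s))
    dfi <- intake_for_tier(tier, s$species, consumption,
                           tier1_rule = config$tier1_rule,
                           tier3_rule = config$tier3_rule)
    edi <- compute_edi(dfi, dpc)
    pa <- percent_adi(edi, tox$adi, bw)
    data.frame(pesticide = s$pesticide, species = s$species,
               scenario_id = id, tier = tier, dpc_option = opt,
               dfi = dfi, dpc = dpc, edi = edi, percent_adi = pa,
               status = "ok",
               classification = if (pa < config$risk_threshold) "minimal"
                                else "concern")
  })
  out <- do.call(rbind, rows)
  out[order(out$scenario_id), , drop = FALSE]
}

#' Impute missing consumption data from similar species
#'
#' Species absent from the national consumption survey receive half the
#' minimum mean and half the minimum extreme (99th percentile) intake
#' observed among similar species (default similarity: finfish /
#' crustacean / shellfish, see [similarity_group()]).
#'
#' @param consumption Consumption table in which rows to impute carry
#'   `NA` intakes.
#' @param groups Optional named character vector mapping species to
#'   similarity groups; defaults to [similarity_group()] of each species.
#' @return Completed consumption table with `imputed` flags set.
#' @export
impute_consumption <- function(consumption, groups = NULL) {
  if (is.null(groups)) {
    groups <- stats::setNames(similarity_group(consumption$species),
                              consumption$species)
  }
  grp <- unname(groups[consumption$species])
  gap <- is.na(consumption$mean_intake) | is.na(consumption$extreme_intake)
  if (!any(gap)) return(consumption)
  for (i in which(gap)) {
    peers <- which(!gap & grp == grp[i])
    if (!length(peers)) {
      stop(sprintf("no observed similar species for '%s' (group '%s')",
                   consumption$species[i], grp[i]), call. = FALSE)
    }
    consumption$mean_intake[i] <- min(consumption$mean_intake[peers]) / 2
    consumption$extreme_intake[i] <-
      min(consumption$extreme_intake[peers]) / 2
    consumption$imputed[i] <- TRUE
  }
  validate_table(consumption, "consumption")
  consumption
}

#' Summarise monitoring records into detection summaries
#'
#' Groups validated residue records by pesticide x species, counting
#' tests, collecting detected (uncensored) concentrations and resolving
#' the applicable LOQ via [lookup_limit()].  Integrity checks: duplicate
#' `sample_id` x `pesticide` rows error; a detected concentration below
#' its resolved LOQ errors (it should have been censored).
#'
#' @param records Residue records (schema `"residues"`).
#' @param limits Limits table (schema `"limits"`).
#' @return List of [detection_summary()] objects, one per pesticide x
#'   species combination present in `records`.
#' @export
detection_table <- function(records, limits) {
  key <- paste(records$sample_id, records$pesticide, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate sample_id x pesticide records", call. = FALSE)
  }
  groups <- split(records,
                  list(records$pesticide, records$species), drop = TRUE)
  out <- lapply(groups, function(g) {
    lim <- lookup_limit(limits, g$pesticide[1], g$species[1])
    det <- g$concentration[!g$censored]
    if (length(det) && any(det < lim$loq)) {
      stop(sprintf("detected %s in %s below the applicable LOQ (%g ng/g)",
                   g$pesticide[1], g$species[1], lim$loq), call. = FALSE)
    }
    detection_summary(g$pesticide[1], g$species[1], n_tests = nrow(g),
                      detections = det, loq = lim$loq)
  })
  names(out) <- vapply(out, function(s) paste(s$pesticide, s$species,
                                              sep = " / "), "")
  out[order(names(out))]
}
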