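lufenuron_case <- function() {
  detection_summary("Lufenuron", "Eel", n_tests = 20, detections = 10,
                    loq = 5)
}

test_that("DPC estimators follow their censoring conventions", {
  s <- lufenuron_case()
  expect_equal(dpc_option_a(s), 5.25)    # (10 + 19 x 5) / 20
  expect_equal(dpc_option_b(s), 10)
  expect_equal(dpc_option_c(s), 10)

  none <- detection_summary("Lufenuron", "Eel", n_tests = 20, loq = 5)
  expect_equal(dpc_option_a(none), 5)    # all-censored collapses to the LOQ
  expect_error(dpc_option_b(none), "zero detections")
  expect_error(dpc_option_c(none), "zero detections")

  full <- detection_summary("Lufenuron", "Eel", n_tests = 20,
                            detections = rep(10, 20), loq = 5)
  expect_equal(dpc_option_a(full), 10)

  two <- detection_summary("Lufenuron", "Eel", n_tests = 20,
                           detections = c(8, 12), loq = 5)
  expect_equal(dpc_option_b(two), 10)
  expect_equal(dpc_option_c(two), 12)

  expect_error(detection_summary("Lufenuron", "Eel", detections = 3,
                                 loq = 5), ">= the LOQ")
})

test_that("intake tiers resolve from the consumption table", {
  cons <- consumption_table()
  expect_equal(intake_for_tier(2, "Eel", cons), 24.24)
  expect_equal(intake_for_tier(1, "Eel", cons), 1.32)
  expect_equal(intake_for_tier(3, "Eel", cons), 320.85)
  expect_equal(intake_for_tier(1, "Eel", cons, tier1_rule = "sum"), 11.55)
  expect_equal(intake_for_tier(3, "Eel", cons, tier3_rule = "max"), 50.4)
  expect_equal(intake_for_tier(3, "Eel", cons, tier3_rule = "detected"),
               24.24)
  expect_error(intake_for_tier(2, "Tuna", cons), "not in consumption")
})

test_that("EDI and %ADI arithmetic and units", {
  expect_equal(compute_edi(24.24, 5.25), 127.26)
  expect_equal(compute_edi(24.24, 10), 242.4)
  expect_equal(compute_edi(0, 99), 0)
  # ADI x bw x 1e6 converts mg/kg bw/day to a ng/person/day budget
  expect_equal(percent_adi(127.26, 0.015, 60), 0.01414)
  expect_equal(round(percent_adi(242.4, 0.015, 60), 4), 0.0269)
  expect_equal(percent_adi(0.015 * 60 * 1e6, 0.015, 60), 100)
})

test_that("nine scenarios reproduce the published tier-2 hazard indices", {
  rr <- run_scenarios(lufenuron_case(), consumption_table(), toxref_table())
  expect_equal(nrow(rr), 9)
  expect_equal(rr$scenario_id, 1:9)
  expect_equal(rr$tier, rep(1:3, each = 3))
  expect_equal(rr$dpc_option, rep(c("A", "B", "C"), 3))
  expect_equal(round(rr$percent_adi[rr$scenario_id == 4], 4), 0.0141)
  expect_equal(round(rr$percent_adi[rr$scenario_id == 6], 4), 0.0269)
  # a single detection makes the detections-mean equal the maximum
  expect_equal(rr$percent_adi[rr$scenario_id == 5],
               rr$percent_adi[rr$scenario_id == 6])
  expect_true(all(rr$classification == "minimal"))
  expect_true(all(rr$percent_adi < 10))
})

test_that("zero-detection summaries report B/C as not evaluable", {
  none <- detection_summary("Lufenuron", "Eel", n_tests = 20, loq = 5)
  rr <- run_scenarios(none, consumption_table(), toxref_table())
  expect_equal(rr$status[rr$dpc_option == "A"], rep("ok", 3))
  expect_equal(rr$status[rr$dpc_option != "A"], rep("not_evaluable", 6))
  expect_true(all(is.na(rr$percent_adi[rr$dpc_option != "A"])))
})

test_that("risk threshold drives the classification", {
  cfg <- load_config()
  cfg$risk_threshold <- 0.01
  rr <- run_scenarios(lufenuron_case(), consumption_table(), toxref_table(),
                      cfg)
  expect_equal(rr$classification[rr$scenario_id == 4], "concern")
  expect_equal(rr$classification[rr$scenario_id == 1], "minimal")
})

test_that("consumption imputation halves group minima", {
  cons <- consumption_table()
  gap <- cons
  fill <- gap$imputed
  gap$mean_intake[fill] <- NA
  gap$extreme_intake[fill] <- NA
  done <- impute_consumption(gap)
  # observed finfish minima: mean 0.96, extreme 24.24 -> halves
  expect_equal(unique(done$mean_intake[fill]), 0.48)
  expect_equal(unique(done$extreme_intake[fill]), 12.12)
  expect_true(all(done$imputed[fill]))
  expect_identical(done, cons)

  # single observed member in the group
  solo <- data.frame(species = c("Eel", "Carp"),
                     mean_intake = c(2, NA), extreme_intake = c(20, NA),
                     imputed = c(FALSE, FALSE))
  out <- impute_consumption(solo)
  expect_equal(out$mean_intake[2], 1)
  expect_equal(out$extreme_intake[2], 10)

  expect_identical(impute_consumption(cons), cons)  # no gaps -> identity

  orphan <- data.frame(species = c("Abalone", "Eel"),
                       mean_intake = c(NA, 2), extreme_intake = c(NA, 20),
                       imputed = FALSE)
  expect_error(impute_consumption(orphan), "no observed similar species")
})

test_that("detection_table summarises the packaged survey", {
  recs <- monitoring_table()
  limits <- limits_from_validation()
  det <- detection_table(recs, limits)
  expect_equal(length(det), 15)   # lufenuron x 15 species
  n_det <- vapply(det, function(s) length(s$detections), 0L)
  expect_equal(sum(n_det), 1)
  s <- det[["Lufenuron / Eel"]]
  expect_equal(s$n_tests, 20L)
  expect_equal(s$detections, 10)
  expect_equal(s$loq, 5)

  expect_error(detection_table(rbind(recs, recs[1, ]), limits), "duplicate")

  low <- recs
  low$concentration[1] <- 1
  low$censored[1] <- FALSE
  expect_error(detection_table(low, limits), "below the applicable LOQ")
})

test_that("estimator ordering and monotonicity hold on random summaries", {
  set.seed(99)
  for (i in 1:1000) {
    s <- random_summary()
    a <- dpc_option_a(s)
    if (length(s$detections)) {
      expect_lte(a, max(s$loq, dpc_option_c(s)))
      expect_lte(dpc_option_b(s), dpc_option_c(s))
    } else {
      expect_equal(a, s$loq)
    }
  }
  # %ADI strictly decreasing in body weight and ADI, nondecreasing in
  # DFI and DPC
  expect_lt(percent_adi(100, 0.015, 70), percent_adi(100, 0.015, 60))
  expect_lt(percent_adi(100, 0.02, 60), percent_adi(100, 0.015, 60))
  expect_lte(compute_edi(10, 5), compute_edi(11, 5))
  expect_lte(compute_edi(10, 5), compute_edi(10, 6))
})
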