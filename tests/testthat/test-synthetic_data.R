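test_that("monitoring generator honours degenerate detection regimes", {
  spec0 <- generator_spec(seed = 1, pesticides = "Lufenuron", plant = NULL,
                          detection_prob = 0)
  all_cens <- generate_monitoring(spec0)
  expect_equal(nrow(all_cens), 300)    # 15 species x 20 samples
  expect_true(all(all_cens$censored))

  spec1 <- generator_spec(seed = 1, pesticides = "Lufenuron", plant = NULL,
                          detection_prob = 1, conc_median = 10,
                          conc_gsd = 1, loq = 5)
  all_det <- generate_monitoring(spec1)
  expect_true(all(!all_det$censored))
  expect_true(all(all_det$concentration == 10))
})

test_that("default generator reproduces the survey outcome", {
  df <- generate_monitoring(generator_spec())
  expect_equal(nrow(df), 15 * 20 * 24)
  hit <- df[!df$censored, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$species, "Eel")
  expect_equal(hit$pesticide, "Lufenuron")
  expect_equal(hit$concentration, 10)
})

test_that("a fixed seed gives identical output; detections are binomial", {
  spec <- generator_spec(seed = 77, species = "Eel",
                         pesticides = "Lufenuron", plant = NULL,
                         detection_prob = 1 / 20, conc_median = 10,
                         conc_gsd = 1.5, loq = 5)
  expect_identical(generate_monitoring(spec), generate_monitoring(spec))
  expect_identical(generate_validation(spec), generate_validation(spec))
  expect_identical(generate_calibration(spec), generate_calibration(spec))

  # detections per 20-sample species ~ Binomial(20, 1/20): mean 1,
  # variance 20 x (1/20) x (19/20) = 0.95; check the empirical mean over
  # many seeds against 3 standard errors
  n_seeds <- 10000
  counts <- vapply(seq_len(n_seeds), function(sd) {
    sum(!generate_monitoring(generator_spec(
      seed = sd, species = "Eel", pesticides = "Lufenuron", plant = NULL,
      detection_prob = 1 / 20))$censored)
  }, 0L)
  se <- sqrt(0.95 / n_seeds)
  expect_lt(abs(mean(counts) - 1), 3 * se)
  # detected concentrations respect the LOQ truncation
  det <- generate_monitoring(generator_spec(
    seed = 3, species = "Eel", pesticides = "Lufenuron", plant = NULL,
    detection_prob = 1, conc_median = 4, conc_gsd = 2, loq = 5))
  expect_true(all(det$concentration >= 5))
})

test_that("validation generator: noiseless identity and truncation", {
  spec <- generator_spec(seed = 5, pesticides = "Lufenuron",
                         recovery_true = 90, recovery_cv = 0)
  runs <- generate_validation(spec)
  expect_equal(nrow(runs), 15)  # 3 levels x 5 replicates
  for (g in split(runs, runs$level_class)) {
    expect_equal(compute_recovery(g$spike_level[1], g$measured)$recovery_mean,
                 90)
  }
  expect_equal(attr(runs, "n_truncated"), 0)

  # absurd CV forces negative draws; they are clamped at 0 and counted
  noisy <- generate_validation(generator_spec(seed = 5,
                                              pesticides = "Lufenuron",
                                              recovery_cv = 200))
  expect_true(all(noisy$measured >= 0))
  expect_gt(attr(noisy, "n_truncated"), 0)
})

test_that("calibration generator hits the planted slope ratio", {
  spec <- generator_spec(seed = 9, pesticides = "Lufenuron",
                         matrix_factor = 1.25, response_noise_sd = 0)
  cal <- generate_calibration(spec)
  fits <- lapply(split(cal, cal$matrix_label), function(g) {
    fit_calibration(g$level, g$response, pesticide = g$pesticide[1],
                    matrix_label = g$matrix_label[1])
  })
  expect_equal(fits[["solvent"]]$r_squared, 1)
  expect_equal(fits[["matrix:Eel"]]$r_squared, 1)
  me <- matrix_effect(fits[["matrix:Eel"]], fits[["solvent"]])
  expect_equal(me$me, 25)
  expect_equal(me$category, "medium")

  expect_equal(calibration_level_grid(3),
               c(0.25, 0.75, 1.5, 3.75, 7.5, 12, 15))
  expect_error(calibration_level_grid(6), "no calibration grid")
})

test_that("ground-truth manifest mirrors the generator parameters", {
  gt <- ground_truth(generator_spec())
  expect_equal(gt$n_species, 15)
  expect_equal(gt$n_pesticides, 24)
  expect_equal(gt$plant_pesticide, "Lufenuron")
  expect_equal(gt$plant_concentration, 10)
})
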