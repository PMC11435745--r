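# Independent oracles: deliberately written as plain loops / normal
# equations, sharing no code with the package's implementation paths.

# Ordinary least squares via the normal equations, plus R^2.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

# Brute-force nine-scenario enumeration from first principles.
oracle_scenarios <- function(detections, loq, n_tests, species, consumption,
                             adi, bw, tier1_rule = "detected",
                             tier3_rule = "sum") {
  out <- data.frame()
  row <- which(consumption$species == species)
  for (tier in 1:3) {
    for (oi in 1:3) {
      opt <- c("A", "B", "C")[oi]
      if (opt == "A") {
        dpc <- (sum(detections) + loq * (n_tests - length(detections))) /
          n_tests
      } else if (length(detections) == 0) {
        dpc <- NA_real_
      } else if (opt == "B") {
        dpc <- sum(detections) / length(detections)
      } else {
        dpc <- detections[1]
        for (d in detections) if (d > dpc) dpc <- d
      }
      dfi <- if (tier == 1) {
        if (tier1_rule == "detected") consumption$mean_intake[row]
        else sum(consumption$mean_intake)
      } else if (tier == 2) {
        consumption$extreme_intake[row]
      } else {
        if (tier3_rule == "sum") sum(consumption$extreme_intake)
        else if (tier3_rule == "max") max(consumption$extreme_intake)
        else consumption$extreme_intake[row]
      }
      edi <- dfi * dpc
      out <- rbind(out, data.frame(
        scenario_id = 3 * (tier - 1) + oi, tier = tier, dpc_option = opt,
        dfi = dfi, dpc = dpc, edi = edi,
        percent_adi = edi / (adi * bw * 1e6) * 100))
    }
  }
  out
}

# Random detection summary for property tests.
random_summary <- function(loq_range = c(0.5, 10)) {
  n_tests <- sample(1:30, 1)
  k <- sample(0:n_tests, 1)
  loq <- stats::runif(1, loq_range[1], loq_range[2])
  detection_summary("Lufenuron", "Eel", n_tests = n_tests,
                    detections = loq + stats::rexp(k, rate = 0.2), loq = loq)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
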