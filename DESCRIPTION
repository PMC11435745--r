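Package: residuerisk
Title: Method Validation and Dietary Risk Assessment for Pesticide
    Residues in Fishery Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multiresidue pesticide monitoring data in
    fishery products: Codex-style method-validation statistics (spike
    recovery, relative standard deviation, matrix-matched calibration
    linearity, matrix effect, signal-to-noise scaled limits of detection
    and quantification), censoring-aware summarisation of residue surveys
    in which most samples fall below the limit of quantification, and a
    nine-scenario estimated-daily-intake / percent-of-ADI dietary risk
    assessment combining three residue-concentration estimators with three
    food-consumption tiers.  Ships national food-consumption and
    method-performance reference tables as plain-text fixtures and a
    seeded synthetic-data generator that reproduces the structure of a
    national monitoring survey (15 species, 20 samples each, 24 analytes)
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
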