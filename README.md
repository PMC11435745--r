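# residuerisk

Method validation and dietary risk assessment for multiresidue pesticide
monitoring in fishery products.

National residue surveys of farmed fish share an awkward statistical
shape: dozens of analytes screened across many species, and almost every
measurement censored below the limit of quantification (LOQ). This
package is for analysts who must answer the two questions such surveys
pose — *is the analytical method fit for purpose?* and *what fraction of
the acceptable daily intake could consumers be exposed to, given the few
detections?* — with auditable, tested code rather than spreadsheet
arithmetic.

## What it computes

**Method validation** (Codex acceptance windows for multiresidue
analysis):

- spike recovery `mean(x)/spike × 100` and precision
  `%RSD = sd(x)/mean(x) × 100` (sample SD), pass window 70–120 % and
  ≤ 20 %;
- matrix-matched calibration by ordinary least squares, pass at
  R² > 0.98;
- matrix effect as the slope ratio
  `ME = (b_matrix/b_solvent − 1) × 100`, with |ME| ≤ 20 % minimal,
  > 50 % strong;
- LOD/LOQ by linear signal-to-noise scaling to S/N = 3 and 10.

**Exposure assessment** — nine scenarios crossing three censoring-aware
residue estimators (DPC) with three consumption tiers (DFI):

```
EDI (ng/person/day) = DFI (g/person/day) × DPC (ng/g)
%ADI = EDI / (ADI × bw × 10^6) × 100
```

DPC options: **A** substitutes the LOQ for non-detects,
`(Σ detections + LOQ·n_censored)/n_tests`; **B** averages detections
only; **C** takes the maximum detection. Tiers: **1** average consumer,
**2** extreme (99th-percentile) consumer of the detected species,
**3** extreme consumer across species. %ADI below 10 % is classified as
minimal risk (FAO/WHO convention).

The package ships the national consumption table (KNHANES 2017–2021,
15 species), the per-matrix method-performance table, an
extraction-method comparison table, a toxicological reference, and a
synthetic reconstruction of the 300-sample monitoring survey, all as
plain CSV under `inst/extdata/`. A seeded generator
(`generator_spec()`, `generate_monitoring()`, `generate_validation()`,
`generate_calibration()`) reproduces the survey's structure with known
ground truth.

## Worked example

One lufenuron detection at 10 ng/g among 20 eel samples (LOQ 5 ng/g),
extreme eel intake 24.24 g/person/day, ADI 0.015 mg/kg bw/day, 60 kg
body weight:

```r
library(residuerisk)

rr <- risk_report(monitoring_table(), limits_from_validation(),
                  consumption_table(), toxref_table())
rr$report[rr$report$tier == 2,
          c("scenario_id", "dpc_option", "dfi", "dpc", "edi", "percent_adi")]
#>   scenario_id dpc_option   dfi   dpc    edi percent_adi
#> 4           4          A 24.24  5.25 127.26  0.01414000
#> 5           5          B 24.24 10.00 242.40  0.02693333
#> 6           6          C 24.24 10.00 242.40  0.02693333
cat(rr$headline)
#> Maximum %ADI 0.3565% (Lufenuron in Eel, scenario 8, tier 3 option B): minimal risk.
```

Scenario 4 reads: even an extreme eel consumer, with every non-detect
counted at the LOQ, ingests 127.26 ng/day — 0.0141 % of the acceptable
daily intake. The worst case across all nine scenarios (0.3565 %) stays
far below the 10 % minimal-risk threshold.

The full workflow is scripted as a sequence of analysis drivers:

```sh
Rscript analysis/01_simulate.R          # synthetic survey + experiments
Rscript analysis/02_method_validation.R # Codex grading + published ranges
Rscript analysis/03_monitoring.R        # censoring-aware detection summary
Rscript analysis/04_risk_assessment.R   # nine-scenario %ADI report
```

Each stage prints what it found and writes its tables under `results/`.

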