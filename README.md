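# gastricus

Point-of-care gastric ultrasound (GUS) analysis for emergency abdominal
surgery cohorts.

After emergency abdominal surgery, postoperative nausea and vomiting and
postoperative ileus are common, and deciding who needs a nasogastric tube or
antiemetics is mostly guesswork. Bedside ultrasound of the gastric antrum
gives a measurable handle: the antral cross-sectional area (CSA), imaged
semi-recumbent ("supine") and in right lateral decubitus (RLD), predicts
gastric content type and volume. `gastricus` implements the full analysis
pipeline for such cohorts, for clinical researchers evaluating GUS as a
perioperative triage tool:

* **Antrum metrics** — ellipse CSA from two perpendicular diameters,
  `CSA (cm²) = (D1/10)·(D2/10)·π/4`, and the Perlas gastric-volume model
  `V (mL) = 27.0 + 14.6·CSA_RLD − 1.28·age`, with physically impossible
  negative predictions clamped to 0 and flagged.
* **Grading and risk** — the three-level antral grade (G0 no fluid / G1
  fluid in RLD only / G2 fluid in both) and the Van de Putte–Perlas
  aspiration-risk flowchart: solid content, grade-2 fluid, or predicted
  volume > 1.5 mL/kg ⇒ high risk; patient-level aggregation and a
  confusion summary against adverse outcomes.
* **Cohort statistics** — detection rates per scan or per patient with
  arbitrary stratification, uncorrected Pearson chi-squared tests on 2×2
  tables, pooled Student t-tests, median/IQR descriptives.
* **Trajectories** — relative CSA series (CSA_x/CSA_0 vs postoperative
  day) and their pooled linear regression.
* **Synthetic cohorts** — a seeded generator with the statistical
  structure of a real emergency-surgery GUS cohort, plus a deterministic
  results-like fixture whose marginal counts are exact by construction.
* **Pipeline** — `run_simulate()` / `run_assess()` / `run_stats()` /
  `run_trajectory()` over CSV cohort files, each writing a run manifest;
  a thin CLI wrapper lives at `inst/cli/gastricus.R`.

## Worked example

```r
library(gastricus)

fx <- results_fixture()            # deterministic 41-patient, 94-scan cohort

detection_rate(fx)                 # antrum seen in either position
#> $numerator   62
#> $denominator 94
#> $fraction    0.6595745           # 66.0% of scans

# laparoscopic vs open access, per patient: 15/19 vs 7/22
chi_squared_2x2(15, 4, 7, 15)
#> Pearson chi-squared (uncorrected): statistic = 9.1068, df = 1, p = 0.002547

# risk flowchart on one scan (patient F01, POD 3: liquid in both positions)
scan <- fx$scans[fx$scans$patient_id == "F01" & fx$scans$pod %in% 3, ]
pat  <- fx$patients[fx$patients$patient_id == "F01", ]
classify_risk(scan, pat)
#> $grade "G2"  $volume_ml 102.4  $volume_ml_per_kg 1.14
#> $risk "high"  $fired_rule "grade2_fluid"

# sensitivity of the flowchart in the 18-patient major-surgery subgroup
sub  <- major_surgery_subgroup(fx)
conf <- prediction_confusion(assess_cohort(sub)$patients, sub$patients)
conf$prediction_rate_pct
#> 16.66667                          # 1 of 6 adverse patients flagged

# relative CSA trajectory of the adverse patients
fit_trajectory(cohort_trajectory_points(fx, "measured", adverse_only = TRUE))
#> Relative-CSA trajectory: slope = 0.1667 /day, intercept = 0.8333, R^2 = 1.0000 (n = 24)
```

The example reads: two thirds of scans visualize the antrum, detection
depends strongly on surgical access (p ≈ 0.003), the preoperative
aspiration-risk flowchart catches only 1 of 6 patients who go on to adverse
outcomes, and in those patients the antrum dilates ~17% of baseline per day
(+50% over 72 h) — which is why a relative CSA threshold, not the absolute
flowchart, is the promising predictor of postoperative ileus.

A quantitative one-liner:

```r
predicted_gastric_volume(5, 50, weight_kg = 72)
#>   volume_ml volume_ml_per_kg clamped
#> 1        36              0.5   FALSE
```

See `vignettes/gastric-ultrasound-methods.Rmd` for the models, the decision
rules, every tunable parameter of the generator, and the package's design
decisions.

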