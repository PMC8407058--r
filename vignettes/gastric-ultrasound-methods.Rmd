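---
title: "Gastric ultrasound cohort analysis: models, decision rules and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gastric ultrasound cohort analysis: models, decision rules and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastricus)
```

## The clinical problem

Postoperative nausea and vomiting (PONV) and postoperative ileus (POI) are
frequent after emergency abdominal surgery, and the usual remedies —
prophylactic nasogastric tubes, empirical antiemetics — are blunt. Bedside
gastric ultrasound (GUS) of the antrum offers a measurable proxy for gastric
content and volume: the antral cross-sectional area (CSA), imaged in the
epigastrium with the patient semi-recumbent (here called "supine") and in
right lateral decubitus (RLD). `gastricus` implements the quantitative
models, the qualitative grading, the aspiration-risk decision rule, and the
cohort statistics used to evaluate this technique in emergency-surgery
cohorts, together with a seeded synthetic-cohort generator so that the whole
pipeline can be exercised, calibrated and stress-tested without patient
data.

## Quantitative models

**Antral CSA from diameters.** The antrum is treated as an ellipse with
axes equal to the anteroposterior (D1) and craniocaudal (D2) diameters,
measured serosa-to-serosa in millimetres:

$$\mathrm{CSA}\ (\mathrm{cm^2}) = \frac{D_1}{10}\cdot\frac{D_2}{10}\cdot\frac{\pi}{4}.$$

Diameters are stored in mm (the unit in which they are reported clinically)
and converted internally, so `csa_from_diameters(20, 20)` is the area of a
2 cm circle, `r round(pi, 4)` cm². The traced CSA from the ultrasound
machine's planimetry ("measured") is stored separately and never conflated
with the diameter-derived value ("calculated").

**Predicted gastric volume.** Perlas' linear model maps RLD CSA and age to
total gastric volume:

$$V\ (\mathrm{mL}) = 27.0 + 14.6\,\mathrm{CSA_{RLD}} - 1.28\,\mathrm{age}.$$

Only the RLD CSA is a valid predictor here; `predicted_gastric_volume()`
never substitutes a supine measurement. The model is linear and can go
negative for small antra in elderly patients; since a negative gastric
volume is physically meaningless, such predictions are clamped to 0 mL and
flagged (`clamped = TRUE`). Risk thresholding uses the weight-normalized
volume in mL/kg.

## Grading and the aspiration-risk flowchart

The three-level antral grade scores fluid by position: G0 — no fluid in
either position; G1 — fluid only in RLD; G2 — fluid in both. "Fluid-
bearing" content is `liquid` or `mixed`. Two edge cases needed decisions:

* *Unknown supine, fluid in RLD.* Reported as **G1**, the minimum grade
  consistent with the observation, rather than indeterminate. This keeps
  the volume branch of the risk rule evaluable; G2 cannot be asserted, and
  the high-risk decision never depends on the difference.
* *Fluid in supine but not in RLD.* Physiologically anomalous (fluid pools
  dependently) and outside the grading system's definitions; reported
  **indeterminate**. Because of this cell, the "more fluid never lowers the
  grade" monotonicity holds on the determinate part of the lattice, which
  is what the test suite asserts.

The Van de Putte–Perlas flowchart is implemented in `classify_risk()` with
a fixed branch order: (1) solid-bearing content (`solid` or `mixed`) in
either position → high; (2) grade 2 → high; (3) predicted volume strictly
greater than 1.5 mL/kg → high; (4) low only when *all three* branches were
evaluable and negative; anything else is indeterminate. Treating `mixed`
under the solid branch is a deliberate choice — mixed content contains
solid matter — and the threshold comparison is strict, so exactly
1.5 mL/kg is not high risk. Missing data is an outcome, never an error: a
scan with an unknown position cannot certify the absence of solid or of
grade-2 fluid, so it can be called high (e.g. by the volume branch) but
never low.

Patient-level aggregation (`assess_cohort()`): high if any postoperative
scan is high; indeterminate if every scan is indeterminate; otherwise low.
Outcome adjudication is postoperative, so preoperative high scans alone do
not label a patient high. `prediction_confusion()` cross-tabulates the
patient labels against the composite adverse outcome (nausea/vomiting,
antiemetics, delayed return of bowel function, or NGT placement); the
prediction rate is the sensitivity, with indeterminate patients counted
separately and excluded from the denominator.

## Cohort statistics

Detection rates are computed per scan (denominator = scans) or per patient
(denominator = patients; a patient counts as detected if the antrum was
seen in any position of any scan). The per-patient convention is used for
the surgical-access comparison, whose denominators are patient counts.

Categorical comparisons use the **uncorrected** Pearson chi-squared
statistic on 2×2 tables, $X^2 = n(ad-bc)^2 /((a{+}b)(c{+}d)(a{+}c)(b{+}d))$
on 1 df. The continuity-corrected statistic systematically fails to
reproduce the p-values that the uncorrected one yields on the detection
tables this package targets, so the uncorrected form is the package
convention; a zero marginal returns statistic 0 and p = 1 with a warning.
Numerical comparisons use the pooled-variance two-tailed Student t-test
(`var_equal = FALSE` switches to Welch, not the default). Descriptives are
median and IQR with linear-interpolation quartiles (`quantile type 7`),
plus mean and n−1 SD. The position comparison (supine vs RLD detection) is
performed as an unpaired test on the two marginal rates even though the
underlying observations are paired; a McNemar-style paired analysis would
need the discordant-pair counts, which the reported marginals do not
determine.

## Relative-CSA trajectories

Because antral size is strongly anatomy-dependent, postoperative dynamics
are analysed on the relative scale $\mathrm{CSA}_x/\mathrm{CSA}_0$, where
$\mathrm{CSA}_0$ is the value on the first postoperative day (POD 1). When
POD 1 has no usable value — detection fails in roughly a third of scans —
the baseline falls back to the earliest available postoperative scan;
without that fallback a large fraction of patients would be unusable. The
baseline point (ratio exactly 1) is included in the regression by default
(`include_baseline = FALSE` to drop it). The fit is a single pooled OLS
regression of ratio on POD across patients, because a single slope and R²
per CSA source is the quantity of clinical interest; per-patient series are
available from `relative_csa_series()`. R² is reported as `NA` when the
ratios have zero variance. RLD is the default position, as the position in
which CSA tracks volume.

## The synthetic-cohort generator

`generate_cohort()` emulates the *statistical* structure of an
emergency-surgery GUS cohort; it does not model gastric physiology
(emptying kinetics, content dynamics). Defaults, all overridable in
`cohort_config()`:

* **Cohort shape.** 41 patients; a preoperative scan with probability
  28/41; 1–2 postoperative scans on consecutive PODs for uneventful
  patients and 4 (PODs 1–4) for adverse ones, who are followed through the
  72-h window of interest. Generated cohorts therefore carry somewhat more
  postoperative scans per patient than a typical opportunistic clinical
  series.
* **Detection.** Bernoulli per position given surgical access: 0.318 open,
  0.789 laparoscopic, 0.66 other — surgical wounds and scars shadow the
  epigastric window, so access drives sensitivity. With probability
  `detection_concordance` (default 0.85) both positions share one draw;
  this leaves the marginal rates untouched while reproducing the high
  supine/RLD agreement seen clinically. Concordance and the per-patient
  scan-count distribution are documented guesses: cohort reports print
  marginal rates only.
* **Content.** Conditional on detection: empty 0.71, liquid 0.20, mixed
  0.06, solid 0.03. Undetected positions carry `unknown` content and no
  measurements.
* **CSA.** Lognormal (positive, right-skewed), parameterized by arithmetic
  mean and log-SD: preoperative mean 4.93 cm², postoperative 6.92 cm²,
  `sdlog = 0.38` — the log-SD implied by reported IQR/median ratios of
  traced CSA (≈0.34–0.42). Adverse patients instead get a patient-level
  baseline scaled so their postoperative mean is 12.95 cm², multiplied by
  a trajectory $1 + s\,(\mathrm{POD}-1) + \varepsilon$ with
  $s = 1/6$ per day (+50% over 72 h) and $\varepsilon \sim N(0, 0.1)$.
  The traced CSA adds a ×1.1 bias and 8% lognormal noise relative to the
  diameter-derived value, mirroring the tendency of planimetry to read
  slightly larger than the ellipse approximation.
* **Outcome.** Adverse fraction 1/3.

What passing tests on generated data do **not** show: robustness to
informative missingness (here detection is independent of CSA given
access), to non-lognormal CSA shapes, to within-patient correlation beyond
the adverse baseline factor, or to any real relationship between content
type and volume. Those are properties of real cohorts the generator does
not attempt to encode.

`results_fixture()` is different in kind: a fully deterministic 41-patient
/ 94-scan cohort built by explicit counting so that its detection
fractions (62/94, 59/94, 57/94, 16/28, 46/66; 15/19 and 7/22 per patient),
grade distribution (34/5/16/39) and subgroup structure (18 major-surgery
patients, 6 adverse, exactly one flagged by the flowchart → 16.7%
sensitivity) are exact regardless of RNG. Only those counts are faithful;
its individual ages, weights and CSA values are invented plausible numbers,
and the file writer labels it synthetic.

## Numerical and testing choices

Problem sizes in the test suite were chosen to make Monte-Carlo noise small
relative to the property being asserted: type-I error calibration uses
10⁴ replicates of 150-per-stratum binomial nulls (chi-squared) and
20-per-arm Gaussian nulls (t-test); slope recovery uses 200 six-patient
adverse cohorts; the subgroup power property uses 500 eighteen-patient
cohorts. The permutation cross-check of the chi-squared p-value exploits
the fact that conditioning a 2×2 table on both margins makes the
permutation null hypergeometric in a single cell, so it can be sampled
directly with `rhyper`; agreement to three decimals is only meaningful
where the null's discreteness atom is below ~10⁻³, hence that check runs on
large balanced tables (n = 10⁷) — on small clinical tables the permutation
p sits visibly above the asymptotic one because of the atom at the observed
statistic.

Randomness is always injected through explicit seeds (`cohort_config(seed =
...)`, or the `--seed` of `scripts/acceptance.R`); no function consumes
hidden RNG state silently. CSV serialization writes booleans as
`true`/`false` and absent optionals as empty cells, and `read_cohort()` ∘
`write_cohort()` is the identity on valid cohorts.

## Limitations

* The flowchart's handling of `mixed` content and of partially unknown
  scans is a package decision; source descriptions of the rule name only
  "solid contents" and grade 2.
* The pooled trajectory regression ignores within-patient correlation of
  ratios; with few, short series a mixed-effects model would be fragile,
  but for larger cohorts `lme4` on the points table is the natural
  extension.
* The generator's adverse group differs from the uneventful group in CSA
  level and trajectory only; it encodes no causal link between gastric
  distension and the outcome flag beyond that marginal difference.
* Reported R² values for relative-CSA regressions depend on the underlying
  per-scan data; on synthetic cohorts they are meaningful only relative to
  the generator's own noise settings.
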