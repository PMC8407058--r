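Package: gastricus
Title: Point-of-Care Gastric Ultrasound Analysis for Emergency Surgery Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing point-of-care gastric ultrasound (GUS)
    examinations of the gastric antrum in patients undergoing emergency
    abdominal surgery. Implements antral cross-sectional area (CSA)
    estimation from perpendicular diameters, the Perlas age-adjusted
    gastric-volume model, the three-level antral grading system, and the
    Van de Putte-Perlas aspiration-risk flowchart (volume per kg, grade 2
    fluid, or solid content). Provides cohort-level statistics (detection
    rates with stratification, uncorrected Pearson chi-squared tests on
    2x2 tables, pooled two-sample Student t-tests, median/IQR summaries),
    relative antral CSA trajectory regression against postoperative day,
    a seeded synthetic-cohort generator for method evaluation, and a
    small command-line pipeline over CSV cohort files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
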