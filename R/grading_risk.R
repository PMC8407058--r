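## Qualitative grading and the Van de Putte-Perlas aspiration-risk flowchart.

is_fluid <- function(content) content %in% c("liquid", "mixed")
is_solid_bearing <- function(content) content %in% c("solid", "mixed")

#' Antral grade from per-position content
#'
#' The three-level grading system scores gastric fluid by position:
#' grade 0 = no fluid in either supine or right lateral decubitus (RLD),
#' grade 1 = fluid in RLD only, grade 2 = fluid in both positions.
#' "Fluid-bearing" content is `liquid` or `mixed`. When the content of a
#' position needed to decide is `unknown` (typically an undetected antrum)
#' the grade is `indeterminate`, with one deliberate exception: unknown
#' supine content with fluid in RLD is reported as `G1`, the minimum grade
#' consistent with the observation, so downstream volume assessment can
#' still run. Fluid seen in supine but not in RLD falls outside the grading
#' system's definitions and is reported `indeterminate`.
#'
#' @param supine_content,rld_content content class per position: one of
#'   `empty`, `liquid`, `solid`, `mixed`, `unknown`. Vectorized.
#' @return Character vector in `c("G0", "G1", "G2", "indeterminate")`.
#' @examples
#' antral_grade("empty", "liquid")  # G1
#' antral_grade("liquid", "liquid") # G2
#' @export
antral_grade <- function(supine_content, rld_content) {
  supine_content <- as.character(supine_content)
  rld_content <- as.character(rld_content)
  bad <- c(setdiff(supine_content, gus_content_levels),
           setdiff(rld_content, gus_content_levels))
  if (length(bad) || anyNA(supine_content) || anyNA(rld_content)) {
    gus_domain_error(sprintf("invalid content value: %s",
                             paste(unique(c(bad, NA)), collapse = ", ")))
  }
  n <- max(length(supine_content), length(rld_content))
  supine_content <- rep_len(supine_content, n)
  rld_content <- rep_len(rld_content, n)
  su_known <- supine_content != "unknown"
  rl_known <- rld_content != "unknown"
  su_fluid <- is_fluid(supine_content)
  rl_fluid <- is_fluid(rld_content)
  grade <- rep("indeterminate", n)
  grade[su_known & rl_known & !su_fluid & !rl_fluid] <- "G0"
  grade[su_known & rl_known & !su_fluid & rl_fluid] <- "G1"
  grade[su_fluid & rl_fluid] <- "G2"
  # unknown supine + fluid RLD: at least grade 1, reported G1
  grade[!su_known & rl_fluid] <- "G1"
  grade
}

#' Resolve the RLD CSA used for volume prediction
#'
#' Prefers the traced (machine-measured) CSA; falls back to the ellipse
#' formula when both RLD diameters are recorded; `NA` otherwise.
#' @param scan one scan record (list or one-row data.frame).
#' @return RLD CSA in cm^2 or `NA`.
#' @keywords internal
scan_rld_csa <- function(scan) {
  if (!is.na(scan$rld_csa_cm2)) return(as.numeric(scan$rld_csa_cm2))
  if (!is.na(scan$rld_d1_mm) && !is.na(scan$rld_d2_mm)) {
    return(csa_from_diameters(scan$rld_d1_mm, scan$rld_d2_mm))
  }
  NA_real_
}

#' Classify aspiration risk for one scan
#'
#' Implements the Van de Putte-Perlas flowchart combining content type,
#' antral grade and predicted gastric volume. Branches are evaluated in
#' order:
#' 1. solid-bearing content (`solid` or `mixed`) in either detected
#'    position -> `high` / `solid_content`;
#' 2. antral grade 2 (fluid in both positions) -> `high` / `grade2_fluid`;
#' 3. predicted gastric volume above `threshold_ml_per_kg` (strictly
#'    greater), computable only when an RLD CSA (traced, else from the two
#'    RLD diameters) and the patient's weight are available ->
#'    `high` / `volume_over_threshold`;
#' 4. all three branches evaluable and negative -> `low` / `below_threshold`;
#'    otherwise `indeterminate` / `insufficient_data`.
#'
#' Missing data is an outcome (`indeterminate`), never an error: a scan with
#' an unknown position content cannot certify the absence of solid matter or
#' of grade-2 fluid, so it can only be called high, never low.
#'
#' @param scan a scan record: list or one-row data.frame with the scan
#'   columns of [read_cohort()].
#' @param patient the matching patient record (needs `age`, `weight_kg`).
#' @param threshold_ml_per_kg volume threshold, mL/kg; default 1.5.
#' @return A list with `grade`, `volume_ml`, `volume_ml_per_kg`, `clamped`,
#'   `risk` (`high`/`low`/`indeterminate`) and `fired_rule`.
#' @export
classify_risk <- function(scan, patient, threshold_ml_per_kg = 1.5) {
  if (!is.numeric(threshold_ml_per_kg) || threshold_ml_per_kg <= 0) {
    gus_domain_error("threshold_ml_per_kg must be positive")
  }
  scan <- as.list(scan)
  patient <- as.list(patient)
  grade <- antral_grade(scan$supine_content, scan$rld_content)

  csa <- scan_rld_csa(scan)
  weight <- suppressWarnings(as.numeric(patient$weight_kg))
  vol <- NA_real_; vpk <- NA_real_; clamped <- NA
  if (!is.na(csa)) {
    est <- predicted_gastric_volume(csa, patient$age)
    vol <- est$volume_ml; clamped <- est$clamped
    if (!is.na(weight) && weight > 0) vpk <- vol / weight
  }

  contents <- c(scan$supine_content, scan$rld_content)
  out <- function(risk, rule) {
    list(grade = grade, volume_ml = vol, volume_ml_per_kg = vpk,
         clamped = clamped, risk = risk, fired_rule = rule)
  }
  if (any(is_solid_bearing(contents))) return(out("high", "solid_content"))
  if (grade == "G2") return(out("high", "grade2_fluid"))
  if (!is.na(vpk) && vpk > threshold_ml_per_kg) {
    return(out("high", "volume_over_threshold"))
  }
  evaluable <- all(contents != "unknown") && grade != "indeterminate" && !is.na(vpk)
  if (evaluable) out("low", "below_threshold") else out("indeterminate", "insufficient_data")
}

#' Assess every scan of a cohort and aggregate per patient
#'
#' Runs [classify_risk()] on each scan and aggregates a per-patient risk:
#' `high` if any postoperative scan is high, `indeterminate` if every scan
#' of the patient is indeterminate, otherwise `low`. Patients without scans
#' are not assessed.
#'
#' @param cohort a [gus_cohort()].
#' @param threshold_ml_per_kg volume threshold, mL/kg.
#' @return A list with `scans` (per-scan data.frame: identifiers, grade,
#'   volume, risk, fired rule) and `patients` (patient_id, risk).
#' @export
assess_cohort <- function(cohort, threshold_ml_per_kg = 1.5) {
  scans <- cohort$scans
  patients <- cohort$patients
  idx <- match(scans$patient_id, patients$patient_id)
  res <- lapply(seq_len(nrow(scans)), function(i) {
    classify_risk(scans[i, ], patients[idx[i], ], threshold_ml_per_kg)
  })
  per_scan <- data.frame(
    patient_id = scans$patient_id,
    phase = scans$phase,
    pod = scans$pod,
    grade = vapply(res, `[[`, "", "grade"),
    volume_ml = vapply(res, `[[`, 0, "volume_ml"),
    volume_ml_per_kg = vapply(res, `[[`, 0, "volume_ml_per_kg"),
    risk = vapply(res, `[[`, "", "risk"),
    fired_rule = vapply(res, `[[`, "", "fired_rule"),
    stringsAsFactors = FALSE)

  ids <- unique(per_scan$patient_id)
  agg <- vapply(ids, function(id) {
    rows <- per_scan[per_scan$patient_id == id, ]
    if (any(rows$risk == "high" & rows$phase == "postoperative")) "high"
    else if (all(rows$risk == "indeterminate")) "indeterminate"
    else "low"
  }, "")
  list(scans = per_scan,
       patients = data.frame(patient_id = ids, risk = unname(agg),
                             stringsAsFactors = FALSE))
}

#' Confusion summary of patient-level risk against adverse outcomes
#'
#' Cross-tabulates assessed risk against the composite adverse-outcome flag
#' (nausea/vomiting, antiemetic therapy, delayed return of bowel function,
#' or nasogastric tube placement). Indeterminate assessments are counted
#' separately and excluded from the prediction rate.
#'
#' @param assessments data.frame with `patient_id` and `risk` (one row per
#'   patient, e.g. `assess_cohort(x)$patients`).
#' @param patients patient table carrying `adverse_outcome`.
#' @return A list of counts `true_pos`, `false_neg`, `false_pos`,
#'   `true_neg`, `indeterminate`, and `prediction_rate_pct` =
#'   100 * true_pos / (true_pos + false_neg) — the sensitivity for adverse
#'   outcomes (`NA` with a warning when no determinate adverse patient
#'   exists).
#' @export
prediction_confusion <- function(assessments, patients) {
  if (anyDuplicated(assessments$patient_id)) {
    gus_domain_error("each patient may be assessed at most once")
  }
  idx <- match(assessments$patient_id, patients$patient_id)
  if (anyNA(idx)) {
    gus_referential_error(sprintf("assessed patient_id '%s' not in patients table",
                                  assessments$patient_id[which(is.na(idx))[1]]))
  }
  adverse <- patients$adverse_outcome[idx]
  risk <- assessments$risk
  counts <- list(
    true_pos = sum(adverse & risk == "high"),
    false_neg = sum(adverse & risk == "low"),
    false_pos = sum(!adverse & risk == "high"),
    true_neg = sum(!adverse & risk == "low"),
    indeterminate = sum(risk == "indeterminate"))
  denom <- counts$true_pos + counts$false_neg
  if (denom == 0) {
    warning("no determinate adverse-outcome patients: prediction rate undefined")
    counts$prediction_rate_pct <- NA_real_
  } else {
    counts$prediction_rate_pct <- 100 * counts$true_pos / denom
  }
  counts
}
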