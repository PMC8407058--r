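## Deterministic "results-like" cohort: 41 patients / 94 scans constructed
## by explicit assignment (no RNG) so that its marginal counts equal the
## headline figures of the study design this package analyses:
##   detection 62/94 either, 59/94 supine, 57/94 RLD,
##   16/28 preoperative, 46/66 postoperative (per scan),
##   15/19 laparoscopic, 7/22 open (per patient),
##   grades 34 G0 / 5 G1 / 16 G2 / 39 indeterminate,
##   an 18-patient major-surgery subgroup with 6 adverse patients of whom
##   exactly one meets the high-risk flowchart criteria (16.7% sensitivity).
## This is SYNTHETIC data: only the counts above are faithful; individual
## ages, weights and CSA values are invented plausible numbers.

fixture_position <- function(detected, content, csa) {
  if (!detected) {
    return(list(detected = FALSE, content = "unknown",
                d1 = NA_real_, d2 = NA_real_, csa = NA_real_))
  }
  d <- round(20 * sqrt(csa / pi), 3)  # circular antrum: ellipse formula inverts
  list(detected = TRUE, content = content, d1 = d, d2 = d, csa = csa)
}

fixture_scan <- function(pid, phase, pod,
                         su_detected, su_content, su_csa,
                         rl_detected, rl_content, rl_csa) {
  su <- fixture_position(su_detected, su_content, su_csa)
  rl <- fixture_position(rl_detected, rl_content, rl_csa)
  data.frame(patient_id = pid, phase = phase,
             pod = if (is.na(pod)) NA_integer_ else as.integer(pod),
             supine_detected = su$detected, supine_content = su$content,
             supine_d1_mm = su$d1, supine_d2_mm = su$d2, supine_csa_cm2 = su$csa,
             rld_detected = rl$detected, rld_content = rl$content,
             rld_d1_mm = rl$d1, rld_d2_mm = rl$d2, rld_csa_cm2 = rl$csa,
             stringsAsFactors = FALSE)
}

#' Deterministic results-like synthetic cohort
#'
#' A fixed 41-patient, 94-scan synthetic cohort whose marginal counts match
#' the headline detection, grading and subgroup figures of an
#' emergency-surgery gastric-ultrasound cohort (see the package vignette).
#' Built by deterministic assignment, not sampling, so every derived count
#' is exact and independent of RNG state. The six adverse patients carry a
#' rising postoperative CSA trajectory (+50% from POD 1 to POD 4).
#'
#' @return A [gus_cohort()].
#' @export
results_fixture <- function() {
  id <- sprintf("F%02d", 1:41)
  lap <- c(1:10, 19, 21, 24, 26, 28, 29, 31, 34, 36)
  female <- c(2, 5, 8, 11, 14, 17, 20, 23, 26, 29, 33, 37, 41)
  surgery <- c(rep("colorectal", 11), rep("small_bowel", 7),
               rep("cholecystectomy", 7), rep("appendectomy", 7),
               rep("hernioplasty", 4), rep("other", 5))
  age <- c(rep(78L, 6), rep(60L, 12), rep(55L, 23))
  weight <- c(rep(90, 6), rep(70, 12), rep(75, 23))
  patients <- data.frame(
    patient_id = id,
    age = age,
    sex = ifelse(seq_len(41) %in% female, "female", "male"),
    weight_kg = weight,
    bmi = 24.1,
    surgery_type = surgery,
    surgical_access = ifelse(seq_len(41) %in% lap, "laparoscopic", "open"),
    prior_abdominal_surgery = seq_len(41) %in% 3:17,
    adverse_outcome = seq_len(41) %in% 1:6,
    stringsAsFactors = FALSE)

  sc <- list()
  add <- function(...) sc[[length(sc) + 1]] <<- fixture_scan(...)
  both <- function(pid, phase, pod, su_content, rl_content, su_csa, rl_csa) {
    add(pid, phase, pod, TRUE, su_content, su_csa, TRUE, rl_content, rl_csa)
  }
  neither <- function(pid, phase, pod) {
    add(pid, phase, pod, FALSE, "unknown", NA, FALSE, "unknown", NA)
  }

  traj <- c(9.0, 10.5, 12.0, 13.5)  # adverse RLD CSA, POD 1..4 (+50%/72 h)

  ## F01: the one adverse patient the flowchart flags (grade-2 fluid, POD 3-4)
  both("F01", "preoperative", NA, "empty", "empty", 4.0, 5.0)
  both("F01", "postoperative", 1, "empty", "empty", 4.0, traj[1])
  both("F01", "postoperative", 2, "empty", "empty", 4.0, traj[2])
  both("F01", "postoperative", 3, "liquid", "liquid", 4.0, traj[3])
  both("F01", "postoperative", 4, "liquid", "liquid", 4.0, traj[4])
  ## F02-F06: adverse, dilating antrum, but everything the flowchart sees is
  ## reassuring (empty content, volume under threshold) -> missed by the rule
  for (p in sprintf("F%02d", 2:6)) {
    both(p, "preoperative", NA, "empty", "empty", 4.0, 5.0)
    for (pod in 1:4) both(p, "postoperative", pod, "empty", "empty", 4.0, traj[pod])
  }
  ## F07-F08: single-position detections (indeterminate) plus one clean scan
  for (p in c("F07", "F08")) {
    add(p, "preoperative", NA, TRUE, "empty", 4.0, FALSE, "unknown", NA)
    add(p, "postoperative", 1, FALSE, "unknown", NA, TRUE, "empty", 5.0)
    both(p, "postoperative", 2, "empty", "empty", 4.0, 5.0)
  }
  ## F09-F11: supine-only preop; grade-1 fluid on POD 1, settled by POD 2
  for (p in c("F09", "F10", "F11")) {
    add(p, "preoperative", NA, TRUE, "empty", 4.0, FALSE, "unknown", NA)
    both(p, "postoperative", 1, "empty", "liquid", 4.0, 5.0)
    both(p, "postoperative", 2, "empty", "empty", 4.0, 5.0)
  }
  ## F12: RLD-only fluid preop (reported G1), then grade 1 -> grade 0
  add("F12", "preoperative", NA, FALSE, "unknown", NA, TRUE, "liquid", 6.0)
  both("F12", "postoperative", 1, "empty", "liquid", 4.0, 5.0)
  both("F12", "postoperative", 2, "empty", "empty", 4.0, 5.0)
  ## F13-F18: subgroup patients in whom the antrum was never seen
  for (p in sprintf("F%02d", 13:18)) {
    neither(p, "preoperative", NA)
    neither(p, "postoperative", 1)
  }
  ## F19-F28: non-subgroup detected patients, all grade-2 scans
  g2 <- function(pid, phase, pod) both(pid, phase, pod, "liquid", "liquid", 7.0, 8.0)
  neither("F19", "preoperative", NA); g2("F19", "postoperative", 1); g2("F19", "postoperative", 2)
  g2("F20", "preoperative", NA); g2("F20", "postoperative", 1); g2("F20", "postoperative", 2)
  for (p in c("F21", "F22", "F23")) g2(p, "preoperative", NA)
  g2("F24", "postoperative", 1); neither("F24", "postoperative", 2)
  g2("F25", "postoperative", 1); g2("F25", "postoperative", 2)
  for (p in c("F26", "F27", "F28")) g2(p, "postoperative", 1)
  ## F29-F33: scanned pre and post, never detected
  for (p in sprintf("F%02d", 29:33)) {
    neither(p, "preoperative", NA)
    neither(p, "postoperative", 1)
  }
  ## F34-F41: one undetected postoperative scan each
  for (p in sprintf("F%02d", 34:41)) neither(p, "postoperative", 1)

  scans <- do.call(rbind, sc)
  rownames(scans) <- NULL
  gus_cohort(patients, scans)
}

#' Major-surgery subgroup of the results-like fixture
#'
#' The 18 colorectal / small-bowel patients of [results_fixture()], the
#' stratum at highest postoperative-ileus risk on which risk prediction and
#' trajectory analysis are evaluated.
#'
#' @param cohort a cohort; defaults to [results_fixture()].
#' @return A [gus_cohort()] restricted to the subgroup.
#' @export
major_surgery_subgroup <- function(cohort = results_fixture()) {
  keep <- cohort$patients$surgery_type %in% c("colorectal", "small_bowel")
  ids <- cohort$patients$patient_id[keep]
  gus_cohort(cohort$patients[keep, , drop = FALSE],
             cohort$scans[cohort$scans$patient_id %in% ids, , drop = FALSE])
}

#' Write the results-like fixture to CSV files
#'
#' @param out_dir writable output directory.
#' @return Named character vector of the written `patients`/`scans` paths.
#' @export
make_fixture_resultslike <- function(out_dir) {
  write_cohort(results_fixture(), out_dir)
}
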