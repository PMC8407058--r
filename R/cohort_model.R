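## Cohort data model: patients + scans data frames, validation, CSV round-trip.
##
## patients.csv: patient_id, age, sex, weight_kg, bmi, surgery_type,
##               surgical_access, prior_abdominal_surgery, adverse_outcome
## scans.csv:    patient_id, phase, pod, then per position (supine_, rld_):
##               detected, content, d1_mm, d2_mm, csa_cm2
## Booleans serialize as true/false; optional numerics as empty cells.

gus_patient_cols <- c("patient_id", "age", "sex", "weight_kg", "bmi",
                      "surgery_type", "surgical_access",
                      "prior_abdominal_surgery", "adverse_outcome")

gus_scan_cols <- c("patient_id", "phase", "pod",
                   "supine_detected", "supine_content", "supine_d1_mm",
                   "supine_d2_mm", "supine_csa_cm2",
                   "rld_detected", "rld_content", "rld_d1_mm",
                   "rld_d2_mm", "rld_csa_cm2")

#' Bundle validated patient and scan tables into a cohort
#'
#' A cohort is a list with elements `patients` and `scans`, each a
#' `data.frame` with the fixed column sets used by the CSV interface.
#' Construction validates every record invariant and the referential link
#' from scans to patients.
#'
#' @param patients data.frame of per-patient clinical records.
#' @param scans data.frame of per-examination ultrasound records.
#' @return An object of class `gus_cohort`.
#' @export
gus_cohort <- function(patients, scans) {
  patients <- validate_patients(patients)
  scans <- validate_scans(scans, patients$patient_id)
  structure(list(patients = patients, scans = scans), class = "gus_cohort")
}

#' @export
print.gus_cohort <- function(x, ...) {
  cat(sprintf("<gus_cohort> %d patients, %d scans (%d preoperative, %d postoperative)\n",
              nrow(x$patients), nrow(x$scans),
              sum(x$scans$phase == "preoperative"),
              sum(x$scans$phase == "postoperative")))
  invisible(x)
}

## ---- validation ---------------------------------------------------------

check_enum <- function(x, levels, field, where) {
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    gus_validation_error(sprintf(
      "%s row %d: field '%s' has value '%s'; allowed: %s",
      where, bad[1], field, x[bad[1]], paste(levels, collapse = ", ")))
  }
  x
}

validate_patients <- function(patients) {
  if (!is.data.frame(patients)) gus_schema_error("patients must be a data.frame")
  missing_cols <- setdiff(gus_patient_cols, names(patients))
  if (length(missing_cols)) {
    gus_schema_error(paste0("patients: missing required column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(patients), gus_patient_cols)
  if (length(extra)) {
    warning(sprintf("patients: ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")))
  }
  p <- patients[gus_patient_cols]
  p$patient_id <- as.character(p$patient_id)
  if (anyNA(p$patient_id) || any(!nzchar(p$patient_id))) {
    gus_validation_error("patients: empty patient_id")
  }
  if (anyDuplicated(p$patient_id)) {
    gus_validation_error(sprintf("patients: duplicated patient_id '%s'",
                                 p$patient_id[duplicated(p$patient_id)][1]))
  }
  p$age <- as.integer(p$age)
  bad <- which(is.na(p$age) | p$age < 0)
  if (length(bad)) {
    gus_validation_error(sprintf("patients row %d: field 'age' must be an integer >= 0", bad[1]))
  }
  check_enum(p$sex, gus_sex_levels, "sex", "patients")
  if (anyNA(p$sex)) gus_validation_error("patients: 'sex' is required")
  for (f in c("weight_kg", "bmi")) {
    p[[f]] <- as.numeric(p[[f]])
    bad <- which(!is.na(p[[f]]) & (!is.finite(p[[f]]) | p[[f]] <= 0))
    if (length(bad)) {
      gus_validation_error(sprintf("patients row %d: field '%s' must be positive when present",
                                   bad[1], f))
    }
  }
  check_enum(p$surgery_type, gus_surgery_levels, "surgery_type", "patients")
  check_enum(p$surgical_access, gus_access_levels, "surgical_access", "patients")
  if (anyNA(p$surgery_type) || anyNA(p$surgical_access)) {
    gus_validation_error("patients: 'surgery_type' and 'surgical_access' are required")
  }
  for (f in c("prior_abdominal_surgery", "adverse_outcome")) {
    p[[f]] <- as.logical(p[[f]])
    if (anyNA(p[[f]])) {
      gus_validation_error(sprintf("patients: field '%s' must be true/false", f))
    }
  }
  rownames(p) <- NULL
  p
}

validate_scans <- function(scans, patient_ids = NULL) {
  if (!is.data.frame(scans)) gus_schema_error("scans must be a data.frame")
  missing_cols <- setdiff(gus_scan_cols, names(scans))
  if (length(missing_cols)) {
    gus_schema_error(paste0("scans: missing required column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(scans), gus_scan_cols)
  if (length(extra)) {
    warning(sprintf("scans: ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")))
  }
  s <- scans[gus_scan_cols]
  s$patient_id <- as.character(s$patient_id)
  check_enum(s$phase, gus_phase_levels, "phase", "scans")
  if (anyNA(s$phase)) gus_validation_error("scans: 'phase' is required")
  s$pod <- as.integer(s$pod)
  bad <- which(s$phase == "preoperative" & !is.na(s$pod))
  if (length(bad)) {
    gus_validation_error(sprintf(
      "scans row %d: 'pod' must be absent for preoperative scans", bad[1]))
  }
  bad <- which(s$phase == "postoperative" & (is.na(s$pod) | s$pod < 1))
  if (length(bad)) {
    gus_validation_error(sprintf(
      "scans row %d: 'pod' must be an integer >= 1 for postoperative scans", bad[1]))
  }
  for (pos in c("supine", "rld")) {
    det <- as.logical(s[[paste0(pos, "_detected")]])
    if (anyNA(det)) {
      gus_validation_error(sprintf("scans: field '%s_detected' must be true/false", pos))
    }
    s[[paste0(pos, "_detected")]] <- det
    cont <- check_enum(s[[paste0(pos, "_content")]], gus_content_levels,
                       paste0(pos, "_content"), "scans")
    if (anyNA(cont)) {
      gus_validation_error(sprintf("scans: field '%s_content' is required", pos))
    }
    meas <- paste0(pos, c("_d1_mm", "_d2_mm", "_csa_cm2"))
    for (f in meas) {
      s[[f]] <- as.numeric(s[[f]])
      bad <- which(!is.na(s[[f]]) & (!is.finite(s[[f]]) | s[[f]] < 0))
      if (length(bad)) {
        gus_validation_error(sprintf(
          "scans row %d: field '%s' must be finite and non-negative", bad[1], f))
      }
    }
    # undetected position: content unknown, no measurements
    bad <- which(!det & (cont != "unknown" |
                           !is.na(s[[meas[1]]]) | !is.na(s[[meas[2]]]) |
                           !is.na(s[[meas[3]]])))
    if (length(bad)) {
      gus_validation_error(sprintf(
        "scans row %d: position '%s' not detected but carries content or measurements",
        bad[1], pos))
    }
  }
  if (!is.null(patient_ids)) {
    bad <- which(!(s$patient_id %in% patient_ids))
    if (length(bad)) {
      gus_referential_error(sprintf(
        "scans row %d: patient_id '%s' not present in patients table",
        bad[1], s$patient_id[bad[1]]))
    }
  }
  rownames(s) <- NULL
  s
}

## ---- CSV I/O ------------------------------------------------------------

parse_bool_col <- function(x, field, where) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("true"), TRUE, ifelse(x %in% c("false"), FALSE, NA))
  if (anyNA(out)) {
    gus_validation_error(sprintf("%s: field '%s' must be true/false", where, field))
  }
  out
}

read_cohort_table <- function(path, what) {
  if (!file.exists(path)) gus_io_error(sprintf("%s file not found: %s", what, path))
  utils::read.csv(path, colClasses = "character", check.names = TRUE,
                  fileEncoding = "UTF-8")
}

blank_to_na <- function(df) {
  for (j in seq_along(df)) df[[j]][!nzchar(trimws(df[[j]]))] <- NA
  df
}

#' Read a two-file CSV cohort
#'
#' Reads `patients.csv` / `scans.csv`-style files, validates every record
#' invariant (closed vocabularies, non-negative measurements, preoperative
#' scans without a postoperative day, undetected positions carrying no
#' content or measurements) and the referential link from scans to patients.
#' Unknown columns are dropped with a warning; a missing required column is a
#' schema error naming the column.
#'
#' @param patients_path path to the patients CSV file.
#' @param scans_path path to the scans CSV file.
#' @return A [gus_cohort()] list with `patients` and `scans` data frames,
#'   row order preserved.
#' @seealso [write_cohort()] for the inverse; `read_cohort(write_cohort(x))`
#'   restores `x` exactly.
#' @export
read_cohort <- function(patients_path, scans_path) {
  p <- blank_to_na(read_cohort_table(patients_path, "patients"))
  s <- blank_to_na(read_cohort_table(scans_path, "scans"))
  for (f in intersect(c("prior_abdominal_surgery", "adverse_outcome"), names(p))) {
    p[[f]] <- parse_bool_col(p[[f]], f, "patients")
  }
  for (f in intersect(c("supine_detected", "rld_detected"), names(s))) {
    s[[f]] <- parse_bool_col(s[[f]], f, "scans")
  }
  gus_cohort(p, s)
}

format_csv_col <- function(x) {
  if (is.logical(x)) ifelse(is.na(x), "", ifelse(x, "true", "false"))
  else ifelse(is.na(x), "", as.character(x))
}

write_gus_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, format_csv_col), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

#' Write a cohort to a two-file CSV layout
#'
#' Serializes booleans as `true`/`false` and absent optional values as empty
#' cells. The written files read back to an identical cohort.
#'
#' @param cohort a [gus_cohort()] (or any list with valid `patients` and
#'   `scans` data frames).
#' @param out_dir output directory, created if needed.
#' @return Named character vector with elements `patients` and `scans`
#'   giving the written paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  patients <- validate_patients(cohort$patients)
  scans <- validate_scans(cohort$scans, patients$patient_id)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    gus_io_error(sprintf("cannot create output directory: %s", out_dir))
  }
  if (file.access(out_dir, mode = 2) != 0) {
    gus_io_error(sprintf("output directory not writable: %s", out_dir))
  }
  c(patients = write_gus_csv(patients, file.path(out_dir, "patients.csv")),
    scans = write_gus_csv(scans, file.path(out_dir, "scans.csv")))
}
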