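## File-level pipeline: simulate / assess / stats / trajectory, each writing
## its outputs plus a run manifest (command, config hash, seed, inputs,
## outputs, package version, timestamp) for reproducibility.

write_manifest <- function(out_dir, command, inputs, outputs,
                           seed = NA_integer_, config_hash = NA_character_,
                           options = list()) {
  manifest <- list(
    command = command,
    config_hash = config_hash,
    seed = seed,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    options = options,
    package_version = as.character(utils::packageVersion("gastricus")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  path
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    gus_io_error(sprintf("cannot create output directory: %s", out_dir))
  }
  out_dir
}

config_from_yaml <- function(config_path) {
  raw <- tryCatch(yaml::read_yaml(config_path),
                  error = function(e) gus_schema_error(
                    sprintf("cannot parse config %s: %s", config_path,
                            conditionMessage(e))))
  if (!is.list(raw)) gus_schema_error("config must be a YAML mapping")
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    gus_schema_error(sprintf("unknown config field(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  for (f in c("detection_prob", "access_mix", "content_mix")) {
    if (f %in% names(raw)) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(cohort_config, raw)
}

#' Simulate a cohort to CSV files
#'
#' Generates a synthetic cohort from a [cohort_config()] (optionally read
#' from a YAML file) and writes `patients.csv`, `scans.csv`, the resolved
#' configuration and a run manifest. Identical config and seed give
#' byte-identical cohort files.
#'
#' @param out_dir output directory.
#' @param config a [cohort_config()]; ignored when `config_path` is given.
#' @param config_path optional YAML file whose fields override the defaults.
#' @param seed optional integer overriding the config seed.
#' @return Invisibly, named paths of the written files.
#' @export
run_simulate <- function(out_dir, config = cohort_config(), config_path = NULL,
                         seed = NULL) {
  if (!is.null(config_path)) config <- config_from_yaml(config_path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config <- validate_cohort_config(config)
  ensure_dir(out_dir)
  cohort <- generate_cohort(config)
  paths <- write_cohort(cohort, out_dir)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, na = "null", digits = NA)
  manifest <- write_manifest(out_dir, "simulate",
                             inputs = if (is.null(config_path)) character() else config_path,
                             outputs = c(paths, config = cfg_path),
                             seed = config$seed,
                             config_hash = unname(tools::md5sum(cfg_path)))
  invisible(c(paths, config = cfg_path, manifest = manifest))
}

#' Assess aspiration risk for a cohort on disk
#'
#' Reads a CSV cohort, runs the risk flowchart on every scan, aggregates a
#' per-patient risk, and writes per-scan assessments, per-patient risk and
#' (when any adverse outcome is recorded) the confusion summary against the
#' adverse-outcome flag.
#'
#' @param patients_path,scans_path cohort CSV files.
#' @param out_dir output directory.
#' @param threshold_ml_per_kg volume threshold of the risk rule, mL/kg.
#' @return Invisibly, named paths of the written files.
#' @export
run_assess <- function(patients_path, scans_path, out_dir,
                       threshold_ml_per_kg = 1.5) {
  cohort <- read_cohort(patients_path, scans_path)
  if (nrow(cohort$scans) == 0) gus_domain_error("no scans to assess")
  ensure_dir(out_dir)
  ass <- assess_cohort(cohort, threshold_ml_per_kg)
  scan_path <- write_gus_csv(ass$scans, file.path(out_dir, "risk_scans.csv"))
  patient_path <- write_gus_csv(ass$patients, file.path(out_dir, "risk_patients.csv"))
  outputs <- c(risk_scans = scan_path, risk_patients = patient_path)
  if (any(cohort$patients$adverse_outcome)) {
    conf <- prediction_confusion(ass$patients, cohort$patients)
    conf_path <- file.path(out_dir, "confusion.json")
    jsonlite::write_json(conf, conf_path, auto_unbox = TRUE, pretty = TRUE,
                         na = "null", digits = NA)
    outputs <- c(outputs, confusion = conf_path)
  }
  manifest <- write_manifest(out_dir, "assess",
                             inputs = c(patients = patients_path, scans = scans_path),
                             outputs = outputs,
                             options = list(threshold_ml_per_kg = threshold_ml_per_kg))
  invisible(c(outputs, manifest = manifest))
}

#' Stratified statistics for a cohort on disk
#'
#' Writes the detection comparison table (position, phase, surgical access,
#' each with the uncorrected chi-squared test) and the pre/post RLD CSA
#' comparison for both CSA sources.
#'
#' @inheritParams run_assess
#' @return Invisibly, named paths of the written files.
#' @export
run_stats <- function(patients_path, scans_path, out_dir) {
  cohort <- read_cohort(patients_path, scans_path)
  ensure_dir(out_dir)
  tab <- cohort_comparison_table(cohort)
  tab_path <- write_gus_csv(tab, file.path(out_dir, "detection_comparisons.csv"))
  csa <- list(calculated = csa_phase_comparison(cohort, "calculated"),
              measured = csa_phase_comparison(cohort, "measured"))
  strip_class <- function(x) if (is.null(x)) NULL else unclass(x)
  csa_out <- lapply(csa, function(cc) list(preop = cc$preop, postop = cc$postop,
                                           test = strip_class(cc$test)))
  csa_path <- file.path(out_dir, "csa_phase_comparison.json")
  jsonlite::write_json(csa_out, csa_path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  manifest <- write_manifest(out_dir, "stats",
                             inputs = c(patients = patients_path, scans = scans_path),
                             outputs = c(detection = tab_path, csa = csa_path))
  invisible(c(detection = tab_path, csa = csa_path, manifest = manifest))
}

#' Relative-CSA trajectory analysis for a cohort on disk
#'
#' Builds CSA_x/CSA_0 trajectory points for every usable patient, fits the
#' pooled regression against postoperative day, and writes the points, the
#' fit summary and optionally a scatter-plus-line plot.
#'
#' @inheritParams run_assess
#' @param source `"calculated"` or `"measured"` CSA.
#' @param position `"rld"` or `"supine"`.
#' @param adverse_only restrict to adverse-outcome patients (the subgroup of
#'   clinical interest); default `TRUE`.
#' @param plot also write `trajectory.png`.
#' @return Invisibly, named paths of the written files.
#' @export
run_trajectory <- function(patients_path, scans_path, out_dir,
                           source = c("calculated", "measured"),
                           position = c("rld", "supine"),
                           adverse_only = TRUE, plot = FALSE) {
  source <- match.arg(source)
  position <- match.arg(position)
  cohort <- read_cohort(patients_path, scans_path)
  points <- cohort_trajectory_points(cohort, source, position, adverse_only)
  if (nrow(points) == 0) {
    gus_domain_error("no patient has a usable postoperative CSA series")
  }
  ensure_dir(out_dir)
  pts_path <- write_gus_csv(points, file.path(out_dir, "trajectory_points.csv"))
  fit <- tryCatch(fit_trajectory(points), gus_domain_error = function(e) NULL)
  fit_path <- file.path(out_dir, "trajectory_fit.json")
  jsonlite::write_json(if (is.null(fit)) list(error = "fewer than 2 distinct PODs")
                       else unclass(fit),
                       fit_path, auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)
  outputs <- c(points = pts_path, fit = fit_path)
  if (plot) {
    png_path <- file.path(out_dir, "trajectory.png")
    grDevices::png(png_path, width = 700, height = 500)
    plot(points$pod, points$ratio, pch = 19,
         xlab = "Postoperative day", ylab = expression(CSA[x] / CSA[0]),
         main = sprintf("Relative antral CSA (%s, %s)", source, position))
    if (!is.null(fit)) graphics::abline(fit$intercept, fit$slope, col = "red3", lwd = 2)
    grDevices::dev.off()
    outputs <- c(outputs, plot = png_path)
  }
  manifest <- write_manifest(out_dir, "trajectory",
                             inputs = c(patients = patients_path, scans = scans_path),
                             outputs = outputs,
                             options = list(source = source, position = position,
                                            adverse_only = adverse_only))
  invisible(c(outputs, manifest = manifest))
}
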