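## Seeded synthetic-cohort generator. Defaults emulate the cohort structure
## an emergency-surgery gastric-ultrasound study reports: 41 patients,
## access-dependent detection (about 79% laparoscopic, 32% open), mostly
## empty/liquid content when seen, right-skewed CSA around 4.9 cm^2 before
## and 6.9 cm^2 after surgery, a one-third adverse-outcome fraction with
## dilated antra (about 13 cm^2) whose relative CSA rises about 50% over
## the first 72 h.

#' Configuration for the synthetic cohort generator
#'
#' All probabilities, mixtures and distribution parameters used by
#' [generate_cohort()], validated on construction. CSA values are drawn
#' from lognormal distributions (positive, right-skewed) parameterized by
#' their arithmetic mean and log-scale SD.
#'
#' @param n_patients number of patients.
#' @param preop_prob probability a patient receives a preoperative scan.
#' @param postop_scans_range integer `c(min, max)`: postoperative scans per
#'   non-adverse patient, uniform over the range, scheduled on consecutive
#'   postoperative days from POD 1.
#' @param adverse_postop_scans postoperative scans for adverse patients
#'   (PODs 1..k), enough to observe a 72-h trajectory.
#' @param detection_prob named probabilities of detecting the antrum, by
#'   surgical access (`open`, `laparoscopic`, `other`).
#' @param detection_concordance probability that supine and RLD share one
#'   detection draw for a scan (the marginal rate is unchanged; higher
#'   values raise supine/RLD agreement, which is high in practice).
#' @param access_mix probabilities over surgical access types.
#' @param content_mix probabilities over content types (`empty`, `liquid`,
#'   `mixed`, `solid`) conditional on detection.
#' @param csa_preop,csa_postop lists `list(mean, sdlog)` for the
#'   preoperative and postoperative RLD CSA distributions, cm^2.
#' @param adverse_fraction probability of the composite adverse outcome.
#' @param adverse_csa_mean mean postoperative RLD CSA of adverse patients,
#'   cm^2 (averaged over their trajectory).
#' @param adverse_daily_ratio_slope mean daily increase of the adverse
#'   relative-CSA trajectory (1/6 per day = +50% over 72 h).
#' @param ratio_noise_sd SD of the additive noise on the relative-CSA
#'   trajectory.
#' @param measured_bias multiplicative bias of the traced CSA relative to
#'   the diameter-derived one (traced areas tend to read slightly larger).
#' @param measured_noise_sdlog log-scale SD of traced-CSA measurement noise.
#' @param age_range,weight_range,bmi_range uniform sampling bounds.
#' @param seed integer seed; `NA` leaves the RNG state alone.
#' @return A validated `gus_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 41,
                          preop_prob = 28 / 41,
                          postop_scans_range = c(1L, 2L),
                          adverse_postop_scans = 4L,
                          detection_prob = c(open = 0.318, laparoscopic = 0.789,
                                             other = 0.66),
                          detection_concordance = 0.85,
                          access_mix = c(open = 22 / 41, laparoscopic = 19 / 41,
                                         other = 0),
                          content_mix = c(empty = 0.71, liquid = 0.20,
                                          mixed = 0.06, solid = 0.03),
                          csa_preop = list(mean = 4.93, sdlog = 0.38),
                          csa_postop = list(mean = 6.92, sdlog = 0.38),
                          adverse_fraction = 1 / 3,
                          adverse_csa_mean = 12.95,
                          adverse_daily_ratio_slope = 1 / 6,
                          ratio_noise_sd = 0.1,
                          measured_bias = 1.1,
                          measured_noise_sdlog = 0.08,
                          age_range = c(35, 89),
                          weight_range = c(55, 95),
                          bmi_range = c(19, 30),
                          seed = NA_integer_) {
  cfg <- list(n_patients = as.integer(n_patients), preop_prob = preop_prob,
              postop_scans_range = as.integer(postop_scans_range),
              adverse_postop_scans = as.integer(adverse_postop_scans),
              detection_prob = detection_prob,
              detection_concordance = detection_concordance,
              access_mix = access_mix, content_mix = content_mix,
              csa_preop = csa_preop, csa_postop = csa_postop,
              adverse_fraction = adverse_fraction,
              adverse_csa_mean = adverse_csa_mean,
              adverse_daily_ratio_slope = adverse_daily_ratio_slope,
              ratio_noise_sd = ratio_noise_sd,
              measured_bias = measured_bias,
              measured_noise_sdlog = measured_noise_sdlog,
              age_range = age_range, weight_range = weight_range,
              bmi_range = bmi_range,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) gus_validation_error(paste0("config: ", msg))
  chk(length(cfg$n_patients) == 1 && !is.na(cfg$n_patients) && cfg$n_patients >= 1,
      "n_patients must be a positive integer")
  probs <- c(preop_prob = cfg$preop_prob,
             detection_concordance = cfg$detection_concordance,
             adverse_fraction = cfg$adverse_fraction, cfg$detection_prob)
  chk(all(is.finite(probs)) && all(probs >= 0) && all(probs <= 1),
      "probabilities must lie in [0, 1]")
  chk(all(sort(names(cfg$detection_prob)) == sort(gus_access_levels)),
      "detection_prob must name open, laparoscopic, other")
  chk(all(sort(names(cfg$access_mix)) == sort(gus_access_levels)) &&
        all(cfg$access_mix >= 0) && abs(sum(cfg$access_mix) - 1) < 1e-8,
      "access_mix must be probabilities over access types summing to 1")
  chk(all(sort(names(cfg$content_mix)) ==
            sort(setdiff(gus_content_levels, "unknown"))) &&
        all(cfg$content_mix >= 0) && abs(sum(cfg$content_mix) - 1) < 1e-8,
      "content_mix must be probabilities over known content types summing to 1")
  chk(length(cfg$postop_scans_range) == 2 &&
        all(cfg$postop_scans_range >= 0) && !anyNA(cfg$postop_scans_range) &&
        cfg$postop_scans_range[1] <= cfg$postop_scans_range[2],
      "postop_scans_range must be c(min, max) with 0 <= min <= max")
  chk(cfg$adverse_postop_scans >= 2,
      "adverse_postop_scans must be >= 2 (a trajectory needs two days)")
  for (f in c("csa_preop", "csa_postop")) {
    chk(is.list(cfg[[f]]) && all(c("mean", "sdlog") %in% names(cfg[[f]])) &&
          cfg[[f]]$mean > 0 && cfg[[f]]$sdlog > 0,
        sprintf("%s must be list(mean > 0, sdlog > 0)", f))
  }
  chk(cfg$adverse_csa_mean > 0 && cfg$ratio_noise_sd >= 0 &&
        cfg$measured_bias > 0 && cfg$measured_noise_sdlog >= 0,
      "distribution parameters must be positive")
  for (f in c("age_range", "weight_range", "bmi_range")) {
    chk(length(cfg[[f]]) == 2 && all(is.finite(cfg[[f]])) &&
          cfg[[f]][1] >= 0 && cfg[[f]][1] <= cfg[[f]][2],
        sprintf("%s must be c(lo, hi) with 0 <= lo <= hi", f))
  }
  structure(cfg, class = "gus_cohort_config")
}

## lognormal with a target arithmetic mean
rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## diameters (mm) whose ellipse area equals csa (cm^2), random aspect ratio
diameters_for_csa <- function(csa_cm2) {
  r <- stats::runif(length(csa_cm2), 0.8, 1.25)
  base <- sqrt(4 * csa_cm2 / pi)
  cbind(d1 = 10 * base * sqrt(r), d2 = 10 * base / sqrt(r))
}

#' Generate a synthetic GUS cohort
#'
#' Deterministic for a given `config$seed`. Adverse-outcome patients receive
#' elevated postoperative CSA whose relative trajectory rises with mean
#' daily slope `adverse_daily_ratio_slope`; detection failures produce
#' positions with unknown content and no measurements; every emitted record
#' satisfies the cohort invariants (checked by construction through
#' [gus_cohort()]).
#'
#' @param config a [cohort_config()].
#' @return A [gus_cohort()].
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  if (!is.na(config$seed)) set.seed(config$seed)
  n <- config$n_patients

  patients <- data.frame(
    patient_id = sprintf("S%03d", seq_len(n)),
    age = as.integer(round(stats::runif(n, config$age_range[1], config$age_range[2]))),
    sex = sample(gus_sex_levels, n, replace = TRUE, prob = c(0.32, 0.68)),
    weight_kg = round(stats::runif(n, config$weight_range[1], config$weight_range[2]), 1),
    bmi = round(stats::runif(n, config$bmi_range[1], config$bmi_range[2]), 1),
    surgery_type = sample(gus_surgery_levels, n, replace = TRUE,
                          prob = c(0.29, 0.17, 0.17, 0.17, 0.10, 0.10)),
    surgical_access = sample(names(config$access_mix), n, replace = TRUE,
                             prob = config$access_mix),
    prior_abdominal_surgery = stats::runif(n) < 0.37,
    adverse_outcome = stats::runif(n) < config$adverse_fraction,
    stringsAsFactors = FALSE)

  content_levels <- names(config$content_mix)
  draw_position <- function(detected, csa_mean, sdlog, csa_fixed = NA) {
    if (!detected) {
      return(list(detected = FALSE, content = "unknown",
                  d1 = NA_real_, d2 = NA_real_, csa = NA_real_))
    }
    content <- sample(content_levels, 1, prob = config$content_mix)
    csa <- if (is.na(csa_fixed)) rlnorm_mean(1, csa_mean, sdlog) else csa_fixed
    dd <- diameters_for_csa(csa)
    traced <- csa * config$measured_bias *
      stats::rlnorm(1, -config$measured_noise_sdlog^2 / 2, config$measured_noise_sdlog)
    list(detected = TRUE, content = content,
         d1 = round(dd[1, "d1"], 1), d2 = round(dd[1, "d2"], 1),
         csa = round(traced, 2))
  }

  rows <- list()
  for (i in seq_len(n)) {
    p_det <- config$detection_prob[[patients$surgical_access[i]]]
    adverse <- patients$adverse_outcome[i]

    detect_pair <- function() {
      if (stats::runif(1) < config$detection_concordance) {
        rep(stats::runif(1) < p_det, 2)
      } else {
        stats::runif(2) < p_det
      }
    }

    scan_row <- function(phase, pod, csa_mean, sdlog, csa_fixed = NA) {
      det <- detect_pair()
      su <- draw_position(det[1], csa_mean, sdlog)
      rl <- draw_position(det[2], csa_mean, sdlog,
                          csa_fixed = if (det[2]) csa_fixed else NA)
      list(patient_id = patients$patient_id[i], phase = phase,
           pod = if (is.na(pod)) NA_integer_ else as.integer(pod),
           supine_detected = su$detected, supine_content = su$content,
           supine_d1_mm = su$d1, supine_d2_mm = su$d2, supine_csa_cm2 = su$csa,
           rld_detected = rl$detected, rld_content = rl$content,
           rld_d1_mm = rl$d1, rld_d2_mm = rl$d2, rld_csa_cm2 = rl$csa)
    }

    if (stats::runif(1) < config$preop_prob) {
      rows[[length(rows) + 1]] <- scan_row("preoperative", NA, config$csa_preop$mean,
                                          config$csa_preop$sdlog)
    }
    if (adverse) {
      pods <- seq_len(config$adverse_postop_scans)
      slope <- config$adverse_daily_ratio_slope
      base_mean <- config$adverse_csa_mean / (1 + slope * mean(pods - 1))
      base <- rlnorm_mean(1, base_mean, config$csa_postop$sdlog)
      for (pod in pods) {
        mult <- 1 + slope * (pod - 1) + stats::rnorm(1, 0, config$ratio_noise_sd)
        csa_fixed <- round(max(base * mult, 0.2), 2)
        rows[[length(rows) + 1]] <-
          scan_row("postoperative", pod, config$csa_postop$mean,
                   config$csa_postop$sdlog, csa_fixed = csa_fixed)
      }
    } else {
      k <- if (config$postop_scans_range[1] == config$postop_scans_range[2]) {
        config$postop_scans_range[1]
      } else {
        sample(seq(config$postop_scans_range[1], config$postop_scans_range[2]), 1)
      }
      for (pod in seq_len(k)) {
        rows[[length(rows) + 1]] <-
          scan_row("postoperative", pod, config$csa_postop$mean, config$csa_postop$sdlog)
      }
    }
  }
  # assemble column-wise: rbind-ing thousands of one-row frames is quadratic
  col <- function(field, template) vapply(rows, function(r) r[[field]], template)
  scans <- data.frame(
    patient_id = col("patient_id", ""), phase = col("phase", ""),
    pod = col("pod", NA_integer_),
    supine_detected = col("supine_detected", NA),
    supine_content = col("supine_content", ""),
    supine_d1_mm = col("supine_d1_mm", NA_real_),
    supine_d2_mm = col("supine_d2_mm", NA_real_),
    supine_csa_cm2 = col("supine_csa_cm2", NA_real_),
    rld_detected = col("rld_detected", NA),
    rld_content = col("rld_content", ""),
    rld_d1_mm = col("rld_d1_mm", NA_real_),
    rld_d2_mm = col("rld_d2_mm", NA_real_),
    rld_csa_cm2 = col("rld_csa_cm2", NA_real_),
    stringsAsFactors = FALSE)
  gus_cohort(patients, scans)
}

## In the "calculated CSA" pathway the diameters, not the traced value,
## define the adverse trajectory; keep them exact for fixed-CSA draws by
## reusing the ellipse inversion above. (Rounding to 0.1 mm adds < 1%
## relative error, below the configured trajectory noise.)
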