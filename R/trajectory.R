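## Relative antral-CSA trajectories (CSA_x / CSA_0 vs postoperative day)
## and their pooled linear regression.

#' Extract per-scan CSA values for one source and position
#'
#' `"measured"` returns the traced CSA column; `"calculated"` evaluates the
#' ellipse formula on the two recorded diameters (NA when either diameter is
#' missing).
#'
#' @param scans scan table.
#' @param source `"calculated"` or `"measured"`.
#' @param position `"rld"` or `"supine"`.
#' @return Numeric vector of CSA values (cm^2), NA where unavailable.
#' @export
scan_csa_values <- function(scans, source = c("calculated", "measured"),
                            position = c("rld", "supine")) {
  source <- match.arg(source)
  position <- match.arg(position)
  if (source == "measured") return(as.numeric(scans[[paste0(position, "_csa_cm2")]]))
  d1 <- as.numeric(scans[[paste0(position, "_d1_mm")]])
  d2 <- as.numeric(scans[[paste0(position, "_d2_mm")]])
  out <- rep(NA_real_, nrow(scans))
  ok <- !is.na(d1) & !is.na(d2)
  if (any(ok)) out[ok] <- csa_from_diameters(d1[ok], d2[ok])
  out
}

#' Relative CSA series for one patient
#'
#' Builds the `CSA_x / CSA_0` series over postoperative days, where `CSA_0`
#' is the CSA on the first postoperative day. When no usable CSA exists on
#' POD 1 (detection failures are common), the baseline falls back to the
#' earliest postoperative scan with an available value. The baseline point
#' itself (ratio exactly 1) is included and flagged.
#'
#' @param scans scan table of a single patient.
#' @param source `"calculated"` or `"measured"` CSA.
#' @param position `"rld"` (default, the position in which CSA tracks
#'   volume) or `"supine"`.
#' @return data.frame of trajectory points: `patient_id`, `pod`, `ratio`,
#'   `source`, `baseline`.
#' @export
relative_csa_series <- function(scans, source = c("calculated", "measured"),
                                position = c("rld", "supine")) {
  source <- match.arg(source)
  position <- match.arg(position)
  ids <- unique(scans$patient_id)
  if (length(ids) != 1) {
    gus_domain_error("relative_csa_series expects the scans of exactly one patient")
  }
  post <- scans[scans$phase == "postoperative", , drop = FALSE]
  csa <- scan_csa_values(post, source = source, position = position)
  usable <- !is.na(csa) & csa > 0
  if (!any(usable)) {
    gus_domain_error(sprintf("patient %s: no usable postoperative %s CSA (%s)",
                             ids, position, source))
  }
  post <- post[usable, , drop = FALSE]
  csa <- csa[usable]
  ord <- order(post$pod)
  post <- post[ord, , drop = FALSE]
  csa <- csa[ord]
  data.frame(patient_id = ids,
             pod = post$pod,
             ratio = csa / csa[1],
             source = source,
             baseline = seq_along(csa) == 1,
             stringsAsFactors = FALSE)
}

#' Trajectory points for every usable patient of a cohort
#'
#' Applies [relative_csa_series()] to each patient with at least one usable
#' postoperative CSA; others are skipped with a message. Optionally restricts
#' to patients with adverse outcomes, the subgroup on which the relative-CSA
#' model is of clinical interest.
#'
#' @param cohort a [gus_cohort()].
#' @inheritParams relative_csa_series
#' @param adverse_only keep only adverse-outcome patients.
#' @return Pooled data.frame of trajectory points (possibly 0 rows).
#' @export
cohort_trajectory_points <- function(cohort, source = c("calculated", "measured"),
                                     position = c("rld", "supine"),
                                     adverse_only = FALSE) {
  source <- match.arg(source)
  position <- match.arg(position)
  patients <- cohort$patients
  if (adverse_only) patients <- patients[patients$adverse_outcome, , drop = FALSE]
  pieces <- lapply(patients$patient_id, function(id) {
    s <- cohort$scans[cohort$scans$patient_id == id, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    tryCatch(relative_csa_series(s, source, position),
             gus_domain_error = function(e) {
               message("skipping: ", conditionMessage(e))
               NULL
             })
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), pod = integer(),
                      ratio = numeric(), source = character(),
                      baseline = logical(), stringsAsFactors = FALSE)
  }
  out
}

#' Pooled linear regression of relative CSA on postoperative day
#'
#' Ordinary least squares of `ratio` on `pod`, pooling all patients' points
#' in one regression (one R^2 per CSA source, matching how such models are
#' reported). Baseline points are included by default; set
#' `include_baseline = FALSE` to regress on the post-baseline points only.
#'
#' @param points trajectory points from [relative_csa_series()] or
#'   [cohort_trajectory_points()].
#' @param include_baseline keep the ratio-1 baseline points.
#' @return A `gus_trajectory_fit` list: `slope` (ratio units per day),
#'   `intercept`, `r_squared` (`NA` when the ratios have zero variance),
#'   `n_points`.
#' @export
fit_trajectory <- function(points, include_baseline = TRUE) {
  if (!include_baseline && "baseline" %in% names(points)) {
    points <- points[!points$baseline, , drop = FALSE]
  }
  if (nrow(points) < 2 || length(unique(points$pod)) < 2) {
    gus_domain_error("need at least 2 points over at least 2 distinct postoperative days")
  }
  fit <- stats::lm(ratio ~ pod, data = points)
  coefs <- stats::coef(fit)
  # suppressWarnings: summary.lm warns on exactly collinear (perfect) fits,
  # which are legitimate inputs here
  r2 <- if (stats::var(points$ratio) == 0) NA_real_
        else suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(coefs["pod"]),
                 intercept = unname(coefs["(Intercept)"]),
                 r_squared = r2,
                 n_points = nrow(points)),
            class = "gus_trajectory_fit")
}

#' @export
print.gus_trajectory_fit <- function(x, ...) {
  cat(sprintf("Relative-CSA trajectory: slope = %.4f /day, intercept = %.4f, R^2 = %s (n = %d)\n",
              x$slope, x$intercept,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$n_points))
  invisible(x)
}
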