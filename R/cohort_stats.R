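## Cohort-level statistics: detection rates, 2x2 chi-squared, Student t,
## median/IQR descriptives, and the stratified comparison table.

#' Antrum detection rate, optionally stratified
#'
#' Counts scans (or patients) in which the gastric antrum was sonographically
#' detected. With `unit = "scan"` the denominator is the number of scans
#' after filtering; `position = "either"` counts a scan as detected when the
#' antrum was seen in the supine or the RLD view. With `unit = "patient"` a
#' patient counts as detected when the antrum was seen in at least one of
#' their scans — the convention used when comparing surgical-access strata,
#' where rates like 15/19 are per patient.
#'
#' @param cohort a [gus_cohort()].
#' @param position `"either"`, `"supine"` or `"rld"`.
#' @param unit `"scan"` or `"patient"`.
#' @param filter optional predicate: a function taking the scan table and
#'   the row-matched patient table and returning a logical vector selecting
#'   scans (e.g. `function(s, p) p$surgical_access == "laparoscopic"`).
#' @return A list with `numerator`, `denominator` and `fraction`.
#' @export
detection_rate <- function(cohort, position = c("either", "supine", "rld"),
                           unit = c("scan", "patient"), filter = NULL) {
  position <- match.arg(position)
  unit <- match.arg(unit)
  scans <- cohort$scans
  patients <- cohort$patients[match(scans$patient_id, cohort$patients$patient_id), ]
  if (!is.null(filter)) {
    keep <- filter(scans, patients)
    scans <- scans[keep, , drop = FALSE]
  }
  if (nrow(scans) == 0) gus_domain_error("no scans left after filtering")
  det <- switch(position,
                either = scans$supine_detected | scans$rld_detected,
                supine = scans$supine_detected,
                rld = scans$rld_detected)
  if (unit == "scan") {
    num <- sum(det); den <- nrow(scans)
  } else {
    by_patient <- tapply(det, scans$patient_id, any)
    num <- sum(by_patient); den <- length(by_patient)
  }
  list(numerator = as.integer(num), denominator = as.integer(den),
       fraction = num / den)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Uncorrected Pearson test of independence:
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom.
#' No Yates continuity correction is applied — the uncorrected statistic is
#' the convention this package standardizes on for detection-rate
#' comparisons. A table with a zero marginal carries no information about
#' association and returns statistic 0, p 1 with a warning.
#'
#' @param a,b,c,d cell counts; rows are the two strata, columns
#'   detected/not-detected. Alternatively `a` may be a 2x2 matrix or table.
#' @return A `gus_test` list: `statistic`, `p_value`, `df`, `method`.
#' @examples
#' chi_squared_2x2(15, 4, 7, 15) # laparoscopic vs open detection
#' @export
chi_squared_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) || is.table(a)) {
    m <- as.matrix(a)
    if (!all(dim(m) == c(2, 2))) gus_domain_error("table must be 2x2")
    b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]; a <- m[1, 1]
  }
  counts <- c(a, b, c, d)
  if (length(counts) != 4 || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    gus_domain_error("cell counts must be four non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) gus_domain_error("table must contain at least one observation")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    warning("zero marginal total: chi-squared statistic undefined, reporting 0")
    stat <- 0
  } else {
    stat <- n * (a * d - b * c)^2 / prod(marg)
  }
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1,
                 method = "Pearson chi-squared (uncorrected)"),
            class = "gus_test")
}

#' Two-sample Student t-test (pooled variance)
#'
#' Classical two-tailed Student t-test with pooled variance and
#' `n_x + n_y - 2` degrees of freedom, the test form used for numerical
#' comparisons throughout. Welch's unequal-variance form is available via
#' `var_equal = FALSE` but is not the default. Two identical constant
#' samples give t = 0, p = 1.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param var_equal pool the variances (classical Student form) if `TRUE`.
#' @return A `gus_test` list: `statistic`, `p_value`, `df`, `method`.
#' @export
student_t_two_sample <- function(x, y, var_equal = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    gus_domain_error("each sample needs at least 2 finite values")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(structure(list(statistic = 0, p_value = 1,
                            df = length(x) + length(y) - 2,
                            method = "Two-sample Student t (pooled)"),
                       class = "gus_test"))
    }
    gus_domain_error("both samples are constant with different means: t undefined")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 df = unname(tt$parameter),
                 method = if (var_equal) "Two-sample Student t (pooled)"
                          else "Welch two-sample t"),
            class = "gus_test")
}

#' @export
print.gus_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Median/IQR descriptive summary
#'
#' Numerical variables are summarised as median and interquartile range
#' (Q3 - Q1, linear-interpolation quartiles), with mean, SD (n-1
#' denominator, `NA` for a single value) and n alongside.
#'
#' @param values numeric vector with at least one finite value; `NA`s are
#'   dropped.
#' @return A list: `n`, `median`, `q1`, `q3`, `iqr`, `mean`, `sd`.
#' @export
descriptive_summary <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 1) gus_domain_error("need at least one finite value")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  list(n = length(values),
       median = stats::median(values),
       q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
       mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_)
}

## ---- stratified comparison table ---------------------------------------

#' Stratified detection and CSA comparison table for a cohort
#'
#' Reproduces the standard results layout: detection rates supine vs RLD
#' (per scan), preoperative vs postoperative (per scan, either position) and
#' laparoscopic vs open access (per patient, either position), each with an
#' uncorrected chi-squared test; plus RLD CSA descriptives pre vs post with
#' a pooled Student t-test, for the traced and the diameter-derived CSA.
#' Strata with no observations yield `NA` rows rather than errors.
#'
#' @param cohort a [gus_cohort()].
#' @return A data.frame, one comparison per row: `comparison`, `group1`,
#'   `k1`, `n1`, `group2`, `k2`, `n2`, `statistic`, `p_value`.
#' @export
cohort_comparison_table <- function(cohort) {
  safe_rate <- function(...) {
    tryCatch(detection_rate(cohort, ...),
             gus_domain_error = function(e) list(numerator = NA_integer_,
                                                 denominator = NA_integer_))
  }
  row_of <- function(comparison, g1, r1, g2, r2) {
    if (anyNA(c(r1$numerator, r2$numerator))) {
      stat <- NA_real_; p <- NA_real_
    } else {
      ts <- chi_squared_2x2(r1$numerator, r1$denominator - r1$numerator,
                            r2$numerator, r2$denominator - r2$numerator)
      stat <- ts$statistic; p <- ts$p_value
    }
    data.frame(comparison = comparison, group1 = g1,
               k1 = r1$numerator, n1 = r1$denominator,
               group2 = g2, k2 = r2$numerator, n2 = r2$denominator,
               statistic = stat, p_value = p, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row_of("position", "supine", safe_rate(position = "supine"),
           "rld", safe_rate(position = "rld")),
    row_of("phase", "preoperative",
           safe_rate(filter = function(s, p) s$phase == "preoperative"),
           "postoperative",
           safe_rate(filter = function(s, p) s$phase == "postoperative")),
    row_of("access", "laparoscopic",
           safe_rate(unit = "patient",
                     filter = function(s, p) p$surgical_access == "laparoscopic"),
           "open",
           safe_rate(unit = "patient",
                     filter = function(s, p) p$surgical_access == "open")))
  tab
}

#' Pre- vs postoperative RLD CSA comparison
#'
#' Splits the requested RLD CSA (traced or diameter-derived) by phase,
#' summarises both groups (median/IQR, mean) and tests the difference with
#' a pooled Student t-test.
#'
#' @param cohort a [gus_cohort()].
#' @param source `"measured"` (traced CSA) or `"calculated"` (from the two
#'   diameters).
#' @return A list with `preop`, `postop` (descriptive summaries) and `test`
#'   (`gus_test`, `NULL` when a group has fewer than 2 values).
#' @export
csa_phase_comparison <- function(cohort, source = c("calculated", "measured")) {
  source <- match.arg(source)
  s <- cohort$scans
  csa <- scan_csa_values(s, source = source, position = "rld")
  pre <- csa[s$phase == "preoperative" & !is.na(csa)]
  post <- csa[s$phase == "postoperative" & !is.na(csa)]
  list(preop = if (length(pre)) descriptive_summary(pre) else NULL,
       postop = if (length(post)) descriptive_summary(post) else NULL,
       test = if (length(pre) >= 2 && length(post) >= 2)
         student_t_two_sample(pre, post) else NULL)
}
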