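test_that("detection rates count scans and patients correctly", {
  co <- tiny_cohort()
  r <- detection_rate(co)  # either position, per scan
  expect_identical(r$numerator, 2L)
  expect_identical(r$denominator, 3L)

  r <- detection_rate(co, unit = "patient")
  expect_identical(r$numerator, 1L)
  expect_identical(r$denominator, 2L)

  r <- detection_rate(co, filter = function(s, p) p$surgical_access == "laparoscopic")
  expect_identical(r$denominator, 2L)

  # all-undetected cohort
  s <- co$scans
  for (pos in c("supine", "rld")) {
    s[[paste0(pos, "_detected")]] <- FALSE
    s[[paste0(pos, "_content")]] <- "unknown"
    for (f in paste0(pos, c("_d1_mm", "_d2_mm", "_csa_cm2"))) s[[f]] <- NA_real_
  }
  expect_equal(detection_rate(gus_cohort(co$patients, s))$fraction, 0)

  expect_error(detection_rate(co, filter = function(s, p) rep(FALSE, nrow(s))),
               class = "gus_domain_error")
})

test_that("uncorrected Pearson chi-squared matches closed form and chisq.test", {
  ts <- chi_squared_2x2(15, 4, 7, 15)
  expect_equal(ts$statistic, 9.107, tolerance = 1e-4)
  expect_equal(ts$p_value, 0.00255, tolerance = 1e-2)
  expect_identical(ts$df, 1)

  expect_equal(chi_squared_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_squared_2x2(10, 10, 10, 10)$p_value, 1)

  expect_equal(chi_squared_2x2(59, 35, 57, 37)$p_value, 0.764, tolerance = 1e-3)

  # matrix input and independent reference implementation
  set.seed(4)
  for (i in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2)
    ours <- chi_squared_2x2(m)
    ref <- stats::chisq.test(m, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
    # invariance under simultaneous row and column swaps
    swapped <- chi_squared_2x2(m[2:1, 2:1])
    expect_equal(swapped$statistic, ours$statistic)
  }

  expect_warning(z <- chi_squared_2x2(0, 0, 5, 5), "marginal")
  expect_equal(z$p_value, 1)
  expect_error(chi_squared_2x2(-1, 2, 3, 4), class = "gus_domain_error")
})

test_that("pooled Student t-test matches hand computation and t.test", {
  ts <- student_t_two_sample(c(1, 2, 3), c(4, 5, 6))
  # pooled variance 1, SE = sqrt(2/3): t = -3 / sqrt(2/3)
  expect_equal(ts$statistic, -3 / sqrt(2 / 3))
  expect_equal(round(ts$statistic, 3), -3.674)
  expect_identical(ts$df, 4)
  expect_equal(ts$p_value, 0.0213, tolerance = 1e-2)

  # identical samples
  ts <- student_t_two_sample(c(2, 2), c(2, 2))
  expect_equal(ts$statistic, 0); expect_equal(ts$p_value, 1)

  # antisymmetry
  set.seed(5)
  x <- rnorm(10); y <- rnorm(12, 1)
  expect_equal(student_t_two_sample(x, y)$statistic,
               -student_t_two_sample(y, x)$statistic)
  expect_equal(student_t_two_sample(x, y)$p_value,
               student_t_two_sample(y, x)$p_value)
  # reference implementation agreement
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(student_t_two_sample(x, y)$p_value, ref$p.value)

  expect_error(student_t_two_sample(1, 1:5), class = "gus_domain_error")
})

test_that("descriptive summaries use median, linear-interpolated IQR, n-1 SD", {
  s <- descriptive_summary(1:5)
  expect_equal(s$median, 3); expect_equal(s$iqr, 2); expect_equal(s$mean, 3)

  s <- descriptive_summary(7)
  expect_equal(s$median, 7); expect_equal(s$iqr, 0); expect_true(is.na(s$sd))

  s <- descriptive_summary(c(2, 4))
  expect_equal(s$mean, 3); expect_equal(s$sd, sqrt(2))

  expect_error(descriptive_summary(numeric()), class = "gus_domain_error")
  expect_error(descriptive_summary(c(NA, NaN)), class = "gus_domain_error")
})

test_that("comparison table reports strata and NA rows without crashing", {
  tab <- cohort_comparison_table(results_fixture())
  expect_identical(tab$comparison, c("position", "phase", "access"))
  expect_identical(tab$k1, c(59L, 16L, 15L))
  expect_identical(tab$k2, c(57L, 46L, 7L))

  # single-stratum cohort: access comparison row has NA statistic
  co <- tiny_cohort()
  co$patients$surgical_access <- "laparoscopic"
  tab <- cohort_comparison_table(gus_cohort(co$patients, co$scans))
  expect_true(is.na(tab$statistic[tab$comparison == "access"]))
})
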