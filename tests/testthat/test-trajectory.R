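traj_scans <- function(pid, pods, csas, phase = "postoperative") {
  do.call(rbind, Map(function(pod, csa) {
    scan_row(pid, phase, pod, rld_content = "empty", rld_csa = csa,
             rld_d1 = 20 * sqrt(csa / pi), rld_d2 = 20 * sqrt(csa / pi))
  }, pods, csas))
}

test_that("relative CSA series normalizes to the first postoperative day", {
  s <- traj_scans("P1", c(1L, 3L), c(6.0, 9.0))
  pts <- relative_csa_series(s, source = "measured")
  expect_equal(pts$pod, c(1L, 3L))
  expect_equal(pts$ratio, c(1.0, 1.5))
  expect_identical(pts$baseline, c(TRUE, FALSE))

  # constant CSA: all ratios 1
  s <- traj_scans("P1", 1:4, rep(5, 4))
  expect_equal(relative_csa_series(s, "measured")$ratio, rep(1, 4))

  # baseline falls back to the earliest available POD when POD 1 is missing
  s <- traj_scans("P1", c(2L, 4L), c(8.0, 10.0))
  pts <- relative_csa_series(s, "measured")
  expect_equal(pts$pod, c(2L, 4L))
  expect_equal(pts$ratio, c(1.0, 1.25))

  # calculated source uses the diameters
  pts_calc <- relative_csa_series(s, "calculated")
  expect_equal(pts_calc$ratio, c(1.0, 1.25), tolerance = 1e-9)

  # no usable postoperative CSA -> error naming the patient
  s <- scan_row("P9", "postoperative", 1L, detected = FALSE)
  expect_error(relative_csa_series(s, "measured"), "P9",
               class = "gus_domain_error")
  expect_error(relative_csa_series(rbind(traj_scans("A", 1L, 5),
                                         traj_scans("B", 1L, 5))),
               class = "gus_domain_error")
})

test_that("ratios are invariant to rescaling a patient's CSA values", {
  s <- traj_scans("P1", 1:4, c(6, 7.5, 9, 10))
  base <- relative_csa_series(s, "measured")$ratio
  for (k in c(0.5, 2, 13.7)) {
    sk <- traj_scans("P1", 1:4, k * c(6, 7.5, 9, 10))
    expect_equal(relative_csa_series(sk, "measured")$ratio, base)
  }
})

test_that("trajectory fit recovers exact lines and degenerate cases", {
  pts <- data.frame(patient_id = "P1", pod = 1:4,
                    ratio = 0.8 + 0.2 * (1:4), source = "measured",
                    baseline = FALSE)
  fit <- fit_trajectory(pts)
  expect_equal(fit$slope, 0.2)
  expect_equal(fit$intercept, 0.8)
  expect_equal(fit$r_squared, 1)

  # zero ratio variance: slope 0, R^2 undefined
  pts$ratio <- 1
  fit <- fit_trajectory(pts)
  expect_equal(fit$slope, 0)
  expect_true(is.na(fit$r_squared))

  expect_error(fit_trajectory(pts[1, ]), class = "gus_domain_error")
  pts$pod <- 2L
  expect_error(fit_trajectory(pts), class = "gus_domain_error")
})

test_that("R^2 equals the squared Pearson correlation (independent oracle)", {
  set.seed(8)
  pts <- data.frame(patient_id = "P1", pod = rep(1:5, 3),
                    ratio = 1 + 0.15 * rep(1:5, 3) + rnorm(15, 0, 0.1),
                    source = "measured", baseline = FALSE)
  fit <- fit_trajectory(pts)
  expect_equal(fit$r_squared, cor(pts$pod, pts$ratio)^2)
  # and the slope equals the closed-form least-squares slope
  expect_equal(fit$slope, cov(pts$pod, pts$ratio) / var(pts$pod))
})

test_that("pooled fit recovers the generator's slope on a small adverse cohort", {
  # 6 patients x 4 PODs, daily ratio slope 1/6, noise sd 0.1
  cfg <- cohort_config(n_patients = 6, adverse_fraction = 1,
                       detection_prob = c(open = 1, laparoscopic = 1, other = 1),
                       ratio_noise_sd = 0.1, seed = 99L)
  co <- generate_cohort(cfg)
  pts <- cohort_trajectory_points(co, source = "calculated", adverse_only = TRUE)
  fit <- fit_trajectory(pts)
  expect_equal(fit$slope, 1 / 6, tolerance = 0.05 / (1 / 6))
})
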