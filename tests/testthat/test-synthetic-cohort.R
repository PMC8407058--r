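test_that("generation is deterministic given a seed and validates its config", {
  cfg <- cohort_config(n_patients = 20, seed = 7L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  expect_error(cohort_config(n_patients = 0), class = "gus_validation_error")
  expect_error(cohort_config(adverse_fraction = 1.2), class = "gus_validation_error")
  expect_error(cohort_config(access_mix = c(open = 0.5, laparoscopic = 0.4,
                                            other = 0.2)),
               class = "gus_validation_error")
  expect_error(cohort_config(csa_preop = list(mean = -1, sdlog = 0.3)),
               class = "gus_validation_error")
  expect_error(cohort_config(postop_scans_range = c(3, 1)),
               class = "gus_validation_error")
})

test_that("degenerate config: full detection and all-empty content gives G0 everywhere", {
  cfg <- cohort_config(n_patients = 12,
                       detection_prob = c(open = 1, laparoscopic = 1, other = 1),
                       content_mix = c(empty = 1, liquid = 0, mixed = 0, solid = 0),
                       seed = 3L)
  co <- generate_cohort(cfg)
  expect_true(all(co$scans$supine_detected & co$scans$rld_detected))
  grades <- antral_grade(co$scans$supine_content, co$scans$rld_content)
  expect_true(all(grades == "G0"))
})

test_that("either-position detection rate matches the configured probabilities", {
  cfg <- cohort_config(n_patients = 410, seed = 21L)
  co <- generate_cohort(cfg)
  scans <- co$scans
  access <- co$patients$surgical_access[match(scans$patient_id,
                                              co$patients$patient_id)]
  either <- scans$supine_detected | scans$rld_detected
  conc <- cfg$detection_concordance
  for (a in c("open", "laparoscopic")) {
    p <- cfg$detection_prob[[a]]
    # shared draw with prob conc, independent otherwise
    p_either <- conc * p + (1 - conc) * (1 - (1 - p)^2)
    n <- sum(access == a); k <- sum(either[access == a])
    ci <- qbinom(c(0.005, 0.995), n, p_either)
    expect_gte(k, ci[1]); expect_lte(k, ci[2])
  }
})

test_that("stratum detection rates converge to detection_prob (LLN)", {
  cfg <- cohort_config(n_patients = 3500, detection_concordance = 0,
                       postop_scans_range = c(2L, 2L), seed = 33L)
  co <- generate_cohort(cfg)
  scans <- co$scans
  expect_gt(nrow(scans), 9000)
  access <- co$patients$surgical_access[match(scans$patient_id,
                                              co$patients$patient_id)]
  for (a in c("open", "laparoscopic")) {
    for (pos in c("supine", "rld")) {
      obs <- mean(scans[[paste0(pos, "_detected")]][access == a])
      expect_equal(obs, cfg$detection_prob[[a]], tolerance = 0.05)
    }
  }
})

test_that("adverse patients carry elevated, rising postoperative CSA", {
  cfg <- cohort_config(n_patients = 300,
                       detection_prob = c(open = 1, laparoscopic = 1, other = 1),
                       seed = 5L)
  co <- generate_cohort(cfg)
  post <- co$scans[co$scans$phase == "postoperative", ]
  adverse <- co$patients$adverse_outcome[match(post$patient_id,
                                               co$patients$patient_id)]
  csa <- scan_csa_values(post, "calculated", "rld")
  # group means near their configured targets
  expect_equal(mean(csa[adverse]), cfg$adverse_csa_mean, tolerance = 0.1)
  expect_equal(mean(csa[!adverse]), cfg$csa_postop$mean, tolerance = 0.1)
  # relative trajectory slope near the configured +50%/72 h
  pts <- cohort_trajectory_points(co, "calculated", adverse_only = TRUE)
  expect_equal(fit_trajectory(pts)$slope, cfg$adverse_daily_ratio_slope,
               tolerance = 0.1)
})
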