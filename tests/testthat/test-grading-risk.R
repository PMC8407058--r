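test_that("antral grading matches the three-level definition", {
  expect_identical(antral_grade("empty", "empty"), "G0")
  expect_identical(antral_grade("empty", "liquid"), "G1")
  expect_identical(antral_grade("liquid", "liquid"), "G2")
  expect_identical(antral_grade("mixed", "mixed"), "G2")     # mixed is fluid-bearing
  expect_identical(antral_grade("solid", "empty"), "G0")     # solid is not fluid
  expect_identical(antral_grade("unknown", "liquid"), "G1")  # minimum consistent grade
  expect_identical(antral_grade("unknown", "empty"), "indeterminate")
  expect_identical(antral_grade("empty", "unknown"), "indeterminate")
  expect_identical(antral_grade("liquid", "empty"), "indeterminate") # outside the system
  expect_error(antral_grade("fluid", "empty"), class = "gus_domain_error")
})

test_that("grading is monotone under adding fluid", {
  rank <- c(G0 = 0, G1 = 1, G2 = 2)
  contents <- c("empty", "liquid", "solid", "mixed", "unknown")
  for (su in contents) for (rl in contents) {
    g0 <- antral_grade(su, rl)
    for (pos in 1:2) {
      orig <- c(su, rl)
      if (orig[pos] %in% c("liquid", "mixed")) next
      repl <- orig; repl[pos] <- "liquid"
      g1 <- antral_grade(repl[1], repl[2])
      if (g0 %in% names(rank) && g1 %in% names(rank)) {
        expect_gte(rank[[g1]], rank[[g0]])
      }
      if (g0 == "G2") expect_identical(g1, "G2")
    }
  }
})

risk_case <- function(su, rl, csa_rld, weight, age = 0L, threshold = 1.5) {
  scan <- scan_row("P1", "postoperative", 1L,
                   supine_content = su, rld_content = rl, rld_csa = csa_rld)
  classify_risk(scan, patient_row(age = age, weight = weight), threshold)
}

test_that("risk flowchart reproduces its canonical branches", {
  r <- risk_case("liquid", "liquid", 5.0, 70)
  expect_identical(r$risk, "high"); expect_identical(r$fired_rule, "grade2_fluid")

  r <- risk_case("solid", "empty", 5.0, 70)
  expect_identical(r$risk, "high"); expect_identical(r$fired_rule, "solid_content")

  # empty both positions, CSA 5 cm^2, age 50, weight 72: 36 mL = 0.5 mL/kg
  r <- risk_case("empty", "empty", 5.0, 72, age = 50L)
  expect_equal(r$volume_ml_per_kg, 0.5)
  expect_identical(r$risk, "low"); expect_identical(r$fired_rule, "below_threshold")

  # threshold comparison is strict: exactly 1.5 mL/kg is not high
  r <- risk_case("empty", "empty", (1.5 * 60 - 27) / 14.6, 60)
  expect_equal(r$volume_ml_per_kg, 1.5)
  expect_identical(r$risk, "low")

  # volume branch needs RLD CSA and weight
  r <- risk_case("empty", "empty", NA_real_, 70)
  expect_identical(r$risk, "indeterminate")
  expect_identical(r$fired_rule, "insufficient_data")
  r <- risk_case("empty", "empty", 5.0, NA_real_)
  expect_identical(r$risk, "indeterminate")

  # RLD CSA falls back to the two diameters when the traced value is absent
  scan <- scan_row("P1", "postoperative", 1L, rld_csa = NA_real_,
                   rld_d1 = 20, rld_d2 = 20)
  r <- classify_risk(scan, patient_row(age = 0L, weight = 60))
  expect_equal(r$volume_ml, 27 + 14.6 * pi)
})

test_that("risk flowchart agrees with the exhaustive truth-table oracle", {
  contents <- c("empty", "liquid", "solid", "mixed", "unknown")
  # vpk targets are hit by inverting the volume model at age 0 / age 50
  vpk_cases <- list(
    list(vpk = NA_real_, csa = NA_real_, weight = 60, age = 0L),    # CSA missing
    list(vpk = NA_real_, csa = 5.0, weight = NA_real_, age = 0L),   # weight missing
    list(vpk = 0, csa = 0, weight = 60, age = 50L),                 # clamped to 0
    list(vpk = 1.5, csa = (1.5 * 60 - 27) / 14.6, weight = 60, age = 0L),
    list(vpk = 1.6, csa = (1.6 * 60 - 27) / 14.6, weight = 60, age = 0L))
  for (su in contents) for (rl in contents) for (vc in vpk_cases) {
    got <- risk_case(su, rl, vc$csa, vc$weight, vc$age)
    want <- oracle_risk(su, rl, vc$vpk)
    expect_identical(got$risk, want,
                     info = sprintf("su=%s rl=%s vpk=%s", su, rl, vc$vpk))
    # label/rule invariants
    expect_identical(got$risk == "high",
                     got$fired_rule %in% c("solid_content", "grade2_fluid",
                                           "volume_over_threshold"))
    expect_identical(got$risk == "indeterminate",
                     got$fired_rule == "insufficient_data")
  }
})

test_that("raising volume per kg never turns a high assessment low", {
  contents <- c("empty", "liquid", "solid", "mixed", "unknown")
  csa_lo <- 2.0; csa_hi <- 12.0  # 0.95 vs 5.4 mL/kg at age 0, 60 kg
  for (su in contents) for (rl in contents) {
    lo <- risk_case(su, rl, csa_lo, 60)$risk
    hi <- risk_case(su, rl, csa_hi, 60)$risk
    if (lo == "high") expect_identical(hi, "high")
  }
})

test_that("patient aggregation and confusion counts behave", {
  co <- tiny_cohort()
  ass <- assess_cohort(co)
  expect_identical(nrow(ass$scans), 3L)
  # P1: postoperative scan has liquid RLD only -> G1, low (volume evaluable)
  expect_identical(ass$patients$risk[ass$patients$patient_id == "P1"], "low")
  # P2: single undetected scan -> indeterminate
  expect_identical(ass$patients$risk[ass$patients$patient_id == "P2"], "indeterminate")

  # all adverse flagged high -> 100% prediction rate
  ass2 <- data.frame(patient_id = c("P1", "P2"), risk = c("high", "low"))
  conf <- prediction_confusion(ass2, co$patients)
  expect_identical(conf$true_pos, 1L)
  expect_equal(conf$prediction_rate_pct, 100)

  # no adverse outcomes -> rate undefined, counts still returned
  p <- co$patients; p$adverse_outcome <- FALSE
  expect_warning(conf <- prediction_confusion(ass2, p), "undefined")
  expect_true(is.na(conf$prediction_rate_pct))
  expect_identical(conf$false_pos, 1L)

  expect_error(prediction_confusion(rbind(ass2, ass2), co$patients),
               class = "gus_domain_error")
})
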