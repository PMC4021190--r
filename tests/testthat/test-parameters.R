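test_that("bundled default profile carries the published parameter values", {
  p <- crc_parameters()

  # screening test characteristics
  expect_equal(p$ifobt$sensitivity_crc, 0.479)
  expect_equal(p$ifobt$sensitivity_polyp, 0.2119)
  expect_equal(p$ifobt$specificity, 0.9146)
  expect_equal(p$colonoscopy$sensitivity_crc, 0.95)
  expect_equal(p$colonoscopy$sensitivity_polyp, 0.85)
  expect_equal(p$colonoscopy$specificity, 1)
  expect_equal(p$ifobt_uptake, 0.40)
  expect_equal(p$colonoscopy_uptake, 0.40)
  expect_equal(p$followup_colonoscopy_compliance, 0.65)

  # costs
  expect_equal(p$costs$ifobt_invitation_kit, 10)
  expect_equal(p$costs$ifobt_pathology, 20)
  expect_equal(p$costs$gp_visit_referral, 32.10)
  expect_equal(p$costs$colonoscopy, 1082)
  expect_equal(p$costs$colonoscopy_polypectomy, 1606)
  expect_equal(unname(p$costs$annual_treatment),
               c(1716, 4114, 9990.5, 35578))
  expect_equal(p$costs$discount_rate, 0.05)

  # natural history (average-risk scale, as printed)
  expect_equal(p$natural_history$incidence_small_adenoma,
               c(0.24, 0.30, 0.32, 0.27, 0.22))
  expect_equal(p$natural_history$incidence_large_adenoma,
               c(0.07, 0.08, 0.10, 0.16, 0.21))
  expect_equal(unname(p$natural_history$incidence_crc[, "A"]),
               c(0.0012, 0.0022, 0.0033, 0.0050, 0.0067))
  expect_equal(unname(p$natural_history$incidence_crc[5, ]),
               c(0.0067, 0.0031, 0.0027, 0.0009))
  expect_equal(unname(p$natural_history$crc_death),
               c(0.034, 0.051, 0.085, 0.282))
  expect_equal(unname(p$natural_history$symptomatic_dx),
               c(0.091, 0.2948, 0.7613, 1))
  expect_equal(p$natural_history$frac_crc_from_large_adenoma, 0.85)
})

test_that("risk-adjusted initial-state distribution equals the published age-50 prevalences", {
  p4 <- apply_risk_multiplier(crc_parameters(), 4)
  isp <- p4$initial_state_probs
  expect_equal(unname(isp["Normal"]), 0.78)
  expect_equal(unname(isp["AdenomaSmall"]), 0.1668)
  expect_equal(unname(isp["AdenomaLarge"]), 0.0464)
  expect_equal(unname(isp[c("CRC_A", "CRC_B", "CRC_C", "CRC_D")]),
               c(0.0036, 0.0016, 0.0012, 0.0004))
  expect_equal(sum(isp), 1, tolerance = 1e-12)
})

test_that("age bands partition the horizon and lookup is unique", {
  p <- crc_parameters()
  idx <- age_band_index(p, 50:90)
  expect_equal(length(idx), 41)
  expect_true(all(idx %in% 1:5))
  expect_equal(age_band_index(p, c(50, 54, 55, 69, 70, 90)),
               c(1, 1, 2, 4, 5, 5))
  expect_error(age_band_index(p, 49), "horizon")
  expect_error(age_band_index(p, 91), "horizon")
})

test_that("validation errors name the offending field", {
  expect_error(crc_parameters(ifobt = list(specificity = 1.3)),
               "ifobt\\$specificity")
  expect_error(crc_parameters(
    natural_history = list(symptomatic_dx = c(A = 0.1, B = 0.3, C = 0.8, D = 0.9))),
    "symptomatic_dx")
  expect_error(crc_parameters(
    initial_state_probs = stats::setNames(c(0.9, rep(0, 13)), health_states())),
    "initial_state_probs")
  # user life table with a gap names the missing age
  expect_error(
    bundled_life_table("user_supplied",
                       table = stats::setNames(rep(0.01, 40), setdiff(50:90, 73))),
    "73")
})

test_that("risk multiplier scales incidence and prevalence, clamps at 1, and is monotone", {
  base <- crc_parameters()

  # rr = 1 leaves the printed fields untouched (after scale conversion)
  p1 <- apply_risk_multiplier(base, 1)
  expect_equal(p1$initial_state_probs, base$initial_state_probs)
  expect_equal(p1$natural_history$incidence_crc,
               base$natural_history$incidence_crc)

  # clamping: the face-value annual reading overflows and warns
  face <- crc_parameters(adenoma_incidence_scale = "annual")
  expect_warning(p4f <- apply_risk_multiplier(face, 4), "clamped")
  expect_equal(max(p4f$natural_history$incidence_small_adenoma), 1)

  # monotonicity of every scaled probability in rr
  p3 <- apply_risk_multiplier(base, 3, quiet = TRUE)
  p5 <- apply_risk_multiplier(base, 5, quiet = TRUE)
  for (f in c("incidence_small_adenoma", "incidence_large_adenoma", "incidence_crc")) {
    expect_true(all(p3$natural_history[[f]] <= p5$natural_history[[f]]))
  }
  disease <- c("AdenomaSmall", "AdenomaLarge", "CRC_A", "CRC_B", "CRC_C", "CRC_D")
  expect_true(all(p3$initial_state_probs[disease] <= p5$initial_state_probs[disease]))

  # unchanged blocks
  expect_equal(p5$ifobt, base$ifobt)
  expect_equal(p5$costs, base$costs)
  expect_equal(p5$natural_history$crc_death, base$natural_history$crc_death)

  # double application is an error; unnormalisable prevalences are an error
  expect_error(apply_risk_multiplier(p3, 2), "already been applied")
  expect_error(apply_risk_multiplier(base, 19, quiet = TRUE), "normalized")
})

test_that("adenoma incidence scale conversion is 1 - (1 - p)^(1/5)", {
  p <- crc_parameters()  # default per_band
  expect_equal(crcscreen:::adenoma_incidence(p, "small"),
               1 - (1 - c(0.24, 0.30, 0.32, 0.27, 0.22))^(1 / 5))
  face <- crc_parameters(adenoma_incidence_scale = "annual")
  expect_equal(crcscreen:::adenoma_incidence(face, "large"),
               c(0.07, 0.08, 0.10, 0.16, 0.21))
})

test_that("parameters serialise and reload round-trip", {
  p <- crc_parameters(relative_risk = 3,
                      natural_history = list(stage_progression = 0.07))
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, path)
  p2 <- load_parameters(path)
  for (f in c("relative_risk", "ifobt", "colonoscopy", "costs",
              "initial_state_probs", "ifobt_uptake", "surveillance_interval")) {
    expect_equal(p2[[f]], p[[f]], label = f)
  }
  expect_equal(p2$natural_history$stage_progression, 0.07)
  expect_equal(p2$natural_history$incidence_crc,
               p$natural_history$incidence_crc)
  expect_equal(as.numeric(p2$natural_history$other_cause_mortality),
               as.numeric(p$natural_history$other_cause_mortality))
  # and the defaults path
  expect_equal(load_parameters(NULL)$ifobt$sensitivity_crc, 0.479)
})
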