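test_that("built-in strategies encode the four published programmes", {
  s <- built_in_strategies()
  expect_named(s, c("usual_care", "ifobt2", "colo5", "colo10"))
  expect_equal(s$usual_care$invite_ages, c(50L, 55L, 60L, 65L))
  expect_equal(s$usual_care$modality, "iFOBT")
  expect_equal(s$ifobt2$invite_ages, seq(50L, 88L, 2L))
  expect_equal(s$colo5$invite_ages, seq(50L, 85L, 5L))
  expect_equal(s$colo5$modality, "colonoscopy")
  expect_equal(s$colo10$invite_ages, c(50L, 60L, 70L, 80L))
  expect_error(crc_strategy("bad", "iFOBT", ages = c(45, 60)), "\\[50, 90\\)")
})

test_that("screener status is one persistent draw at the uptake probability", {
  rp <- resolved_default()
  s <- built_in_strategies()$usual_care
  set.seed(3)
  expect_false(any(assign_screener_status(
    crc_strategy("s0", "iFOBT", ages = 50, uptake = 0), rp, 1000)))
  expect_true(all(assign_screener_status(
    crc_strategy("s1", "iFOBT", ages = 50, uptake = 1), rp, 1000)))
  frac <- mean(assign_screener_status(s, rp, 1e5))
  expect_within_3se(frac, 0.40, sqrt(0.4 * 0.6 / 1e5))
})

test_that("iFOBT positivity follows sensitivity and specificity by true state", {
  rp <- resolved_default()
  set.seed(7)
  pos_crc <- mean(replicate(2e4, perform_ifobt("CRC_B", rp$ifobt) == "positive"))
  expect_within_3se(pos_crc, 0.479, sqrt(0.479 * 0.521 / 2e4))
  pos_norm <- mean(replicate(2e4, perform_ifobt("Normal", rp$ifobt) == "positive"))
  expect_within_3se(pos_norm, 1 - 0.9146, sqrt(0.0854 * 0.9146 / 2e4))

  perfect <- list(sensitivity_crc = 1, sensitivity_polyp = 1, specificity = 1)
  expect_equal(perform_ifobt("CRC_A", perfect), "positive")
  expect_equal(perform_ifobt("AdenomaLarge", perfect), "positive")
  expect_equal(perform_ifobt("Normal", perfect), "negative")
  expect_error(perform_ifobt("Treat_A", rp$ifobt), "cannot be performed")
  expect_error(perform_ifobt("DeadCRC", rp$ifobt), "cannot be performed")
})

test_that("colonoscopy findings trigger polypectomy, surveillance entry and diagnosis", {
  rp <- resolved_default()
  perfect <- list(sensitivity_crc = 1, sensitivity_polyp = 1, specificity = 1)
  blind <- list(sensitivity_crc = 1, sensitivity_polyp = 0, specificity = 1)

  out <- perform_colonoscopy("AdenomaSmall", perfect, rp$costs)
  expect_equal(out$finding, "small_adenoma_found")
  expect_equal(out$new_state, 1L)
  expect_true(out$polypectomy)
  expect_equal(out$cost, 1606)

  out <- perform_colonoscopy("AdenomaSmall", perfect, rp$costs, in_surveillance = TRUE)
  expect_equal(out$new_state, 4L)

  out <- perform_colonoscopy("AdenomaLarge", perfect, rp$costs)
  expect_equal(out$finding, "large_adenoma_found")
  expect_equal(out$new_state, 4L)

  out <- perform_colonoscopy("CRC_C", perfect, rp$costs)
  expect_equal(out$finding, "crc_found")
  expect_equal(out$new_state, 11L)  # Treat_C
  expect_false(out$polypectomy)
  expect_equal(out$cost, 1082)

  out <- perform_colonoscopy("Normal", perfect, rp$costs)
  expect_equal(out$finding, "negative")
  expect_equal(out$cost, 1082)

  # sensitivity 0 for polyps: adenomas are never found
  set.seed(1)
  found <- replicate(200, perform_colonoscopy("AdenomaLarge", blind, rp$costs)$finding)
  expect_true(all(found == "negative"))
  expect_error(perform_colonoscopy("Treat_B", perfect, rp$costs), "cannot")
})

test_that("run_screening_round implements the iFOBT cascade and its costs", {
  rp <- resolved_default()
  uc <- built_in_strategies()$usual_care
  base_ind <- list(state = 1L, screener = TRUE, in_surveillance = FALSE,
                   entered_surveillance_at = NA_integer_,
                   diagnosed_stage = NA_character_,
                   counters = c(ifobt = 0L, diagnostic_colonoscopy = 0L,
                                screening_colonoscopy = 0L,
                                surveillance_colonoscopy = 0L, polypectomy = 0L))

  expect_error(run_screening_round(base_ind, uc, 52, rp), "not an invitation age")

  # non-screener: no events, no cost
  ns <- base_ind; ns$screener <- FALSE
  out <- run_screening_round(ns, uc, 55, rp)
  expect_equal(nrow(out$events), 0)

  # screener with a guaranteed-negative test: invitation + pathology only
  rp_neg <- rp; rp_neg$ifobt$specificity <- 1
  out <- run_screening_round(base_ind, uc, 55, rp_neg)
  expect_equal(out$events$procedure, "iFOBT")
  expect_equal(sum(out$events$cost), 30)
  expect_equal(unname(out$counters["ifobt"]), 1L)

  # positive with zero follow-up compliance: no diagnostic colonoscopy
  crc_ind <- base_ind; crc_ind$state <- 6L  # CRC_B
  rp_pos <- rp; rp_pos$ifobt$sensitivity_crc <- 1
  rp_pos$followup_colonoscopy_compliance <- 0
  out <- run_screening_round(crc_ind, uc, 60, rp_pos)
  expect_equal(out$events$procedure, "iFOBT")
  expect_equal(unname(out$counters["diagnostic_colonoscopy"]), 0L)

  # positive, compliant, detected: GP referral + colonoscopy, diagnosis
  rp_pos$followup_colonoscopy_compliance <- 1
  rp_pos$colonoscopy$sensitivity_crc <- 1
  out <- run_screening_round(crc_ind, uc, 60, rp_pos)
  expect_equal(out$events$procedure, c("iFOBT", "diagnostic_colonoscopy"))
  expect_equal(sum(out$events$cost), 30 + 32.10 + 1082)
  expect_equal(out$state, 10L)  # Treat_B
  expect_equal(out$diagnosed_stage, "B")
})

test_that("surveillance rounds recur five-yearly and detect new disease", {
  rp <- resolved_default()
  ind <- list(state = 4L, screener = TRUE, in_surveillance = TRUE,
              entered_surveillance_at = 60L, diagnosed_stage = NA_character_,
              counters = c(ifobt = 0L, diagnostic_colonoscopy = 0L,
                           screening_colonoscopy = 0L,
                           surveillance_colonoscopy = 0L, polypectomy = 0L))
  out <- surveillance_round(ind, 65, rp)
  expect_equal(out$events$procedure, "surveillance_colonoscopy")
  expect_equal(unname(out$counters["surveillance_colonoscopy"]), 1L)
  expect_true(out$in_surveillance)

  # a surveillance patient with preclinical CRC is detected at ~0.95
  crc <- ind; crc$state <- 5L
  set.seed(8)
  det <- replicate(2000, {
    r <- surveillance_round(crc, 65, rp)
    identical(r$state, 9L)
  })
  expect_within_3se(mean(det), 0.95, sqrt(0.95 * 0.05 / 2000))

  # dead or diagnosed: no round
  dead <- ind; dead$state <- 14L
  expect_equal(nrow(surveillance_round(dead, 65, rp)$events), 0)
})

test_that("per-lifetime surveillance cadence holds in full simulation", {
  # force: screener, large adenoma at entry, perfect colonoscopy at age 50
  # -> surveillance entry at 50, surveillance colonoscopies at 55, 60, ...
  p <- crc_parameters(
    natural_history = list(
      incidence_small_adenoma = rep(0, 5),
      incidence_large_adenoma = rep(0, 5),
      incidence_crc = matrix(0, 5, 4, dimnames = list(NULL, c("A", "B", "C", "D"))),
      other_cause_mortality = stats::setNames(rep(0, 41), 50:90)),
    initial_state_probs = stats::setNames(
      c(0, 0, 1, rep(0, 11)), health_states()),
    relative_risk = 1,
    colonoscopy_uptake = 1)
  rp <- crcscreen:::resolve_parameters(p)
  rp$colonoscopy$sensitivity_polyp <- 1
  res <- run_cohort(built_in_strategies()$colo10, rp, n = 50, seed = 2)
  # screening colonoscopy at 50 (all 50), then surveillance at 55,60,...,85
  # on the 5-year clock (7 rounds); no further primary screening
  expect_equal(unname(res$colonoscopies["screening"]), 50)
  expect_equal(unname(res$colonoscopies["surveillance"]), 50 * 7)
  expect_equal(res$polypectomies, 50)
})

test_that("uptake zero reproduces the no-screening run exactly", {
  p <- crc_parameters(ifobt_uptake = 0, colonoscopy_uptake = 0)
  none <- run_cohort(NULL, p, n = 4000, seed = 9)
  for (s in built_in_strategies()) {
    res <- run_cohort(s, p, n = 4000, seed = 9)
    expect_equal(res$crc_cases, none$crc_cases)
    expect_equal(res$crc_deaths, none$crc_deaths)
    expect_equal(res$total_colonoscopies, 0)
    expect_equal(res$mean_discounted_cost, none$mean_discounted_cost)
    expect_equal(res$mean_discounted_life_years, none$mean_discounted_life_years)
  }
})
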