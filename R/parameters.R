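#' Model parameters
#'
#' `crc_parameters()` builds the complete, validated parameter set of the
#' model. The bundled default profile carries the published Australian
#' estimates this package re-implements: age-band incidence of small/large
#' adenomas and of Dukes' A-D colorectal cancer, stage-specific annual CRC
#' mortality, symptomatic-diagnosis probabilities, iFOBT and colonoscopy test
#' characteristics, uptake and follow-up compliance, unit and annual
#' treatment costs, a 5% annual discount rate, and the age-50 initial-state
#' prevalences.
#'
#' Incidence and prevalence defaults are AVERAGE-RISK values; the familial
#' risk multiplier (`relative_risk`, default 4 for the "moderately increased
#' risk" NHMRC category) is applied by [apply_risk_multiplier()] — the
#' simulation engine does this automatically. After multiplication the
#' initial-state distribution equals the published moderately-increased-risk
#' prevalences (e.g. small adenoma 0.0417 * 4 = 0.1668, normal 0.78).
#'
#' Two quantities are not published and are package choices:
#' `stage_progression`, the annual probability that an (undiagnosed or
#' treated) cancer advances one Dukes' stage, calibrated once against the
#' published usual-care event counts (see the methods vignette), and the
#' stand-in life table ([bundled_life_table()]).
#'
#' @param ... named overrides of any top-level field (e.g.
#'   `relative_risk = 3`, `costs = list(...)`). Nested lists are merged
#'   field-by-field over the defaults.
#' @return an object of class `crc_parameters` (a validated nested list).
#' @seealso [load_parameters()], [apply_risk_multiplier()]
#' @export
#' @examples
#' p <- crc_parameters()
#' p$ifobt$sensitivity_crc     # 0.479
#' p$costs$annual_treatment["D"]  # 35578
crc_parameters <- function(...) {
  defaults <- list(
    age_bands = data.frame(lower = c(50L, 55L, 60L, 65L, 70L),
                           upper = c(54L, 59L, 64L, 69L, 90L)),
    natural_history = list(
      # annual average-risk onset probabilities by age band (50-54 ... >=70)
      incidence_small_adenoma = c(0.24, 0.30, 0.32, 0.27, 0.22),
      incidence_large_adenoma = c(0.07, 0.08, 0.10, 0.16, 0.21),
      # rows = age band, cols = Dukes' stage at onset
      incidence_crc = matrix(
        c(0.0012, 0.0005, 0.0005, 0.0001,
          0.0022, 0.0010, 0.0008, 0.0003,
          0.0033, 0.0016, 0.0013, 0.0004,
          0.0050, 0.0023, 0.0020, 0.0007,
          0.0067, 0.0031, 0.0027, 0.0009),
        nrow = 5, byrow = TRUE, dimnames = list(NULL, c("A", "B", "C", "D"))),
      crc_death = c(A = 0.034, B = 0.051, C = 0.085, D = 0.282),
      symptomatic_dx = c(A = 0.091, B = 0.2948, C = 0.7613, D = 1),
      # annual probability of advancing one Dukes' stage (undiagnosed and
      # treated disease alike). Not published; jointly calibrated with
      # cure_rate, once, against the published usual-care anchors (cases,
      # deaths, mean cost, life expectancy) — see the methods vignette.
      stage_progression = 0.01,
      # annual probability that a treated (diagnosed) patient exits the
      # treatment phase cured. The stage-specific yearly CRC mortality is
      # derived from survival measured from diagnosis over a bounded
      # follow-up, so the excess-risk (and treatment-cost) phase must be
      # bounded too; the geometric exit gives a mean phase of ~3 years.
      # Cured patients face no further CRC mortality or treatment cost,
      # never re-enter screening, but can develop a new primary.
      cure_rate = 0.35,
      # the stage-specific yearly CRC mortality derives from survival
      # measured FROM DIAGNOSIS, so by default it applies only to diagnosed
      # (treatment) states; preclinical undiagnosed disease progresses and
      # presents symptomatically but carries no excess mortality. Set TRUE
      # to apply the same mortality to undiagnosed CRC states as well.
      undiagnosed_crc_mortality = FALSE,
      frac_crc_from_large_adenoma = 0.85,
      other_cause_mortality = bundled_life_table()
    ),
    ifobt = list(sensitivity_crc = 0.479, sensitivity_polyp = 0.2119,
                 specificity = 0.9146),
    colonoscopy = list(sensitivity_crc = 0.95, sensitivity_polyp = 0.85,
                       specificity = 1),
    costs = list(
      ifobt_invitation_kit = 10, ifobt_pathology = 20,
      gp_visit_referral = 32.10,
      colonoscopy = 1082, colonoscopy_polypectomy = 1606,
      annual_treatment = c(A = 1716, B = 4114, C = 9990.5, D = 35578),
      discount_rate = 0.05
    ),
    # average-risk prevalences at age 50 (disease values are the published
    # moderately-increased-risk prevalences divided by the base RR of 4)
    initial_state_probs = stats::setNames(
      c(0.945, 0.0417, 0.0116, 0, 0.0009, 0.0004, 0.0003, 0.0001,
        0, 0, 0, 0, 0, 0),
      health_states()),
    relative_risk = 4,
    risk_applied = FALSE,
    ifobt_uptake = 0.40,
    colonoscopy_uptake = 0.40,
    followup_colonoscopy_compliance = 0.65,
    surveillance_interval = 5L,
    horizon = c(start = 50L, end = 90L),
    # interpretation flag for the adenoma incidence rows: "per_band" (the
    # default) reads the published values as per-5-year-band probabilities
    # and converts to annual via 1 - (1 - p)^(1/5); "annual" takes them at
    # face value. Face value is epidemiologically implausible after risk
    # multiplication (0.30 * 4 -> certain annual onset) and makes the
    # adenoma-carcinoma apportionment of CRC onset incoherent (large-adenoma
    # occupancy exceeding the 85% origination share); see methods vignette.
    adenoma_incidence_scale = "per_band",
    # competing-risk ordering toggle (see methods vignette)
    diagnosis_before_progression = TRUE
  )
  params <- modify_list_deep(defaults, list(...))
  class(params) <- "crc_parameters"
  validate_parameters(params)
  params
}

# recursive version of modifyList that merges nested named lists
modify_list_deep <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && !is.data.frame(base[[nm]]) &&
        is.list(overrides[[nm]]) && !is.data.frame(overrides[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set: probabilities in
#' \[0, 1\], age bands partitioning the 50-90 horizon, an initial-state
#' distribution summing to 1, a complete other-cause mortality schedule,
#' non-negative costs, and the published constraint that symptomatic
#' diagnosis of Dukes' D disease is certain. Errors name the offending
#' field.
#'
#' @param params a `crc_parameters` object (or plain list with the same
#'   structure).
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg) stop("invalid parameter `", field, "`: ", msg,
                                    call. = FALSE)
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
      fail(field, "probabilities must lie in [0, 1]")
  }

  ab <- params$age_bands
  if (!identical(ab$lower[1], 50L) && ab$lower[1] != 50)
    fail("age_bands", "first band must start at age 50")
  if (ab$upper[nrow(ab)] < 90) fail("age_bands", "last band must reach age 90")
  if (nrow(ab) > 1 && !all(ab$lower[-1] == ab$upper[-nrow(ab)] + 1L))
    fail("age_bands", "bands must partition [50, 90] without gaps or overlap")

  nh <- params$natural_history
  n_bands <- nrow(ab)
  for (f in c("incidence_small_adenoma", "incidence_large_adenoma")) {
    if (length(nh[[f]]) != n_bands)
      fail(paste0("natural_history$", f), "one value per age band required")
    chk_prob(nh[[f]], paste0("natural_history$", f))
  }
  if (!is.matrix(nh$incidence_crc) || nrow(nh$incidence_crc) != n_bands ||
      ncol(nh$incidence_crc) != 4)
    fail("natural_history$incidence_crc", "must be a bands x 4 (A-D) matrix")
  chk_prob(nh$incidence_crc, "natural_history$incidence_crc")
  chk_prob(nh$crc_death, "natural_history$crc_death")
  chk_prob(nh$symptomatic_dx, "natural_history$symptomatic_dx")
  if (nh$symptomatic_dx[["D"]] != 1)
    fail("natural_history$symptomatic_dx", "Dukes' D diagnosis probability must be 1")
  chk_prob(nh$stage_progression, "natural_history$stage_progression")
  chk_prob(nh$cure_rate, "natural_history$cure_rate")
  chk_prob(nh$frac_crc_from_large_adenoma,
           "natural_history$frac_crc_from_large_adenoma")
  qx <- nh$other_cause_mortality
  missing_ages <- setdiff(50:90, as.integer(names(qx)))
  if (length(missing_ages) > 0)
    fail("natural_history$other_cause_mortality",
         paste("missing ages:", paste(missing_ages, collapse = ", ")))
  chk_prob(as.numeric(qx), "natural_history$other_cause_mortality")

  for (tst in c("ifobt", "colonoscopy")) {
    for (f in c("sensitivity_crc", "sensitivity_polyp", "specificity"))
      chk_prob(params[[tst]][[f]], paste0(tst, "$", f))
  }

  co <- params$costs
  for (f in c("ifobt_invitation_kit", "ifobt_pathology", "gp_visit_referral",
              "colonoscopy", "colonoscopy_polypectomy", "annual_treatment")) {
    if (any(co[[f]] < 0)) fail(paste0("costs$", f), "costs must be >= 0")
  }
  if (co$discount_rate < 0) fail("costs$discount_rate", "must be >= 0")

  isp <- params$initial_state_probs
  if (length(isp) != .N_STATES)
    fail("initial_state_probs", "must give one probability per health state")
  chk_prob(isp, "initial_state_probs")
  if (abs(sum(isp) - 1) > 1e-9)
    fail("initial_state_probs", sprintf("must sum to 1 (got %.12f)", sum(isp)))
  nonzero <- isp[c("Surveillance", "Treat_A", "Treat_B", "Treat_C", "Treat_D",
                   "DeadCRC", "DeadOther")]
  if (any(nonzero > 0))
    fail("initial_state_probs",
         "surveillance, treatment and death states must start empty")

  if (params$relative_risk <= 0) fail("relative_risk", "must be > 0")
  chk_prob(params$ifobt_uptake, "ifobt_uptake")
  chk_prob(params$colonoscopy_uptake, "colonoscopy_uptake")
  chk_prob(params$followup_colonoscopy_compliance,
           "followup_colonoscopy_compliance")
  if (params$surveillance_interval < 1)
    fail("surveillance_interval", "must be >= 1 year")
  if (!params$adenoma_incidence_scale %in% c("annual", "per_band"))
    fail("adenoma_incidence_scale", "must be 'annual' or 'per_band'")
  invisible(params)
}

#' Load parameters from a configuration document
#'
#' Reads a JSON configuration (path or pre-parsed list) of overrides and
#' merges it over the bundled default profile, then validates. The
#' configuration mirrors the structure of [crc_parameters()]; any subset of
#' fields may be given. `write_parameters()` serialises a parameter set to
#' JSON so that a full editable profile can be emitted and reloaded
#' round-trip.
#'
#' @param config a path to a JSON file, a parsed list of overrides, or
#'   `NULL` for the bundled defaults.
#' @return a validated `crc_parameters` object.
#' @export
load_parameters <- function(config = NULL) {
  if (is.null(config)) return(crc_parameters())
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  config <- restore_parameter_shapes(config)
  do.call(crc_parameters, config)
}

# JSON round-trips turn named vectors into named lists and matrices into
# data frames; restore the expected shapes
restore_parameter_shapes <- function(config) {
  named_num <- function(x) stats::setNames(as.numeric(unlist(x)),
                                           names(unlist(x)))
  nh <- config$natural_history
  if (!is.null(nh$incidence_crc) && !is.matrix(nh$incidence_crc)) {
    m <- as.matrix(as.data.frame(nh$incidence_crc))
    config$natural_history$incidence_crc <-
      matrix(as.numeric(m), nrow = nrow(m),
             dimnames = list(NULL, colnames(m)))
  }
  for (f in c("other_cause_mortality", "symptomatic_dx", "crc_death"))
    if (!is.null(nh[[f]]) && is.list(nh[[f]]))
      config$natural_history[[f]] <- named_num(nh[[f]])
  if (!is.null(config$costs$annual_treatment) &&
      is.list(config$costs$annual_treatment))
    config$costs$annual_treatment <- named_num(config$costs$annual_treatment)
  if (!is.null(config$age_bands))
    config$age_bands <- as.data.frame(config$age_bands)
  if (!is.null(config$initial_state_probs) &&
      is.list(config$initial_state_probs))
    config$initial_state_probs <- named_num(config$initial_state_probs)
  if (!is.null(config$horizon))
    config$horizon <- stats::setNames(as.integer(unlist(config$horizon)),
                                      names(unlist(config$horizon)))
  config
}

#' @rdname load_parameters
#' @param params a `crc_parameters` object.
#' @param path output JSON path.
#' @export
write_parameters <- function(params, path) {
  x <- unclass(params)
  x$crc_onset_by_age <- NULL    # derived, recomputed on demand
  x$matrix_cache <- NULL
  # JSON keeps names only on lists, not atomic vectors
  x$natural_history$other_cause_mortality <-
    as.list(x$natural_history$other_cause_mortality)
  for (f in c("symptomatic_dx", "crc_death"))
    x$natural_history[[f]] <- as.list(x$natural_history[[f]])
  x$natural_history$incidence_crc <-
    as.data.frame(x$natural_history$incidence_crc)
  x$costs$annual_treatment <- as.list(x$costs$annual_treatment)
  x$initial_state_probs <- as.list(x$initial_state_probs)
  x$horizon <- as.list(x$horizon)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Scale a parameter set by a familial relative risk
#'
#' Multiplies the average-risk disease prevalences at age 50 (small/large
#' adenoma and Dukes' A-D CRC) and all onset incidence probabilities
#' (small-adenoma onset, small-to-large growth, stage-specific CRC onset) by
#' `rr`. Each scaled value is clamped to at most 1 (with a warning unless
#' `quiet = TRUE`, since e.g. 0.30 * 4 cannot remain a probability). The
#' "Normal" initial probability is recomputed as one minus the scaled disease
#' prevalences. Mortality, diagnosis probabilities, test characteristics and
#' costs are unchanged.
#'
#' @param base a `crc_parameters` object with `risk_applied = FALSE`.
#' @param rr positive relative risk (the published base case uses 4; the
#'   sensitivity analysis varies 3-6).
#' @param quiet suppress the clamping warning.
#' @return a new `crc_parameters` object with `risk_applied = TRUE`.
#' @export
#' @examples
#' p4 <- apply_risk_multiplier(crc_parameters(), 4, quiet = TRUE)
#' p4$initial_state_probs["AdenomaSmall"]  # 0.1668
apply_risk_multiplier <- function(base, rr, quiet = FALSE) {
  stopifnot(rr > 0)
  if (isTRUE(base$risk_applied))
    stop("risk multiplier has already been applied to this parameter set")
  p <- base
  clamped <- character(0)
  scale_clamp <- function(x, field) {
    y <- x * rr
    if (any(y > 1)) {
      clamped <<- c(clamped, field)
      y <- pmin(y, 1)
    }
    y
  }
  nh <- p$natural_history
  # convert the adenoma rows to annual scale before risk multiplication
  nh$incidence_small_adenoma <- adenoma_incidence(p, "small")
  nh$incidence_large_adenoma <- adenoma_incidence(p, "large")
  p$adenoma_incidence_scale <- "annual"
  nh$incidence_small_adenoma <-
    scale_clamp(nh$incidence_small_adenoma, "incidence_small_adenoma")
  nh$incidence_large_adenoma <-
    scale_clamp(nh$incidence_large_adenoma, "incidence_large_adenoma")
  nh$incidence_crc <- scale_clamp(nh$incidence_crc, "incidence_crc")
  p$natural_history <- nh

  isp <- p$initial_state_probs
  disease <- c("AdenomaSmall", "AdenomaLarge", "CRC_A", "CRC_B", "CRC_C", "CRC_D")
  isp[disease] <- pmin(isp[disease] * rr, 1)
  if (sum(isp[disease]) > 1 + 1e-12)
    stop("scaled initial disease-state probabilities sum to more than 1; ",
         "cohort cannot be normalized (rr = ", rr, ")")
  isp["Normal"] <- 1 - sum(isp[disease])
  p$initial_state_probs <- isp

  if (length(clamped) > 0 && !quiet)
    warning("risk multiplier clamped probabilities at 1 in: ",
            paste(unique(clamped), collapse = ", "), call. = FALSE)
  p$relative_risk <- rr
  p$risk_applied <- TRUE
  p$crc_onset_by_age <- derive_onset_rates(p)
  # per-age transition-matrix memo (environments are shared across copies;
  # created only after all law-determining fields are final)
  p$matrix_cache <- new.env(parent = emptyenv())
  p
}

# Age-dependent per-occupant CRC onset rates consistent with the printed
# population incidence. The band incidence is a population rate among
# persons at risk (alive, CRC-free); per-occupant rates are apportioned so
# that `frac_crc_from_large_adenoma` of incident cancers originate in
# large-adenoma carriers:
#   r_large(t, s) = f * inc(band(t), s) / share_large(t)
#   r_other(t, s) = (1 - f) * inc(band(t), s) / (1 - share_large(t))
# where share_large(t) is the large-adenoma share of the at-risk occupancy
# under the no-screening law. Since the shares depend on the law, they are
# solved by a short deterministic fixed-point iteration. If the share ever
# reaches f the apportionment degenerates and uniform rates are used.
derive_onset_rates <- function(p) {
  nh <- p$natural_history
  f <- nh$frac_crc_from_large_adenoma
  start_age <- p$horizon[["start"]]
  n_cycles <- p$horizon[["end"]] - start_age
  bands <- age_band_index(p, start_age:(p$horizon[["end"]] - 1L))
  inc <- nh$incidence_crc[bands, , drop = FALSE]   # n_cycles x 4

  rates_large <- inc
  rates_other <- inc * (1 - f)
  at_risk <- .S$Normal:.S$Surveillance
  for (iter in 1:6) {
    p$crc_onset_by_age <- list(large = rates_large, other = rates_other)
    occ <- p$initial_state_probs
    share <- numeric(n_cycles)
    for (t in seq_len(n_cycles)) {
      a <- sum(occ[at_risk])
      share[t] <- if (a > 0) occ[.S$AdenomaLarge] / a else 0
      occ <- as.numeric(occ %*% transition_matrix(p, start_age + t - 1L))
    }
    share <- pmin(pmax(share, 1e-3), f - 1e-3)
    rates_large <- pmin(f * inc / share, 1)
    rates_other <- pmin((1 - f) * inc / (1 - share), 1)
  }
  list(large = rates_large, other = rates_other)
}

# resolve the run-time parameter set: apply the stored relative risk unless
# it has been applied already
resolve_parameters <- function(params) {
  if (isTRUE(params$risk_applied)) return(params)
  apply_risk_multiplier(params, params$relative_risk, quiet = TRUE)
}

#' Age-band lookup
#'
#' Resolves integer ages to the row index of the parameter set's age bands
#' (default bands 50-54, 55-59, 60-64, 65-69, >=70).
#'
#' @param params a `crc_parameters` object.
#' @param age integer age(s) in \[50, 90\].
#' @return integer band indices.
#' @export
age_band_index <- function(params, age) {
  ab <- params$age_bands
  if (any(age < ab$lower[1] | age > ab$upper[nrow(ab)]))
    stop("age outside the model horizon [", ab$lower[1], ", ",
         ab$upper[nrow(ab)], "]")
  findInterval(age, ab$lower)
}

# adenoma incidence under the configured interpretation flag
adenoma_incidence <- function(params, which = c("small", "large")) {
  which <- match.arg(which)
  x <- if (which == "small") params$natural_history$incidence_small_adenoma
       else params$natural_history$incidence_large_adenoma
  if (identical(params$adenoma_incidence_scale, "per_band"))
    x <- 1 - (1 - x)^(1 / 5)
  x
}

#' @export
print.crc_parameters <- function(x, ...) {
  cat("<crc_parameters>\n")
  cat("  relative risk:", x$relative_risk,
      if (isTRUE(x$risk_applied)) "(applied)" else "(not yet applied)", "\n")
  cat("  horizon: ages", x$horizon[["start"]], "-", x$horizon[["end"]], "\n")
  cat("  discount rate:", x$costs$discount_rate, "\n")
  cat("  iFOBT uptake:", x$ifobt_uptake,
      "| colonoscopy uptake:", x$colonoscopy_uptake,
      "| follow-up compliance:", x$followup_colonoscopy_compliance, "\n")
  cat("  stage progression:", x$natural_history$stage_progression, "/year\n")
  invisible(x)
}
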