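#' Screening strategy definitions
#'
#' A strategy is a screening modality (`"iFOBT"` or `"colonoscopy"`), a
#' schedule of invitation ages, and optional per-strategy overrides of uptake
#' and (for iFOBT) diagnostic-colonoscopy follow-up compliance. When an
#' override is `NULL` the parameter set's modality-specific default applies
#' (40% uptake, 65% compliance in the bundled profile).
#'
#' The four built-in strategies (`built_in_strategies()`) are:
#' \describe{
#'   \item{usual_care}{one-off iFOBT invitations at ages 50, 55, 60 and 65
#'     (the Australian NBCSP baseline)}
#'   \item{ifobt2}{biennial iFOBT from age 50}
#'   \item{colo5}{colonoscopy every 5 years from age 50 (the NHMRC
#'     recommendation for the moderately-increased-risk category)}
#'   \item{colo10}{colonoscopy every 10 years from age 50}
#' }
#'
#' @param name strategy identifier.
#' @param modality `"iFOBT"` or `"colonoscopy"`.
#' @param ages explicit invitation ages (within \[50, 90)); alternatively give
#'   `every` for a fixed interval from `start`.
#' @param every invitation interval in years.
#' @param start first invitation age (default 50).
#' @param uptake optional probability overriding the modality default.
#' @param followup_compliance optional probability overriding the default
#'   (iFOBT only).
#' @return an object of class `crc_strategy`.
#' @export
#' @examples
#' crc_strategy("colo5", "colonoscopy", every = 5)
crc_strategy <- function(name, modality = c("iFOBT", "colonoscopy"),
                         ages = NULL, every = NULL, start = 50L,
                         uptake = NULL, followup_compliance = NULL) {
  modality <- match.arg(modality)
  if (is.null(ages)) {
    if (is.null(every)) stop("give either `ages` or `every`")
    ages <- seq.int(start, 89L, by = every)
  }
  ages <- as.integer(sort(unique(ages)))
  if (any(ages < 50L | ages > 89L))
    stop("invitation ages must lie within [50, 90)")
  structure(list(name = name, modality = modality, invite_ages = ages,
                 uptake = uptake, followup_compliance = followup_compliance),
            class = "crc_strategy")
}

#' @rdname crc_strategy
#' @export
built_in_strategies <- function() {
  list(
    usual_care = crc_strategy("usual_care", "iFOBT", ages = c(50L, 55L, 60L, 65L)),
    ifobt2 = crc_strategy("ifobt2", "iFOBT", every = 2),
    colo5 = crc_strategy("colo5", "colonoscopy", every = 5),
    colo10 = crc_strategy("colo10", "colonoscopy", every = 10)
  )
}

# uptake / compliance resolution against the parameter defaults
strategy_uptake <- function(strategy, params) {
  if (!is.null(strategy$uptake)) return(strategy$uptake)
  if (strategy$modality == "iFOBT") params$ifobt_uptake else params$colonoscopy_uptake
}

strategy_compliance <- function(strategy, params) {
  if (!is.null(strategy$followup_compliance)) return(strategy$followup_compliance)
  params$followup_colonoscopy_compliance
}

#' @export
print.crc_strategy <- function(x, ...) {
  cat("<crc_strategy ", x$name, ">: ", x$modality, " at ages ",
      paste(x$invite_ages, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assign persistent screener status
#'
#' One Bernoulli draw per individual per lifetime: invited persons either
#' take part in every round they are eligible for (screeners) or never do
#' (non-screeners).
#'
#' @param strategy a `crc_strategy`.
#' @param params a `crc_parameters` object supplying the modality default
#'   uptake.
#' @param n number of individuals.
#' @return logical vector of length `n`.
#' @export
assign_screener_status <- function(strategy, params, n = 1) {
  stats::runif(n) < strategy_uptake(strategy, params)
}

#' Perform an immunochemical faecal occult blood test
#'
#' Test outcome given the true underlying state: CRC states test positive
#' with `sensitivity_crc`, adenoma states with `sensitivity_polyp`,
#' disease-free states (normal or clean surveillance) with
#' `1 - specificity`. Calling on a treatment or death state is a contract
#' violation.
#'
#' @param true_state health-state label or code.
#' @param chars a `TestCharacteristics` list (`sensitivity_crc`,
#'   `sensitivity_polyp`, `specificity`).
#' @return `"positive"` or `"negative"`.
#' @export
perform_ifobt <- function(true_state, chars) {
  code <- if (is.character(true_state)) state_code(true_state) else as.integer(true_state)
  p <- ifobt_positive_prob(code, chars)
  if (stats::runif(1) < p) "positive" else "negative"
}

# vectorised positive-test probability by state code
ifobt_positive_prob <- function(code, chars) {
  if (any(is_treat(code) | is_absorbing(code)))
    stop("iFOBT cannot be performed on treatment or death states")
  p <- rep(1 - chars$specificity, length(code))
  p[code %in% c(.S$AdenomaSmall, .S$AdenomaLarge)] <- chars$sensitivity_polyp
  p[is_crc(code)] <- chars$sensitivity_crc
  p
}

#' Perform a colonoscopy (with polypectomy of detected adenomas)
#'
#' Detects CRC with `sensitivity_crc` and adenomas with `sensitivity_polyp`;
#' with specificity 1 there are no false positives. A detected small adenoma
#' is removed and the person returns to the normal state; a detected large
#' adenoma is removed and the person enters the surveillance pathway; a
#' detected cancer at Dukes' stage s moves to the corresponding treatment
#' state. Undetected lesions remain (false negative returns to the natural
#' history). The cost is the polypectomy tariff when an adenoma is removed,
#' the plain colonoscopy tariff otherwise.
#'
#' @inheritParams perform_ifobt
#' @param costs the `costs` component of a `crc_parameters` object.
#' @param in_surveillance whether the person is already in the surveillance
#'   pathway (a removed small adenoma then returns them to the clean
#'   surveillance state instead of normal).
#' @return a list: `finding` (one of `"negative"`, `"small_adenoma_found"`,
#'   `"large_adenoma_found"`, `"crc_found"`), `new_state` (integer code),
#'   `polypectomy` (logical), `cost` (AU$).
#' @export
perform_colonoscopy <- function(true_state, chars, costs,
                                in_surveillance = FALSE) {
  code <- if (is.character(true_state)) state_code(true_state) else as.integer(true_state)
  if (is_treat(code) || is_absorbing(code))
    stop("colonoscopy cannot be performed on treatment or death states")
  u <- stats::runif(1)
  colonoscopy_outcome(code, u, chars, costs, in_surveillance)
}

# deterministic outcome given the uniform draw; shared with the cohort engine
colonoscopy_outcome <- function(code, u, chars, costs, in_surveillance) {
  res <- list(finding = "negative", new_state = code, polypectomy = FALSE,
              cost = costs$colonoscopy)
  if (code == .S$AdenomaSmall && u < chars$sensitivity_polyp) {
    res$finding <- "small_adenoma_found"
    res$new_state <- if (in_surveillance) .S$Surveillance else .S$Normal
    res$polypectomy <- TRUE
    res$cost <- costs$colonoscopy_polypectomy
  } else if (code == .S$AdenomaLarge && u < chars$sensitivity_polyp) {
    res$finding <- "large_adenoma_found"
    res$new_state <- .S$Surveillance
    res$polypectomy <- TRUE
    res$cost <- costs$colonoscopy_polypectomy
  } else if (is_crc(code) && u < chars$sensitivity_crc) {
    res$finding <- "crc_found"
    res$new_state <- code + 4L   # CRC_s -> Treat_s
  } else if (code %in% c(.S$Normal, .S$Surveillance) &&
             u < 1 - chars$specificity) {
    res$finding <- "false_positive"
  }
  res
}

#' Run one screening round for an individual
#'
#' Applies the full invitation cascade at an invitation age. Non-screeners
#' accrue nothing. iFOBT screeners accrue the invitation+kit and pathology
#' costs; positives proceed to a GP-referred diagnostic colonoscopy with the
#' follow-up compliance probability (decliners return to the natural
#' history). Colonoscopy-strategy screeners receive a screening colonoscopy
#' directly. All costs returned are undiscounted; the engine discounts at
#' accrual.
#'
#' @param individual a list with at least `state` (integer code), `screener`
#'   (logical) and `in_surveillance` (logical); see [run_individual()].
#' @param strategy a `crc_strategy`.
#' @param age current age (must be one of the strategy's invitation ages).
#' @param params a risk-resolved or base `crc_parameters` object.
#' @return the updated individual, with an `events` data.frame attached
#'   (columns `age`, `procedure`, `result`, `cost`).
#' @export
run_screening_round <- function(individual, strategy, age, params) {
  if (!age %in% strategy$invite_ages)
    stop("age ", age, " is not an invitation age for strategy ", strategy$name)
  rp <- resolve_parameters(params)
  events <- data.frame(age = integer(), procedure = character(),
                       result = character(), cost = numeric())
  add <- function(procedure, result, cost) {
    events <<- rbind(events, data.frame(age = age, procedure = procedure,
                                        result = result, cost = cost))
  }
  st <- individual$state
  eligible <- !is_treat(st) && !is_absorbing(st) &&
    !isTRUE(individual$in_surveillance)
  if (eligible && isTRUE(individual$screener)) {
    co <- rp$costs
    if (strategy$modality == "iFOBT") {
      result <- perform_ifobt(st, rp$ifobt)
      add("iFOBT", result, co$ifobt_invitation_kit + co$ifobt_pathology)
      individual$counters["ifobt"] <- individual$counters["ifobt"] + 1L
      if (result == "positive" &&
          stats::runif(1) < strategy_compliance(strategy, rp)) {
        out <- perform_colonoscopy(st, rp$colonoscopy, co,
                                   isTRUE(individual$in_surveillance))
        add("diagnostic_colonoscopy", out$finding, co$gp_visit_referral + out$cost)
        individual <- apply_colonoscopy_result(individual, out, age,
                                               "diagnostic_colonoscopy")
      }
    } else {
      out <- perform_colonoscopy(st, rp$colonoscopy, co,
                                 isTRUE(individual$in_surveillance))
      add("screening_colonoscopy", out$finding, out$cost)
      individual <- apply_colonoscopy_result(individual, out, age,
                                             "screening_colonoscopy")
    }
  }
  individual$events <- events
  individual
}

#' Run a surveillance colonoscopy round
#'
#' Individuals who had a large adenoma removed exit primary screening and
#' receive surveillance colonoscopy every `surveillance_interval` years
#' (default 5) after entry, for as long as they are alive and undiagnosed.
#' Findings are handled exactly as in [perform_colonoscopy()]; the person
#' remains in the surveillance pathway afterwards.
#'
#' @inheritParams run_screening_round
#' @return the updated individual with an `events` data.frame attached.
#' @export
surveillance_round <- function(individual, age, params) {
  rp <- resolve_parameters(params)
  individual$events <- data.frame(age = integer(), procedure = character(),
                                  result = character(), cost = numeric())
  st <- individual$state
  if (!isTRUE(individual$in_surveillance) || is_treat(st) || is_absorbing(st))
    return(individual)
  out <- perform_colonoscopy(st, rp$colonoscopy, rp$costs, TRUE)
  individual$events <- data.frame(age = age,
                                  procedure = "surveillance_colonoscopy",
                                  result = out$finding, cost = out$cost)
  apply_colonoscopy_result(individual, out, age, "surveillance_colonoscopy")
}

# bookkeeping shared by all colonoscopy pathways
apply_colonoscopy_result <- function(individual, out, age, type) {
  individual$counters[type] <- individual$counters[type] + 1L
  if (out$polypectomy)
    individual$counters["polypectomy"] <- individual$counters["polypectomy"] + 1L
  if (out$finding == "large_adenoma_found" && !isTRUE(individual$in_surveillance)) {
    individual$in_surveillance <- TRUE
    individual$entered_surveillance_at <- age
  }
  if (out$finding == "crc_found") {
    individual$diagnosed_stage <- .STAGES[stage_of(out$new_state)]
  }
  individual$state <- out$new_state
  individual
}
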