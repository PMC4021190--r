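#' One-cycle transition law of the natural-history model
#'
#' Assembles the annual transition distribution out of a (non-absorbing)
#' health state at a given age, combining competing risks in a fixed order,
#' each later event conditioned on the earlier ones not occurring:
#'
#' 1. other-cause death (life-table probability for the current age);
#' 2. CRC death (treatment states, stage-specific; undiagnosed preclinical
#'    CRC carries it only when `undiagnosed_crc_mortality = TRUE`, since the
#'    yearly rates derive from survival measured from diagnosis);
#' 3. symptomatic diagnosis (undiagnosed CRC, stage-specific; certain at
#'    Dukes' D), moving `CRC_s` to `Treat_s`;
#' 4. one-stage disease progression (undiagnosed CRC and treated disease,
#'    at the common `stage_progression` rate; Dukes' D does not progress);
#' 5. lesion onset/growth: stage-specific CRC onset, then adenoma onset or
#'    small-to-large growth.
#'
#' Setting `diagnosis_before_progression = FALSE` in the parameters swaps
#' steps 3 and 4. In treatment states, surviving patients exit the bounded
#' treatment phase cured — a transition back to `Normal` at `cure_rate` per
#' year, taking precedence over treated-stage progression — reflecting that
#' the stage-specific yearly mortality derives from five-year survival data.
#'
#' CRC onset applies the age-band, stage-specific incidence to large-adenoma
#' occupants at the full rate, and to normal / small-adenoma / surveillance
#' occupants at the de-novo residual share `1 - frac_crc_from_large_adenoma`,
#' so that incident cancers predominantly originate from large adenomas (the
#' adenoma-carcinoma sequence).
#'
#' @param params a `crc_parameters` object. If the relative risk has not yet
#'   been applied it is applied here, so the law reflects the at-risk cohort.
#' @param state a non-absorbing health-state label or code.
#' @param age integer age in \[50, 89\] (the age at the start of the cycle).
#' @return a list of class `crc_transition` with fields `source`, `age` and
#'   `probs` (a named numeric vector over the 14 states summing to 1).
#' @export
#' @examples
#' tr <- build_transition(crc_parameters(), "CRC_D", 60)
#' sum(tr$probs)  # 1
build_transition <- function(params, state, age) {
  code <- if (is.character(state)) state_code(state) else as.integer(state)
  if (is_absorbing(code))
    stop("build_transition: source state ", state_label(code), " is absorbing")
  rp <- resolve_parameters(params)
  P <- transition_matrix(rp, age)
  structure(list(source = state_label(code), age = as.integer(age),
                 probs = P[code, ]),
            class = "crc_transition")
}

# Full 14x14 one-cycle matrix at a given age. `params` must already be
# risk-resolved. Rows of absorbing states are identity (guard convention).
transition_matrix <- function(params, age) {
  cache <- params$matrix_cache
  if (!is.null(cache)) {
    hit <- cache[[as.character(age)]]
    if (!is.null(hit)) return(hit)
  }
  nh <- params$natural_history
  b <- age_band_index(params, age)
  q <- as.numeric(nh$other_cause_mortality[as.character(age)])
  inc_s <- adenoma_incidence(params, "small")[b]
  inc_l <- adenoma_incidence(params, "large")[b]
  inc_c <- nh$incidence_crc[b, ]                 # named A-D
  m <- nh$crc_death
  d <- nh$symptomatic_dx
  prog <- nh$stage_progression
  f <- nh$frac_crc_from_large_adenoma

  P <- matrix(0, .N_STATES, .N_STATES,
              dimnames = list(health_states(), health_states()))

  # CRC onset: per-occupant rates apportioned between large-adenoma
  # carriers and everyone else at risk (see derive_onset_rates); fall back
  # to a static split when the derived rates are absent
  if (!is.null(params$crc_onset_by_age)) {
    ti <- age - params$horizon[["start"]] + 1L
    onset_lo <- params$crc_onset_by_age$other[ti, ]
    onset_hi <- params$crc_onset_by_age$large[ti, ]
  } else {
    onset_lo <- pmin(inc_c * (1 - f), 1)
    onset_hi <- inc_c
  }
  fill_onset <- function(row, surv, onset, after) {
    # `after`: function(remaining) filling the non-CRC mass
    tot <- sum(onset)
    if (tot > 1) onset <- onset / tot
    P[row, .S$CRC_A:.S$CRC_D] <<- surv * onset
    after(surv * (1 - min(tot, 1)))
  }

  ## Normal
  fill_onset(.S$Normal, 1 - q, onset_lo, function(rem) {
    P[.S$Normal, .S$AdenomaSmall] <<- rem * inc_s
    P[.S$Normal, .S$Normal] <<- rem * (1 - inc_s)
  })
  P[.S$Normal, .S$DeadOther] <- q

  ## Small adenoma: growth to large at the large-adenoma incidence
  fill_onset(.S$AdenomaSmall, 1 - q, onset_lo, function(rem) {
    P[.S$AdenomaSmall, .S$AdenomaLarge] <<- rem * inc_l
    P[.S$AdenomaSmall, .S$AdenomaSmall] <<- rem * (1 - inc_l)
  })
  P[.S$AdenomaSmall, .S$DeadOther] <- q

  ## Large adenoma: full stage-specific CRC onset; no regression
  fill_onset(.S$AdenomaLarge, 1 - q, onset_hi, function(rem) {
    P[.S$AdenomaLarge, .S$AdenomaLarge] <<- rem
  })
  P[.S$AdenomaLarge, .S$DeadOther] <- q

  ## Surveillance (clean bowel post-polypectomy): like Normal, but a new
  ## small adenoma is tracked while the person stays in the pathway
  fill_onset(.S$Surveillance, 1 - q, onset_lo, function(rem) {
    P[.S$Surveillance, .S$AdenomaSmall] <<- rem * inc_s
    P[.S$Surveillance, .S$Surveillance] <<- rem * (1 - inc_s)
  })
  P[.S$Surveillance, .S$DeadOther] <- q

  ## Undiagnosed (preclinical) CRC by stage
  m_undx <- if (isTRUE(nh$undiagnosed_crc_mortality)) m else m * 0
  for (s in 1:4) {
    row <- .S$CRC_A + s - 1L
    surv <- (1 - q) * (1 - m_undx[s])
    P[row, .S$DeadOther] <- q
    P[row, .S$DeadCRC] <- (1 - q) * m_undx[s]
    p_next <- if (s < 4) prog else 0
    if (isTRUE(params$diagnosis_before_progression)) {
      P[row, .S$Treat_A + s - 1L] <- surv * d[s]
      rem <- surv * (1 - d[s])
      if (s < 4) P[row, row + 1L] <- rem * p_next
      P[row, row] <- rem * (1 - p_next)
    } else {
      if (s < 4) P[row, row + 1L] <- surv * p_next
      rem <- surv * (1 - p_next)
      P[row, .S$Treat_A + s - 1L] <- rem * d[s]
      P[row, row] <- rem * (1 - d[s])
    }
  }

  ## Treatment states: stage-specific CRC death, then cure (exit of the
  ## bounded treatment phase back to Normal; the engine flags cured
  ## individuals as never re-entering screening), then treated progression
  cure <- nh$cure_rate
  for (s in 1:4) {
    row <- .S$Treat_A + s - 1L
    surv <- (1 - q) * (1 - m[s])
    P[row, .S$DeadOther] <- q
    P[row, .S$DeadCRC] <- (1 - q) * m[s]
    P[row, .S$Normal] <- surv * cure
    rem <- surv * (1 - cure)
    p_next <- if (s < 4) prog else 0
    if (s < 4) P[row, row + 1L] <- rem * p_next
    P[row, row] <- rem * (1 - p_next)
  }

  ## absorbing states
  P[.S$DeadCRC, .S$DeadCRC] <- 1
  P[.S$DeadOther, .S$DeadOther] <- 1
  if (!is.null(cache)) cache[[as.character(age)]] <- P
  P
}

# list of 14x14 transition matrices for ages start..(end-1);
# params must be risk-resolved
transition_matrices <- function(params) {
  ages <- params$horizon[["start"]]:(params$horizon[["end"]] - 1L)
  lapply(ages, function(a) transition_matrix(params, a))
}

#' Draw an initial health state at model entry
#'
#' Samples the age-50 state from the (risk-adjusted) initial-state
#' distribution: normal bowel, small/large adenoma, or undiagnosed CRC at
#' Dukes' A-D. Surveillance, treatment and death states have zero initial
#' probability.
#'
#' @inheritParams build_transition
#' @param n number of draws.
#' @return integer state codes (length `n`); use [health_states()] to label.
#' @export
initial_state <- function(params, n = 1) {
  rp <- resolve_parameters(params)
  isp <- rp$initial_state_probs
  sample.int(.N_STATES, n, replace = TRUE, prob = isp)
}

#' Advance a health state by one annual cycle
#'
#' One random draw from [build_transition()]. Absorbing states are returned
#' unchanged (guard path).
#'
#' @inheritParams build_transition
#' @return the next state's integer code.
#' @export
step <- function(state, age, params) {
  code <- if (is.character(state)) state_code(state) else as.integer(state)
  if (is_absorbing(code)) return(code)
  tr <- build_transition(params, code, age)
  sample.int(.N_STATES, 1, prob = tr$probs)
}

#' Export the per-age transition law as a data frame
#'
#' Flattens the full transition array (state x state x age) for inspection or
#' CSV export.
#'
#' @inheritParams build_transition
#' @return a data.frame with columns `age`, `from`, `to`, `prob`.
#' @export
transition_law_table <- function(params) {
  rp <- resolve_parameters(params)
  ages <- rp$horizon[["start"]]:(rp$horizon[["end"]] - 1L)
  do.call(rbind, lapply(ages, function(a) {
    P <- transition_matrix(rp, a)
    df <- expand.grid(from = health_states(), to = health_states(),
                      stringsAsFactors = FALSE)
    df$age <- a
    df$prob <- as.vector(P)
    df[df$prob > 0, c("age", "from", "to", "prob")]
  }))
}

#' @export
print.crc_transition <- function(x, ...) {
  cat("<transition from", x$source, "at age", x$age, ">\n")
  nz <- x$probs[x$probs > 0]
  print(round(nz, 6))
  invisible(x)
}
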