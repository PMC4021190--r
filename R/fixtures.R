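#' Toy Markov models with closed-form solutions
#'
#' Small state-transition models used as independent oracles in the test
#' suite. Each spec carries an explicit transition law and, where derivable,
#' closed-form quantities under the package's cycle convention (a cycle is
#' credited only if the individual is alive at its end, so mean credited
#' cycles in the geometric model with death probability q is `(1 - q) / q`).
#'
#' @return a named list of `toy_model` specs, each with fields `name`,
#'   `states`, `P` (a transition matrix, or function of cycle index),
#'   `init`, and `closed_form` (a list of analytic values).
#' @export
make_toy_models <- function() {
  models <- list()

  # (a) pure life-table model: alive -> dead at an age-varying probability
  qx <- pmin(1, 0.01 * exp(0.08 * (0:39)))
  models$life_table <- list(
    name = "life_table",
    states = c("Alive", "Dead"),
    P = function(t) matrix(c(1 - qx[t], qx[t], 0, 1), 2, byrow = TRUE),
    init = c(1, 0),
    closed_form = list(
      life_expectancy = sum(cumprod(1 - qx)),
      qx = qx))

  # (b) alive -> dead geometric model, constant q
  q <- 0.2
  models$geometric <- list(
    name = "geometric",
    states = c("Alive", "Dead"),
    P = matrix(c(1 - q, q, 0, 1), 2, byrow = TRUE),
    init = c(1, 0),
    closed_form = list(
      q = q,
      mean_credited_cycles = (1 - q) / q,   # E[cycles alive at cycle end]
      survival = function(t) (1 - q)^t))

  # (c) illness-death model: healthy -> ill -> dead, plus healthy -> dead
  lam <- 0.1; mu_h <- 0.02; mu_i <- 0.15
  models$illness_death <- list(
    name = "illness_death",
    states = c("Healthy", "Ill", "Dead"),
    P = matrix(c(1 - lam - mu_h, lam, mu_h,
                 0, 1 - mu_i, mu_i,
                 0, 0, 1), 3, byrow = TRUE),
    init = c(1, 0, 0),
    closed_form = list(
      rates = c(lambda = lam, mu_healthy = mu_h, mu_ill = mu_i),
      # absorption: P(ever ill before death)
      p_ever_ill = lam / (lam + mu_h),
      # expected credited cycles: E[healthy cycles] + P(ill) * E[ill cycles]
      life_expectancy = (1 - lam - mu_h) / (lam + mu_h) +
        (lam / (lam + mu_h)) * (1 + (1 - mu_i) / mu_i)))

  # (d) miniature 5-state CRC-like model, small enough for exhaustive
  # path enumeration over a few cycles
  P5 <- matrix(0, 5, 5, dimnames = rep(list(
    c("Normal", "Adenoma", "CRC", "DeadCRC", "DeadOther")), 2))
  P5["Normal", ] <- c(0.80, 0.12, 0.02, 0, 0.06)
  P5["Adenoma", ] <- c(0, 0.82, 0.10, 0, 0.08)
  P5["CRC", ] <- c(0, 0, 0.70, 0.20, 0.10)
  P5["DeadCRC", "DeadCRC"] <- 1
  P5["DeadOther", "DeadOther"] <- 1
  models$mini_crc <- list(
    name = "mini_crc",
    states = colnames(P5),
    P = P5,
    init = c(1, 0, 0, 0, 0),
    closed_form = list())

  models
}

#' Exhaustive path-enumeration distribution for a toy model
#'
#' Brute-force oracle: enumerates every state path of length `cycles` and
#' accumulates path probabilities, yielding the exact occupancy distribution
#' after `cycles` transitions. Exponential in `cycles`; only for tiny models.
#'
#' @param P a square transition matrix.
#' @param init initial occupancy vector.
#' @param cycles number of transitions (keep small).
#' @return the occupancy probability vector after `cycles` transitions.
#' @export
enumerate_paths <- function(P, init, cycles) {
  k <- nrow(P)
  occ <- numeric(k)
  recurse <- function(state_prob, state, depth) {
    if (depth == cycles) {
      occ[state] <<- occ[state] + state_prob
      return(invisible())
    }
    for (j in seq_len(k)) {
      pj <- P[state, j]
      if (pj > 0) recurse(state_prob * pj, j, depth + 1L)
    }
  }
  for (s in seq_len(k)) if (init[s] > 0) recurse(init[s], s, 0L)
  occ
}

#' Deterministic cohort-matrix oracle
#'
#' The expected-value twin of the microsimulation for the no-screening
#' configuration: propagates the state-occupancy vector through the per-age
#' transition matrices and accumulates expected life-years, treatment costs,
#' incident CRC cases and deaths under exactly the engine's accrual
#' convention (accrual at cycle end, discounting at `(1+r)^-t`,
#' `t = age - 50`). Contains no randomness, so microsimulation means must
#' converge to its output.
#'
#' Screening strategies are not expressible in this 14-state expected-value
#' form (screening history makes individuals non-exchangeable within a
#' state); passing a strategy raises an unsupported-strategy error.
#'
#' @param params a `crc_parameters` object.
#' @param strategy must be `NULL` (no screening).
#' @return a list: expected `life_years`, `discounted_life_years`, `cost`,
#'   `discounted_cost`, `crc_cases`, `crc_deaths` (all per person), and the
#'   `occupancy` matrix (cycles + 1 rows, 14 columns).
#' @export
#' @examples
#' cohort_matrix_oracle(crc_parameters())$crc_cases
cohort_matrix_oracle <- function(params, strategy = NULL) {
  if (!is.null(strategy))
    stop("unsupported: the cohort-matrix oracle covers the no-screening ",
         "configuration only")
  rp <- resolve_parameters(params)
  start_age <- rp$horizon[["start"]]
  n_cycles <- rp$horizon[["end"]] - start_age
  df <- (1 + rp$costs$discount_rate)^(-(seq_len(n_cycles) - 1L))
  treat_cost <- as.numeric(rp$costs$annual_treatment)
  mats <- transition_matrices(rp)

  occ <- matrix(0, n_cycles + 1L, .N_STATES,
                dimnames = list(NULL, health_states()))
  occ[1, ] <- rp$initial_state_probs
  ly <- dly <- cost <- dcost <- cases <- deaths <- 0
  pre_crc <- .S$Normal:.S$Surveillance
  crc_states <- .S$CRC_A:.S$CRC_D
  treat_states <- .S$Treat_A:.S$Treat_D

  for (t in seq_len(n_cycles)) {
    P <- mats[[t]]
    v <- occ[t, ]
    occ[t + 1L, ] <- as.numeric(v %*% P)
    # incident cases: flux from pre-CRC states into CRC states
    cases <- cases + sum(v[pre_crc] %*% P[pre_crc, crc_states, drop = FALSE])
    deaths <- deaths + sum(v[-.S$DeadCRC] * P[-.S$DeadCRC, .S$DeadCRC])
    alive_mass <- sum(occ[t + 1L, 1:12])
    ly <- ly + alive_mass
    dly <- dly + df[t] * alive_mass
    tc <- sum(occ[t + 1L, treat_states] * treat_cost)
    cost <- cost + tc
    dcost <- dcost + df[t] * tc
  }
  list(life_years = ly, discounted_life_years = dly,
       cost = cost, discounted_cost = dcost,
       crc_cases = cases + sum(occ[1, crc_states]),  # prevalent at entry
       crc_deaths = deaths, occupancy = occ)
}
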