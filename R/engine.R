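#' Microsimulation engine
#'
#' [run_cohort()] simulates `n` individuals from age 50 to 90 under a
#' screening strategy, in annual cycles: (1) primary screening round if the
#' age is an invitation age and the person is eligible (alive, undiagnosed,
#' not in the surveillance pathway); (2) surveillance colonoscopy if due;
#' (3) one natural-history transition; (4) accrual of the cycle's life-year
#' and treatment cost, discounted at `(1 + r)^-t` with `t = age - 50`.
#' Events and accruals fall at cycle end (no half-cycle correction): the
#' life-year and treatment cost of a cycle are credited only to individuals
#' alive after the cycle's transition.
#'
#' All randomness is pre-drawn from `seed` as per-individual uniform streams
#' in a fixed layout, so that (a) identical `(strategy, params, n, seed)`
#' give bit-identical results and (b) different strategies evaluated via
#' [run_all_strategies()] share individual-level random numbers (common
#' random numbers), which sharpens incremental comparisons.
#'
#' @param strategy a `crc_strategy`, or `NULL` for no screening.
#' @param params a `crc_parameters` object; the familial relative risk is
#'   applied automatically if not already applied.
#' @param n cohort size.
#' @param seed integer seed.
#' @return an object of class `cohort_result`: counts of CRC cases (total
#'   and by Dukes' stage at diagnosis, or at death/model exit if never
#'   diagnosed), CRC deaths, colonoscopies by type, polypectomies, iFOBT
#'   tests, and mean (un)discounted cost and life-years per person.
#' @export
#' @examples
#' \donttest{
#' p <- crc_parameters()
#' res <- run_cohort(built_in_strategies()$usual_care, p, n = 2000, seed = 1)
#' res$crc_cases
#' }
run_cohort <- function(strategy, params, n, seed) {
  stopifnot(n >= 1)
  rp <- resolve_parameters(params)
  draws <- make_draws(n, seed)
  res <- run_cohort_core(strategy, rp, n, draws)
  res$seed <- seed
  res
}

#' @rdname run_cohort
#' @param strategies a named list of `crc_strategy` objects (default: the
#'   four built-ins). All are run with common random numbers.
#' @return `run_all_strategies()` returns a named list of `cohort_result`s.
#' @export
run_all_strategies <- function(params, n, seed, strategies = built_in_strategies()) {
  rp <- resolve_parameters(params)
  draws <- make_draws(n, seed)
  out <- lapply(strategies, function(s) {
    r <- run_cohort_core(s, rp, n, draws)
    r$seed <- seed
    r
  })
  names(out) <- vapply(strategies, function(s) s$name, character(1))
  out
}

# fixed-layout uniform draws: one stream per purpose so that strategies
# consume identical randomness wherever their decision paths coincide
make_draws <- function(n, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  list(
    u_init = stats::runif(n),
    u_scr = stats::runif(n),
    u_nh = matrix(stats::runif(n * 40L), n, 40L),
    u_test = matrix(stats::runif(n * 40L), n, 40L),
    u_follow = matrix(stats::runif(n * 40L), n, 40L),
    u_detect = matrix(stats::runif(n * 40L), n, 40L)
  )
}

# inverse-CDF draw of initial states from the cumulative distribution
draw_initial_states <- function(isp, u) {
  cum <- cumsum(isp)
  findInterval(u, cum) + 1L
}

# vectorised annual-cycle cohort simulation; rp must be risk-resolved
run_cohort_core <- function(strategy, rp, n, draws, detail = FALSE) {
  start_age <- rp$horizon[["start"]]
  n_cycles <- rp$horizon[["end"]] - start_age
  df <- (1 + rp$costs$discount_rate)^(-(seq_len(n_cycles) - 1L))
  mats <- transition_matrices(rp)
  cums <- lapply(mats, function(P) t(apply(P, 1, cumsum)))
  co <- rp$costs
  treat_cost <- as.numeric(co$annual_treatment)

  uptake <- if (is.null(strategy)) 0 else strategy_uptake(strategy, rp)
  compliance <- if (is.null(strategy)) 0 else strategy_compliance(strategy, rp)
  invite <- if (is.null(strategy)) integer(0) else strategy$invite_ages

  state <- draw_initial_states(rp$initial_state_probs, draws$u_init)
  screener <- draws$u_scr < uptake
  in_surv <- rep(FALSE, n)
  surv_entry <- rep(NA_integer_, n)

  cost <- numeric(n); dcost <- numeric(n)
  ly <- numeric(n); dly <- numeric(n)
  n_ifobt <- integer(n); n_diag <- integer(n); n_screen <- integer(n)
  n_surv <- integer(n); n_polyp <- integer(n)
  is_case <- is_crc(state)             # prevalent undiagnosed CRC at entry
  onset_events <- sum(is_case)         # event count (incl. new primaries)
  ever_dx <- rep(FALSE, n)             # diagnosed once: no more screening
  dx_stage <- integer(n)               # 0 = undiagnosed
  exit_stage <- integer(n)             # stage at death/exit if undiagnosed
  crc_death <- rep(FALSE, n)

  # vectorised colonoscopy on index set idx with uniforms u; `kind` selects
  # the counter; returns nothing, mutates the enclosing frame
  do_colonoscopy <- local(function(idx, u, age, t, kind) {
    if (length(idx) == 0) return(invisible())
    st <- state[idx]
    sens_p <- rp$colonoscopy$sensitivity_polyp
    sens_c <- rp$colonoscopy$sensitivity_crc
    det_small <- st == .S$AdenomaSmall & u < sens_p
    det_large <- st == .S$AdenomaLarge & u < sens_p
    det_crc <- is_crc(st) & u < sens_c
    polyp <- det_small | det_large
    c_amt <- ifelse(polyp, co$colonoscopy_polypectomy, co$colonoscopy)
    cost[idx] <<- cost[idx] + c_amt
    dcost[idx] <<- dcost[idx] + c_amt * df[t]
    if (kind == "diag") n_diag[idx] <<- n_diag[idx] + 1L
    if (kind == "screen") n_screen[idx] <<- n_screen[idx] + 1L
    if (kind == "surv") n_surv[idx] <<- n_surv[idx] + 1L
    n_polyp[idx] <<- n_polyp[idx] + as.integer(polyp)
    # state updates
    i_small <- idx[det_small]
    state[i_small] <<- ifelse(in_surv[i_small], .S$Surveillance, .S$Normal)
    i_large <- idx[det_large]
    state[i_large] <<- .S$Surveillance
    newly <- i_large[!in_surv[i_large]]
    in_surv[newly] <<- TRUE
    surv_entry[newly] <<- age
    i_crc <- idx[det_crc]
    state[i_crc] <<- state[i_crc] + 4L
    first <- i_crc[dx_stage[i_crc] == 0L]
    dx_stage[first] <<- stage_of(state[first])
    invisible()
  }, envir = environment())

  for (t in seq_len(n_cycles)) {
    age <- start_age + t - 1L
    alive <- state < .S$DeadCRC
    screenable <- alive & state <= .S$CRC_D

    ## 1. primary screening round
    if (age %in% invite) {
      elig <- which(screenable & !in_surv & !ever_dx & screener)
      if (length(elig) > 0) {
        if (strategy$modality == "iFOBT") {
          kit <- co$ifobt_invitation_kit + co$ifobt_pathology
          cost[elig] <- cost[elig] + kit
          dcost[elig] <- dcost[elig] + kit * df[t]
          n_ifobt[elig] <- n_ifobt[elig] + 1L
          p_pos <- ifobt_positive_prob(state[elig], rp$ifobt)
          pos <- draws$u_test[elig, t] < p_pos
          fol <- elig[pos & draws$u_follow[elig, t] < compliance]
          if (length(fol) > 0) {
            cost[fol] <- cost[fol] + co$gp_visit_referral
            dcost[fol] <- dcost[fol] + co$gp_visit_referral * df[t]
            do_colonoscopy(fol, draws$u_detect[fol, t], age, t, "diag")
          }
        } else {
          do_colonoscopy(elig, draws$u_detect[elig, t], age, t, "screen")
        }
      }
    }

    ## 2. surveillance colonoscopy if due
    due <- which(screenable & in_surv & !ever_dx & !is.na(surv_entry) &
                   age > surv_entry &
                   (age - surv_entry) %% rp$surveillance_interval == 0L)
    ever_dx <- ever_dx | dx_stage > 0L
    if (length(due) > 0)
      do_colonoscopy(due, draws$u_detect[due, t], age, t, "surv")

    ## 3. natural-history transition
    alive_idx <- which(state < .S$DeadCRC)
    if (length(alive_idx) > 0) {
      st_al <- state[alive_idx]
      u <- draws$u_nh[alive_idx, t]
      nxt <- st_al
      for (s in unique(st_al)) {
        sel <- st_al == s
        nxt[sel] <- findInterval(u[sel], cums[[t]][s, ]) + 1L
      }
      prev <- st_al
      # bookkeeping: incident cases, diagnoses, deaths, exit stages
      onset <- prev <= .S$Surveillance & nxt >= .S$CRC_A & nxt <= .S$CRC_D
      if (any(onset)) {
        is_case[alive_idx[onset]] <- TRUE
        onset_events <- onset_events + sum(onset)
      }
      dxed <- prev >= .S$CRC_A & prev <= .S$CRC_D &
        nxt >= .S$Treat_A & nxt <= .S$Treat_D
      if (any(dxed)) {
        i_dx <- alive_idx[dxed]
        first <- i_dx[dx_stage[i_dx] == 0L]
        dx_stage[first] <- nxt[dxed][dx_stage[i_dx] == 0L] - .S$Treat_A + 1L
      }
      died <- nxt >= .S$DeadCRC
      if (any(died)) {
        undiag <- died & prev >= .S$CRC_A & prev <= .S$CRC_D
        exit_stage[alive_idx[undiag]] <- prev[undiag] - .S$CRC_A + 1L
        crc_death[alive_idx[nxt == .S$DeadCRC]] <- TRUE
      }
      state[alive_idx] <- nxt
    }

    ## 4. accrual at cycle end
    alive2 <- state < .S$DeadCRC
    ly[alive2] <- ly[alive2] + 1
    dly[alive2] <- dly[alive2] + df[t]
    tr <- which(state >= .S$Treat_A & state <= .S$Treat_D)
    if (length(tr) > 0) {
      amt <- treat_cost[state[tr] - .S$Treat_A + 1L]
      cost[tr] <- cost[tr] + amt
      dcost[tr] <- dcost[tr] + amt * df[t]
    }
  }

  # undiagnosed CRC still present at the end of the horizon
  left <- state >= .S$CRC_A & state <= .S$CRC_D & dx_stage == 0L
  exit_stage[left] <- state[left] - .S$CRC_A + 1L

  case_stage <- ifelse(dx_stage > 0L, dx_stage, exit_stage)
  stage_counts <- stats::setNames(
    tabulate(case_stage[is_case & case_stage > 0L], nbins = 4L), .STAGES)

  res <- structure(list(
    n = n,
    strategy = if (is.null(strategy)) "none" else strategy$name,
    crc_cases = sum(is_case),
    crc_onset_events = onset_events,
    crc_cases_by_stage = stage_counts,
    crc_deaths = sum(crc_death),
    total_colonoscopies = sum(n_diag) + sum(n_screen) + sum(n_surv),
    colonoscopies = c(diagnostic = sum(n_diag), screening = sum(n_screen),
                      surveillance = sum(n_surv)),
    polypectomies = sum(n_polyp),
    ifobt_tests = sum(n_ifobt),
    mean_cost = mean(cost),
    mean_discounted_cost = mean(dcost),
    mean_life_years = mean(ly),
    mean_discounted_life_years = mean(dly),
    seed = NA_integer_
  ), class = "cohort_result")
  if (detail) {
    res$individuals <- data.frame(
      id = seq_len(n), screener = screener, final_state = state_label(state),
      in_surveillance = in_surv, entered_surveillance_at = surv_entry,
      cost = cost, discounted_cost = dcost,
      life_years = ly, discounted_life_years = dly,
      ifobt = n_ifobt, diagnostic_colonoscopy = n_diag,
      screening_colonoscopy = n_screen, surveillance_colonoscopy = n_surv,
      polypectomy = n_polyp, crc_case = is_case,
      diagnosed_stage = ifelse(dx_stage > 0, .STAGES[pmax(dx_stage, 1)], NA),
      crc_death = crc_death)
  }
  res
}

#' Simulate a single individual (reference path)
#'
#' A readable per-individual annual loop built from the exported operations
#' ([run_screening_round()], [surveillance_round()], [step()]), following
#' exactly the same cycle conventions as the vectorised [run_cohort()]
#' engine. It consumes the R session's RNG stream (set a seed beforehand for
#' reproducibility). Used as the engine's behavioural twin in the test suite;
#' prefer [run_cohort()] for anything larger than a handful of individuals.
#'
#' @inheritParams run_cohort
#' @param id identifier stored on the record.
#' @return an `individual_record` list: final `state`, `screener` status,
#'   surveillance entry age, (un)discounted cost and life-years, procedure
#'   `counters`, `diagnosed_stage`, `crc_case`/`crc_death` flags and the full
#'   `events` log.
#' @export
run_individual <- function(strategy, params, id = 1L) {
  rp <- resolve_parameters(params)
  start_age <- rp$horizon[["start"]]
  n_cycles <- rp$horizon[["end"]] - start_age
  df <- (1 + rp$costs$discount_rate)^(-(seq_len(n_cycles) - 1L))
  treat_cost <- as.numeric(rp$costs$annual_treatment)
  invite <- if (is.null(strategy)) integer(0) else strategy$invite_ages

  ind <- list(
    id = id,
    state = initial_state(rp, 1),
    screener = if (is.null(strategy)) FALSE
               else as.logical(assign_screener_status(strategy, rp, 1)),
    in_surveillance = FALSE, entered_surveillance_at = NA_integer_,
    counters = c(ifobt = 0L, diagnostic_colonoscopy = 0L,
                 screening_colonoscopy = 0L, surveillance_colonoscopy = 0L,
                 polypectomy = 0L),
    cost = 0, discounted_cost = 0, life_years = 0, discounted_life_years = 0,
    diagnosed_stage = NA_character_, crc_case = FALSE, crc_death = FALSE,
    events = data.frame(age = integer(), procedure = character(),
                        result = character(), cost = numeric())
  )
  ind$crc_case <- is_crc(ind$state)

  accrue <- function(ind, amount, t) {
    ind$cost <- ind$cost + amount
    ind$discounted_cost <- ind$discounted_cost + amount * df[t]
    ind
  }

  for (t in seq_len(n_cycles)) {
    age <- start_age + t - 1L
    if (is_absorbing(ind$state)) break
    screenable <- !is_treat(ind$state)

    if (age %in% invite && screenable && !ind$in_surveillance &&
        is.na(ind$diagnosed_stage)) {
      ind2 <- run_screening_round(ind, strategy, age, rp)
      if (nrow(ind2$events) > 0) {
        for (cst in ind2$events$cost) ind2 <- accrue(ind2, cst, t)
        ind2$events <- rbind(ind$events, ind2$events)
      } else ind2$events <- ind$events
      ind <- ind2
    }
    if (ind$in_surveillance && screenable && !is_treat(ind$state) &&
        is.na(ind$diagnosed_stage) &&
        age > ind$entered_surveillance_at &&
        (age - ind$entered_surveillance_at) %% rp$surveillance_interval == 0L) {
      prev_events <- ind$events
      ind2 <- surveillance_round(ind, age, rp)
      if (nrow(ind2$events) > 0)
        for (cst in ind2$events$cost) ind2 <- accrue(ind2, cst, t)
      ind2$events <- rbind(prev_events, ind2$events)
      ind <- ind2
    }

    prev <- ind$state
    ind$state <- step(prev, age, rp)
    if (!is_crc(prev) && !is_treat(prev) && is_crc(ind$state))
      ind$crc_case <- TRUE
    if (is_crc(prev) && is_treat(ind$state) && is.na(ind$diagnosed_stage))
      ind$diagnosed_stage <- .STAGES[stage_of(ind$state)]
    if (ind$state == .S$DeadCRC) ind$crc_death <- TRUE
    if (is_absorbing(ind$state) && is_crc(prev) && is.na(ind$diagnosed_stage))
      ind$exit_stage <- .STAGES[stage_of(prev)]

    if (!is_absorbing(ind$state)) {
      ind$life_years <- ind$life_years + 1
      ind$discounted_life_years <- ind$discounted_life_years + df[t]
      if (is_treat(ind$state))
        ind <- accrue(ind, treat_cost[stage_of(ind$state)], t)
    }
  }
  if (is_crc(ind$state) && is.na(ind$diagnosed_stage))
    ind$exit_stage <- .STAGES[stage_of(ind$state)]
  ind$state <- state_label(ind$state)
  class(ind) <- "individual_record"
  ind
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> strategy:", x$strategy, " n:", x$n, " seed:", x$seed, "\n")
  cat(sprintf("  CRC cases: %d (A/B/C/D = %s)\n", x$crc_cases,
              paste(x$crc_cases_by_stage, collapse = "/")))
  cat(sprintf("  CRC deaths: %d | colonoscopies: %d\n",
              x$crc_deaths, x$total_colonoscopies))
  cat(sprintf("  mean discounted cost: %.2f AU$ | mean discounted LY: %.3f\n",
              x$mean_discounted_cost, x$mean_discounted_life_years))
  invisible(x)
}
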