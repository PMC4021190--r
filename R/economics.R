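#' Present-value discount factor
#'
#' `(1 + rate)^(-year_index)`, with year index 0 at model entry (age 50).
#'
#' @param year_index non-negative integer year index (vectorised).
#' @param rate annual discount rate (the bundled profile uses 0.05).
#' @return numeric discount factor(s).
#' @export
#' @examples
#' discount_factor(2, 0.05)  # 0.9070295
discount_factor <- function(year_index, rate) {
  if (any(year_index < 0)) stop("year_index must be >= 0")
  (1 + rate)^(-year_index)
}

#' Percentage reduction of an event count versus baseline
#'
#' `100 * (baseline - strategy) / baseline`. Returned at full precision;
#' display tables round to integer percent.
#'
#' @param baseline_count baseline event count (> 0).
#' @param strategy_count comparator event count.
#' @return percentage (vectorised over `strategy_count`).
#' @export
#' @examples
#' percent_reduction(6491, 2568)  # 60.44
percent_reduction <- function(baseline_count, strategy_count) {
  if (any(baseline_count <= 0)) stop("baseline count must be > 0")
  100 * (baseline_count - strategy_count) / baseline_count
}

#' Colonoscopies per CRC death averted
#'
#' Total colonoscopies performed under a strategy divided by the CRC deaths
#' it averts relative to baseline, floored to an integer (the convention that
#' reproduces the published cells).
#'
#' @param total_colos total colonoscopies under the strategy.
#' @param baseline_deaths CRC deaths under the baseline.
#' @param strategy_deaths CRC deaths under the strategy.
#' @return integer ratio, or `NA` (with a warning) when no deaths are
#'   averted.
#' @export
#' @examples
#' colonoscopies_per_life_saved(72885, 983, 830)  # 476
colonoscopies_per_life_saved <- function(total_colos, baseline_deaths,
                                         strategy_deaths) {
  averted <- baseline_deaths - strategy_deaths
  if (averted <= 0) {
    warning("no CRC deaths averted: colonoscopies per life saved undefined")
    return(NA_integer_)
  }
  as.integer(floor(total_colos / averted))
}

#' Incremental cost-effectiveness table with dominance analysis
#'
#' Sorts strategies by effectiveness, removes strongly dominated options
#' (costlier and no more effective than another) and extendedly dominated
#' options (an ICER higher than that of a more effective alternative), and
#' reports incremental costs, incremental effects and ICERs pairwise along
#' the retained efficiency frontier. ICERs along the frontier are strictly
#' increasing by construction.
#'
#' @param results either a named list of `cohort_result` objects or a
#'   data.frame with columns `strategy`, `cost`, `effect` (mean discounted
#'   cost and life-years per person).
#' @param baseline name of the anchor strategy (first frontier point by
#'   convention; it must be the least costly option).
#' @param discounted when `results` are `cohort_result`s, use discounted
#'   (default) or undiscounted accruals.
#' @return a `data.frame` of class `cea_comparison`: one row per strategy
#'   with `cost`, `effect`, `incremental_cost`, `incremental_effect`, `icer`
#'   and `status` (`baseline`, `frontier`, `dominated`,
#'   `extendedly_dominated`). Dominated strategies carry `NA` ICERs.
#' @export
#' @examples
#' icer_table(data.frame(
#'   strategy = c("usual_care", "colo10", "colo5"),
#'   cost = c(3441, 6278, 8734),
#'   effect = c(15.545, 15.886, 16.084)))
icer_table <- function(results, baseline = "usual_care", discounted = TRUE) {
  df <- as_cea_frame(results, discounted)
  if (anyDuplicated(df$strategy))
    stop("duplicate strategy names in ICER table input")
  if (!baseline %in% df$strategy) baseline <- df$strategy[which.min(df$cost)]

  df <- df[order(df$effect, df$cost), ]
  df$status <- "frontier"
  # strong dominance: some other strategy is no costlier and more effective,
  # or cheaper and no less effective
  for (i in seq_len(nrow(df))) {
    others <- df[-i, ]
    dom <- (others$cost <= df$cost[i] & others$effect > df$effect[i]) |
      (others$cost < df$cost[i] & others$effect >= df$effect[i])
    if (any(dom)) df$status[i] <- "dominated"
  }
  # extended dominance: iteratively drop frontier candidates whose ICER
  # (vs previous retained) exceeds the next candidate's
  repeat {
    keep <- which(df$status == "frontier")
    if (length(keep) < 3) break
    cand <- df[keep, ]
    icers <- diff(cand$cost) / diff(cand$effect)
    bad <- which(diff(icers) < 0)
    if (length(bad) == 0) break
    df$status[keep[bad[1] + 1L]] <- "extendedly_dominated"
  }

  keep <- which(df$status == "frontier")
  df$incremental_cost <- NA_real_
  df$incremental_effect <- NA_real_
  df$icer <- NA_real_
  if (length(keep) > 1) {
    for (j in seq_along(keep)[-1]) {
      i <- keep[j]; prev <- keep[j - 1L]
      df$incremental_cost[i] <- df$cost[i] - df$cost[prev]
      df$incremental_effect[i] <- df$effect[i] - df$effect[prev]
      df$icer[i] <- df$incremental_cost[i] / df$incremental_effect[i]
    }
  }
  df$status[df$strategy == baseline & df$status == "frontier"] <- "baseline"
  rownames(df) <- NULL
  class(df) <- c("cea_comparison", "data.frame")
  df
}

as_cea_frame <- function(results, discounted = TRUE) {
  if (is.data.frame(results)) {
    stopifnot(all(c("strategy", "cost", "effect") %in% names(results)))
    return(results[, c("strategy", "cost", "effect")])
  }
  data.frame(
    strategy = vapply(results, function(r) r$strategy, character(1)),
    cost = vapply(results, function(r)
      if (discounted) r$mean_discounted_cost else r$mean_cost, numeric(1)),
    effect = vapply(results, function(r)
      if (discounted) r$mean_discounted_life_years else r$mean_life_years,
      numeric(1)),
    row.names = NULL)
}

#' Clinical events summary table
#'
#' Lays out per-strategy event counts in the published format: total CRC
#' cases, percent incidence reduction versus baseline, cases by Dukes' stage,
#' CRC deaths, percent mortality reduction, total colonoscopies, and
#' colonoscopies per life saved.
#'
#' @param results a named list of `cohort_result` objects including the
#'   baseline.
#' @param baseline baseline strategy name.
#' @return a data.frame with one row per measure and one column per strategy.
#' @export
clinical_events_table <- function(results, baseline = "usual_care") {
  stopifnot(baseline %in% names(results))
  base <- results[[baseline]]
  cols <- lapply(results, function(r) {
    c(crc_cases = r$crc_cases,
      incidence_reduction_pct =
        if (identical(r$strategy, base$strategy)) NA
        else round(percent_reduction(base$crc_cases, r$crc_cases)),
      dukes_A = unname(r$crc_cases_by_stage["A"]),
      dukes_B = unname(r$crc_cases_by_stage["B"]),
      dukes_C = unname(r$crc_cases_by_stage["C"]),
      dukes_D = unname(r$crc_cases_by_stage["D"]),
      crc_deaths = r$crc_deaths,
      mortality_reduction_pct =
        if (identical(r$strategy, base$strategy)) NA
        else round(percent_reduction(base$crc_deaths, r$crc_deaths)),
      total_colonoscopies = r$total_colonoscopies,
      colonoscopies_per_life_saved =
        if (identical(r$strategy, base$strategy)) NA
        else suppressWarnings(colonoscopies_per_life_saved(
          r$total_colonoscopies, base$crc_deaths, r$crc_deaths)))
  })
  out <- as.data.frame(cols)
  names(out) <- names(results)
  cbind(measure = rownames(out), out, row.names = NULL)
}

#' Cost-effectiveness plane points
#'
#' Per-strategy (discounted) mean cost and life-years, for plotting the
#' cost-effectiveness plane.
#'
#' @inheritParams clinical_events_table
#' @param discounted use discounted accruals.
#' @return a data.frame with columns `strategy`, `cost`, `effect`.
#' @export
ce_plane_points <- function(results, discounted = TRUE) {
  as_cea_frame(results, discounted)
}
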