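#' Bundled life table for other-cause mortality
#'
#' Age-specific annual probabilities of death from causes other than
#' colorectal cancer, for ages 50-90. The bundled `"standin_gompertz"`
#' profile is a deterministic Gompertz schedule, q(a) = A * exp(B * (a - 50))
#' with A = 0.0025 and B = 0.105, anchored to plausible contemporary
#' Australian all-cause values (q roughly 0.0025 at age 50 and 0.17 at 90).
#' It is a clearly non-authoritative stand-in for an official national life
#' table: supply `table` to replace it with real values.
#'
#' @param profile `"standin_gompertz"` for the bundled schedule, or
#'   `"user_supplied"` together with `table`.
#' @param table for `"user_supplied"`: a named numeric vector or two-column
#'   data frame (`age`, `qx`) covering every integer age 50-90.
#' @return a named numeric vector of annual death probabilities, names
#'   `"50"`..`"90"`, with attribute `"authoritative"` (FALSE for the
#'   stand-in).
#' @export
#' @examples
#' lt <- bundled_life_table()
#' lt["50"]
bundled_life_table <- function(profile = c("standin_gompertz", "user_supplied"),
                               table = NULL) {
  profile <- match.arg(profile)
  ages <- 50:90
  if (profile == "standin_gompertz") {
    qx <- pmin(1, 0.0025 * exp(0.105 * (ages - 50)))
    out <- stats::setNames(qx, ages)
    attr(out, "authoritative") <- FALSE
    return(out)
  }
  if (is.null(table)) stop("profile 'user_supplied' requires `table`")
  if (is.data.frame(table)) {
    if (!all(c("age", "qx") %in% names(table)))
      stop("user life table must have columns `age` and `qx`")
    qx <- stats::setNames(table$qx, table$age)
  } else {
    qx <- table
  }
  missing_ages <- setdiff(ages, as.integer(names(qx)))
  if (length(missing_ages) > 0)
    stop("user life table is missing ages: ", paste(missing_ages, collapse = ", "))
  if (any(qx < 0 | qx > 1)) stop("life table qx values must lie in [0, 1]")
  out <- stats::setNames(as.numeric(qx[as.character(ages)]), ages)
  attr(out, "authoritative") <- TRUE
  out
}

# analytic (expected-value) life expectancy over the 40-cycle horizon under
# the engine's accrual convention: one year is credited, discounted at
# (1+r)^-t with t = age - 50, for each cycle the individual survives.
life_table_expectancy <- function(qx, discount_rate = 0) {
  ages <- 50:89
  q <- as.numeric(qx[as.character(ages)])
  surv <- cumprod(1 - q)            # P(alive at end of cycle t), t = 0..39
  df <- (1 + discount_rate)^(-(0:39))
  sum(df * surv)
}
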