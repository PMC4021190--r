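# shared fixtures: built in code, no files

# default profile, risk-resolved once (derive_onset_rates is not free)
resolved_default <- function() {
  if (is.null(.helper_env$resolved))
    .helper_env$resolved <- crcscreen:::resolve_parameters(crc_parameters())
  .helper_env$resolved
}
.helper_env <- new.env()

# a degenerate configuration: no disease, constant other-cause mortality q
zero_disease_params <- function(q = 0.2, discount_rate = 0) {
  crc_parameters(
    natural_history = list(
      incidence_small_adenoma = rep(0, 5),
      incidence_large_adenoma = rep(0, 5),
      incidence_crc = matrix(0, 5, 4, dimnames = list(NULL, c("A", "B", "C", "D"))),
      other_cause_mortality = stats::setNames(rep(q, 41), 50:90)
    ),
    initial_state_probs = stats::setNames(
      c(1, rep(0, 13)), health_states()),
    relative_risk = 1,
    costs = list(discount_rate = discount_rate)
  )
}

expect_within_3se <- function(observed, expected, se, label = NULL) {
  expect_lt(abs(observed - expected), 3 * se, label = label)
}
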