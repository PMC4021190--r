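#' Health-state space of the natural-history model
#'
#' The model distinguishes 14 mutually exclusive health states: disease-free
#' bowel, small (<10 mm) and large (>=10 mm) adenomas, a post-polypectomy
#' surveillance state, undiagnosed colorectal cancer at Dukes' stages A-D,
#' diagnosed-and-under-treatment cancer at the same stages, and two absorbing
#' death states (CRC death, other-cause death).
#'
#' States are encoded as integers 1..14 in the order given by
#' `health_states()`; all transition machinery uses this encoding.
#'
#' @return `health_states()` returns the character vector of the 14 state
#'   labels in encoding order.
#' @export
health_states <- function() {
  c("Normal", "AdenomaSmall", "AdenomaLarge", "Surveillance",
    "CRC_A", "CRC_B", "CRC_C", "CRC_D",
    "Treat_A", "Treat_B", "Treat_C", "Treat_D",
    "DeadCRC", "DeadOther")
}

# integer codes used throughout the engine
.S <- list(
  Normal = 1L, AdenomaSmall = 2L, AdenomaLarge = 3L, Surveillance = 4L,
  CRC_A = 5L, CRC_B = 6L, CRC_C = 7L, CRC_D = 8L,
  Treat_A = 9L, Treat_B = 10L, Treat_C = 11L, Treat_D = 12L,
  DeadCRC = 13L, DeadOther = 14L
)

.N_STATES <- 14L
.STAGES <- c("A", "B", "C", "D")

state_code <- function(label) {
  i <- match(label, health_states())
  if (anyNA(i)) stop("unknown health state: ", paste(label[is.na(i)], collapse = ", "))
  i
}

state_label <- function(code) health_states()[code]

#' @rdname health_states
#' @param state a state label or integer code (vectorised).
#' @return `is_absorbing()`, `is_crc()`, `is_treat()` return logical vectors.
#' @export
is_absorbing <- function(state) {
  code <- if (is.character(state)) state_code(state) else as.integer(state)
  code >= .S$DeadCRC
}

#' @rdname health_states
#' @export
is_crc <- function(state) {
  code <- if (is.character(state)) state_code(state) else as.integer(state)
  code >= .S$CRC_A & code <= .S$CRC_D
}

#' @rdname health_states
#' @export
is_treat <- function(state) {
  code <- if (is.character(state)) state_code(state) else as.integer(state)
  code >= .S$Treat_A & code <= .S$Treat_D
}

# Dukes' stage index (1..4) of a CRC or Treat state code, NA otherwise
stage_of <- function(code) {
  code <- as.integer(code)
  out <- rep(NA_integer_, length(code))
  crc <- code >= .S$CRC_A & code <= .S$CRC_D
  trt <- code >= .S$Treat_A & code <= .S$Treat_D
  out[crc] <- code[crc] - .S$CRC_A + 1L
  out[trt] <- code[trt] - .S$Treat_A + 1L
  out
}
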