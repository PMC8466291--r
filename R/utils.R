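#' Round half away from zero
#'
#' Base [round()] rounds half to even; the exposure category boundaries are
#' printed two-decimal values, so proportions are matched after conventional
#' half-up rounding (0.325 -> 0.33).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Whole days elapsed between two datetimes
#'
#' Ages are calf-relative: a calf turns one day old exactly 24 h after its
#' birth timestamp, not at calendar midnight.
#'
#' @param from,to POSIXct datetimes.
#' @return integer vector of completed 24-h periods.
#' @keywords internal
whole_days <- function(from, to) {
  floor(as.numeric(difftime(to, from, units = "hours")) / 24)
}

# Seed a substream keyed by purpose, so adding a new draw site never
# reorders existing streams. Keeps derived seeds below 2^31.
seed_substream <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose))) %% 99991L
  set.seed(((as.integer(seed) %% 20011L) + 1L) * 99989L + h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
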