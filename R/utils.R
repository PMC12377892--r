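# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used when report tables are emitted;
#' internal arithmetic is never rounded. `round()` in R rounds half to even,
#' which does not reproduce printed report cells such as 20.45 -> 20.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# hazard -> one-cycle probability (annual cycles)
hazard_to_prob <- function(h) -expm1(-h)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-cycle seed derived from the master seed; kept well below
# .Machine$integer.max for 32-bit safety
cycle_seed <- function(seed, t) {
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(t)
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
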