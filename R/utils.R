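#' @keywords internal
"_PACKAGE"

# Rounding conventions used for publication-style output: counts to integers,
# percentages to 1 decimal, both half-away-from-zero (base round() is
# half-to-even, which does not reproduce printed registry tables).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_canestim <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

warn_canestim <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

# Seeds derived from a single user seed, one per independent random table;
# kept below 2^31 - 1 so they remain valid R integers.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}
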