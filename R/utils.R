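# Internal helpers shared across modules.

# Deterministic per-stage child seed below 2^31, so one top-level seed
# drives independent RNG streams for truth / expression / prediction draws.
childSeed <- function(seed, stage) {
  (as.integer(seed) %% 599479L) * 3571L + as.integer(stage) * 7919L
}

# round() uses banker's rounding; printed percentages in array reports use
# round-half-away-from-zero, so 0.5 -> 1.
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNotProb <- function(p, what) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("%s must lie in [0, 1] (no missing values)", what),
         call. = FALSE)
  invisible(p)
}
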