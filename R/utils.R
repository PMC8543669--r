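# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rounding "half away from zero" (2.5 -> 3, -2.5 -> -3).  base::round() uses
# banker's rounding, which does not reproduce clinically reported percentages.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

ec_stop <- function(msg, class = "eyecode_validation_error") {
  stop(structure(
    class = c(class, "eyecode_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ec_assert <- function(ok, msg, class = "eyecode_validation_error") {
  if (!isTRUE(ok)) ec_stop(msg, class)
  invisible(TRUE)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state;
# with a NULL seed the current stream is used (and advanced).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
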