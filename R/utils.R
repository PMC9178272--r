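# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed means "use the current RNG stream".
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Trapezoidal integral of y over an ordered grid x.
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Drop non-finite entries, remembering how many were removed.
finite_values <- function(x, what = "values") {
  x <- as.numeric(x)
  keep <- is.finite(x)
  out <- x[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}
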