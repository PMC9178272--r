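# The three per-fly behavioral statistics computed from raw left/right
# choice sequences: turn bias, number of turns, and turn switchiness.

#' Construct a turn sequence
#'
#' A turn sequence is an individual fly's ordered binary choices, encoded
#' as a character vector of `"L"`/`"R"` labels, optionally with strictly
#' increasing timestamps (seconds). All measure functions also accept a
#' plain character vector.
#'
#' @param turns Character vector with elements `"L"` or `"R"` (a factor or
#'   logical vector is accepted; `TRUE` means a right turn).
#' @param times Optional numeric vector of the same length, strictly
#'   increasing.
#' @return A character vector of class `"turn_sequence"`, with a `times`
#'   attribute if timestamps were supplied.
#' @export
#' @examples
#' turn_sequence(c("L", "R", "R"))
turn_sequence <- function(turns, times = NULL) {
  turns <- as_turns(turns)
  if (!is.null(times)) {
    if (length(times) != length(turns)) {
      stop("'times' must match the number of turns", call. = FALSE)
    }
    if (length(times) > 1 && any(diff(times) <= 0)) {
      stop("'times' must be strictly increasing", call. = FALSE)
    }
    attr(turns, "times") <- as.numeric(times)
  }
  class(turns) <- c("turn_sequence", class(turns))
  turns
}

# Normalize the accepted encodings to a bare character vector of L/R.
as_turns <- function(x) {
  if (is.logical(x)) {
    return(c("L", "R")[x + 1L])
  }
  x <- as.character(x)
  if (length(x) && !all(x %in% c("L", "R"))) {
    stop("turn labels must be 'L' or 'R'", call. = FALSE)
  }
  x
}

#' Turn bias: fraction of right turns
#'
#' The plug-in maximum-likelihood estimate (number of `R` turns divided by
#' sequence length, no continuity correction), so the discreteness of
#' possible values at a given turn count is preserved.
#'
#' @param seq A turn sequence (see [turn_sequence()]).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' turn_bias(c("R", "R", "L")) # 2/3
turn_bias <- function(seq) {
  t <- as_turns(seq)
  if (length(t) == 0) {
    stop("turn bias is undefined for an empty sequence", call. = FALSE)
  }
  mean(t == "R")
}

#' Number of adjacent L/R alternations
#'
#' Counts adjacent index pairs whose labels differ (the `LR` and `RL`
#' transitions); the raw ingredient of switchiness.
#'
#' @inheritParams turn_bias
#' @return Integer in `0..(n - 1)`.
#' @export
alternation_count <- function(seq) {
  t <- as_turns(seq)
  n <- length(t)
  if (n == 0) {
    stop("alternation count is undefined for an empty sequence",
      call. = FALSE)
  }
  if (n == 1) return(0L)
  sum(t[-1] != t[-n])
}

#' Turn switchiness
#'
#' Observed alternations divided by their expectation under independent
#' draws at the fly's own bias:
#' \deqn{S = A / ((n - 1) \cdot 2 \hat p (1 - \hat p)).}
#' A fly alternating exactly as a binomial model predicts has S = 1; lower
#' values mean longer streaks of same-direction turns, higher values mean
#' over-alternation. S is undefined (missing) when the normalizer is zero,
#' i.e. when n < 2 or the observed bias is exactly 0 or 1.
#'
#' @inheritParams turn_bias
#' @return Non-negative real, or `NA` when undefined.
#' @seealso [switchiness_stat()] for the pure function of (A, n, p).
#' @export
#' @examples
#' switchiness(c("L", "R", "L", "R", "L", "R")) # 2.0: perfect alternation
#' switchiness(c("L", "L", "L", "R", "R", "R")) # 0.4: one long streak each
switchiness <- function(seq) {
  t <- as_turns(seq)
  n <- length(t)
  if (n < 2) return(NA_real_)
  switchiness_stat(alternation_count(t), n, mean(t == "R"))
}

#' @param A Alternation count.
#' @param n Number of turns.
#' @param p Observed fraction of right turns.
#' @rdname switchiness
#' @export
switchiness_stat <- function(A, n, p) {
  out <- A / ((n - 1) * 2 * p * (1 - p))
  out[n < 2 | p <= 0 | p >= 1] <- NA_real_
  out
}

#' Compute all measures for a collection of sequences
#'
#' Element-wise application of [turn_bias()], [alternation_count()] and
#' [switchiness()], order preserved. Per-fly undefined values (empty
#' sequences, one-sided flies) propagate as missing rather than erroring.
#'
#' @param seqs List of turn sequences; names, if present, become `flyID`.
#' @param min_turns Minimum-turn filter: flies with fewer turns have their
#'   `turn_bias` and `switchiness` masked to missing. The default 0
#'   disables the filter, so that grand analyses use every fly.
#' @return A tibble with columns `flyID`, `num_turns`, `turn_bias`,
#'   `alternation_count`, `switchiness`.
#' @export
compute_measures <- function(seqs, min_turns = 0) {
  if (length(seqs) == 0) {
    return(tibble(
      flyID = character(0), num_turns = integer(0), turn_bias = numeric(0),
      alternation_count = integer(0), switchiness = numeric(0)
    ))
  }
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  n <- integer(length(seqs))
  p <- a <- s <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    t <- as_turns(seqs[[i]])
    ni <- length(t)
    n[i] <- ni
    if (ni == 0) {
      p[i] <- a[i] <- s[i] <- NA_real_
    } else {
      p[i] <- mean(t == "R")
      a[i] <- if (ni == 1) 0 else sum(t[-1] != t[-ni])
      s[i] <- switchiness_stat(a[i], ni, p[i])
    }
  }
  low <- n < min_turns
  p[low] <- NA_real_
  s[low] <- NA_real_
  tibble(
    flyID = ids, num_turns = n, turn_bias = p,
    alternation_count = as.integer(round(a)), switchiness = s
  )
}
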