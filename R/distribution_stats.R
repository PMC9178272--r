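# Characterization of the across-fly distribution of a behavioral
# measure: standardized moments, bootstrap confidence intervals, kernel
# density estimates, Gaussian best fit, and subsample stability curves.

# Moments 1..max_order of x in the panel convention: order 1 is the mean,
# order 2 the sample variance, order k >= 3 the standardized central
# moment mean(((x - xbar)/s)^k) with s the root mean squared deviation
# (population SD), so that the standardized second moment is 1 by
# construction and the Gaussian kurtosis is the non-excess value 3.
panel_moments <- function(x, max_order) {
  m <- mean(x)
  out <- numeric(max_order)
  out[1] <- m
  if (max_order >= 2) out[2] <- var(x)
  if (max_order >= 3) {
    xc <- x - m
    s <- sqrt(mean(xc * xc))
    z <- xc / s
    zk <- z * z
    for (k in 3:max_order) {
      zk <- zk * z
      out[k] <- mean(zk)
    }
  }
  out
}

#' Standardized moment of a sample
#'
#' Order 1 returns the mean and order 2 the sample variance; orders
#' \eqn{k \ge 3} return the standardized central moment
#' \eqn{m_k / m_2^{k/2}} with \eqn{m_j = \frac{1}{n}\sum (x_i - \bar x)^j},
#' so order 3 is skewness and order 4 is non-excess kurtosis (Gaussian
#' value 3).
#'
#' @param values Numeric vector; non-finite entries are dropped. At least
#'   3 finite values with positive spread are required.
#' @param k Moment order, integer \eqn{\ge 1}.
#' @return A single real.
#' @export
#' @examples
#' standardized_moment(c(-1, 0, 1), 3) # 0 by symmetry
standardized_moment <- function(values, k) {
  stopifnot(length(k) == 1, k >= 1, k == round(k))
  x <- finite_values(values)
  if (length(x) < 3) {
    stop("need at least 3 finite values", call. = FALSE)
  }
  if (sd(x) == 0) {
    stop("degenerate scale: all values identical", call. = FALSE)
  }
  panel_moments(x, k)[k]
}

#' Bootstrap a statistic with the +/- 2 SD confidence interval
#'
#' Draws `B` resamples with replacement of the full sample size, applies
#' `statistic` to each, and forms the 95% confidence interval as the point
#' estimate plus/minus twice the standard deviation of the replicate
#' values. Replicates on which the statistic errors or is non-finite are
#' recorded as missing, excluded from the SD, and counted.
#'
#' @param values Numeric vector (resampling unit = one fly).
#' @param statistic Function of a numeric vector returning one number.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Optional integer; fixes the replicate stream.
#' @return An object of class `"ymi_boot"`: a list with `estimate`,
#'   `replicates`, `boot_mean`, `boot_sd`, `ci_low`, `ci_high`,
#'   `n_failed`, `B`, `n`, `seed`.
#' @export
bootstrap_statistic <- function(values, statistic, B = 1000, seed = NULL) {
  stopifnot(B >= 2)
  x <- finite_values(values)
  n <- length(x)
  if (n == 0) stop("no finite values to bootstrap", call. = FALSE)
  estimate <- statistic(x)
  reps <- maybe_with_seed(seed, {
    vapply(seq_len(B), function(b) {
      r <- tryCatch(statistic(x[sample.int(n, n, replace = TRUE)]),
        error = function(e) NA_real_)
      if (is.finite(r)) r else NA_real_
    }, numeric(1))
  })
  boot_sd <- sd(reps, na.rm = TRUE)
  structure(
    list(
      estimate = estimate,
      replicates = reps,
      boot_mean = mean(reps, na.rm = TRUE),
      boot_sd = boot_sd,
      ci_low = estimate - 2 * boot_sd,
      ci_high = estimate + 2 * boot_sd,
      n_failed = sum(is.na(reps)),
      B = B, n = n, seed = seed
    ),
    class = "ymi_boot"
  )
}

#' @export
print.ymi_boot <- function(x, ...) {
  cat(sprintf(
    "Bootstrap estimate: %.6g  (95%% CI %.6g .. %.6g; B = %d, n = %d%s)\n",
    x$estimate, x$ci_low, x$ci_high, x$B, x$n,
    if (x$n_failed > 0) sprintf(", %d failed replicates", x$n_failed) else ""
  ))
  invisible(x)
}

#' Bootstrap panel of moments up to a maximum order
#'
#' One report per order 1..`max_order` (mean, variance, then standardized
#' moments). All orders share the same resample stream so the panel is
#' internally consistent: each replicate contributes a full moment vector.
#' The significance ratio `|boot_mean| / boot_sd` implements the rule that
#' a moment is distinguishable from 0 at p = 0.05 when the ratio exceeds 2.
#'
#' @inheritParams bootstrap_statistic
#' @param max_order Highest moment order (default 20).
#' @return A tibble with columns `order`, `point_estimate`, `boot_mean`,
#'   `boot_sd`, `ci_low`, `ci_high`, `signif_ratio`.
#' @export
moment_panel <- function(values, max_order = 20, B = 1000, seed = NULL) {
  stopifnot(max_order >= 2, B >= 2)
  x <- finite_values(values)
  if (length(x) < 3) stop("need at least 3 finite values", call. = FALSE)
  if (sd(x) == 0) {
    stop("degenerate scale: all values identical", call. = FALSE)
  }
  n <- length(x)
  point <- panel_moments(x, max_order)
  reps <- maybe_with_seed(seed, {
    out <- matrix(NA_real_, nrow = B, ncol = max_order)
    for (b in seq_len(B)) {
      out[b, ] <- panel_moments(x[sample.int(n, n, replace = TRUE)],
        max_order)
    }
    out
  })
  boot_mean <- colMeans(reps, na.rm = TRUE)
  boot_sd <- apply(reps, 2, sd, na.rm = TRUE)
  tibble(
    order = seq_len(max_order),
    point_estimate = point,
    boot_mean = boot_mean,
    boot_sd = boot_sd,
    ci_low = point - 2 * boot_sd,
    ci_high = point + 2 * boot_sd,
    signif_ratio = abs(boot_mean) / boot_sd
  )
}

#' Moment stability under subsampling
#'
#' For each fraction, draws one random subset without replacement (plus
#' optional repeats) and recomputes the bootstrap moment panel, tracing
#' how estimate reliability degrades as the data set shrinks. Which orders
#' retain `signif_ratio >= 2` at small fractions depends strongly on the
#' underlying distribution, not just the sample size.
#'
#' @inheritParams moment_panel
#' @param fractions Distinct subsample fractions in (0, 1\]; each
#'   subsample must keep at least 10 values.
#' @param repeats Independent subset draws per fraction (default 1,
#'   mirroring a single random subset per size).
#' @return A tibble: the moment panel columns plus `fraction`, `draw`,
#'   `n_used`.
#' @export
stability_curve <- function(values, max_order = 20,
                            fractions = c(1, 0.1, 0.01),
                            B = 1000, seed = NULL, repeats = 1) {
  x <- finite_values(values)
  if (any(fractions > 1 | fractions <= 0)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(fractions)) {
    stop("fractions must be distinct", call. = FALSE)
  }
  fractions <- sort(fractions, decreasing = TRUE)
  n <- length(x)
  if (round(min(fractions) * n) < 10) {
    stop("smallest fraction leaves fewer than 10 values", call. = FALSE)
  }
  maybe_with_seed(seed, {
    out <- list()
    for (f in fractions) {
      for (r in seq_len(repeats)) {
        idx <- sample.int(n, round(f * n), replace = FALSE)
        panel <- moment_panel(x[idx], max_order = max_order, B = B,
          seed = NULL)
        panel$fraction <- f
        panel$draw <- r
        panel$n_used <- length(idx)
        out[[length(out) + 1L]] <- panel
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Gaussian-kernel density estimate with optional bootstrap band
#'
#' Kernel density on a regular grid using a Gaussian kernel and
#' Silverman's rule-of-thumb bandwidth by default. No boundary correction
#' is applied at 0/1 for bias-like measures; the bandwidth is exposed as a
#' knob. With `B > 0`, a pointwise 95% band is formed as the density
#' plus/minus twice the SD of replicate densities (same grid, same
#' bandwidth, fly-wise resampling).
#'
#' @inheritParams bootstrap_statistic
#' @param bandwidth Positive numeric bandwidth, or `NULL` for Silverman's
#'   rule.
#' @param n_grid Number of grid points (default 512).
#' @param from,to Optional grid limits; defaults follow
#'   [stats::density()].
#' @param B Bootstrap replicates for the band; 0 (default) for no band.
#' @return An object of class `"density_estimate"`: list with `grid`,
#'   `density`, `bandwidth`, `n`, and if banded `ci_low`, `ci_high`.
#' @export
kde <- function(values, bandwidth = NULL, n_grid = 512,
                from = NULL, to = NULL, B = 0, seed = NULL) {
  x <- finite_values(values)
  if (length(x) < 10) stop("need at least 10 finite values", call. = FALSE)
  if (!is.null(bandwidth) && bandwidth <= 0) {
    stop("bandwidth must be positive", call. = FALSE)
  }
  args <- list(x = x, kernel = "gaussian", n = n_grid,
    bw = bandwidth %||% "nrd0")
  if (!is.null(from)) args$from <- from
  if (!is.null(to)) args$to <- to
  d <- do.call(density, args)
  out <- list(grid = d$x, density = d$y, bandwidth = d$bw, n = length(x))
  if (B > 0) {
    lo <- min(d$x)
    hi <- max(d$x)
    reps <- maybe_with_seed(seed, {
      m <- matrix(NA_real_, nrow = B, ncol = n_grid)
      for (b in seq_len(B)) {
        xb <- x[sample.int(length(x), length(x), replace = TRUE)]
        m[b, ] <- density(xb, bw = d$bw, kernel = "gaussian",
          n = n_grid, from = lo, to = hi)$y
      }
      m
    })
    sds <- apply(reps, 2, sd)
    out$ci_low <- pmax(0, d$y - 2 * sds)
    out$ci_high <- d$y + 2 * sds
    out$B <- B
  }
  structure(out, class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(
    "Kernel density estimate: n = %d, bandwidth = %.4g, grid of %d points%s\n",
    x$n, x$bandwidth, length(x$grid),
    if (!is.null(x$ci_low)) sprintf(", bootstrap band (B = %d)", x$B) else ""
  ))
  invisible(x)
}

#' Maximum-likelihood Gaussian fit
#'
#' The Gaussian that best fits the sample: mean and ML standard deviation
#' (root mean squared deviation, i.e. the n-denominator form). Comparing
#' this fit with the kernel density estimate shows how a measure deviates
#' from normality (e.g. a distribution denser at its mode, with heavier
#' tails).
#'
#' @inheritParams bootstrap_statistic
#' @return List with elements `mean`, `sd`, `n`. A zero SD (constant
#'   input) is flagged with a warning.
#' @export
#' @examples
#' gaussian_fit(c(0, 2)) # mean 1, sd 1
gaussian_fit <- function(values) {
  x <- finite_values(values)
  if (length(x) < 2) stop("need at least 2 finite values", call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) warning("degenerate fit: sd is 0", call. = FALSE)
  list(mean = m, sd = s, n = length(x))
}
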