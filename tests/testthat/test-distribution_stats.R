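# Moment machinery, bootstrap CIs, KDE and Gaussian fit.

test_that("standardized moments match closed forms and a quadrature oracle", {
  expect_equal(standardized_moment(c(-1, 0, 1), 3), 0)

  x <- withr::with_seed(31, rnorm(1e5))
  expect_lt(abs(standardized_moment(x, 4) - 3), 0.1)

  # Quadrature oracle for the 6th standardized moment of Beta(2, 5).
  dens <- function(t) dbeta(t, 2, 5)
  mu <- integrate(function(t) t * dens(t), 0, 1)$value
  m2 <- integrate(function(t) (t - mu)^2 * dens(t), 0, 1)$value
  m6 <- integrate(function(t) (t - mu)^6 * dens(t), 0, 1)$value
  oracle <- m6 / m2^3
  xb <- withr::with_seed(32, rbeta(3e5, 2, 5))
  expect_lt(abs(standardized_moment(xb, 6) - oracle) / oracle, 0.1)

  expect_error(standardized_moment(rep(1, 10), 4), "degenerate")
  expect_error(standardized_moment(c(1, 2), 3), "at least 3")
})

test_that("standardized moments are affine-invariant; odd orders flip sign under reflection", {
  x <- withr::with_seed(33, rgamma(5000, shape = 2))
  for (k in c(3, 4, 5, 6)) {
    base <- standardized_moment(x, k)
    expect_equal(standardized_moment(3.7 * x - 11, k), base,
      tolerance = 1e-10)
    flipped <- standardized_moment(-2 * x + 5, k)
    expect_equal(flipped, if (k %% 2 == 1) -base else base,
      tolerance = 1e-10)
  }
})

test_that("bootstrap CI is the estimate plus/minus twice the replicate SD", {
  # Constant values: any averaging statistic has a zero-width CI.
  b <- bootstrap_statistic(rep(2.5, 40), mean, B = 100, seed = 1)
  expect_equal(b$ci_low, 2.5)
  expect_equal(b$ci_high, 2.5)

  # Closed-form SEM oracle: mean of n standard normals.
  n <- 1e4
  x <- withr::with_seed(41, rnorm(n))
  b <- bootstrap_statistic(x, mean, B = 1000, seed = 2)
  half <- (b$ci_high - b$ci_low) / 2
  expect_lt(abs(half - 2 / sqrt(n)), 0.002)
  expect_equal(b$ci_low, b$estimate - 2 * b$boot_sd)

  # Reproducible from the seed, bit for bit.
  b2 <- bootstrap_statistic(x, mean, B = 1000, seed = 2)
  expect_identical(b$replicates, b2$replicates)
  # Different seeds agree closely on the interval.
  b3 <- bootstrap_statistic(x, mean, B = 1000, seed = 99)
  expect_lt(abs(b3$ci_low - b$ci_low), 0.005)

  # Failing replicates are excluded and counted; the full-sample
  # estimate is defined, but resamples missing the value 1 error out.
  flaky <- function(v) if (!any(v == 1)) stop("bad resample") else mean(v)
  bf <- bootstrap_statistic(c(1, rep(10, 9)), flaky, B = 200, seed = 3)
  expect_gt(bf$n_failed, 0)
  expect_true(is.finite(bf$boot_sd))
})

test_that("moment panel: uniform kurtosis, odd-moment insignificance, shared-stream consistency", {
  u <- withr::with_seed(51, runif(4e4))
  panel <- moment_panel(u, max_order = 4, B = 300, seed = 52)
  expect_lt(abs(panel$point_estimate[4] - 1.8), 0.05)
  expect_equal(panel$signif_ratio, abs(panel$boot_mean) / panel$boot_sd)

  # Symmetric +/-1 sample: odd orders are indistinguishable from zero.
  coin <- withr::with_seed(53, sample(c(-1, 1), 400, replace = TRUE))
  p2 <- moment_panel(coin, max_order = 5, B = 300, seed = 54)
  expect_lt(p2$signif_ratio[3], 2)
  expect_lt(p2$signif_ratio[5], 2)

  # Same seed reruns bit-identically.
  p3 <- moment_panel(u, max_order = 4, B = 300, seed = 52)
  expect_identical(panel, p3)
})

test_that("moment panel matches Gaussian double factorials within its own CI at moderate n", {
  x <- withr::with_seed(61, rnorm(2e4))
  panel <- moment_panel(x, max_order = 8, B = 200, seed = 62)
  dfact <- c(0, 1, 0, 3, 0, 15, 0, 105) # (k-1)!! for even k, 0 for odd
  for (k in 2:8) {
    expect_lt(panel$ci_low[k], dfact[k] + 1e-9)
    expect_gt(panel$ci_high[k], dfact[k] - 1e-9)
  }
})

test_that("stability curve reduces to the moment panel at fraction 1 and tracks subsample size", {
  x <- withr::with_seed(71, rbeta(2000, 5, 5))
  sc <- stability_curve(x, max_order = 6, fractions = 1, B = 150,
    seed = 72)
  mp <- moment_panel(x, max_order = 6, B = 150, seed = 72)
  expect_equal(sc$point_estimate, mp$point_estimate)
  expect_equal(sc$n_used, rep(2000, 6))

  sc2 <- stability_curve(x, max_order = 6, fractions = c(1, 0.1),
    B = 150, seed = 73)
  expect_setequal(unique(sc2$n_used), c(2000, 200))
  # Subsampled estimates are noisier for the top order.
  top <- sc2[sc2$order == 6, ]
  expect_gt(top$boot_sd[top$fraction == 0.1],
    top$boot_sd[top$fraction == 1])

  expect_error(stability_curve(x, fractions = c(1, 2)), "\\(0, 1\\]")
  expect_error(stability_curve(x, fractions = c(0.5, 0.5)), "distinct")
  expect_error(stability_curve(rnorm(50), fractions = 0.01), "fewer than 10")
})

test_that("high-order estimates are less reliable for heavy-tailed samples", {
  # Estimator reliability depends on the underlying distribution, not
  # just the sample size: at a 10-fold subsample, the top-order moment
  # of a bounded sample stays sharply resolved while a log-normal
  # sample's does not.
  n <- 5000
  bounded <- withr::with_seed(81, rbeta(n, 2, 2))
  heavy <- withr::with_seed(82, rlnorm(n, 0, 1))
  f <- c(1, 0.1)
  sb <- stability_curve(bounded, max_order = 10, fractions = f, B = 150,
    seed = 83, repeats = 3)
  sh <- stability_curve(heavy, max_order = 10, fractions = f, B = 150,
    seed = 84, repeats = 3)
  ratio_at <- function(sc, fr) {
    mean(sc$signif_ratio[sc$order == 10 & sc$fraction == fr])
  }
  expect_gt(ratio_at(sb, 0.1), 2)            # bounded: still significant
  expect_lt(ratio_at(sh, 0.1), ratio_at(sb, 0.1))
  expect_lt(ratio_at(sh, 1), ratio_at(sb, 1))
})

test_that("kde integrates to one, finds the right mode, and bands are ordered", {
  x <- withr::with_seed(91, rnorm(5000))
  d <- kde(x)
  integral <- sum(diff(d$grid) * (d$density[-1] + d$density[-512]) / 2)
  expect_lt(abs(integral - 1), 0.01)
  expect_lt(abs(max(d$density) - dnorm(0)), 0.03)

  spike <- withr::with_seed(92, rnorm(200, mean = 3, sd = 1e-3))
  ds <- kde(spike)
  expect_lt(abs(ds$grid[which.max(ds$density)] - 3), 0.01)

  db <- kde(x, B = 50, seed = 93)
  expect_true(all(db$ci_low <= db$density + 1e-12))
  expect_true(all(db$ci_high >= db$density - 1e-12))

  expect_error(kde(x, bandwidth = -1), "positive")
  expect_error(kde(rnorm(5)), "at least 10")
})

test_that("gaussian fit returns ML parameters and flags degenerate input", {
  f <- gaussian_fit(c(0, 2))
  expect_equal(f$mean, 1)
  expect_equal(f$sd, 1)

  x <- withr::with_seed(95, rnorm(5e4, 0.5, 0.1))
  f2 <- gaussian_fit(x)
  expect_lt(abs(f2$mean - 0.5), 0.005)
  expect_lt(abs(f2$sd - 0.1), 0.005)

  expect_warning(gaussian_fit(rep(1, 5)), "degenerate")
})

test_that("a leptokurtic bias distribution is denser at its mode than its Gaussian fit", {
  # Beta mixture: a tight core plus broad tails, the heavy-mode shape.
  spec <- population_spec(
    n_per_group = 4000, turns_mean = 200, turns_cv = 0.5,
    bias_mixture = list(
      weights = c(0.55, 0.35, 0.10),
      means = c(0.5, 0.496, 0.5),
      sds = c(0.05, 0.15, 0.28)
    ),
    seed = 96
  )
  h <- generate_cohort(spec)$cohort$handedness
  h <- h[is.finite(h)]
  expect_gt(standardized_moment(h, 4), 3)
  d <- kde(h)
  fit <- gaussian_fit(h)
  mode_density <- max(d$density)
  fitted_at_mode <- dnorm(d$grid[which.max(d$density)], fit$mean, fit$sd)
  expect_gt(mode_density, fitted_at_mode)
})
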