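# Levene transforms, group CVs, metadata models, enrichment,
# correlations and paired effect sizes.

test_that("levene transform is the absolute deviation from the group mean", {
  expect_equal(levene_transform(c(1, 3), c("a", "a")), c(1, 1))
  expect_equal(
    levene_transform(c(0, 0, -2, 2), c("g1", "g1", "g2", "g2")),
    c(0, 0, 2, 2)
  )
  expect_warning(
    d <- levene_transform(c(1, 2, 5), c("a", "a", "b")),
    "singleton"
  )
  expect_true(is.na(d[3]))
  expect_equal(d[1:2], c(0.5, 0.5))
})

test_that("OLS on Levene deviations reproduces the classical Levene test", {
  withr::with_seed(101, {
    for (i in 1:20) {
      k <- sample(2:4, 1)
      sizes <- sample(3:8, k, replace = TRUE)
      g <- rep(letters[1:k], sizes)
      y <- rnorm(length(g), sd = rep(runif(k, 0.5, 3), sizes))
      ours <- levene_test(y, g)
      oracle <- car::leveneTest(y ~ factor(g), center = mean)
      expect_equal(ours$statistic, oracle[1, "F value"], tolerance = 1e-6)
      expect_equal(ours$p_value, oracle[1, "Pr(>F)"], tolerance = 1e-6)
    }
  })
})

test_that("group CV is sd over mean, scale-invariant, and guards degenerate groups", {
  out <- group_cv(c(0.4, 0.5, 0.6), rep("g", 3))
  expect_equal(out$cv, 0.2) # sd of the three values is exactly 0.1
  expect_equal(group_cv(rep(3, 5), rep("g", 5))$cv, 0)

  withr::with_seed(111, {
    v <- rlnorm(60)
    g <- rep(c("a", "b"), each = 30)
    base <- group_cv(v, g)
    scaled <- group_cv(v * 17.3, g)
    expect_equal(scaled$cv, base$cv, tolerance = 1e-12)
  })

  expect_warning(
    neg <- group_cv(c(-1, -2, 0.5, 0.7), c("n", "n", "p", "p")),
    "non-positive"
  )
  expect_true(is.na(neg$cv[neg$group == "n"]))
  # min_n threshold drops small groups.
  expect_equal(nrow(group_cv(c(1, 2, 3), c("a", "a", "b"), min_n = 2)), 1)
})

test_that("group CVs injected by the generator are recovered from measured handedness", {
  spec <- population_spec(
    genotypes = c("lowvar", "midvar", "highvar"),
    n_per_group = 200,
    bias_mean = 0.5,
    bias_sd = c(0.1, 0.15, 0.2), # one per genotype, design order
    turns_mean = 435, turns_cv = 0.45,
    seed = 112
  )
  coh <- generate_cohort(spec)$cohort
  cv <- group_cv(coh$handedness, coh$genotype)
  truth <- c(highvar = 0.4, lowvar = 0.2, midvar = 0.3)
  expect_equal(cv$group, names(truth))
  expect_true(all(abs(cv$cv - truth) < 0.02))
})

test_that("metadata OLS recovers group contrasts and reports rank deficiency", {
  jitter6 <- c(-1, 2, -2, 1, 3, -3) * 1e-3
  tab <- tibble::tibble(
    y = c(0.4 + jitter6, 0.6 + jitter6),
    grp = rep(c("a", "b"), each = 6)
  )
  fit <- fit_metadata_model(tab, "y", "grp")
  expect_equal(
    fit$coefficients$estimate[fit$coefficients$term == "grpb"], 0.2,
    ignore_attr = TRUE
  )
  expect_equal(fit$intercept, 0.4)

  tab$grp2 <- tab$grp # duplicated predictor: aliased design
  expect_error(
    fit_metadata_model(tab, "y", c("grp", "grp2")),
    "rank-deficient.*grp2"
  )
  expect_error(fit_metadata_model(tab, "y", "nope"), "missing column")
  tab$const <- "x"
  expect_error(fit_metadata_model(tab, "y", "const"), "fewer than 2")
})

test_that("null-response p-values from random predictors are roughly uniform", {
  withr::with_seed(121, {
    n <- 400
    dat <- tibble::tibble(y = rnorm(n))
    preds <- sprintf("x%02d", 1:10)
    for (p in preds) dat[[p]] <- sample(c("u", "v"), n, replace = TRUE)
    fit <- fit_metadata_model(dat, "y", preds)
    pv <- fit$coefficients$p_value[fit$coefficients$term != "(Intercept)"]
    expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  })
})

test_that("per-genotype indicator p-values are uniform under the null and power the enrichment test", {
  withr::with_seed(131, {
    g <- rep(sprintf("g%02d", 1:50), each = 30)
    y <- rbeta(length(g), 10, 10) # all genotype means equal
    gp <- genotype_pvalues(y, g)
    expect_equal(nrow(gp), 50)
    expect_gt(ks.test(gp$p_value, "punif")$p.value, 0.01)
    # No enrichment beyond chance: the sub-alpha count stays within
    # binomial bounds and the enrichment test is not extreme.
    enr <- genotype_enrichment(gp$p_value)
    expect_lte(enr$n_significant, qbinom(0.9995, 50, 0.05))
    expect_gt(enr$p_value, 0.01)
  })

  # Strong shared effects: everything significant, enrichment certain.
  all_hits <- genotype_enrichment(rep(0.001, 30), alpha = 0.05)
  expect_equal(all_hits$n_significant, 30)
  expect_lt(all_hits$p_value, 1e-12)

  # Binomial oracle equivalence on an arbitrary configuration.
  pv <- c(runif(12, 0, 0.0499), runif(88, 0.06, 1))
  enr <- genotype_enrichment(pv, alpha = 0.05)
  expect_equal(
    enr$p_value,
    binom.test(12, 100, 0.05, alternative = "greater")$p.value
  )
  expect_error(genotype_enrichment(numeric(0)), "no p-values")
  expect_error(genotype_enrichment(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("pearson correlation matches a hand-computed covariance ratio", {
  expect_equal(measure_correlation(1:10, 1:10)$r, 1)
  expect_equal(measure_correlation(1:10, 11 - (1:10))$r, -1)

  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(measure_correlation(x, y)$r, num / den)

  expect_error(measure_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(measure_correlation(1:2, 1:2), "at least 3")
})

test_that("absolute bias folds turn bias around one half", {
  expect_equal(absolute_bias(0.5), 0)
  expect_equal(absolute_bias(0.1), 0.4)
  expect_error(absolute_bias(1.2), "\\[0, 1\\]")
  # Fold-and-compare against the generator's latent biases.
  truth <- sample_population(population_spec(n_per_group = 2000,
    seed = 141))
  folded <- absolute_bias(truth$p_true)
  expect_equal(folded, abs(truth$p_true - 0.5))
  expect_true(all(folded <= 0.5))
})

test_that("temperature groups merge 22 with 23 and 32 with 33", {
  expect_equal(
    temperature_group(c(22, 23, 25, 32, 33)),
    c("23", "23", "25", "33", "33")
  )
})

test_that("paired effects: identical conditions are null, swapping flips sign, p preserved", {
  coh <- generate_cohort(two_condition_spec(
    n_genotypes = 8, n_per_group = 60, treatment_cv_factor = 0.8,
    seed = 151
  ))$cohort

  # Identical conditions: compare ctrl against itself.
  same <- paired_effect(coh, "numTurns", "ctrl", "ctrl")
  expect_equal(same$effect_pct, 0)
  expect_equal(same$p_value, 1)

  fwd <- paired_effect(coh, "numTurns", "ctrl", "trt")
  rev <- paired_effect(coh, "numTurns", "trt", "ctrl")
  expect_equal(rev$p_value, fwd$p_value)
  expect_equal(rev$t_statistic, -fwd$t_statistic)
  expect_lt(fwd$effect_pct * rev$effect_pct, 0)
  # Approximate antisymmetry of the relative-change aggregation.
  expect_equal(rev$effect_pct,
    -100 * fwd$effect_pct / (100 + fwd$effect_pct),
    tolerance = 0.15)

  one <- coh[coh$genotype == "line01", ]
  expect_error(paired_effect(one, "numTurns", "ctrl", "trt")
    , "pairing error")
  expect_error(paired_effect(coh, "numTurns", "ctrl", "nosuch"),
    "pairing error")
})

test_that("the sex Levene model recovers an injected male-variance inflation", {
  spec <- population_spec(
    genotypes = sprintf("g%d", 1:5),
    sexes = c("female", "male"),
    n_per_group = 400,
    bias_mean = 0.5, bias_sd = 0.1,
    turns_mean = 435, turns_cv = 0.45,
    seed = 161
  )
  male <- spec$design$sex == "male"
  spec$design$bias_sd[male] <- 0.13
  coh <- generate_cohort(spec)$cohort
  res <- sex_variability_effect(coh, "handedness")

  # Expected percent inflation of measured spread, accounting for the
  # binomial measurement noise at the simulated turn counts.
  noise <- 0.25 / 435
  expected <- 100 * (sqrt(0.13^2 + noise) / sqrt(0.1^2 + noise) - 1)
  se_pct <- 100 * res$se / res$female_mean_deviation
  expect_gt(res$effect_pct, 0)
  expect_lt(abs(res$effect_pct - expected), 2 * se_pct + 2)
  expect_lt(res$p_value, 0.001)
})
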