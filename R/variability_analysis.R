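# Group-level variability analyses: Levene transforms and their linear
# models, coefficients of variation by group, genotype p-value
# enrichment, measure-measure correlations, and paired treatment/control
# effect sizes.

resolve_groups <- function(groups, n) {
  if (is.data.frame(groups) || (is.list(groups) && !is.factor(groups))) {
    g <- interaction(groups, drop = TRUE, sep = ":")
  } else {
    g <- factor(groups)
  }
  if (length(g) != n) {
    stop("'groups' must match the length of 'values'", call. = FALSE)
  }
  g
}

#' Levene transform: absolute deviation from the group mean
#'
#' Replaces each observation by \eqn{d_{ij} = |y_{ij} - \bar y_j|} with
#' \eqn{\bar y_j} the mean of its group, so that ordinary linear models on
#' the transformed data model variance heterogeneity. The mean (not the
#' median) is used, the classical Levene form, appropriate for
#' near-symmetric measures such as turn bias. Groups with fewer than two
#' non-missing observations are excluded (their deviations set missing)
#' with a warning.
#'
#' @param values Numeric vector.
#' @param groups Grouping labels: a vector, or a data frame / list of
#'   vectors that are crossed (e.g. genotype and condition).
#' @return Numeric vector of deviations, aligned with `values`.
#' @export
#' @examples
#' levene_transform(c(1, 3), c("a", "a")) # both 1
levene_transform <- function(values, groups) {
  values <- as.numeric(values)
  g <- resolve_groups(groups, length(values))
  ok <- !is.na(values) & !is.na(g)
  sizes <- table(g[ok])
  singletons <- names(sizes)[sizes < 2]
  d <- rep(NA_real_, length(values))
  use <- ok & !(as.character(g) %in% singletons)
  if (any(use)) {
    gm <- stats::ave(values[use], droplevels(g[use]), FUN = mean)
    d[use] <- abs(values[use] - gm)
  }
  if (length(singletons)) {
    warning(
      length(singletons),
      " singleton group(s) excluded from Levene transform",
      call. = FALSE
    )
  }
  d
}

#' Levene variance-homogeneity test via OLS on transformed data
#'
#' Runs the one-way ANOVA F-test of the Levene deviations on the group
#' factor; with mean centering this reproduces the classical Levene test.
#'
#' @inheritParams levene_transform
#' @return List with `statistic` (F), `df`, `df_residual`, `p_value`.
#' @export
levene_test <- function(values, groups) {
  values <- as.numeric(values)
  g <- resolve_groups(groups, length(values))
  d <- suppressWarnings(levene_transform(values, g))
  keep <- !is.na(d) & !is.na(g)
  fit <- lm(d[keep] ~ droplevels(g[keep]))
  a <- anova(fit)
  list(
    statistic = a[1, "F value"],
    df = a[1, "Df"],
    df_residual = a[2, "Df"],
    p_value = a[1, "Pr(>F)"]
  )
}

#' Coefficient of variation per group
#'
#' The group-wise variability measure: sample SD divided by sample mean.
#' Groups below the size threshold are dropped; groups whose mean is not
#' positive get a missing CV with a warning (the ratio is not
#' interpretable there).
#'
#' @inheritParams levene_transform
#' @param min_n Minimum non-missing group size (default 2).
#' @return Tibble with columns `group`, `n`, `mean`, `sd`, `cv`.
#' @export
#' @examples
#' group_cv(c(0.4, 0.5, 0.6), rep("g1", 3)) # cv = 0.2
group_cv <- function(values, groups, min_n = 2) {
  values <- as.numeric(values)
  g <- resolve_groups(groups, length(values))
  out <- tibble(group = as.character(g), value = values) |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= min_n) |>
    dplyr::mutate(cv = ifelse(.data$mean > 0, .data$sd / .data$mean,
      NA_real_))
  if (any(is.na(out$cv))) {
    warning(sum(is.na(out$cv)),
      " group(s) with non-positive mean: cv undefined", call. = FALSE)
  }
  out
}

#' Ordinary least squares on measure ~ metadata predictors
#'
#' Fits an OLS model of a numeric response on metadata columns, with
#' treatment (reference-level) coding for categorical predictors, and
#' reports coefficients, standard errors and two-sided t p-values. A
#' rank-deficient design is an error naming the aliased terms, mirroring
#' the fact that including the experiment date makes the released data
#' set's model unidentifiable.
#'
#' @param table A `cohort_table` or data frame.
#' @param response Name of the numeric response column.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `"metadata_model"`: list with `response`,
#'   `predictors`, `coefficients` (tibble: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`), `intercept`, `n`,
#'   `df_residual`, `fit` (the `lm` object).
#' @export
fit_metadata_model <- function(table, response, predictors) {
  missing_cols <- setdiff(c(response, predictors), names(table))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE)
  }
  dat <- tibble::as_tibble(as.data.frame(table))[, c(response, predictors)]
  for (p in predictors) {
    if (is.character(dat[[p]])) dat[[p]] <- factor(dat[[p]])
    if (is.factor(dat[[p]]) && nlevels(droplevels(dat[[p]])) < 2) {
      stop("predictor '", p, "' has fewer than 2 observed levels",
        call. = FALSE)
    }
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- lm(fml, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    aliased <- names(cf)[is.na(cf)]
    asgn <- fit$assign[is.na(cf)]
    labels <- attr(stats::terms(fit), "term.labels")
    cols <- unique(labels[asgn[asgn > 0]])
    stop(
      "rank-deficient design; aliased column(s): ",
      paste(cols, collapse = ", "),
      " (coefficients: ", paste(aliased, collapse = ", "), ")",
      call. = FALSE
    )
  }
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = sm[, "Pr(>|t|)"]
  )
  structure(
    list(
      response = response,
      predictors = predictors,
      coefficients = coefs,
      intercept = unname(cf["(Intercept)"]),
      n = length(fit$residuals),
      df_residual = fit$df.residual,
      fit = fit
    ),
    class = "metadata_model"
  )
}

#' @export
print.metadata_model <- function(x, ...) {
  cat(sprintf(
    "OLS model: %s ~ %s  (n = %d, %d coefficients, intercept = %.4g)\n",
    x$response, paste(x$predictors, collapse = " + "), x$n,
    nrow(x$coefficients), x$intercept
  ))
  invisible(x)
}

#' Per-genotype p-values for a measure
#'
#' One indicator-coded OLS per genotype: does genotype *g* differ from all
#' other flies in the mean of the measure? Implemented as the equivalent
#' pooled-variance two-sample t-test, vectorized over genotypes. Feeds
#' [genotype_enrichment()].
#'
#' @param values Numeric measure per fly.
#' @param genotypes Genotype label per fly.
#' @param min_n Minimum flies per genotype to test (default 2).
#' @return Tibble: `genotype`, `n`, `estimate` (group mean minus rest
#'   mean), `statistic`, `p_value`.
#' @export
genotype_pvalues <- function(values, genotypes, min_n = 2) {
  values <- as.numeric(values)
  keep <- !is.na(values) & !is.na(genotypes)
  x <- values[keep]
  g <- factor(genotypes[keep])
  N <- length(x)
  tot_sum <- sum(x)
  tot_sq <- sum(x^2)
  n_g <- tapply(x, g, length)
  sum_g <- tapply(x, g, sum)
  sq_g <- tapply(x, g, function(v) sum(v^2))
  n_r <- N - n_g
  mean_g <- sum_g / n_g
  mean_r <- (tot_sum - sum_g) / n_r
  ssd_g <- sq_g - n_g * mean_g^2
  ssd_r <- (tot_sq - sq_g) - n_r * mean_r^2
  s2 <- (ssd_g + ssd_r) / (N - 2)
  tstat <- (mean_g - mean_r) / sqrt(s2 * (1 / n_g + 1 / n_r))
  p <- 2 * pt(-abs(tstat), df = N - 2)
  bad <- n_g < min_n | n_r < min_n | !is.finite(tstat)
  tstat[bad] <- NA_real_
  p[bad] <- NA_real_
  tibble(
    genotype = names(n_g),
    n = as.integer(n_g),
    estimate = as.numeric(mean_g - mean_r),
    statistic = as.numeric(tstat),
    p_value = as.numeric(p)
  )
}

#' Enrichment of small p-values over the uniform null
#'
#' Binomial test of the observed count of p-values below `alpha` against
#' the `alpha * N` expected under the null (one-sided, enrichment). This
#' is the check behind the observation that far more genotypes than
#' expected by chance have significant effects on mean turn bias.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @param alpha Significance threshold (default 0.05).
#' @return List: `n`, `alpha`, `n_significant`, `expected`, `p_value`.
#' @export
#' @examples
#' genotype_enrichment(c(rep(0.001, 47), runif(522, 0.05, 1)))
genotype_enrichment <- function(p_values, alpha = 0.05) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) stop("no p-values supplied", call. = FALSE)
  if (any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  count <- sum(p < alpha)
  bt <- binom.test(count, length(p), p = alpha, alternative = "greater")
  list(
    n = length(p),
    alpha = alpha,
    n_significant = count,
    expected = alpha * length(p),
    p_value = bt$p.value
  )
}

#' Pearson correlation between two measures
#'
#' Product-moment correlation with the t-distribution two-sided p-value,
#' on pairwise-complete observations.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List: `r`, `p_value`, `n`.
#' @export
measure_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Turn bias magnitude
#'
#' The folded, direction-free strength of bias: `|p - 0.5|`.
#'
#' @param p Turn bias values in \[0, 1\] (missing allowed).
#' @return Values in \[0, 0.5\].
#' @export
absolute_bias <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("turn bias must lie in [0, 1]", call. = FALSE)
  }
  abs(p - 0.5)
}

#' Merge behavioral-testing temperatures into analysis groups
#'
#' Collapses 22 with 23 and 32 with 33 degrees C into single groups, the
#' convention used for the temperature-variability contrast; other
#' temperatures are passed through unchanged.
#'
#' @param temp Numeric temperatures (degrees C).
#' @return Character group labels ("23", "33", or the input value).
#' @export
temperature_group <- function(temp) {
  out <- as.character(temp)
  out[temp %in% c(22, 23)] <- "23"
  out[temp %in% c(32, 33)] <- "33"
  out
}

#' Paired treatment/control effect on group variability
#'
#' For each pairing unit (genotype by default) present in both conditions,
#' computes the coefficient of variation of the measure in each condition;
#' the effect size is the mean over units of the relative CV change from
#' control to treatment (in percent), matching a per-unit pairing-line
#' reading, and significance is a two-sided paired t-test on the CV pairs.
#' Pooled-change aggregation is available as an option.
#'
#' @param table A `cohort_table` or data frame with the measure, condition
#'   and pairing columns.
#' @param measure Name of the numeric measure column.
#' @param control,treatment Condition labels to contrast.
#' @param pair_by Pairing column (default `"genotype"`).
#' @param cond_col Condition column (default `"expCond"`; pass a derived
#'   column such as a temperature group for other contrasts).
#' @param min_n Minimum flies per unit-condition cell (default 2).
#' @param aggregate `"mean_relative"` (default) averages per-unit relative
#'   changes; `"pooled"` contrasts the means of the per-unit CVs.
#' @return An object of class `"effect_size"`: list with `measure`,
#'   `control`, `treatment`, `pair_by`, `pairs` (tibble of per-unit CVs),
#'   `effect_pct`, `t_statistic`, `df`, `p_value`.
#' @export
paired_effect <- function(table, measure, control, treatment,
                          pair_by = "genotype", cond_col = "expCond",
                          min_n = 2,
                          aggregate = c("mean_relative", "pooled")) {
  aggregate <- match.arg(aggregate)
  dat <- tibble::as_tibble(as.data.frame(table))
  missing_cols <- setdiff(c(measure, pair_by, cond_col), names(dat))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE)
  }
  cv_in <- function(cond) {
    sub <- dat[!is.na(dat[[cond_col]]) & dat[[cond_col]] == cond, ]
    group_cv(sub[[measure]], sub[[pair_by]], min_n = min_n)
  }
  cv_c <- cv_in(control)
  cv_t <- cv_in(treatment)
  pairs <- dplyr::inner_join(
    cv_c, cv_t,
    by = "group", suffix = c("_control", "_treatment")
  ) |>
    dplyr::filter(
      is.finite(.data$cv_control), is.finite(.data$cv_treatment),
      .data$cv_control > 0
    ) |>
    dplyr::mutate(
      rel_change = (.data$cv_treatment - .data$cv_control) /
        .data$cv_control
    )
  if (nrow(pairs) < 2) {
    stop(
      "pairing error: fewer than 2 ", pair_by,
      " units present in both conditions", call. = FALSE
    )
  }
  effect_pct <- switch(aggregate,
    mean_relative = 100 * mean(pairs$rel_change),
    pooled = 100 * (mean(pairs$cv_treatment) - mean(pairs$cv_control)) /
      mean(pairs$cv_control)
  )
  diffs <- pairs$cv_treatment - pairs$cv_control
  if (sd(diffs) == 0) {
    # Degenerate paired t: identical conditions give a flat zero
    # difference; a constant nonzero difference is infinitely significant.
    tt <- list(
      statistic = if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf,
      parameter = nrow(pairs) - 1,
      p.value = if (mean(diffs) == 0) 1 else 0
    )
  } else {
    raw <- t.test(pairs$cv_treatment, pairs$cv_control, paired = TRUE)
    tt <- list(
      statistic = unname(raw$statistic),
      parameter = unname(raw$parameter),
      p.value = raw$p.value
    )
  }
  structure(
    list(
      measure = measure,
      control = control,
      treatment = treatment,
      pair_by = pair_by,
      pairs = pairs,
      effect_pct = effect_pct,
      t_statistic = tt$statistic,
      df = tt$parameter,
      p_value = tt$p.value
    ),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf(
    "%s variability, %s -> %s: %+.1f%% (paired t = %.3g, df = %d, p = %.3g; %d %s pairs)\n",
    x$measure, x$control, x$treatment, x$effect_pct, x$t_statistic,
    x$df, x$p_value, nrow(x$pairs), x$pair_by
  ))
  invisible(x)
}

#' Sex effect on variability via a Levene-transformed linear model
#'
#' Levene-transforms the measure within genotype x condition x sex cells
#' (so deviations quantify within-cell spread), fits
#' `deviation ~ genotype + sex` by OLS, and expresses the male coefficient
#' as a percent of the mean female deviation — the percent excess (or
#' deficit) of spread in males. Flies recorded with mixed sex are
#' excluded.
#'
#' @param table A `cohort_table` or data frame.
#' @param measure Numeric measure column name.
#' @param condition_col Condition column used in the Levene grouping
#'   (default `"expCond"`).
#' @return List: `measure`, `model` (the `"metadata_model"`),
#'   `male_coefficient`, `se`, `p_value`, `effect_pct`,
#'   `female_mean_deviation`, `n`.
#' @export
sex_variability_effect <- function(table, measure,
                                   condition_col = "expCond") {
  dat <- tibble::as_tibble(as.data.frame(table))
  dat <- dat[dat$sex %in% c("male", "female"), ]
  if (length(unique(dat$sex)) < 2) {
    stop("both sexes must be present", call. = FALSE)
  }
  dat$.lev <- suppressWarnings(levene_transform(
    dat[[measure]],
    list(dat$genotype, dat[[condition_col]], dat$sex)
  ))
  dat$sex <- factor(dat$sex, levels = c("female", "male"))
  model <- fit_metadata_model(
    dat[!is.na(dat$.lev), ],
    response = ".lev",
    predictors = c("genotype", "sex")
  )
  row <- model$coefficients[model$coefficients$term == "sexmale", ]
  fem <- mean(dat$.lev[dat$sex == "female"], na.rm = TRUE)
  list(
    measure = measure,
    model = model,
    male_coefficient = row$estimate,
    se = row$std_error,
    p_value = row$p_value,
    effect_pct = 100 * row$estimate / fem,
    female_mean_deviation = fem,
    n = model$n
  )
}
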