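# Study-level orchestration: descriptive distribution reports, the
# turn-bias asymmetry analysis, and the variability analyses, each as a
# reproducible report embedding its resolved configuration and seed.

measure_columns <- c("handedness", "numTurns", "switchiness")

as_cohort_data <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  tibble::as_tibble(as.data.frame(cohort))
}

report_skeleton <- function(analysis, config, n_flies) {
  list(
    analysis = analysis,
    package = "ymi",
    version = as.character(utils::packageVersion("ymi")),
    config = config,
    n_flies = n_flies
  )
}

#' Descriptive distribution report for each behavioral measure
#'
#' For each requested measure: kernel density estimate, Gaussian best
#' fit, bootstrap moment panel up to `max_order`, and a subsample
#' stability curve. Missing values are excluded per measure with
#' exclusion counts recorded.
#'
#' @param cohort A `cohort_table` (or a [generate_cohort()] result).
#' @param measures Measure columns to describe.
#' @param max_order Highest moment order (default 20).
#' @param B Bootstrap replicates (default 1000).
#' @param fractions Subsample fractions for the stability curve.
#' @param seed Integer seed; each measure gets a deterministic sub-seed.
#' @param kde_band_B Replicates for the KDE confidence band (0 = none).
#' @return A report list of class `"ymi_report"`, JSON-serializable via
#'   [write_report()].
#' @export
run_descriptive <- function(cohort, measures = measure_columns,
                            max_order = 20, B = 1000,
                            fractions = c(1, 0.1), seed = 1,
                            kde_band_B = 0) {
  dat <- as_cohort_data(cohort)
  missing_cols <- setdiff(measures, names(dat))
  if (length(missing_cols)) {
    stop("missing measure column(s): ",
      paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  config <- list(
    measures = measures, max_order = max_order, B = B,
    fractions = fractions, seed = seed, kde_band_B = kde_band_B
  )
  report <- report_skeleton("descriptive", config, nrow(dat))
  report$measures <- list()
  for (i in seq_along(measures)) {
    m <- measures[i]
    x <- finite_values(dat[[m]])
    sub_seed <- seed + i
    dens <- kde(x, B = kde_band_B, seed = sub_seed)
    report$measures[[m]] <- list(
      n_used = length(x),
      n_excluded = attr(x, "n_excluded"),
      gaussian_fit = gaussian_fit(x),
      kde = list(
        grid = dens$grid, density = dens$density,
        bandwidth = dens$bandwidth,
        ci_low = dens$ci_low, ci_high = dens$ci_high
      ),
      moments = moment_panel(x, max_order = max_order, B = B,
        seed = sub_seed),
      stability = stability_curve(x, max_order = max_order,
        fractions = fractions, B = B, seed = sub_seed)
    )
  }
  structure(report, class = "ymi_report")
}

#' Turn-bias asymmetry report
#'
#' The grand mean turn bias with its bootstrap confidence interval, an
#' OLS model of turn bias on the metadata predictors (all informative
#' metadata columns except the date, which would make the design rank
#' deficient), and the genotype p-value enrichment analysis.
#'
#' @inheritParams run_descriptive
#' @param predictors Metadata columns for the linear model; `NULL`
#'   selects every categorical/numeric metadata column (except `date`
#'   and the `lev_*` columns) with at least two observed levels.
#' @param alpha Enrichment significance threshold (default 0.05).
#' @return A report list of class `"ymi_report"` with `grand_mean`,
#'   `metadata_model`, `genotype_pvalues`, `enrichment`.
#' @export
run_asymmetry <- function(cohort, B = 1000, seed = 1, predictors = NULL,
                          alpha = 0.05) {
  dat <- as_cohort_data(cohort)
  if (!"genotype" %in% names(dat)) {
    stop("cohort must carry a genotype column", call. = FALSE)
  }
  x <- finite_values(dat$handedness)
  grand <- bootstrap_statistic(x, mean, B = B, seed = seed)

  if (is.null(predictors)) {
    candidates <- c(
      "genotype", "expCond", "expTemp", "age", "experimenterID",
      "trayID", "boxID", "arrayFormat", "mazeNum", "acquisition",
      "analysis", "sex", "eyeColor"
    )
    # Informative columns only: at least two observed levels, and for
    # categoricals not so many levels that the design degenerates.
    predictors <- Filter(function(cl) {
      if (!cl %in% names(dat)) return(FALSE)
      v <- dat[[cl]][!is.na(dat[[cl]])]
      k <- length(unique(v))
      k >= 2 && (is.numeric(v) || k <= length(v) / 2)
    }, candidates)
  }
  model <- if (length(predictors)) {
    fit_metadata_model(dat, "handedness", predictors)
  }

  gp <- genotype_pvalues(dat$handedness, dat$genotype)
  pv <- gp$p_value[!is.na(gp$p_value)]
  if (length(unique(dat$genotype[!is.na(dat$genotype)])) < 2 ||
      length(pv) < 2) {
    stop("enrichment needs at least 2 genotypes", call. = FALSE)
  }
  enrich <- genotype_enrichment(pv, alpha = alpha)

  config <- list(B = B, seed = seed, predictors = predictors,
    alpha = alpha)
  report <- report_skeleton("turn-bias-asymmetry", config, nrow(dat))
  report$grand_mean <- list(
    estimate = grand$estimate,
    ci_low = grand$ci_low,
    ci_high = grand$ci_high,
    boot_sd = grand$boot_sd,
    B = grand$B,
    n = grand$n
  )
  report$metadata_model <- if (!is.null(model)) {
    list(
      intercept = model$intercept,
      n = model$n,
      n_coefficients = nrow(model$coefficients),
      coefficients = model$coefficients
    )
  }
  report$genotype_pvalues <- gp
  report$enrichment <- enrich
  structure(report, class = "ymi_report")
}

#' Variability report: CVs, sex models and paired effects
#'
#' Genotype-wise coefficients of variation for each measure; the
#' Levene-model sex effect (when both sexes are present); paired
#' control/treatment effect sizes for each named condition pair; and the
#' low/high temperature contrast (22/23 vs 32/33 degrees C merged) when
#' both temperature groups occur.
#'
#' @inheritParams run_descriptive
#' @param condition_pairs List of `c(control, treatment)` label pairs in
#'   `expCond` to contrast.
#' @param temperature_pair Two temperature-group labels to contrast (see
#'   [temperature_group()]), or `NULL` to skip.
#' @param pair_by Pairing column for effects (default `"genotype"`).
#' @param min_n Minimum flies per group cell.
#' @return A report list of class `"ymi_report"` with `group_cv`,
#'   `sex_effects`, `paired_effects`, `temperature_effects`.
#' @export
run_variability <- function(cohort, measures = measure_columns,
                            condition_pairs = list(),
                            temperature_pair = c("23", "33"),
                            pair_by = "genotype", min_n = 2, seed = 1) {
  dat <- as_cohort_data(cohort)
  config <- list(
    measures = measures, condition_pairs = condition_pairs,
    temperature_pair = temperature_pair, pair_by = pair_by,
    min_n = min_n, seed = seed
  )
  report <- report_skeleton("variability", config, nrow(dat))

  report$group_cv <- lapply(stats::setNames(measures, measures),
    function(m) group_cv(dat[[m]], dat$genotype, min_n = min_n))

  both_sexes <- all(c("male", "female") %in% dat$sex)
  report$sex_effects <- if (both_sexes) {
    lapply(stats::setNames(measures, measures), function(m) {
      res <- sex_variability_effect(dat, m)
      res$model <- NULL # keep the report JSON-sized
      res
    })
  }

  effect_entry <- function(eff) {
    list(
      measure = eff$measure, control = eff$control,
      treatment = eff$treatment, n_pairs = nrow(eff$pairs),
      effect_pct = eff$effect_pct, t_statistic = eff$t_statistic,
      df = eff$df, p_value = eff$p_value, pairs = eff$pairs
    )
  }
  report$paired_effects <- list()
  for (pair in condition_pairs) {
    for (m in measures) {
      key <- paste(m, pair[1], pair[2], sep = "|")
      report$paired_effects[[key]] <- effect_entry(paired_effect(
        dat, m, control = pair[1], treatment = pair[2],
        pair_by = pair_by, min_n = min_n
      ))
    }
  }

  report$temperature_effects <- NULL
  if (!is.null(temperature_pair)) {
    dat$tempGroup <- temperature_group(dat$expTemp)
    if (all(temperature_pair %in% dat$tempGroup)) {
      report$temperature_effects <- lapply(
        stats::setNames(measures, measures),
        function(m) effect_entry(paired_effect(
          dat, m, control = temperature_pair[1],
          treatment = temperature_pair[2], pair_by = pair_by,
          cond_col = "tempGroup", min_n = min_n
        ))
      )
    }
  }
  structure(report, class = "ymi_report")
}

#' @export
print.ymi_report <- function(x, ...) {
  cat(sprintf("ymi %s report: %d flies (seed %s)\n", x$analysis,
    x$n_flies, format(x$config$seed)))
  invisible(x)
}

#' Write a report as JSON
#'
#' Serializes a report (including its resolved configuration and seed,
#' from which it is reproducible) to pretty-printed JSON.
#'
#' @param report A `"ymi_report"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    unclass(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE,
    dataframe = "columns", null = "null"
  )
  invisible(path)
}
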