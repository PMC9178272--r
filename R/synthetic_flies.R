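# Synthetic cohort generator: per-fly latent parameters (bias, serial
# dependence, activity) drawn from a population specification, turn
# sequences simulated from a two-state Markov chain, and Table-style
# metadata assembled so every analysis stage is testable without the
# released data set.

beta_shapes <- function(mean, sd) {
  if (any(mean <= 0 | mean >= 1)) {
    stop("bias mean must lie in (0, 1)", call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  if (any(nu <= 0)) {
    stop("bias sd too large for a Beta distribution at this mean",
      call. = FALSE)
  }
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

nb_size <- function(mean, cv) {
  # Negative-binomial size parameter giving the requested count CV:
  # var = mean + mean^2/size = (cv * mean)^2.
  excess <- cv^2 * mean - 1
  if (any(excess <= 0)) {
    stop(
      "turns_cv must exceed sqrt(1/turns_mean): negative-binomial ",
      "counts cannot be underdispersed relative to Poisson",
      call. = FALSE
    )
  }
  mean / excess
}

#' Specify a synthetic fly population
#'
#' Builds the generative parameters for a synthetic cohort. The design is
#' the full crossing of genotypes, experimental conditions, sexes and
#' temperatures, each cell holding `n_per_group` flies. Per fly, the
#' latent turn bias is Beta-distributed (mean/SD parameterization), the
#' target switchiness is normal (mapped to the Markov chain's serial
#' correlation as rho = 1 - S), and the turn count is negative binomial
#' (mean/CV parameterization, right-skewed and overdispersed).
#'
#' Defaults are the grand-cohort conditions: bias mean 0.496 with SD 0.15,
#' switchiness centred at 1, and a mean of 435 turns per fly (the grand
#' ratio of choices to flies) with count CV 0.45.
#'
#' For group-level manipulations, either pass vectors (recycled over the
#' design) or edit the returned `$design` tibble directly — e.g. multiply
#' `bias_sd` in one genotype, or shrink `turns_cv` in a treatment arm.
#'
#' @param genotypes,conditions,sexes,temps Factor levels crossed into the
#'   group design.
#' @param n_per_group Flies per design cell.
#' @param bias_mean,bias_sd Mean and SD of the Beta bias distribution
#'   (per cell, recycled).
#' @param switch_mean,switch_sd Mean and SD of the per-fly target
#'   switchiness (truncated at sampling time to the representable range
#'   for each fly's bias).
#' @param turns_mean,turns_cv Mean and coefficient of variation of the
#'   negative-binomial turn count. `turns_cv` must exceed
#'   `sqrt(1/turns_mean)`.
#' @param bias_mixture Optional heavy-mode/heavy-tail bias shape: a list
#'   with numeric `weights`, `means`, `sds` describing a Beta mixture that
#'   overrides `bias_mean`/`bias_sd` in every cell.
#' @param seed Default seed carried by the spec (can be overridden at
#'   sampling time).
#' @return An object of class `"population_spec"`: list with `design`
#'   (one row per cell), `bias_mixture`, `seed`.
#' @export
#' @examples
#' spec <- population_spec(genotypes = c("dgrp1", "dgrp2"), n_per_group = 50)
#' spec$design
population_spec <- function(genotypes = "line1",
                            conditions = "normal",
                            sexes = "female",
                            temps = 23,
                            n_per_group = 100,
                            bias_mean = 0.496,
                            bias_sd = 0.15,
                            switch_mean = 1,
                            switch_sd = 0.1,
                            turns_mean = 435,
                            turns_cv = 0.45,
                            bias_mixture = NULL,
                            seed = NULL) {
  design <- tibble::as_tibble(expand.grid(
    genotype = as.character(genotypes),
    expCond = as.character(conditions),
    sex = as.character(sexes),
    expTemp = as.numeric(temps),
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  ))
  design$n_flies <- as.integer(rep_len(n_per_group, nrow(design)))
  design$bias_mean <- rep_len(bias_mean, nrow(design))
  design$bias_sd <- rep_len(bias_sd, nrow(design))
  design$switch_mean <- rep_len(switch_mean, nrow(design))
  design$switch_sd <- rep_len(switch_sd, nrow(design))
  design$turns_mean <- rep_len(turns_mean, nrow(design))
  design$turns_cv <- rep_len(turns_cv, nrow(design))
  spec <- structure(
    list(design = design, bias_mixture = bias_mixture, seed = seed),
    class = "population_spec"
  )
  validate_population_spec(spec)
  spec
}

validate_population_spec <- function(spec) {
  d <- spec$design
  if (nrow(d) == 0) stop("empty design", call. = FALSE)
  stopifnot(all(d$n_flies >= 0))
  beta_shapes(d$bias_mean, d$bias_sd)
  if (any(d$switch_mean <= 0)) {
    stop("switch_mean must be positive", call. = FALSE)
  }
  nb_size(d$turns_mean, d$turns_cv)
  mx <- spec$bias_mixture
  if (!is.null(mx)) {
    stopifnot(
      is.list(mx),
      all(c("weights", "means", "sds") %in% names(mx)),
      length(mx$weights) == length(mx$means),
      length(mx$means) == length(mx$sds),
      all(mx$weights > 0)
    )
    beta_shapes(mx$means, mx$sds)
  }
  invisible(spec)
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    "Population spec: %d group(s), %d flies total%s%s\n",
    nrow(x$design), sum(x$design$n_flies),
    if (!is.null(x$bias_mixture)) ", Beta-mixture bias" else "",
    if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""
  ))
  invisible(x)
}

# Lower bound of the serial correlation representable at bias p: below it
# a transition probability would leave [0, 1].
rho_lower <- function(p) {
  -pmin(p, 1 - p) / pmax(p, 1 - p)
}

.sample_population <- function(spec) {
  d <- spec$design
  rows <- rep(seq_len(nrow(d)), d$n_flies)
  N <- length(rows)
  if (N == 0) stop("empty design", call. = FALSE)

  if (is.null(spec$bias_mixture)) {
    sh <- beta_shapes(d$bias_mean[rows], d$bias_sd[rows])
    p <- rbeta(N, sh$alpha, sh$beta)
  } else {
    mx <- spec$bias_mixture
    comp <- sample.int(length(mx$weights), N, replace = TRUE,
      prob = mx$weights)
    sh <- beta_shapes(mx$means[comp], mx$sds[comp])
    p <- rbeta(N, sh$alpha, sh$beta)
  }
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)

  s_target <- rnorm(N, d$switch_mean[rows], d$switch_sd[rows])
  rho_raw <- 1 - s_target
  lo <- rho_lower(p)
  rho <- pmin(pmax(rho_raw, lo + 1e-9), 1 - 1e-9)
  n_clipped <- sum(rho != rho_raw)

  size <- nb_size(d$turns_mean[rows], d$turns_cv[rows])
  n_turns <- rnbinom(N, mu = d$turns_mean[rows], size = size)

  out <- tibble(
    flyID = seq_len(N),
    genotype = d$genotype[rows],
    expCond = d$expCond[rows],
    sex = d$sex[rows],
    expTemp = d$expTemp[rows],
    p_true = p,
    rho_true = rho,
    n_true = as.integer(n_turns)
  )
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Draw per-fly latent parameters from a population spec
#'
#' Samples each fly's true bias, serial correlation and turn count
#' independently according to the spec. The serial correlation is
#' `1 - S_target`, clipped to the range representable at the fly's bias;
#' the number of clipped flies is reported in the `n_clipped` attribute.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed (defaults to the spec's own).
#' @return A tibble of fly-level ground truth: `flyID`, group labels,
#'   `p_true`, `rho_true`, `n_true`.
#' @export
sample_population <- function(spec, seed = spec$seed) {
  validate_population_spec(spec)
  maybe_with_seed(seed, .sample_population(spec))
}

# Vectorized two-state Markov simulation. Flies advance in lock-step;
# fly i stops contributing after its n[i]-th turn.
.simulate_turns_multi <- function(p, rho, n) {
  N <- length(p)
  stopifnot(length(rho) == N, length(n) == N, all(n >= 0))
  pRR <- p + rho * (1 - p)
  pRL <- p * (1 - rho)
  eps <- 1e-12
  if (any(pRR < -eps | pRR > 1 + eps | pRL < -eps | pRL > 1 + eps)) {
    stop("parameter error: transition probability outside [0, 1]",
      call. = FALSE)
  }
  pRR <- pmin(pmax(pRR, 0), 1)
  pRL <- pmin(pmax(pRL, 0), 1)
  maxn <- if (N) max(n) else 0L
  out <- vector("list", N)
  if (maxn == 0L) {
    out[] <- list(character(0))
    return(out)
  }
  M <- matrix(NA, nrow = N, ncol = maxn)
  first <- which(n >= 1L)
  M[first, 1] <- runif(length(first)) < p[first]
  if (maxn >= 2L) {
    for (t in 2:maxn) {
      act <- which(n >= t)
      if (!length(act)) break
      prev <- M[act, t - 1]
      pr <- ifelse(prev, pRR[act], pRL[act])
      M[act, t] <- runif(length(act)) < pr
    }
  }
  lab <- c("L", "R")
  for (i in seq_len(N)) {
    out[[i]] <- if (n[i] == 0L) character(0) else
      lab[M[i, seq_len(n[i])] + 1L]
  }
  out
}

#' Simulate turn sequences from the two-state Markov model
#'
#' Each fly's choices follow a first-order Markov chain with stationary
#' right-turn probability `p` and serial correlation `rho`: the first turn
#' is Bernoulli(`p`), and thereafter
#' \deqn{P(R|R) = p + \rho (1 - p), \qquad P(R|L) = p (1 - \rho).}
#' The stationary marginal is `p`, the expected alternation rate is
#' \eqn{2 p (1 - p)(1 - \rho)}, and hence the expected switchiness of a
#' long sequence is approximately \eqn{1 - \rho} — the model decouples
#' bias from switchiness. `rho = 0` gives i.i.d. choices.
#'
#' @param p Stationary right-turn probability per fly, in (0, 1).
#' @param rho Serial correlation per fly, within
#'   `(-min(p, 1-p)/max(p, 1-p), 1)`.
#' @param n Sequence length per fly (0 allowed).
#' @param seed Optional integer seed.
#' @return `simulate_turn_sequences()`: a list of character `L`/`R`
#'   vectors, one per fly. `simulate_turn_sequence()`: a single vector.
#' @export
simulate_turn_sequences <- function(p, rho, n, seed = NULL) {
  len <- max(length(p), length(rho), length(n))
  p <- rep_len(as.numeric(p), len)
  rho <- rep_len(as.numeric(rho), len)
  n <- rep_len(as.integer(n), len)
  maybe_with_seed(seed, .simulate_turns_multi(p, rho, n))
}

#' @rdname simulate_turn_sequences
#' @export
simulate_turn_sequence <- function(p, rho = 0, n, seed = NULL) {
  stopifnot(length(p) == 1, length(rho) == 1, length(n) == 1)
  simulate_turn_sequences(p, rho, n, seed = seed)[[1]]
}

#' Generate a full synthetic cohort
#'
#' End-to-end generation: latent parameters via [sample_population()],
#' raw sequences via the Markov simulator, measures computed from those
#' sequences with [compute_measures()] (never copied from the latent
#' truth), Levene columns derived by genotype x condition, and metadata
#' filled in to the released-table schema.
#'
#' @inheritParams sample_population
#' @param age Reported age (days) written into the metadata.
#' @param experimenter Experimenter label written into the metadata.
#' @return An object of class `"synthetic_cohort"`: list with
#'   `sequences` (named by flyID), `cohort` (a `cohort_table`), `truth`
#'   (the latent-parameter tibble).
#' @export
#' @examples
#' coh <- generate_cohort(population_spec(n_per_group = 10, turns_mean = 30,
#'   turns_cv = 0.5, seed = 1))
#' coh$cohort[, c("flyID", "handedness", "numTurns", "switchiness")]
generate_cohort <- function(spec, seed = spec$seed, age = 6,
                            experimenter = "sim01") {
  validate_population_spec(spec)
  res <- maybe_with_seed(seed, {
    truth <- .sample_population(spec)
    seqs <- .simulate_turns_multi(truth$p_true, truth$rho_true,
      truth$n_true)
    # Random maze assignment, as in a real tray loading.
    maze <- sample.int(120L, nrow(truth), replace = TRUE)
    list(truth = truth, seqs = seqs, maze = maze)
  })
  truth <- res$truth
  seqs <- res$seqs
  names(seqs) <- as.character(truth$flyID)
  meas <- compute_measures(seqs)
  grp <- list(truth$genotype, truth$expCond)
  records <- tibble(
    flyID = truth$flyID,
    handedness = meas$turn_bias,
    numTurns = as.numeric(meas$num_turns),
    switchiness = meas$switchiness,
    lev_handedness = suppressWarnings(
      levene_transform(meas$turn_bias, grp)),
    lev_numTurns = suppressWarnings(
      levene_transform(meas$num_turns, grp)),
    lev_switchiness = suppressWarnings(
      levene_transform(meas$switchiness, grp)),
    genotype = truth$genotype,
    expCond = truth$expCond,
    expTemp = truth$expTemp,
    age = as.numeric(age),
    experimenterID = experimenter,
    trayID = "T1",
    boxID = "B1",
    date = NA_character_,
    arrayFormat = "120",
    mazeNum = as.character(res$maze),
    acquisition = "synthetic",
    analysis = paste0("ymi-", as.character(utils::packageVersion("ymi"))),
    sex = truth$sex,
    eyeColor = NA_character_
  )
  cohort <- cohort_table(records, provenance = "synthetic cohort (ymi)")
  structure(
    list(sequences = seqs, cohort = cohort, truth = truth),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d flies, %d turns total, %d design group(s)\n",
    nrow(x$cohort), sum(x$truth$n_true),
    nrow(unique(x$truth[, c("genotype", "expCond", "sex", "expTemp")]))
  ))
  invisible(x)
}
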