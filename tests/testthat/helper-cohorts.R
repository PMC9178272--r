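# Shared fixture builders. All fixtures are generated in code, seeded.

# A random L/R sequence of length n at right-turn probability p.
random_turns <- function(n, p = 0.5) {
  c("L", "R")[(runif(n) < p) + 1L]
}

# A small hand-built cohort data frame in the released schema.
toy_records <- function() {
  tibble::tibble(
    flyID = 1:5,
    handedness = c(0.5, 0.25, 1, 0, 0.6),
    numTurns = c(10, 4, 7, 3, 5),
    switchiness = c(1.2, 0.8, NA, NA, 1.0),
    genotype = c("wt", "wt", "dgrp101", "dgrp101", "wt"),
    expCond = "normal",
    expTemp = 23,
    sex = c("male", "male", "female", "female", "male")
  )
}

# Two-condition multi-genotype spec with an optional multiplicative
# change in the treatment arm's turn-count CV.
two_condition_spec <- function(n_genotypes = 20, n_per_group = 200,
                               turns_mean = 50, turns_cv = 0.5,
                               treatment_cv_factor = 1, seed = NULL) {
  spec <- population_spec(
    genotypes = sprintf("line%02d", seq_len(n_genotypes)),
    conditions = c("ctrl", "trt"),
    n_per_group = n_per_group,
    turns_mean = turns_mean,
    turns_cv = turns_cv,
    seed = seed
  )
  trt <- spec$design$expCond == "trt"
  spec$design$turns_cv[trt] <- spec$design$turns_cv[trt] *
    treatment_cv_factor
  spec
}
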