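Package: ymi
Title: Individual Behavioral Statistics and Variability Analysis for
    Y-Maze Choice Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying behavioral individuality from binary
    left/right choice sequences recorded in Y-maze assays. Computes the
    per-fly measures turn bias, number of turns and turn switchiness;
    characterizes their across-individual distributions with kernel
    density estimates, bootstrap confidence intervals, standardized
    moments to arbitrary order and subsample stability curves; and
    analyses variance heterogeneity across genotypes, treatments, sex
    and temperature via coefficients of variation, Levene-transformed
    linear models and paired effect sizes. A two-state Markov-chain
    synthetic cohort generator makes every analysis stage testable
    without the original data set, which can also be ingested from its
    released flat-table schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    arrow,
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
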