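---
title: "Quantifying behavioral individuality in Y-maze choice data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral individuality in Y-maze choice data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ymi)
```

## The problem

Individual animals of the same genotype, reared identically, still behave
differently from one another. In the Y-maze assay each freely walking fly
produces an ordered sequence of binary left/right choices, hundreds per
hour, which makes the assay unusually well suited to measuring such
*intragenotypic variability*: per-individual scores are precise, and
individuals are cheap to accumulate. `ymi` implements the analysis chain
for this kind of data: per-fly measures from raw sequences, precise
characterization of their across-fly distributions, and models of what
moves the *variance* (not just the mean) of behavior across genotypes,
drug treatments, sex and temperature. A synthetic-cohort generator with
known ground truth backs every stage.

## Per-fly measures

From a sequence of $n$ turns with $r$ rightward and $A$ adjacent
alternations:

* **Turn bias** $\hat p = r/n$. We use the plug-in estimate with no
  continuity correction: the lattice of values attainable at a given $n$
  is a real feature of the data (it produces the characteristic
  fractal-like structure in bias-magnitude versus turn-count scatter
  plots), and smoothing it away would misrepresent low-activity flies.
* **Number of turns** $n$, the activity measure.
* **Switchiness** $S = A / [(n-1)\, 2\hat p(1-\hat p)]$. The denominator
  is the expected alternation count for i.i.d. turns at the fly's own
  bias, so $S$ is a bias-normalized alternation index: 1 for a
  binomial-like fly, below 1 for streaky flies, above 1 for
  over-alternators. The exact historical normalizer (whether $n$ or
  $n-1$ multiplies the binomial rate, and whether the expectation is
  conditioned on the observed count) is not pinned down by the verbal
  definition in the literature; we adopt the $(n-1)$ form because the
  alternation count has exactly $n-1$ opportunities. Any correct variant
  must satisfy the same calibration property — Monte-Carlo mean of $S$
  equal to 1 for i.i.d. flies — which the test suite checks across the
  bias range, and at long sequences the variants differ only at
  $O(1/n)$.

$S$ is undefined when its normalizer vanishes ($n < 2$ or
$\hat p \in \{0, 1\}$). Such flies are *retained* with a missing value
rather than dropped: low-activity flies carry information for the other
two measures, and grand analyses simply skip missing entries (a
minimum-turn filter exists but defaults to off, i.e. grand analyses use
every fly). Turn-timing *clumpiness* is deliberately not computed; its
definition was not stable across historical data collection, and
timestamps are carried through IO but unused.

## Distribution characterization

For any measure across flies we provide:

* **Standardized moments.** Order 1 is the mean, order 2 the sample
  variance, and order $k \ge 3$ the standardized central moment
  $m_k / m_2^{k/2}$ with $m_j = \tfrac 1 n \sum(x_i - \bar x)^j$. With
  this (population-denominator) standardization the second standardized
  moment is exactly 1 and kurtosis is the non-excess convention with
  Gaussian value 3. The default panel goes to order 20.
* **Bootstrap intervals.** Resampling is fly-wise (the fly is the unit
  of analysis), with $B = 1000$ replicates by default, and the 95% CI is
  the point estimate $\pm$ twice the SD of replicate values — a
  normal-approximation interval that is cheap, symmetric, and accurate
  for the smooth statistics used here. A moment panel shares one
  resample stream across orders so that the panel is internally
  consistent. Replicates on which a statistic is undefined are dropped
  and counted. The ratio $|\mu_{boot}|/\sigma_{boot} \ge 2$ flags a
  moment as distinguishable from zero at roughly $p = 0.05$.
* **Subsample stability.** For fractions such as 1, 0.1, 0.01 a single
  seeded subset is drawn without replacement and the panel recomputed;
  a `repeats` argument allows dispersion studies. Which orders stay
  significant as data shrink depends on the underlying distribution —
  bounded distributions keep even their 10th–20th moments under 10-fold
  subsampling while heavy-tailed ones do not — and the test suite
  demonstrates exactly this contrast with Beta versus log-normal
  samples.
* **KDE and Gaussian fit.** Gaussian kernel with Silverman's
  rule-of-thumb bandwidth by default (exposed as a parameter), no
  boundary correction at 0/1 — bias densities are allowed to spill past
  the support edge, which slightly flattens the extreme bins but keeps
  the estimator simple and comparable across measures. An optional
  bootstrap band uses the same $\pm 2$ SD convention pointwise, with the
  bandwidth frozen at the full-sample value. The Gaussian fit is the ML
  pair (mean, $n$-denominator SD); comparing fitted and empirical
  density at the mode quantifies mode excess relative to normality.

## Variability analyses

* **Levene transform.** $d_{ij} = |y_{ij} - \bar y_j|$ with $\bar y_j$
  the *mean* of group $j$ (the classical form; bias-like measures are
  near-symmetric, so the robustness gain of median centering is not
  worth departing from the released tables' convention). OLS on $d$
  then models variance heterogeneity; a one-way F-test on $d$ is the
  classical Levene test, and the suite verifies agreement with an
  independent implementation to 6 decimals. The default grouping for
  the stored `lev_*` columns is genotype × condition, so models can add
  further predictors on top. Singleton groups are excluded with a
  warning.
* **Coefficient of variation** $\sigma/\mu$ per group, the
  mean-normalized variability measure (activity measures shift their
  means strongly with temperature, so raw SDs are not comparable). We
  use the standard $\sigma/\mu$ orientation. Groups with non-positive
  means get a flagged missing CV.
* **Paired effects.** For a control/treatment condition pair, each
  genotype present in both arms contributes a CV pair; the effect size
  is $100 \times$ the mean of per-genotype relative changes
  $(\mathrm{cv}_t - \mathrm{cv}_c)/\mathrm{cv}_c$ (matching a
  per-genotype pairing-line reading; pooled aggregation is an option),
  and significance is a two-sided paired t-test on the CV pairs. The
  same machinery serves the temperature contrast, with 22 °C merged
  into the 23 °C group and 32 °C into 33 °C, reflecting how the assays
  were actually binned. Swapping the roles of control and treatment
  negates the t statistic and preserves the p-value exactly.
* **Metadata models and enrichment.** `fit_metadata_model()` is OLS
  with treatment coding and a hard error on rank deficiency that names
  the aliased columns (the experiment date is the canonical offender
  and is excluded from default predictor sets; degenerate
  high-cardinality factors are likewise auto-excluded). Genotype
  effects on mean bias are scored as one indicator model per genotype —
  genotype $g$ versus all other flies, the pooled-variance two-sample
  t — and the count of genotypes below $\alpha$ is compared with the
  $\alpha N$ null expectation by a one-sided binomial test. All
  reported p-values are nominal; no multiple-testing correction is
  applied anywhere, by design, and downstream users should correct as
  their question requires.

## The synthetic generator

Each simulated fly draws independently: a latent bias $p$ from a Beta
distribution (mean/SD parameterization; optionally a Beta mixture for a
heavy-mode, heavy-tailed shape), a target switchiness $S^\ast$ from a
normal distribution mapped to serial correlation $\rho = 1 - S^\ast$,
and a turn count from a negative binomial. Sequences then come from the
two-state Markov chain

$$P(R \mid R) = p + \rho(1 - p), \qquad P(R \mid L) = p(1 - \rho),$$

whose stationary marginal is exactly $p$ and whose alternation rate is
$2p(1-p)(1-\rho)$, so the expected switchiness of a long sequence is
$1-\rho$: the minimal model that decouples bias from switchiness, the
two being separate measures. $\rho$ is clipped to its representable
range $(-\min(p, 1-p)/\max(p, 1-p),\, 1)$ with a clip count reported.

Default parameters are the grand-cohort conditions: bias mean 0.496
(the slight left bias of the real grand data set), bias SD 0.15, target
switchiness $1 \pm 0.1$, turn-count mean 435 (the grand ratio of total
choices to total flies, 79.8 M / 183,496) with CV 0.45. The count CV is
the one defaulted quantity not printed anywhere: we chose 0.45 once as a
clearly overdispersed, right-skewed regime (negative-binomial size
$\approx 5$ at this mean) consistent with the qualitative shape of
published turn-count distributions, and did not revisit it. Group-level
manipulations are expressed by editing the design table (per-cell
`bias_sd`, `turns_cv`, `switch_mean`, …), which is how variability
multipliers are injected in tests. Zero-turn flies occur naturally under
the count distribution and exercise missing-measure handling.

What the generator does **not** emulate: turn timing (no clumpiness
model; optional times would be placeholders); the correlated
second mode seen in real switchiness-versus-bias-magnitude joint
distributions for one rearing medium (it can be approximated via a
mixture, but its parameters would be guesses, so nothing is claimed
about it); experimenter/tray/box batch effects (metadata columns are
written but constant); and any genotype-specific mean structure beyond
what the user injects. Passing tests therefore demonstrate correctness
of the *machinery* under a clean generative model, not fidelity of any
particular biological claim about real cohorts.

## Numerical conventions and edge cases

* Measures computed from sequences always equal measures recomputed
  from stored $(A, n, \hat p)$ — no hidden state.
* All randomized routines take explicit seeds; the same seed is
  bit-reproducible, and cohort generation performs all its draws inside
  one seeded block (population, sequences, maze assignment).
* Bootstrap CIs of width zero are legitimate (constant data).
* A paired design whose CV differences are all exactly zero reports
  $t = 0,\ p = 1$ rather than erroring; a constant nonzero difference
  reports $p = 0$ with infinite $t$.
* Validation treats missing values as allowed everywhere except where a
  schema column is mandatory; the strictness policy defaults to "warn
  and keep", since grand analyses historically used all records, with
  "drop" and "error" available.
* CSV round-trips write missing values as empty cells and use
  shortest-round-trip numeric formatting, so reals survive to full
  precision; the experiment date is carried as an opaque string.

## Problem sizes

The test suite runs its statistical checks at sizes chosen to make
Monte-Carlo error comfortably smaller than the tolerances asserted:
10,000 flies × 1,000 turns for the switchiness calibration ($\pm 0.01$),
$10^5$ values for moment panels against Gaussian double factorials,
20 genotypes × 200 flies/cell for effect-size recovery ($\pm 5$
percentage points on a −35% injection), 200 replicates for type-I
calibration, and 100 seeded runs for bootstrap coverage (expected
93–97%). These sizes are the package's own calibration choices and are
documented here so that users scaling them down know which tolerances
were tuned to which $n$.

## Limitations

* The switchiness normalizer is one of several formulas consistent with
  the verbal definition in the field; see above.
* Variance modelling is OLS on Levene-transformed data throughout — no
  mixed effects, no distributional (e.g. double-GLM) variance models.
* The KDE has no boundary correction, so densities near 0 and 1 are
  biased downward by roughly half a kernel mass at the exact edge.
* The metadata model fits main effects only; interaction structure, if
  present, lands in the residual.
* CV-based effects assume positive group means; measures centered near
  zero would need a different variability metric.
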