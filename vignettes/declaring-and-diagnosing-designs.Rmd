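---
title: "Declaring and diagnosing research designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declaring and diagnosing research designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(designdiag)
```

## The model of a design

`designdiag` treats a research design as four declarable elements:

* **Model (M)** — the units, background variables, and functional
  relations that generate potential outcomes: `declare_population()` and
  `declare_potential_outcomes()`.
* **Inquiry (I)** — the question asked of the model. Its answer under the
  model, the *estimand* $a^M$, is computed fresh each simulation run:
  `declare_inquiry()`.
* **Data strategy (D)** — how the world is turned into data: sampling
  (`declare_sampling()`), treatment assignment (`declare_assignment()`),
  measurement with error (`declare_measurement()`), and the deterministic
  revelation of the assigned potential outcome (`declare_reveal()`).
* **Answer strategy (A)** — estimators mapping realized data to an answer
  $a^A$ with uncertainty: `declare_estimator()` and the bundled
  implementations (difference in means, robust weighted least squares,
  matching, conjugate Bayes, split-sample discovery, QCA minimization,
  process-tracing posteriors).

A design is the ordered composition of these steps. Each run executes them
in order: inquiries summarize whatever data are visible at their position
(so an inquiry declared before sampling is a population-level estimand,
one declared after sampling is its sample-level counterpart), and
estimators see only the revealed, sampled data.

Diagnosis is simulation: `simulate_design()` produces one row per run and
estimator, pairing every estimate with the estimand of the inquiry it
targets; `diagnose_design()` summarizes the distribution of the resulting
*diagnostic statistics* into *diagnosands* — power, bias, RMSE, coverage,
the standard deviations of estimates and estimands, sampling bias,
covariate imbalance, the Type-S rate, the exaggeration ratio, joint
rejection ("robustness"), decision value ("value for money"), and
posterior location/scale shifts for Bayesian strategies.

```{r canonical}
design <- make_design("table3_canonical")
design
diagnose_design(design, c("bias", "power", "coverage"),
                m = 200, n_bootstrap = 100, seed = 42)
```

## Numerical and procedural choices

**Seeds.** One master seed governs everything. Per-run seeds are derived
from it by a counter, so run *i* is reproducible regardless of how many
runs are requested; the bootstrap uses a further derived stream. Identical
inputs give byte-identical outputs.

**Bootstrap.** Diagnosand uncertainty is a nonparametric bootstrap over
*whole simulation runs* (default 100 replicates): run indices are resampled
with replacement and the diagnosand recomputed, so within-run dependence
between estimators is preserved. With `n_bootstrap = 0` the standard error
is reported as unavailable rather than guessed.

**Conditioning conventions.** The Type-S rate and the exaggeration ratio
condition on significance at the same `alpha` used for power (default
0.05, two-sided). When no run qualifies they return `NaN` together with
`n_undefined`, the number of excluded runs — degenerate designs are
reported, not errored. A significant run whose estimand is exactly zero is
likewise counted as undefined for the ratio. Estimator failures inside a
run (for example a singular regression) are recorded as missing rows with
the error message retained, so failure rates remain diagnosable.

**Assignment.** All schemes use complete (urn) randomization: arm counts
are the floor of probability times size, remainders allocated by a
weighted draw, then permuted over units. This matches the semantics of
declaring "assign m of n units" and makes realized arm counts
deterministic. Blocked assignment records each unit's assignment
probability in a `<var>_prob` column, which is what the
inverse-probability weights consume.

**Standard errors.** Least-squares answers use HC2
heteroskedasticity-robust standard errors; when a cluster column is named
they switch to CR1 cluster-robust covariance with cluster-count degrees of
freedom, the convention of applied cluster-randomized analyses. HC2 is
the standard default for randomized designs and is deliberately *not*
corrected further for weighting: how weighted answers' nominal coverage
deteriorates is precisely one of the phenomena the catalogue exhibits.
The matching estimator's standard error is a matched-pair approximation
(standard deviation of pair differences over the square root of the number
of treated units) that ignores control reuse; it is documented as such.

**Imbalance.** The covariate "distance" between arms is operationalized as
the mean absolute standardized mean difference (pooled within-arm standard
deviation); the statistic is pluggable via a custom estimator step.

**Process tracing.** Clue classification uses documented thresholds:
evidence nearly certain under the hypothesis (Pr ≥ 0.9) is a hoop test,
evidence very unlikely under the rival (Pr ≤ 0.1) a smoking gun, both at
once doubly decisive, anything else a straw in the wind. Correlated clues
are modelled by a correlation on the two evidence indicators, clipped to
the Fréchet bounds implied by the marginals (with a warning); process-
tracing accounts typically name the correlation between clues without
committing to a joint model, so this is one concrete, parameterized
stand-in. The expected inferential error of a strategy is
computed by exact enumeration, not simulation. With an uninformative clue
the posterior equals the prior and the expected absolute error is exactly
$2p(1-p)$; any informative clue strictly reduces it.

**QCA.** Truth-table rows are coded positive when their consistency
exceeds 0.5, mirroring the regression-inclusion rule (configurations whose
predicted outcome probability exceeds 0.5); the threshold is exposed.
Unobserved configurations (limited diversity) default to *exclude*
(treated as negative); `dont_care` enables classical merging with
remainders. Quine–McCluskey prime implicants are found by iterative
merging, and the minimal cover is exact (fewest implicants, then fewest
literals, then lexicographic) up to 20 candidate implicants, with a greedy
set cover beyond — far above anything a crisp-set analysis with up to six
causes produces.

## What the catalogue designs emulate

Each `make_design()` entry is a parameterized declaration of one worked
design; the magnitudes below are illustrative defaults, exposed as
parameters, chosen once to place each design in the regime its phenomenon
requires.

* `table3_canonical` — 200 units with standard-normal noise and a unit
  treatment effect, half sampled, half of those treated; the estimand is
  identically 1, which makes it the fixture for calibration checks.
* `confounded_regression` — `Y = bX + Z + e` with `X = Z + e'`; omitting
  `Z` biases the slope by cov(X,Z)/var(X) = 1/2, the closed form the
  diagnosis recovers.
* `blocked_hetero` — eight blocks with sizes 10–112; assignment
  probabilities (0.03–0.97) and treatment effects both increase with block
  size, so effect size, block size, and assignment probability are
  mutually correlated, and unweighted answers are biased. The defaults sit
  deliberately in a moderate-power regime: the inverse-probability-weighted
  block-fixed-effects answer is then better powered and less biased than
  the unweighted one, but only because its weighted HC2 variance estimates
  are anticonservative — its coverage falls well short of 95% and its RMSE
  is no better. At much larger effect sizes the power comparison saturates
  and the coverage deficit shrinks; the tension among these orderings is
  the point of the exercise.
* `factorial_vs_three_arm` — the estimand is the effect of treatment 1
  with treatment 2 at control; the no-interaction regression pools the two
  treatment-2 conditions, so the factorial design's bias tracks half the
  interaction while the three-arm design never realizes the both-treated
  cell.
* `process_tracing` — one case with cause and outcome present; the
  hypothesis holds with the prior probability and clues are drawn from the
  declared likelihoods (0.75/0.25 and 0.30/0.05 by default).
* `qca_crisp` — binary causes drawn uniformly, outcome from a declared
  sum-of-products expression (default: first cause absent and second
  present), optional outcome misclassification; answers are scored by
  semantic equality with the generating expression.
* `likely_voter_survey` — latent turnout and candidate support;
  non-voters overreport turnout, contaminating the likely-voter subsample.
  The exact misreporting mechanism in the original illustration is not
  printed, so who overstates and by how much are exposed parameters with
  documented defaults.
* `bayes_descriptive` — a latent success probability drawn uniformly each
  run, a handful of Bernoulli draws, and two conjugate answers: a flat
  prior (mean 0.50, sd 0.29 — moment-matched to Beta(1,1)) versus a
  concentrated one (sd 0.11 ≈ Beta(9.8, 9.8)). The number of units in the
  original illustration is unprinted; the default of 20 is "relatively
  few" in the sense required for priors to matter.
* `nonlinear_regression` — quadratic response; the estimand is the slope
  of the linear projection under a uniform reference density over the
  treatment grid, so OLS is unbiased under uniform assignment and biased
  once assignment probabilities tilt.
* `matching_probit` — three standard-normal covariates drive assignment
  through a probit and also the outcome; matching on only two of them
  shrinks mean squared error relative to the naive comparison but leaves
  residual confounding bias.
* `rd_polynomial` — potential-outcome functions of a running variable
  with a gap at the cutoff; the answer interacts treatment with a raw
  fourth-order polynomial of the centered running variable.
* `split_sample_discovery` — candidate moderators with declared
  interaction effects; the principled strategy selects on a training split
  (smallest interaction p-value below alpha — one concrete instance of a
  "preferred procedure", exposed as a pluggable rule) and estimates on the
  holdout; a result is "produced" only when discovery and holdout
  significance both occur.
* `truncation_replication` — the cluster-randomized community-health
  replication. Latent family and community health drive both infant
  survival and weight-for-age; the treatment's survival effect is
  concentrated among young, low-health infants, which is exactly the
  selection that biases a naive comparison of surviving infants downward.
  An age stratum whose survival is treatment-independent supports the
  always-survivor subset answer. Cluster counts of 50 versus 187 place
  the mortality answer in low versus adequate power, which is what moves
  the exaggeration ratio from well above one back toward one. CBO
  (community-based organization) presence per cluster is optionally
  correlated with community health and supports four replicator
  strategies (ignore, include, include only if significantly imbalanced
  at the 5% level, include with a treatment interaction). Cluster sizes,
  effect magnitudes, and health loadings are unprinted in the original
  and are exposed parameters; defaults use 10 infants per cluster, an
  85% baseline survival rate, and a survival effect of 0.14 among the
  young (about 0.07 overall).

## Comparing rival answer strategies under rival models

`compare_designs()` diagnoses each answer strategy under each claimed
model (a bundle of population and potential-outcome steps swapped into the
design) and, for the two-by-two case, adjudicates: *home-ground
dominance* when the alternative answer beats the original under the
original's own model; *robustness* when the two tie on the original's
home ground but the alternative wins under the alternative model; *model
plausibility* when each wins at home, in which case the data cannot
settle the argument and the models' credibility must. Ties and wins are
judged at three combined bootstrap standard errors.

## Problem sizes and what passing means

The shipped tests run each claim at the smallest scale at which its
expected effect clears three bootstrap (or Monte Carlo) standard errors —
typically 200–2000 runs per design, 5000 for coverage calibration, and
exact enumeration wherever the design is small enough (all 20 assignments
of 3 treated among 6 units; all 16 labelings of a two-cause truth table).

The generators emulate clean, correctly-specified worlds: independent
noise, exact randomization, no attrition or interference, and measurement
error only where declared. Passing diagnoses therefore demonstrate that
the estimators and diagnosands behave as the theory predicts under the
declared models — not that any real study is unbiased. The value of the
framework on real designs is exactly that these model assumptions are
declared objects a critic can swap out and re-diagnose.

## Known limitations

* Diagnosands are simulation summaries only; no analytic power or bias
  formulas, and no DAG-based identification analysis of declared models.
* Interventions are limited to declared condition sets (no general
  do-calculus), and the only Bayesian answer path is the conjugate
  beta-binomial.
* Crisp-set QCA only: no fuzzy sets, and only Quine–McCluskey
  minimization.
* The matching standard error is approximate, and cluster-robust inference
  uses a simple cluster-count degrees-of-freedom rule.
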