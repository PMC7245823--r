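---
title: "Partitioned GMM marginal models for longitudinal binary outcomes"
author: "partgmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned GMM marginal models for longitudinal binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partgmm)
```

## The model

Consider a balanced panel of `N` subjects observed at waves `t = 1, ..., T`
with a binary outcome `y_it`, time-independent covariates `x_F` and `J`
time-dependent covariates `x_ijt`. Marginal (population-averaged) logistic
regression of `y_it` on the same-wave covariate values alone assumes that a
covariate acts only contemporaneously. In ageing cohorts that assumption is
rarely tenable: exercise or mobility measured three years ago plausibly
still shapes health today, and with a different strength and possibly a
different sign than today's value.

The partitioned model makes the lag structure explicit. For each
time-dependent covariate the subject's `T` values are rearranged into a
`T x T` lower-triangular matrix whose `k`-th column holds the value observed
`k` waves before the outcome (and a structural zero where no such wave
exists). Stacking subjects gives a design matrix with, per covariate, a
lag-0 ("cross-sectional") column and up to `T - 1` lag columns, so the
marginal mean is

```
logit mu_it = b0 + bF' x_F + sum_j [ b_j0 x_ijt + b_j1 x_ij(t-1) + ... ]
```

with one coefficient per (covariate, lag) pair — at most `J x T + 1`
coefficients plus the fixed-covariate block. `exp(b_jk)` is the odds ratio
for the covariate's effect `k` waves ahead, which is exactly the quantity a
decision maker monitoring a risk factor over time needs.

`build_partitioned_design()` constructs this matrix; its lower-triangular
structure is locked down by exhaustive property tests.

## Why GMM, and which moments

With time-dependent covariates, the GEE-style estimating equations implicitly
use cross-products of covariate values at one wave with residuals at
another. Such a product is a *valid moment condition* only if
`E[x_ijs (y_it - mu_it)] = 0`. Cross-sectional products (`s = t`) are valid
under correct mean specification. Products involving different waves are
valid only when the covariate is exogenous with respect to the outcome
process: if a past outcome feeds back into a later covariate value (say, a
health event changes subsequent exercise), the product of that future
covariate with the earlier residual has nonzero expectation and must not be
used for estimation.

The estimator therefore works with two groups of conditions:

* **Baseline** — one condition per design column, pairing the column with
  the residuals of its own rows. These `p` conditions just-identify the
  coefficients; solving them is exactly pooled (working-independence)
  logistic regression on the partitioned design, computed by IRLS in
  `fit_independence()`.
* **Extras** — individual products `x_ijs (y_it - mu_it)` *outside* the
  baseline set: future-covariate pairs (`s > t`) and long-lag pairs
  (`t - s > max_lag`). Each is screened by `test_moment_validity()` and,
  if not rejected, added as an over-identifying condition.

A subtlety fixed during design: pairs with `0 < t - s <= max_lag` are
components of the baseline conditions (the baseline lag-`k` condition is
their sum over waves), so at the fitted coefficients their sample
correlations with the residuals are shrunk toward zero by construction —
for the longest lag, exactly zero. Testing them is vacuous and their
inclusion as extras would make the moment set linearly dependent; they are
therefore neither candidates nor extras. Monte Carlo confirms the
consequence: rejection rates for those pairs sit at 0–2% instead of the
nominal level, while the non-baseline pairs calibrate at the nominal 5%.

### The validity screen

For each candidate `(j, s, t)` the Pearson correlation across subjects
between `x[, s, j]` and the standardized residual
`e_it = (y_it - mu_it) / sqrt(mu_it (1 - mu_it))` — residuals taken at the
working-independence estimate — is tested with the Fisher z transformation,
`z = atanh(r) sqrt(N - 3)`, two-sided. This is the simplest faithful
bivariate-correlation screen; it sits behind a single interface and could be
swapped for another statistic without touching estimation. Defaults:
`alpha = 0.05`, no multiplicity adjustment (Bonferroni available via
`adjust`). Residuals are *not* re-estimated after selection: iterating
selection and estimation would couple the two in ways that are hard to
analyse, so the screen is one-shot by design.

## Two-step estimation

`fit_two_step()` implements standard efficient two-step GMM:

1. `beta_1` from the baseline conditions (IRLS).
2. `W = [ (1/N) sum_i g_i(beta_1) g_i(beta_1)' ]^{-1}` via symmetric
   eigendecomposition, with a ridge `1e-8 * trace/m` added when the
   condition number exceeds `1e12` (an all-zero component is flagged, never
   fatal).
3. Minimize `Q(beta) = gbar' W gbar` by Gauss–Newton with the analytic
   Jacobian `G = d gbar / d beta` (verified against central finite
   differences in the tests) and a backtracking line search, so `Q` is
   non-increasing across accepted steps. Convergence when the gradient norm
   `|2 G' W gbar|` falls below `1e-8` or the step below `1e-10`;
   non-convergence within 200 iterations is an error, never a silent
   result.

Covariance is `(1/N)(G' W G)^{-1}`; the over-identification J statistic is
`N Q` on `m - p` degrees of freedom; per-coefficient Wald z, normal
two-sided p-values, odds ratios and 95% CIs (`exp(b +/- 1.96 se)`) fill the
report. Two-step (rather than continuously-updating or iterated) GMM is the
cheapest member of the family and the standard choice in this methodology;
with a just-identified set, step 2 provably returns the step-1 solution and
a zero objective, which the acceptance suite checks to `1e-8`.

Rank-deficient designs are handled deterministically: columns are screened
in declared order (intercept, wave, fixed, then lag blocks ascending), so a
collinear *later* lag is dropped first; dropped coefficients surface in
`wald_table()` with status `"dropped"` and render as a dash.

## The synthetic generator

No public fixture exists for restricted survey data, so the package ships a
generator whose defaults define the study conditions used throughout the
tests: `N = 2000` subjects, `T = 4` waves, `J = 2` binary time-dependent
covariates, one binary fixed covariate, `rho = 0`, no feedback.

* **Covariates** follow per-covariate first-order Markov chains
  (`p01 = 0.3`, `p11 = 0.7`, initial prevalence 0.5 by default) — enough
  persistence to make lags informative without near-collinearity between
  adjacent lag columns. Alternatively a covariate can be given per-wave
  marginal targets plus a persistence parameter; transitions are then
  solved wave by wave so expected prevalence tracks the targets (re-solving
  under clamping when a target sits near the boundary).
* **True coefficients** default to an intercept of 0.25, fixed effect 0.3,
  and lag profiles `(0.8, 0.4, 0.2, 0.3)` and `(-0.5, 0.3, -0.2, 0)` —
  moderate effects on the logit scale with a sparse lag-3 signal confined
  to the first covariate.
* **Outcomes** are Bernoulli at the model's marginal mean. With `rho = 0`
  they are conditionally independent given covariates, so the fitted
  marginal model is *exactly* true — the cleanest possible
  parameter-recovery surface. With `rho > 0` an exchangeable Gaussian
  copula (`Z_it = sqrt(rho) U_i + sqrt(1-rho) e_it`, `y_it = 1` iff
  `Phi(Z_it) <= mu_it`) adds within-subject correlation while provably
  preserving every marginal mean; the tests verify preservation to
  Monte-Carlo accuracy at `rho` 0.3 and 0.6.
* **Feedback** enters the covariate transitions (log-odds shifted by
  `feedback * y_{t-1}`), the canonical way a time-dependent covariate
  becomes non-exogenous, and the mechanism powering the validity screen's
  power test. Feedback forces interleaved generation
  (`generate_panel()`); all randomness is drawn up front in a fixed order,
  so the interleaved and exogenous paths agree draw-for-draw when feedback
  is off and every output is a pure function of the spec and its seed.

`make_clhls_like_fixture()` produces a deterministic demonstration panel
shaped like a four-wave elderly-health survey: 2021 subjects, 8084 records,
six binary time-dependent covariates tuned to published per-wave prevalence
margins, declining outcome prevalence obtained by solving wave-specific
intercepts by root-finding against the realised covariates, and `rho = 0.3`
outcome correlation. It emulates margins only — effect sizes are synthetic
magnitudes, and nothing in the fixture reproduces any fitted survey result.

## What the simulations do and do not show

The generator's panels are balanced, fully observed, binary, and generated
under the fitted model family (or controlled violations of it). Passing
tests therefore demonstrate internal correctness — consistency, calibrated
test levels, honest intervals *when the marginal model holds* — not
robustness to attrition, missingness, survey weighting, measurement error
or misspecified link functions, none of which the generator emulates (and
the first three of which the data container deliberately rejects rather
than imputes, since the method itself prescribes no missing-data
procedure).

Simulation sizes used by the test suite, chosen to keep Monte-Carlo error
well inside each decision band: parameter recovery at 200 replications of
`N = 2000`; validity-screen calibration at 1000 replications of `N = 500`
with `J = 1` (per-candidate rates compared against the exact binomial 99%
band) and 300 replications of `N = 1000` for the feedback-power arm;
J-statistic calibration at 500 replications of `N = 800` — `N` large
relative to the `m = 22` moment conditions, since the weight matrix is
estimated; copula fidelity at 10^4 replications of a single subject.
Coverage is assessed as the average across coefficients: at 200
replications the per-coefficient binomial noise band is wider than the
acceptance band itself, so per-coefficient assessment would fail by chance
alone with ten coefficients.

## Numerical choices and degenerate inputs

* Structural zeros in lag columns are kept at build time and resolved at
  fit time by the deterministic rank screen.
* Fitted means within `1e-10` of 0 or 1 abort residual computation with a
  separation diagnostic; step-1 coefficients beyond 15 in absolute value
  are treated as separation and named.
* Candidates with a zero-variance covariate wave or residual are excluded
  from the screen with a warning (a correlation is undefined there).
* `atanh` is evaluated on correlations clipped away from ±1 by `1e-15`.
* The critical value 1.96 is fixed for CIs, matching the usual reporting
  convention for this model family; p-values use the normal reference.
* Wave labels (e.g. calendar years 2005/2008/2011/2014) are mapped
  ordinally; unequal spacing is ignored, matching lag-in-waves semantics.
  An optional wave-indicator block (`wave_effects = TRUE`) relaxes the
  single-intercept assumption; the default keeps it, mirroring the model
  as usually written.

## Known limitations

Unbalanced panels are rejected (or incomplete subjects dropped on request);
there is no imputation, no survey weighting, no small-sample (Windmeijer)
covariance correction, and no continuous-outcome variant. The validity
screen is per-pair; pooling candidate pairs across equal lags would be a
natural variant but is not implemented. The J statistic uses the plain
chi-squared reference.

## A short worked example

```{r example, eval = FALSE}
library(partgmm)

spec <- synthetic_spec(N = 800, seed = 7)
panel <- generate_panel(spec)

design <- build_partitioned_design(panel)
step1 <- fit_independence(panel, design)
screen <- test_moment_validity(panel, step1$design, step1$beta)
fit <- fit_two_step(panel, step1$design, screen$moments)
fit
wald_table(fit)
```
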