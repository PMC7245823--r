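# partgmm

Partitioned GMM marginal logistic regression for longitudinal binary
outcomes with time-dependent covariates.

## The problem

In a longitudinal survey a time-dependent covariate — exercise, mobility,
diet — is re-measured at every wave, and its effect on a binary outcome
need not be confined to the wave in which it is measured: last wave's
exercise may still shape this wave's health, with a different strength or
even a different sign than today's. Conventional marginal models (GEE, or
GMM with pooled moment conditions) report a single coefficient per
covariate, averaging these effects together.

The partitioned model separates them. For each subject and covariate the
`T` observed values are rearranged into a `T × T` lower-triangular matrix
whose `k`-th column holds the value observed `k` waves before the outcome,
so the marginal mean of the outcome `y_it` becomes

    logit μ_it = β₀ + β_F' x_F + Σⱼ [ βⱼ⁰ x_ijt + βⱼ¹ x_ij(t−1) + … + βⱼ^(t−1) x_ij1 ]

with one coefficient per (covariate, lag): a cross-sectional effect βⱼ⁰
and delayed effects βⱼ¹, βⱼ², … — at most `J × T + 1` coefficients. Each
`exp(βⱼᵏ)` is an odds ratio for the covariate's effect `k` waves ahead.

Because cross-products of covariates at one wave with residuals at another
are only usable when `E[x_ijs (y_it − μ_it)] = 0`, the package screens
every non-baseline candidate pair with a bivariate correlation test
(Fisher z on the correlation between the covariate value and the
standardized residual) and estimates the coefficients by two-step GMM over
the baseline conditions plus the validated extras, reporting
odds ratios, 95% confidence intervals, Wald p-values and the
over-identification J statistic.

The package is aimed at biostatisticians analysing balanced longitudinal
survey panels (the motivating setting is a four-wave elderly-health
cohort), and at methodologists who need a fully seeded synthetic
generator with known lagged effects, within-subject covariate persistence,
exchangeable Gaussian-copula outcome correlation, and optional
outcome-to-covariate feedback for exogeneity experiments.

## Worked example

```r
library(partgmm)

spec   <- synthetic_spec(N = 800, seed = 7)   # 2 covariates, 4 waves, known truth
panel  <- generate_panel(spec)
design <- build_partitioned_design(panel)
step1  <- fit_independence(panel, design)
screen <- test_moment_validity(panel, step1$design, step1$beta)
fit    <- fit_two_step(panel, step1$design, screen$moments)
fit
```

```
Partitioned GMM marginal logistic regression (two-step)
  N = 800 subjects, T = 4 waves; 22 moments, 10 coefficients
  J statistic = 4.808 on 12 df (p = 0.964)

                   group   covariate   OR         CI95      p
1        Cross sectional (Intercept) 1.28 [1.09, 1.51]   0.00
2        Cross sectional          f1 1.17 [1.00, 1.36]   0.05
3        Cross sectional          x1 2.25 [1.92, 2.63] <0.001
4        Cross sectional          x2 0.65 [0.56, 0.77] <0.001
5    One time period lag          x1 1.43 [1.20, 1.69] <0.001
6    One time period lag          x2 1.35 [1.11, 1.62]   0.00
7    Two time period lag          x1 1.25 [1.01, 1.53]   0.04
8    Two time period lag          x2 0.73 [0.59, 0.91]   0.00
9  Three time period lag          x1 1.16 [0.88, 1.53]   0.28
10 Three time period lag          x2 1.19 [0.90, 1.58]   0.23
```

The generator's truth here is a lag profile of `(0.8, 0.4, 0.2, 0.3)` for
`x1` and `(−0.5, 0.3, −0.2, 0)` for `x2` on the logit scale; the fitted
cross-sectional odds ratios 2.25 and 0.65 sit next to `exp(0.8) = 2.23`
and `exp(−0.5) = 0.61`, the lagged rows recover the decaying profile, and
the J statistic (12 over-identifying validated moments) shows no evidence
against the selected moment set. `wald_table(fit)` returns the same table
with full-precision estimates and standard errors; `sign_summary(fit)`
condenses it to significant directions by lag.

A shell interface wrapping the same functions ships in
`inst/cli/partgmm.R` with `fit`, `simulate` and `describe` subcommands
driven by YAML/JSON configs, and `make_clhls_like_fixture()` builds a
deterministic 2021-subject × 4-wave demonstration panel whose per-wave
margins track a published elderly-health survey's descriptive tables.

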