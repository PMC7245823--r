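Package: partgmm
Title: Partitioned GMM Marginal Logistic Regression for Longitudinal
    Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Marginal logistic regression for balanced longitudinal binary
    outcomes with time-dependent covariates, where each covariate's effect is
    partitioned into a cross-sectional component and separate lag-specific
    components via a lower-triangular expansion of the design matrix.
    Candidate lagged moment conditions are screened for validity with a
    bivariate correlation test between covariate values and standardized
    outcome residuals, and the partitioned coefficients are estimated by
    two-step generalized method of moments over the selected moments, with
    over-identification diagnostics and odds-ratio reporting. Includes a
    seeded generator for balanced binary panels with known lagged effects,
    within-subject covariate persistence, exchangeable Gaussian-copula
    outcome correlation, and optional covariate feedback from past outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
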