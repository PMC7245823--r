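default_beta_lag <- function(J, T) {
  beta <- matrix(0, J, T)
  for (j in seq_len(J)) {
    base <- if (j %% 2 == 1) c(0.8, 0.4, 0.2) else c(-0.5, 0.3, -0.2)
    beta[j, seq_len(min(3, T))] <- base[seq_len(min(3, T))]
  }
  if (T >= 4) beta[1, 4] <- 0.3  # sparse furthermost-lag effect
  beta
}

default_covariate_cfg <- function(J) {
  lapply(seq_len(J), function(j)
    list(init = 0.5, p01 = 0.3, p11 = 0.7))
}

#' Specification for a synthetic balanced binary panel
#'
#' Defines the generating process: `N` subjects by `T` waves; `J` binary
#' time-dependent covariates following first-order Markov chains with
#' transition probabilities `p01 = P(x_t = 1 | x_{t-1} = 0)` and
#' `p11 = P(x_t = 1 | x_{t-1} = 1)`; one binary time-independent
#' covariate; binary outcomes whose marginal logit is
#' `beta0 (+ wave offset) + beta_fixed x_F + sum_j sum_k beta_lag[j, k+1] x_{ij(t-k)}`
#' over lags `k < t`. With `rho > 0` outcomes are correlated within
#' subject through an exchangeable Gaussian copula that preserves the
#' marginal means exactly; with `feedback != 0` the covariate transition
#' log-odds at wave `t` shift by `feedback[j] * y_{i,t-1}`, making the
#' covariate non-exogenous (invalid future-covariate moments).
#'
#' A covariate entry may alternatively give per-wave marginal `targets`
#' (length `T`) plus a `persistence` in \[0, 1); transitions are then
#' solved wave by wave so the expected prevalence tracks the targets.
#'
#' @param N subjects. @param T waves. @param J time-dependent covariates.
#' @param beta0 intercept. @param beta_fixed fixed-covariate effect.
#' @param beta_lag `J x T` matrix of true coefficients; column `k+1` is
#'   the lag-`k` effect. Default: moderate cross-sectional and decaying
#'   lag effects, lag-3 zero except for the first covariate.
#' @param beta_wave optional length-`T` additive intercept offsets
#'   (default all zero).
#' @param covariates list of length `J`: each `list(init, p01, p11)` or
#'   `list(init, targets, persistence)`.
#' @param fixed_prevalence Bernoulli probability of the fixed covariate.
#' @param rho exchangeable latent outcome correlation in \[0, 1).
#' @param feedback scalar or length-`J` log-odds shift of covariate
#'   transitions from the previous outcome (0 = exogenous).
#' @param seed integer seed; all generator output is a pure function of
#'   the spec including the seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(N = 2000L, T = 4L, J = 2L,
                           beta0 = 0.25, beta_fixed = 0.3,
                           beta_lag = NULL, beta_wave = NULL,
                           covariates = NULL, fixed_prevalence = 0.5,
                           rho = 0, feedback = 0, seed = 1L) {
  N <- as.integer(N); T <- as.integer(T); J <- as.integer(J)
  stopifnot(N >= 1L, T >= 1L, J >= 1L)
  if (is.null(beta_lag)) beta_lag <- default_beta_lag(J, T)
  beta_lag <- as.matrix(beta_lag)
  if (nrow(beta_lag) != J || ncol(beta_lag) > T)
    stop("beta_lag must be J x T (no columns beyond lag T-1)", call. = FALSE)
  if (ncol(beta_lag) < T)
    beta_lag <- cbind(beta_lag, matrix(0, J, T - ncol(beta_lag)))
  if (is.null(beta_wave)) beta_wave <- rep(0, T)
  stopifnot(length(beta_wave) == T)
  if (is.null(covariates)) covariates <- default_covariate_cfg(J)
  stopifnot(length(covariates) == J)
  for (cfg in covariates) {
    probs <- unlist(cfg[intersect(names(cfg),
                                  c("init", "p01", "p11", "targets",
                                    "persistence"))])
    if (any(probs < 0 | probs > 1))
      stop("covariate probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  feedback <- rep_len(feedback, J)
  if (fixed_prevalence < 0 || fixed_prevalence > 1)
    stop("fixed_prevalence must be in [0, 1]", call. = FALSE)
  structure(
    list(N = N, T = T, J = J, beta0 = beta0, beta_fixed = beta_fixed,
         beta_lag = beta_lag, beta_wave = beta_wave,
         covariates = covariates, fixed_prevalence = fixed_prevalence,
         rho = rho, feedback = feedback, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic panel spec: N = %d, T = %d, J = %d, rho = %g, feedback = %s, seed = %d\n",
    x$N, x$T, x$J, x$rho, paste(x$feedback, collapse = "/"), x$seed))
  invisible(x)
}

# Transition probability to state 1 at wave t given previous state.
transition_prob <- function(cfg, t, x_prev) {
  if (!is.null(cfg$targets)) {
    pi_t <- cfg$targets[t]
    kappa <- if (is.null(cfg$persistence)) 0.5 else cfg$persistence
    m_prev <- cfg$targets[t - 1]
    p11 <- min(1, pi_t + kappa * (1 - pi_t))
    p01 <- if (m_prev < 1) (pi_t - p11 * m_prev) / (1 - m_prev) else pi_t
    # if the persistence choice is infeasible, re-solve the other
    # transition under the clamp so the expected marginal still hits pi_t
    if (p01 < 0) {
      p01 <- 0
      p11 <- if (m_prev > 0) min(1, pi_t / m_prev) else p11
    } else if (p01 > 1) {
      p01 <- 1
      p11 <- if (m_prev > 0) max(0, (pi_t - (1 - m_prev)) / m_prev) else p11
    }
  } else {
    p01 <- cfg$p01; p11 <- cfg$p11
  }
  ifelse(x_prev == 1, p11, p01)
}

init_prob <- function(cfg) {
  if (!is.null(cfg$targets)) cfg$targets[1] else cfg$init
}

# All random material for one realisation, drawn in a fixed order so the
# exogenous and feedback paths agree draw-for-draw.
draw_covariate_material <- function(spec) {
  x_fixed <- as.double(stats::runif(spec$N) < spec$fixed_prevalence)
  u <- array(stats::runif(spec$N * spec$T * spec$J),
             c(spec$N, spec$T, spec$J))
  list(x_fixed = x_fixed, u = u)
}

draw_outcome_material <- function(spec) {
  shared <- stats::rnorm(spec$N)
  noise <- matrix(stats::rnorm(spec$N * spec$T), spec$N, spec$T)
  sqrt(spec$rho) * shared + sqrt(1 - spec$rho) * noise
}

#' Generate the covariate process (exogenous case)
#'
#' Wave 1 is Bernoulli at the initial prevalence; later waves follow the
#' Markov transitions. This standalone path requires `feedback = 0`
#' (covariates driven by past outcomes must be generated interleaved —
#' use [generate_panel()]).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `x_td` (`N x T x J`) and `x_fixed` (length `N`).
#' @export
generate_covariates <- function(spec) {
  if (any(spec$feedback != 0))
    stop("feedback != 0 requires interleaved generation: use generate_panel()",
         call. = FALSE)
  set.seed(spec$seed)
  mat <- draw_covariate_material(spec)
  x_td <- array(0, c(spec$N, spec$T, spec$J),
                dimnames = list(NULL, NULL, paste0("x", seq_len(spec$J))))
  for (j in seq_len(spec$J)) {
    cfg <- spec$covariates[[j]]
    x_td[, 1, j] <- as.double(mat$u[, 1, j] < init_prob(cfg))
    if (spec$T > 1) for (t in 2:spec$T) {
      p <- transition_prob(cfg, t, x_td[, t - 1, j])
      x_td[, t, j] <- as.double(mat$u[, t, j] < p)
    }
  }
  list(x_td = x_td, x_fixed = mat$x_fixed)
}

true_linear_predictor <- function(spec, x_td, x_fixed) {
  eta <- matrix(spec$beta0, spec$N, spec$T, byrow = FALSE) +
    matrix(spec$beta_wave, spec$N, spec$T, byrow = TRUE) +
    spec$beta_fixed * x_fixed
  for (t in seq_len(spec$T))
    for (j in seq_len(spec$J))
      for (k in 0:(t - 1))
        eta[, t] <- eta[, t] + spec$beta_lag[j, k + 1] * x_td[, t - k, j]
  eta
}

#' Generate outcomes given covariates
#'
#' Marginal means are the inverse-logit of the true linear predictor.
#' With `rho = 0` outcomes are conditionally independent Bernoulli draws;
#' with `rho > 0` an exchangeable Gaussian copula correlates them within
#' subject: latent `Z_it = sqrt(rho) U_i + sqrt(1-rho) e_it` and
#' `y_it = 1(Phi(Z_it) <= mu_it)`, which preserves each marginal mean
#' exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param covariates output of [generate_covariates()].
#' @return list with `y` (`N x T`), `mu` (`N x T` true means).
#' @export
generate_outcomes <- function(spec, covariates) {
  set.seed((spec$seed + 1000003L) %% .Machine$integer.max)
  lat <- draw_outcome_material(spec)
  eta <- true_linear_predictor(spec, covariates$x_td, covariates$x_fixed)
  mu <- stats::plogis(eta)
  y <- (stats::pnorm(lat) <= mu) * 1
  list(y = y, mu = mu)
}

#' Generate a complete synthetic panel
#'
#' Composes [generate_covariates()] and [generate_outcomes()]. When
#' `feedback != 0`, covariates and outcomes are generated interleaved
#' wave by wave (the transition log-odds at wave `t` shift by
#' `feedback[j] * y_{i,t-1}`), using the same underlying random material,
#' so the exogenous case agrees draw-for-draw with the standalone path.
#'
#' @param spec a [synthetic_spec()].
#' @param outcome_name name for the outcome in the returned panel.
#' @return a [panel_dataset()] with attribute `"mu"` (the true means).
#' @export
generate_panel <- function(spec, outcome_name = "y") {
  if (all(spec$feedback == 0)) {
    cov <- generate_covariates(spec)
    out <- generate_outcomes(spec, cov)
  } else {
    set.seed(spec$seed)
    mat <- draw_covariate_material(spec)
    set.seed((spec$seed + 1000003L) %% .Machine$integer.max)
    lat <- draw_outcome_material(spec)

    x_td <- array(0, c(spec$N, spec$T, spec$J),
                  dimnames = list(NULL, NULL, paste0("x", seq_len(spec$J))))
    y <- matrix(0, spec$N, spec$T)
    mu <- matrix(0, spec$N, spec$T)
    for (t in seq_len(spec$T)) {
      for (j in seq_len(spec$J)) {
        cfg <- spec$covariates[[j]]
        if (t == 1) {
          x_td[, 1, j] <- as.double(mat$u[, 1, j] < init_prob(cfg))
        } else {
          p <- transition_prob(cfg, t, x_td[, t - 1, j])
          p <- stats::plogis(stats::qlogis(p) + spec$feedback[j] * y[, t - 1])
          x_td[, t, j] <- as.double(mat$u[, t, j] < p)
        }
      }
      eta_t <- spec$beta0 + spec$beta_wave[t] +
        spec$beta_fixed * mat$x_fixed
      for (j in seq_len(spec$J))
        for (k in 0:(t - 1))
          eta_t <- eta_t + spec$beta_lag[j, k + 1] * x_td[, t - k, j]
      mu[, t] <- stats::plogis(eta_t)
      y[, t] <- (stats::pnorm(lat[, t]) <= mu[, t]) * 1
    }
    cov <- list(x_td = x_td, x_fixed = mat$x_fixed)
    out <- list(y = y, mu = mu)
  }
  pd <- panel_dataset(out$y, cov$x_td,
                      x_fixed = matrix(cov$x_fixed, ncol = 1,
                                       dimnames = list(NULL, "f1")),
                      outcome_name = outcome_name)
  attr(pd, "mu") <- out$mu
  attr(pd, "spec") <- spec
  pd
}

clhls_targets <- function() {
  list(
    outcome = c(0.9476, 0.9441, 0.9198, 0.8669),
    covariates = list(
      own_decision = c(0.9020, 0.8738, 0.8936, 0.8733),
      vegetables   = c(0.8956, 0.9169, 0.9253, 0.9095),
      exercise     = c(0.3805, 0.4270, 0.4879, 0.3953),
      transfer     = c(0.9970, 0.9946, 0.9817, 0.9510),
      visual_difficulty = c(0.1940, 0.1954, 0.2380, 0.2954),
      pick_book    = c(0.9198, 0.9164, 0.8585, 0.7704)))
}

#' Survey-like demonstration fixture
#'
#' A deterministic synthetic panel with the shape of the CLHLS analysis
#' sample: 2021 subjects over 4 waves (8084 records), six binary
#' time-dependent covariates (decision-making autonomy, frequent
#' vegetable consumption, exercise, unassisted transfer, visual
#' difficulty, picking a book up from the floor while standing), and a
#' binary fixed covariate (`male`, prevalence 0.5 — a synthetic choice,
#' not a published margin). Covariate chains are tuned so expected
#' per-wave prevalences track the published survey margins, and
#' wave-specific intercepts are solved by root-finding at generation time
#' so the outcome's declining per-wave prevalence tracks its targets;
#' within-subject outcome correlation `rho = 0.3` adds realism without
#' disturbing the marginals. The covariate effect sizes are plausible
#' synthetic magnitudes; this fixture emulates the survey's margins only,
#' not any fitted result.
#'
#' @param seed integer seed (default 2021).
#' @return a [panel_dataset()] named like the survey variables, with the
#'   generating `synthetic_spec` attached as attribute `"spec"`.
#' @export
make_clhls_like_fixture <- function(seed = 2021L) {
  tg <- clhls_targets()
  J <- length(tg$covariates)
  beta_lag <- rbind(
    own_decision      = c(0.24, -0.05, -0.10, 0.00),
    vegetables        = c(0.53, -0.25, 0.10, 0.28),
    exercise          = c(0.71, 0.33, 0.05, -0.05),
    transfer          = c(1.30, 0.55, -0.80, -0.40),
    visual_difficulty = c(-0.45, 0.05, 0.10, -0.30),
    pick_book         = c(1.40, -0.30, 0.35, -0.10))
  spec <- synthetic_spec(
    N = 2021L, T = 4L, J = J, beta0 = 0, beta_fixed = 0,
    beta_lag = beta_lag,
    covariates = lapply(tg$covariates, function(v)
      list(targets = v, persistence = 0.5)),
    fixed_prevalence = 0.5, rho = 0.3, feedback = 0, seed = seed)

  cov <- generate_covariates(spec)
  dimnames(cov$x_td)[[3]] <- names(tg$covariates)

  # Solve the wave intercepts against the realised covariates so the
  # expected outcome prevalence hits the target in every wave.
  eta0 <- true_linear_predictor(spec, cov$x_td, cov$x_fixed)
  for (t in seq_len(spec$T)) {
    spec$beta_wave[t] <- stats::uniroot(
      function(b) mean(stats::plogis(b + eta0[, t])) - tg$outcome[t],
      c(-10, 10), tol = 1e-10)$root
  }
  out <- generate_outcomes(spec, cov)

  pd <- panel_dataset(out$y, cov$x_td,
                      x_fixed = matrix(cov$x_fixed, ncol = 1,
                                       dimnames = list(NULL, "male")),
                      wave_labels = c(2005, 2008, 2011, 2014),
                      outcome_name = "health")
  attr(pd, "mu") <- out$mu
  attr(pd, "spec") <- spec
  pd
}
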