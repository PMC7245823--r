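lag_group_label <- function(lag) {
  words <- c("One", "Two", "Three", "Four", "Five", "Six", "Seven", "Eight",
             "Nine")
  ifelse(is.na(lag), "Cross sectional",
         ifelse(lag == 0, "Cross sectional",
                paste(ifelse(lag <= length(words), words[pmax(lag, 1)], lag),
                      "time period lag")))
}

# Greedy rank screen: keep columns in declared order (intercept, wave, fixed,
# then lag blocks ascending), so collinear later lags are dropped first.
drop_degenerate_columns <- function(design, tol = 1e-9) {
  Z <- design$Z
  keep <- integer(0)
  R <- NULL
  for (c in seq_len(ncol(Z))) {
    cand <- Z[, c(keep, c), drop = FALSE]
    if (qr(cand, tol = tol)$rank == length(keep) + 1L)
      keep <- c(keep, c)
  }
  dropped <- design$col_info$label[setdiff(seq_len(ncol(Z)), keep)]
  list(design = subset_design(design, keep), dropped = dropped)
}

#' Working-independence (step-1) fit
#'
#' Solves the baseline just-identified moment equations
#' `sum_rows z (y - mu(beta)) = 0` by iteratively reweighted least
#' squares — identical to pooled logistic regression of the stacked
#' outcomes on the partitioned design. Degenerate or collinear columns
#' (e.g. an all-zero lag column) are dropped with a warning, later lags
#' first, and recorded so reports can render the coefficient as absent.
#'
#' @param data a [panel_dataset()].
#' @param design a [build_partitioned_design()] result on `data`.
#' @return list with `beta` (named coefficients over kept columns),
#'   `design` (the possibly pruned design), `dropped` (labels of dropped
#'   columns), `fitted` (row-wise means).
#' @export
fit_independence <- function(data, design) {
  scr <- drop_degenerate_columns(design)
  if (length(scr$dropped))
    warning(sprintf("dropped degenerate/collinear column(s): %s",
                    paste(scr$dropped, collapse = ", ")), call. = FALSE)
  design <- scr$design
  y <- outcome_vector(data)
  fit <- suppressWarnings(
    stats::glm.fit(design$Z, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)))
  beta <- fit$coefficients
  if (anyNA(beta) || !fit$converged || any(abs(beta) > 15)) {
    worst <- design$col_info$label[which.max(abs(beta))]
    stop(sprintf(
      "step-1 logistic fit degenerate (possible complete separation; worst column: %s)",
      worst), call. = FALSE)
  }
  names(beta) <- design$col_info$label
  list(beta = beta, design = design, dropped = scr$dropped,
       fitted = fit$fitted.values)
}

#' Per-subject moment contributions
#'
#' Baseline components: for each design column `c`, the subject's sum
#' over waves of `Z[row, c] * (y - mu)`. Extra components: the single
#' product `x[i, s, j] * (y[i, t] - mu[i, t])` for each over-identifying
#' pair. The sample moment `gbar` is the subject average; GMM drives it
#' to (near) zero.
#'
#' @param beta coefficient vector, length `design$p`.
#' @param data a [panel_dataset()].
#' @param design a [build_partitioned_design()] result on `data`.
#' @param moments a [moment_set()] for this design.
#' @return list with `G_i` (`N x m` matrix of per-subject contributions),
#'   `gbar` (length-`m` mean), `mu` (row means), `resid` (`y - mu`).
#' @export
moment_vector <- function(beta, data, design, moments) {
  if (moments$p != design$p)
    stop("moment set does not match the design's column count", call. = FALSE)
  N <- data$N; T <- data$T
  mu <- marginal_mean(beta, design)
  res <- outcome_vector(data) - mu
  G_base <- rowsum(design$Z * res, group = rep(seq_len(N), each = T),
                   reorder = FALSE)
  ex <- moments$extras
  if (nrow(ex)) {
    res_mat <- matrix(res, N, T, byrow = TRUE)
    G_ext <- vapply(seq_len(nrow(ex)), function(k)
      data$x_td[, ex$cov_wave[k], ex$covariate[k]] * res_mat[, ex$out_wave[k]],
      numeric(N))
    G_i <- cbind(G_base, G_ext)
  } else G_i <- G_base
  colnames(G_i) <- c(design$col_info$label,
                     if (nrow(ex)) sprintf("%s.w%d~y.w%d", ex$covariate,
                                           ex$cov_wave, ex$out_wave))
  list(G_i = G_i, gbar = colMeans(G_i), mu = mu, resid = res)
}

#' Efficient GMM weight matrix
#'
#' Inverse of the sample second-moment matrix `S = (1/N) sum g_i g_i'`,
#' via symmetric eigendecomposition. If `S` is numerically singular
#' (condition number above `1e12`, or a non-positive eigenvalue) a ridge
#' `lambda I` with `lambda = 1e-8 * trace(S)/m` is added before
#' inversion; an all-zero moment component triggers a warning, never a
#' hard failure.
#'
#' @param G_i `N x m` matrix of per-subject moment contributions.
#' @return symmetric positive semi-definite `m x m` weight matrix.
#' @export
weight_matrix <- function(G_i) {
  N <- nrow(G_i)
  S <- crossprod(G_i) / N
  m <- ncol(S)
  zero <- diag(S) == 0
  if (any(zero))
    warning(sprintf("moment component(s) with zero variance: %s",
                    paste(colnames(S)[zero], collapse = ", ")), call. = FALSE)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 0 || max(ev$values) / min(ev$values) > 1e12) {
    lambda <- 1e-8 * sum(diag(S)) / m
    S <- S + diag(lambda, m)
    ev <- eigen(S, symmetric = TRUE)
  }
  W <- ev$vectors %*% (t(ev$vectors) / ev$values)
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(S)
  W
}

# Analytic Jacobian G = d gbar / d beta (m x p).
moment_jacobian <- function(beta, data, design, moments, mu) {
  N <- data$N; T <- data$T
  v <- mu * (1 - mu)
  G <- -crossprod(design$Z, design$Z * v) / N
  ex <- moments$extras
  if (nrow(ex)) {
    v_mat <- matrix(v, N, T, byrow = TRUE)
    G_ext <- t(vapply(seq_len(nrow(ex)), function(k) {
      rows_t <- (seq_len(N) - 1L) * T + ex$out_wave[k]
      w <- data$x_td[, ex$cov_wave[k], ex$covariate[k]] * v_mat[, ex$out_wave[k]]
      -colSums(design$Z[rows_t, , drop = FALSE] * w) / N
    }, numeric(design$p)))
    G <- rbind(G, G_ext)
  }
  G
}

#' Two-step GMM fit of the partitioned model
#'
#' Step 1 estimates `beta` under working independence
#' ([fit_independence()]); the efficient weight matrix `W` is formed from
#' the per-subject moments at that estimate and held fixed; step 2
#' minimizes `Q(beta) = gbar' W gbar` by Gauss-Newton with the analytic
#' gradient `2 G' W gbar` and a backtracking line search, so the
#' objective is non-increasing across accepted steps. Convergence when
#' the gradient norm falls below `grad_tol` or the step below
#' `step_tol`. With a just-identified moment set step 2 leaves the
#' step-1 solution untouched (it already zeroes `gbar`).
#'
#' The asymptotic covariance is `(1/N) (G' W G)^-1`, the
#' over-identification J statistic `N * Q` on `m - p` degrees of
#' freedom, and per-coefficient Wald z, two-sided p, odds ratio
#' `exp(beta)` and 95% CI `exp(beta +/- 1.96 se)` are reported.
#'
#' @param data a [panel_dataset()].
#' @param design a [build_partitioned_design()] result on `data`.
#' @param moments optional [moment_set()]; default is baseline-only
#'   (just-identified). Must be built on the pruned design when columns
#'   are dropped — build it from `fit_independence(data, design)$design`
#'   or let [test_moment_validity()] in the [cli_fit()] pipeline do so.
#' @param control list of tolerances: `max_iter` (200), `grad_tol`
#'   (1e-8), `step_tol` (1e-10).
#' @return An object of class `pgmm_fit`: coefficients table, `beta`,
#'   `vcov`, `objective`, `j_stat`, `df`, `m`, `p`, `moments`,
#'   `convergence`, `dropped`, `N`, `T`.
#' @export
fit_two_step <- function(data, design, moments = NULL, control = list()) {
  ctrl <- utils::modifyList(
    list(max_iter = 200L, grad_tol = 1e-8, step_tol = 1e-10), control)

  step1 <- fit_independence(data, design)
  design <- step1$design
  if (is.null(moments)) moments <- moment_set(design)
  if (moments$p != design$p)
    stop(paste("moment set built on a different design;",
               "rebuild it on fit_independence()$design"), call. = FALSE)

  N <- data$N
  mv1 <- moment_vector(step1$beta, data, design, moments)
  W <- weight_matrix(mv1$G_i)

  beta <- step1$beta
  mv <- mv1
  Q <- drop(crossprod(mv$gbar, W %*% mv$gbar))
  iter <- 0L
  status <- "converged"
  grad_norm <- Inf
  repeat {
    G <- moment_jacobian(beta, data, design, moments, mv$mu)
    Wg <- W %*% mv$gbar
    grad <- drop(2 * crossprod(G, Wg))
    grad_norm <- sqrt(sum(grad^2))
    if (grad_norm < ctrl$grad_tol) break
    if (iter >= ctrl$max_iter) {
      status <- "max_iter"
      break
    }
    A <- crossprod(G, W %*% G)
    delta <- tryCatch(-solve(A, crossprod(G, Wg)),
                      error = function(e) stop(
                        "singular G'WG: consider dropping a design column",
                        call. = FALSE))
    delta <- drop(delta)
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      mv_new <- moment_vector(beta_new, data, design, moments)
      Q_new <- drop(crossprod(mv_new$gbar, W %*% mv_new$gbar))
      if (Q_new <= Q + 1e-14 || step * sqrt(sum(delta^2)) < ctrl$step_tol)
        break
      step <- step / 2
    }
    if (step * sqrt(sum(delta^2)) < ctrl$step_tol) break
    beta <- beta_new
    mv <- mv_new
    Q <- Q_new
    iter <- iter + 1L
  }
  if (status == "max_iter")
    stop(sprintf(
      "two-step GMM failed to converge in %d iterations (|grad| = %.3g, Q = %.3g)",
      ctrl$max_iter, grad_norm, Q), call. = FALSE)

  G <- moment_jacobian(beta, data, design, moments, mv$mu)
  A <- crossprod(G, W %*% G)
  vcov <- tryCatch(solve(A) / N,
                   error = function(e) stop(
                     "singular G'WG at optimum: consider dropping a design column",
                     call. = FALSE))
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(names(beta), names(beta))

  se <- sqrt(pmax(diag(vcov), 0))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  zcrit <- 1.96
  coefs <- data.frame(
    term = names(beta),
    covariate = design$col_info$covariate,
    lag = design$col_info$lag,
    estimate = unname(beta), se = se,
    z = unname(zval), p = unname(pval),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - zcrit * se),
    ci_high = exp(unname(beta) + zcrit * se),
    status = "kept",
    stringsAsFactors = FALSE)

  structure(
    list(coefficients = coefs, beta = beta, vcov = vcov,
         objective = Q, j_stat = N * Q, df = moments$m - moments$p,
         m = moments$m, p = moments$p, moments = moments,
         design_info = design$col_info, dropped = step1$dropped,
         convergence = list(iterations = iter, grad_norm = grad_norm,
                            status = status),
         N = N, T = data$T),
    class = "pgmm_fit")
}

#' @export
print.pgmm_fit <- function(x, ...) {
  cat("Partitioned GMM marginal logistic regression (two-step)\n")
  cat(sprintf("  N = %d subjects, T = %d waves; %d moments, %d coefficients\n",
              x$N, x$T, x$m, x$p))
  if (x$df > 0)
    cat(sprintf("  J statistic = %.3f on %d df (p = %.3f)\n",
                x$j_stat, x$df, stats::pchisq(x$j_stat, x$df,
                                              lower.tail = FALSE)))
  else
    cat(sprintf("  just-identified; objective = %.2e\n", x$objective))
  if (length(x$dropped))
    cat("  dropped columns:", paste(x$dropped, collapse = ", "), "\n")
  cat("\n")
  print(render_results_table(x))
  invisible(x)
}

#' @export
summary.pgmm_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
vcov.pgmm_fit <- function(object, ...) object$vcov

#' @export
coef.pgmm_fit <- function(object, ...) object$beta

#' Per-coefficient Wald table grouped by lag
#'
#' One row per coefficient (dropped columns included with status
#' `"dropped"` and blank statistics), grouped cross-sectional first, then
#' one-, two-, three-(...) period lags, the reporting layout customary
#' for partitioned lag models.
#'
#' @param fit a [fit_two_step()] result.
#' @return data frame with `group`, `covariate`, `lag`, `estimate`, `se`,
#'   `or`, `ci_low`, `ci_high`, `p`, `status`.
#' @export
wald_table <- function(fit) {
  tab <- fit$coefficients
  tab$group <- lag_group_label(tab$lag)
  if (length(fit$dropped)) {
    lab <- fit$dropped
    lag <- suppressWarnings(as.integer(sub(".*\\.lag", "", lab)))
    covariate <- sub("\\.lag[0-9]+$", "", lab)
    tab <- rbind(tab, data.frame(
      term = lab, covariate = covariate, lag = lag,
      estimate = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      status = "dropped", group = lag_group_label(lag),
      stringsAsFactors = FALSE))
  }
  ord <- order(ifelse(is.na(tab$lag), -1L, tab$lag),
               match(tab$covariate, unique(tab$covariate)))
  tab <- tab[ord, c("group", "covariate", "lag", "estimate", "se",
                    "or", "ci_low", "ci_high", "p", "status")]
  rownames(tab) <- NULL
  tab
}
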