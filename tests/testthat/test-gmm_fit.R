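# Brute-force oracle for the sample moment vector: explicit loops over
# subjects, waves and conditions, no shared code with moment_vector().
naive_moment_mean <- function(beta, d, des, ms) {
  N <- d$N; T <- d$T
  g <- matrix(0, N, ms$m)
  for (i in seq_len(N)) {
    for (c in seq_len(des$p)) {
      acc <- 0
      for (t in seq_len(T)) {
        row <- (i - 1) * T + t
        mu <- 1 / (1 + exp(-sum(des$Z[row, ] * beta)))
        acc <- acc + des$Z[row, c] * (d$y[i, t] - mu)
      }
      g[i, c] <- acc
    }
    if (nrow(ms$extras)) for (k in seq_len(nrow(ms$extras))) {
      s <- ms$extras$cov_wave[k]; t <- ms$extras$out_wave[k]
      j <- ms$extras$covariate[k]
      row <- (i - 1) * T + t
      mu <- 1 / (1 + exp(-sum(des$Z[row, ] * beta)))
      g[i, des$p + k] <- d$x_td[i, s, j] * (d$y[i, t] - mu)
    }
  }
  colMeans(g)
}

test_that("the sample moment vector matches a naive double loop", {
  set.seed(21)
  d <- random_panel(N = 9, T = 4, J = 2)
  des <- build_partitioned_design(d, max_lag = 2)
  ms <- moment_set(des, data.frame(
    covariate = c("x1", "x2"), cov_wave = c(4L, 3L), out_wave = c(1L, 1L)))
  beta <- rnorm(des$p, sd = 0.3)
  mv <- moment_vector(beta, d, des, ms)
  expect_equal(unname(mv$gbar), naive_moment_mean(beta, d, des, ms),
               tolerance = 1e-12)
})

test_that("hand-computed single-subject moment components are reproduced", {
  # one subject, one wave: x = 1, y = 1, mu = 0.25 gives component 0.75
  d <- panel_dataset(matrix(1), array(1, c(1, 1, 1),
                                      dimnames = list(NULL, NULL, "x1")))
  des <- subset_design(build_partitioned_design(d, max_lag = 0,
                                                include_fixed = FALSE), 1)
  ms <- moment_set(des)
  mv <- moment_vector(qlogis(0.25), d, des, ms)
  expect_equal(unname(mv$gbar), 0.75)
})

test_that("baseline moments vanish at the independence solution", {
  spec <- synthetic_spec(N = 500, seed = 4)
  d <- generate_panel(spec)
  des <- build_partitioned_design(d)
  s1 <- fit_independence(d, des)
  mv <- moment_vector(s1$beta, d, s1$design, moment_set(s1$design))
  expect_lt(max(abs(mv$gbar)), 1e-8)
})

test_that("the weight matrix inverts the sample second-moment matrix", {
  # symmetric pair: g = (+a, -a) has second moment a^2, weight 1/a^2
  a <- 0.7
  expect_equal(weight_matrix(matrix(c(a, -a), ncol = 1))[1, 1], 1 / a^2)
  # identity second moment -> identity weight
  G <- rbind(c(1, 1), c(1, -1))
  expect_equal(weight_matrix(G), diag(2), ignore_attr = TRUE)
  # random case: W S = I
  set.seed(8)
  G <- matrix(rnorm(200 * 5), 200, 5)
  S <- crossprod(G) / 200
  expect_equal(weight_matrix(G) %*% S, diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # degenerate component is regularized, not fatal
  expect_warning(W <- weight_matrix(cbind(G, 0)), "zero variance")
  expect_true(all(is.finite(W)))
  expect_equal(W, t(W), tolerance = 1e-10)
})

test_that("the analytic moment Jacobian matches central finite differences", {
  set.seed(33)
  d <- random_panel(N = 12, T = 3, J = 2)
  des <- build_partitioned_design(d, max_lag = 1)
  ms <- moment_set(des, data.frame(covariate = "x1", cov_wave = 3L,
                                   out_wave = 1L))
  beta <- rnorm(des$p, sd = 0.2)
  mu <- marginal_mean(beta, des)
  G <- partgmm:::moment_jacobian(beta, d, des, ms, mu)
  h <- 1e-6
  G_fd <- sapply(seq_len(des$p), function(c) {
    bp <- beta; bp[c] <- bp[c] + h
    bm <- beta; bm[c] <- bm[c] - h
    (moment_vector(bp, d, des, ms)$gbar -
       moment_vector(bm, d, des, ms)$gbar) / (2 * h)
  })
  expect_equal(unname(G), unname(G_fd), tolerance = 1e-6)
})

test_that("just-identified two-step GMM reproduces the independence fit", {
  spec <- synthetic_spec(N = 600, seed = 12)
  d <- generate_panel(spec)
  des <- build_partitioned_design(d)
  s1 <- fit_independence(d, des)
  fit <- fit_two_step(d, des)
  expect_equal(fit$beta, s1$beta, tolerance = 1e-6)
  expect_lt(fit$objective, 1e-8)
  expect_equal(fit$df, 0)
  expect_equal(fit$convergence$status, "converged")
})

test_that("estimates recover the generating coefficients at large N", {
  # averaged over a few replications: a single draw of the lag-3
  # coefficient has sampling sd close to the 0.1 bound itself
  est <- NULL
  truth <- NULL
  for (s in 77:81) {
    spec <- synthetic_spec(N = 5000, seed = s)
    truth <- c(spec$beta0, spec$beta_fixed,
               spec$beta_lag[1, ], spec$beta_lag[2, ])
    d <- generate_panel(spec)
    fit <- fit_two_step(d, build_partitioned_design(d))
    est <- rbind(est, unname(fit$beta))
  }
  expect_lt(max(abs(colMeans(est) - truth)), 0.1)
})

test_that("fit results satisfy the reporting invariants", {
  spec <- synthetic_spec(N = 800, seed = 3)
  d <- generate_panel(spec)
  des <- build_partitioned_design(d)
  s1 <- fit_independence(d, des)
  sel <- test_moment_validity(d, s1$design, s1$beta)
  fit <- fit_two_step(d, s1$design, sel$moments)

  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-10)
  expect_gte(min(eigen(fit$vcov, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-12)
  tab <- fit$coefficients
  expect_true(all(tab$or > 0))
  expect_true(all(tab$ci_low <= tab$or & tab$or <= tab$ci_high))
  expect_equal(tab$or, exp(tab$estimate))
  expect_equal(tab$ci_low, exp(tab$estimate - 1.96 * tab$se))
  expect_gte(fit$objective, 0)
  expect_equal(fit$j_stat, fit$N * fit$objective)
  expect_equal(fit$df, fit$m - fit$p)
})

test_that("degenerate columns are dropped and reported absent", {
  set.seed(19)
  y <- matrix(rbinom(120, 1, 0.5), 30, 4)
  x <- array(rbinom(120, 1, 0.5), c(30, 4, 1),
             dimnames = list(NULL, NULL, "x1"))
  x[, 1, 1] <- 0  # covariate absent at wave 1 => lag-3 column all zero
  d <- panel_dataset(y, x)
  des <- build_partitioned_design(d, include_fixed = FALSE)
  expect_warning(s1 <- fit_independence(d, des), "x1.lag3")
  expect_equal(s1$dropped, "x1.lag3")
  expect_warning(fit <- fit_two_step(d, des), "x1.lag3")
  tab <- wald_table(fit)
  drow <- tab[tab$status == "dropped", ]
  expect_equal(drow$covariate, "x1")
  expect_equal(drow$lag, 3L)
  rendered <- render_results_table(fit)
  expect_true(any(rendered$OR == "–"))
})

test_that("estimates are invariant to subject order and equivariant to scaling", {
  spec <- synthetic_spec(N = 500, seed = 25)
  d <- generate_panel(spec)
  fit <- fit_two_step(d, build_partitioned_design(d))

  set.seed(6)
  perm <- sample(d$N)
  dp <- panel_dataset(d$y[perm, ], d$x_td[perm, , , drop = FALSE],
                      d$x_fixed[perm, , drop = FALSE])
  fitp <- fit_two_step(dp, build_partitioned_design(dp))
  expect_equal(fitp$beta, fit$beta, tolerance = 1e-8)

  dc <- d
  dc$x_td[, , 1] <- 2.5 * dc$x_td[, , 1]
  fitc <- fit_two_step(dc, build_partitioned_design(dc))
  sel <- grepl("^x1\\.lag", names(fit$beta))
  expect_equal(fitc$beta[sel], fit$beta[sel] / 2.5, tolerance = 1e-6)
  expect_equal(fitc$beta[!sel], fit$beta[!sel], tolerance = 1e-6)
})

test_that("the Wald table is grouped by lag in reporting order", {
  spec <- synthetic_spec(N = 400, seed = 14)
  d <- generate_panel(spec)
  fit <- fit_two_step(d, build_partitioned_design(d))
  tab <- wald_table(fit)
  expect_equal(unique(tab$group),
               c("Cross sectional", "One time period lag",
                 "Two time period lag", "Three time period lag"))
  expect_equal(nrow(tab), fit$p)
})

test_that("odds-ratio rows render in the OR [CI] p house style", {
  row <- data.frame(group = "Cross sectional", covariate = "pick_book",
                    lag = 0L, estimate = log(4.11), se = 0.15,
                    or = 4.11, ci_low = 3.11, ci_high = 5.43, p = 2e-6,
                    status = "kept")
  out <- render_results_table(row)
  expect_equal(out$OR, "4.11")
  expect_equal(out$CI95, "[3.11, 5.43]")
  expect_equal(out$p, "<0.001")
  # null coefficient with se 0.1: OR 1.00, CI [0.82, 1.22], p ~ 1
  row2 <- within(row, {
    estimate <- 0; or <- 1; se <- 0.1
    ci_low <- exp(-1.96 * 0.1); ci_high <- exp(1.96 * 0.1); p <- 1
  })
  out2 <- render_results_table(row2)
  expect_equal(out2$OR, "1.00")
  expect_equal(out2$CI95, "[0.82, 1.22]")
  expect_equal(out2$p, "1.00")
})

test_that("a moment set from a mismatched design is refused", {
  d <- generate_panel(synthetic_spec(N = 200, seed = 55))
  des3 <- build_partitioned_design(d, max_lag = 3)
  des1 <- build_partitioned_design(d, max_lag = 1)
  expect_error(fit_two_step(d, des3, moment_set(des1)), "design")
})
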