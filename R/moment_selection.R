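#' Standardized outcome residuals at a preliminary estimate
#'
#' Pearson residuals `e[i, t] = (y[i, t] - mu[i, t]) / sqrt(mu (1 - mu))`
#' under the marginal model at `beta`, usually the working-independence
#' estimate from [fit_independence()]. These feed the bivariate
#' correlation test of candidate moment conditions.
#'
#' @param data a [panel_dataset()].
#' @param design a [build_partitioned_design()] result on `data`.
#' @param beta coefficient vector of length `design$p`.
#' @return numeric matrix `N x T` of standardized residuals.
#' @export
standardized_residuals <- function(data, design, beta) {
  mu <- marginal_mean(beta, design)
  eps <- 1e-10
  if (any(mu <= eps | mu >= 1 - eps))
    stop("fitted means at 0 or 1: degenerate fit (possible separation)",
         call. = FALSE)
  mu_mat <- matrix(mu, data$N, data$T, byrow = TRUE)
  (data$y - mu_mat) / sqrt(mu_mat * (1 - mu_mat))
}

#' Selected moment conditions
#'
#' Bundles the `p` baseline (identifying) conditions — one per design
#' column, pairing the column with the residual of its own rows — with
#' zero or more extra over-identifying conditions, each the product of a
#' covariate value at wave `s` with the residual at a different wave `t`.
#' Extras never duplicate a baseline pairing: pairs with
#' `0 < t - s <= max_lag` are already aggregated inside the baseline lag
#' columns and are rejected here.
#'
#' @param design a [build_partitioned_design()] result (defines the
#'   baseline conditions and `max_lag`).
#' @param extras optional data frame with columns `covariate`,
#'   `cov_wave`, `out_wave`.
#' @return An object of class `moment_set`: list with `baseline` (the
#'   design's `col_info`), `extras`, `p`, `m`, `max_lag`.
#' @export
moment_set <- function(design, extras = NULL) {
  if (is.null(extras))
    extras <- data.frame(covariate = character(0), cov_wave = integer(0),
                         out_wave = integer(0), stringsAsFactors = FALSE)
  stopifnot(all(c("covariate", "cov_wave", "out_wave") %in% names(extras)))
  if (nrow(extras)) {
    if (any(extras$cov_wave == extras$out_wave))
      stop("an extra moment cannot pair a covariate with its own wave",
           call. = FALSE)
    d <- extras$out_wave - extras$cov_wave
    if (any(d > 0 & d <= design$max_lag))
      stop("extra duplicates a baseline lag pairing", call. = FALSE)
    if (anyDuplicated(extras[c("covariate", "cov_wave", "out_wave")]))
      stop("duplicate extra moments", call. = FALSE)
    if (any(extras$cov_wave < 1 | extras$cov_wave > design$T |
            extras$out_wave < 1 | extras$out_wave > design$T))
      stop("extra moment wave out of range", call. = FALSE)
  }
  structure(
    list(baseline = design$col_info, extras = extras,
         p = design$p, m = design$p + nrow(extras),
         max_lag = design$max_lag),
    class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("Moment set: %d conditions = %d baseline + %d extra\n",
              x$m, x$p, nrow(x$extras)))
  invisible(x)
}

# Fisher z test of a sample correlation against rho = 0, two-sided.
fisher_z_test <- function(r, n) {
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(n - 3)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Screen candidate lagged moment conditions for validity
#'
#' A pairing of a time-dependent covariate value at wave `s` with the
#' outcome residual at wave `t` is a candidate moment condition
#' `E[x_ijs (y_it - mu_it)] = 0` when it is not already part of the
#' baseline estimating equations: candidates are the future-covariate
#' pairs `s > t` (the ones outcome-to-covariate feedback invalidates)
#' and the long-lag pairs `t - s > max_lag`. Cross-sectional pairings
#' (`s = t`) are assumed valid, and pairings with `0 < t - s <= max_lag`
#' are components of the baseline lag-column conditions — both are
#' enforced by estimation, so their sample correlations with the fitted
#' residuals are zero by construction and testing them is vacuous.
#'
#' Each candidate is tested with the Pearson correlation across subjects
#' between `x[, s, j]` and the standardized residual `e[, t]`, via the
#' Fisher z transformation (`z = atanh(r) * sqrt(N - 3)`), two-sided
#' against `rho = 0`. A candidate is declared valid when not rejected at
#' level `alpha`; valid candidates become the over-identifying extras of
#' the returned [moment_set()].
#'
#' @param data a [panel_dataset()].
#' @param design a [build_partitioned_design()] result on `data`.
#' @param beta0 preliminary coefficient estimate (working-independence
#'   fit) at which residuals are computed.
#' @param alpha test level in (0, 1).
#' @param adjust multiplicity adjustment across candidates, passed to
#'   [stats::p.adjust()] (`"none"` default, `"bonferroni"`, ...).
#' @return list with `tests` (data frame: `covariate`, `cov_wave`,
#'   `out_wave`, `lag`, `n`, `r`, `z`, `p`, `verdict`) of class
#'   `moment_test_result`, and `moments`, the resulting [moment_set()].
#' @export
test_moment_validity <- function(data, design, beta0, alpha = 0.05,
                                 adjust = "none") {
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  e <- standardized_residuals(data, design, beta0)
  T <- data$T; J <- data$J; N <- data$N

  grid <- expand.grid(cov_wave = seq_len(T), out_wave = seq_len(T),
                      j = seq_len(J))
  d <- grid$out_wave - grid$cov_wave
  grid <- grid[d < 0 | d > design$max_lag, , drop = FALSE]

  rows <- vector("list", nrow(grid))
  skipped <- 0L
  for (i in seq_len(nrow(grid))) {
    s <- grid$cov_wave[i]; t <- grid$out_wave[i]; j <- grid$j[i]
    x <- data$x_td[, s, j]
    if (stats::sd(x) == 0 || stats::sd(e[, t]) == 0) {
      skipped <- skipped + 1L
      next
    }
    r <- stats::cor(x, e[, t])
    rows[[i]] <- data.frame(
      covariate = td_names(data)[j], cov_wave = s, out_wave = t,
      lag = t - s, n = N, r = r, stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(sprintf(
      "%d candidate(s) excluded for zero variance in covariate or residual",
      skipped), call. = FALSE)
  tests <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tests) || nrow(tests) == 0L)
    return(list(tests = NULL, moments = moment_set(design)))

  ft <- fisher_z_test(tests$r, N)
  tests$z <- ft$z
  tests$p <- ft$p
  tests$p_adjusted <- stats::p.adjust(tests$p, method = adjust)
  tests$verdict <- ifelse(tests$p_adjusted >= alpha, "valid", "invalid")
  attr(tests, "alpha") <- alpha
  attr(tests, "adjust") <- adjust
  class(tests) <- c("moment_test_result", "data.frame")

  cand <- tests[tests$verdict == "valid", , drop = FALSE]
  extras <- cand[, c("covariate", "cov_wave", "out_wave")]
  rownames(extras) <- NULL
  list(tests = tests, moments = moment_set(design, extras))
}

#' @export
print.moment_test_result <- function(x, ...) {
  cat(sprintf(
    "Moment-validity tests (%d candidates, alpha = %g, adjust = %s)\n",
    nrow(x), attr(x, "alpha"), attr(x, "adjust")))
  cat(sprintf("  invalid: %d\n", sum(x$verdict == "invalid")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Write moment-test results to CSV
#' @param tests a `moment_test_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_moment_tests_csv <- function(tests, path) {
  utils::write.csv(as.data.frame(tests), path, row.names = FALSE)
  invisible(path)
}
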