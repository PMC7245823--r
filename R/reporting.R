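#' Per-wave descriptive percentages
#'
#' Percentage of ones per wave for the outcome and every covariate
#' (fixed covariates repeat their value across waves), the usual
#' first-look table for a binary panel.
#'
#' @param data a [panel_dataset()].
#' @return data frame: `variable`, `role`, one `wave_<label>` column per
#'   wave, percentages rounded to 2 decimals.
#' @export
descriptive_table <- function(data) {
  wave_cols <- paste0("wave_", data$wave_labels)
  rows <- list(data.frame(
    variable = data$outcome_name, role = "outcome",
    t(round(100 * colMeans(data$y), 2)), stringsAsFactors = FALSE))
  for (j in seq_len(data$J))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = td_names(data)[j], role = "time_dependent",
      t(round(100 * colMeans(data$x_td[, , j, drop = FALSE][, , 1]), 2)),
      stringsAsFactors = FALSE)
  if (data$F > 0)
    for (f in seq_len(data$F))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = colnames(data$x_fixed)[f], role = "fixed",
        t(rep(round(100 * mean(data$x_fixed[, f]), 2), data$T)),
        stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  names(out)[-(1:2)] <- wave_cols
  rownames(out) <- NULL
  out
}

format_p <- function(p) ifelse(is.na(p), "–",
                               ifelse(p < 0.001, "<0.001", sprintf("%.2f", p)))

#' Render a fit as a grouped odds-ratio text table
#'
#' One row per coefficient, grouped cross-sectional / one / two / three
#' time period lag, formatted `OR [low, high] p`; p-values below 0.001
#' render as `<0.001` and dropped coefficients as a dash.
#'
#' @param fit a [fit_two_step()] result (or a [wald_table()] data frame).
#' @return character matrix-like data frame ready for printing.
#' @export
render_results_table <- function(fit) {
  tab <- if (inherits(fit, "pgmm_fit")) wald_table(fit) else fit
  dash <- "–"
  data.frame(
    group = tab$group,
    covariate = tab$covariate,
    OR = ifelse(is.na(tab$or), dash, sprintf("%.2f", tab$or)),
    `CI95` = ifelse(is.na(tab$or), dash,
                    sprintf("[%.2f, %.2f]", tab$ci_low, tab$ci_high)),
    p = format_p(tab$p),
    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Sign summary of significant effects
#'
#' Marks `+` where `p < alpha` and OR > 1, `-` where `p < alpha` and
#' OR < 1, blank otherwise — the compact effect-direction overview by
#' covariate and lag.
#'
#' @param fit a [fit_two_step()] result.
#' @param alpha significance threshold (default 0.05).
#' @return data frame, covariates in rows, lag groups in columns.
#' @export
sign_summary <- function(fit, alpha = 0.05) {
  tab <- wald_table(fit)
  tab <- tab[!is.na(tab$lag), , drop = FALSE]
  tab$mark <- ifelse(is.na(tab$p) | tab$p >= alpha, "",
                     ifelse(tab$or > 1, "+", "-"))
  out <- stats::reshape(
    tab[, c("covariate", "group", "mark")],
    idvar = "covariate", timevar = "group", direction = "wide")
  names(out) <- sub("^mark\\.", "", names(out))
  rownames(out) <- NULL
  out
}

#' Write fit results to CSV
#'
#' One row per coefficient (`name`, `lag`, `estimate`, `se`, `or`,
#' `ci_low`, `ci_high`, `p`, `status`); fit metadata (`m`, `p`,
#' `j_stat`, `df`, `objective`, `iterations`) goes to a JSON sidecar of
#' the same stem.
#'
#' @param fit a [fit_two_step()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(fit, path) {
  utils::write.csv(wald_table(fit), path, row.names = FALSE)
  meta <- list(N = fit$N, T = fit$T, m = fit$m, p = fit$p,
               j_stat = fit$j_stat, df = fit$df,
               objective = fit$objective,
               iterations = fit$convergence$iterations,
               dropped = fit$dropped)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the full estimation pipeline from a config
#'
#' Read the long CSV, build the partitioned design, fit the
#' working-independence step, screen moment validity, fit two-step GMM,
#' and write `moments.csv`, `results.csv`, `results.json` and a rendered
#' `results.txt` into the output directory. Progress and the panel/fit
#' dimensions are logged via [message()] (stderr).
#'
#' Config keys: `input`, `columns` (mapping for [read_long_csv()]),
#' `max_lag` (default `T - 1`), `alpha` (0.05), `adjust` ("none"),
#' `drop_incomplete` (FALSE), `wave_effects` (FALSE), `out_dir` (".").
#'
#' @param config list or YAML/JSON file path.
#' @return invisibly, list with the fit, tests and output paths.
#' @export
cli_fit <- function(config) {
  cfg <- resolve_config(config)
  for (key in c("input", "columns"))
    if (is.null(cfg[[key]]))
      stop(sprintf("config is missing key '%s'", key), call. = FALSE)
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  adjust <- if (is.null(cfg$adjust)) "none" else cfg$adjust
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)

  data <- read_long_csv(cfg$input, cfg$columns,
                        drop_incomplete = isTRUE(cfg$drop_incomplete))
  max_lag <- if (is.null(cfg$max_lag)) data$T - 1L else as.integer(cfg$max_lag)
  message(sprintf("panel: N = %d, T = %d, J = %d", data$N, data$T, data$J))

  design <- build_partitioned_design(data, max_lag = max_lag,
                                     wave_effects = isTRUE(cfg$wave_effects))
  step1 <- fit_independence(data, design)
  if (length(step1$dropped))
    message("dropped columns: ", paste(step1$dropped, collapse = ", "))
  sel <- test_moment_validity(data, step1$design, step1$beta,
                              alpha = alpha, adjust = adjust)
  message(sprintf("moments: m = %d (%d baseline + %d extra)",
                  sel$moments$m, sel$moments$p, nrow(sel$moments$extras)))
  fit <- fit_two_step(data, step1$design, sel$moments)
  message(sprintf("converged in %d iteration(s); J = %.3f on %d df",
                  fit$convergence$iterations, fit$j_stat, fit$df))
  fit$dropped <- step1$dropped

  moments_path <- file.path(out_dir, "moments.csv")
  results_path <- file.path(out_dir, "results.csv")
  text_path <- file.path(out_dir, "results.txt")
  if (!is.null(sel$tests)) write_moment_tests_csv(sel$tests, moments_path)
  write_results_csv(fit, results_path)
  writeLines(utils::capture.output(print(render_results_table(fit))),
             text_path)
  invisible(list(fit = fit, tests = sel$tests, moments = sel$moments,
                 paths = c(moments = moments_path, results = results_path,
                           text = text_path)))
}

#' Simulate a panel from a spec file and write it to CSV
#'
#' The spec file (YAML/JSON) carries [synthetic_spec()] arguments
#' (`beta_lag` as a list of rows). Writes the long CSV plus a YAML echo
#' of the spec alongside (`<out>.spec.yaml`); byte-identical for the
#' same seed.
#'
#' @param spec a [synthetic_spec()], or a list/file of its arguments.
#' @param out output CSV path.
#' @return invisibly, the generated [panel_dataset()].
#' @export
cli_simulate <- function(spec, out) {
  if (!inherits(spec, "synthetic_spec")) {
    args <- resolve_config(spec)
    if (!is.null(args$beta_lag))
      args$beta_lag <- do.call(rbind, args$beta_lag)
    spec <- do.call(synthetic_spec, args)
  }
  data <- generate_panel(spec)
  write_long_csv(data, out)
  echo <- unclass(spec)
  echo$beta_lag <- lapply(seq_len(nrow(spec$beta_lag)),
                          function(j) spec$beta_lag[j, ])
  echo$covariates <- lapply(spec$covariates, function(cfg) lapply(cfg, c))
  yaml::write_yaml(echo, paste0(out, ".spec.yaml"))
  message(sprintf("wrote %d rows to %s", spec$N * spec$T, out))
  invisible(data)
}

#' Write the descriptive table for a long CSV
#'
#' @param input CSV path.
#' @param columns mapping for [read_long_csv()], or a full run config
#'   whose `columns` entry holds the mapping.
#' @param out output CSV path.
#' @return invisibly, the descriptive data frame.
#' @export
cli_describe <- function(input, columns, out) {
  columns <- resolve_config(columns)
  if (!is.null(columns$columns)) columns <- columns$columns
  data <- read_long_csv(input, columns)
  tab <- descriptive_table(data)
  utils::write.csv(tab, out, row.names = FALSE)
  invisible(tab)
}
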