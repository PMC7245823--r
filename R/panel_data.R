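#' Balanced longitudinal binary panel
#'
#' Container for a balanced panel of `N` subjects observed at waves
#' `1..T`, with a binary outcome `y[i, t]`, optional time-independent
#' covariates and `J` time-dependent covariates `x[i, t, j]`.
#'
#' @param y integer/numeric matrix `N x T` of 0/1 outcomes, one row per
#'   subject, one column per wave.
#' @param x_td numeric array `N x T x J` of time-dependent covariates.
#'   The third dimension may carry covariate names via `dimnames`.
#' @param x_fixed optional numeric matrix `N x F` of time-independent
#'   covariates (or a vector, taken as a single column).
#' @param subject_ids optional vector of subject identifiers, length `N`.
#' @param wave_labels optional vector of original wave labels, length `T`
#'   (e.g. calendar years); waves are always indexed ordinally `1..T`.
#' @param outcome_name name used for the outcome in reports.
#'
#' @return An object of class `panel_dataset`: a list with elements
#'   `y`, `x_td`, `x_fixed`, `subject_ids`, `wave_labels`, `outcome_name`
#'   and the dimensions `N`, `T`, `J`, `F`.
#' @export
panel_dataset <- function(y, x_td, x_fixed = NULL, subject_ids = NULL,
                          wave_labels = NULL, outcome_name = "y") {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  N <- nrow(y)
  T <- ncol(y)
  if (N < 1L || T < 1L)
    stop("panel must have at least one subject and one wave", call. = FALSE)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1 with no missing values", call. = FALSE)

  if (length(dim(x_td)) != 3L)
    stop("'x_td' must be an N x T x J array", call. = FALSE)
  if (dim(x_td)[1] != N || dim(x_td)[2] != T)
    stop("'x_td' dimensions do not match the outcome matrix", call. = FALSE)
  if (anyNA(x_td))
    stop("missing time-dependent covariate values are not supported",
         call. = FALSE)
  J <- dim(x_td)[3]
  if (J < 1L)
    stop("at least one time-dependent covariate is required", call. = FALSE)
  td_names <- dimnames(x_td)[[3]]
  if (is.null(td_names)) td_names <- paste0("x", seq_len(J))
  dimnames(x_td) <- list(NULL, NULL, td_names)

  if (!is.null(x_fixed)) {
    x_fixed <- as.matrix(x_fixed)
    if (nrow(x_fixed) != N)
      stop("'x_fixed' must have one row per subject", call. = FALSE)
    if (anyNA(x_fixed))
      stop("missing fixed-covariate values are not supported", call. = FALSE)
    if (is.null(colnames(x_fixed)))
      colnames(x_fixed) <- paste0("f", seq_len(ncol(x_fixed)))
  } else {
    x_fixed <- matrix(numeric(0), nrow = N, ncol = 0)
  }

  if (is.null(subject_ids)) subject_ids <- seq_len(N)
  if (length(subject_ids) != N || anyDuplicated(subject_ids))
    stop("'subject_ids' must be unique, one per subject", call. = FALSE)
  if (is.null(wave_labels)) wave_labels <- seq_len(T)
  if (length(wave_labels) != T)
    stop("'wave_labels' must have length T", call. = FALSE)

  structure(
    list(y = y, x_td = x_td, x_fixed = x_fixed,
         subject_ids = subject_ids, wave_labels = wave_labels,
         outcome_name = outcome_name,
         N = N, T = T, J = J, F = ncol(x_fixed)),
    class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf(
    "Balanced binary panel: %d subjects x %d waves (%d records)\n",
    x$N, x$T, x$N * x$T))
  cat(sprintf("  outcome: %s, prevalence by wave: %s\n", x$outcome_name,
              paste(sprintf("%.3f", colMeans(x$y)), collapse = " ")))
  cat(sprintf("  time-dependent covariates (J = %d): %s\n", x$J,
              paste(dimnames(x$x_td)[[3]], collapse = ", ")))
  if (x$F > 0)
    cat(sprintf("  time-independent covariates (F = %d): %s\n", x$F,
                paste(colnames(x$x_fixed), collapse = ", ")))
  invisible(x)
}

#' Names of the time-dependent covariates
#' @param data a [panel_dataset()].
#' @return character vector of length `J`.
#' @export
td_names <- function(data) dimnames(data$x_td)[[3]]

#' Keep a subset of waves
#'
#' Slices a panel down to the given waves (re-indexed `1..T'`). A
#' single-wave slice yields an ordinary cross-sectional dataset.
#'
#' @param data a [panel_dataset()].
#' @param waves integer vector of wave indices to keep, in order.
#' @return a [panel_dataset()] with `T = length(waves)`.
#' @export
subset_waves <- function(data, waves) {
  waves <- as.integer(waves)
  if (any(waves < 1L | waves > data$T))
    stop("wave indices out of range", call. = FALSE)
  panel_dataset(
    y = data$y[, waves, drop = FALSE],
    x_td = data$x_td[, waves, , drop = FALSE],
    x_fixed = if (data$F > 0) data$x_fixed else NULL,
    subject_ids = data$subject_ids,
    wave_labels = data$wave_labels[waves],
    outcome_name = data$outcome_name)
}

# YAML 1.1 treats bare N/T/y/n as booleans, which collides with natural
# key and column names here; keep single-letter scalars literal and only
# honour unambiguous boolean spellings.
yaml_bool_handler <- function(x) {
  low <- tolower(x)
  if (nchar(x) > 1 && low %in% c("true", "yes", "on")) TRUE
  else if (nchar(x) > 1 && low %in% c("false", "no", "off")) FALSE
  else x
}

read_yaml_config <- function(path) {
  yaml::read_yaml(path, handlers = list("bool#yes" = yaml_bool_handler,
                                        "bool#no" = yaml_bool_handler))
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else read_yaml_config(config)
  }
  if (!is.list(config))
    stop("'config' must be a list or a YAML/JSON file path", call. = FALSE)
  config
}

#' Read a long-format panel CSV
#'
#' One row per (subject, wave). The column mapping names the id, wave and
#' outcome columns plus the fixed and time-dependent covariate columns;
#' it may be given as a list or as a path to a YAML/JSON file with keys
#' `id`, `wave`, `outcome`, `fixed` (optional), `time_dependent`.
#'
#' Wave labels are mapped ordinally to `1..T` in ascending order; calendar
#' spacing is ignored. By default an unbalanced panel is an error; with
#' `drop_incomplete = TRUE` subjects lacking any wave are dropped with a
#' message reporting the count.
#'
#' @param path CSV file path.
#' @param config column mapping (list or YAML/JSON path).
#' @param drop_incomplete drop subjects that do not appear in every wave
#'   instead of failing.
#' @return a [panel_dataset()].
#' @export
read_long_csv <- function(path, config, drop_incomplete = FALSE) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  config <- resolve_config(config)
  for (key in c("id", "wave", "outcome", "time_dependent"))
    if (is.null(config[[key]]))
      stop(sprintf("column mapping is missing key '%s'", key), call. = FALSE)
  fixed_cols <- unlist(config$fixed)
  td_cols <- unlist(config$time_dependent)

  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c(config$id, config$wave, config$outcome, fixed_cols, td_cols)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop(sprintf("input lacks mapped column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)

  wave_labels <- sort(unique(df[[config$wave]]))
  T <- length(wave_labels)
  df$.wave <- match(df[[config$wave]], wave_labels)

  counts <- table(df[[config$id]])
  per_subject_ok <- vapply(split(df$.wave, df[[config$id]]), function(w)
    length(w) == T && !anyDuplicated(w), logical(1))
  if (!all(per_subject_ok)) {
    bad <- names(per_subject_ok)[!per_subject_ok]
    if (!drop_incomplete)
      stop(sprintf(
        "unbalanced panel: subject(s) without exactly one record per wave: %s",
        paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    message(sprintf("dropping %d incomplete subject(s)", length(bad)))
    df <- df[!(df[[config$id]] %in% bad), , drop = FALSE]
  }

  ids <- sort(unique(df[[config$id]]))
  N <- length(ids)
  if (N == 0L) stop("no complete subjects remain", call. = FALSE)
  df <- df[order(match(df[[config$id]], ids), df$.wave), , drop = FALSE]

  yv <- df[[config$outcome]]
  if (anyNA(yv) || !all(yv %in% c(0, 1)))
    stop(sprintf("outcome column '%s' is not binary 0/1", config$outcome),
         call. = FALSE)
  y <- matrix(as.double(yv), nrow = N, ncol = T, byrow = TRUE)

  J <- length(td_cols)
  x_td <- array(NA_real_, c(N, T, J), dimnames = list(NULL, NULL, td_cols))
  for (j in seq_len(J))
    x_td[, , j] <- matrix(as.double(df[[td_cols[j]]]), N, T, byrow = TRUE)

  x_fixed <- NULL
  if (length(fixed_cols)) {
    x_fixed <- matrix(NA_real_, N, length(fixed_cols),
                      dimnames = list(NULL, fixed_cols))
    for (f in seq_along(fixed_cols)) {
      m <- matrix(as.double(df[[fixed_cols[f]]]), N, T, byrow = TRUE)
      if (any(apply(m, 1, function(r) length(unique(r)) > 1L)))
        stop(sprintf("column '%s' varies within subject; not time-independent",
                     fixed_cols[f]), call. = FALSE)
      x_fixed[, f] <- m[, 1]
    }
  }

  panel_dataset(y, x_td, x_fixed, subject_ids = ids,
                wave_labels = wave_labels, outcome_name = config$outcome)
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_long_csv()]: one row per (subject, wave), columns
#' `id`, `wave`, the outcome, fixed covariates and time-dependent
#' covariates. Reading the file back with the matching column mapping
#' reproduces the panel exactly.
#'
#' @param data a [panel_dataset()].
#' @param path output CSV path.
#' @return the column-mapping list for [read_long_csv()], invisibly.
#' @export
write_long_csv <- function(data, path) {
  N <- data$N; T <- data$T
  df <- data.frame(
    id = rep(data$subject_ids, each = T),
    wave = rep(data$wave_labels, times = N))
  df[[data$outcome_name]] <- as.vector(t(data$y))
  if (data$F > 0)
    for (f in seq_len(data$F))
      df[[colnames(data$x_fixed)[f]]] <- rep(data$x_fixed[, f], each = T)
  for (j in seq_len(data$J))
    df[[td_names(data)[j]]] <- as.vector(t(data$x_td[, , j]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(list(id = "id", wave = "wave", outcome = data$outcome_name,
                 fixed = if (data$F > 0) colnames(data$x_fixed),
                 time_dependent = td_names(data)))
}

#' Build the partitioned (lower-triangular lagged) design matrix
#'
#' For each time-dependent covariate the subject-level `T x T`
#' lower-triangular expansion is stacked: the lag-`k` column holds the
#' covariate's value `k` waves before the outcome wave, and a structural
#' zero in rows whose wave `t <= k`. Columns are ordered intercept,
#' optional wave indicators, fixed covariates, then each covariate's
#' lag-0..lag-`max_lag` block. The effect of a covariate is thereby
#' partitioned into a cross-sectional coefficient and one coefficient per
#' lag. No column is dropped here, even if degenerate; rank handling
#' happens at fit time.
#'
#' @param data a [panel_dataset()].
#' @param max_lag largest lag included, `0 <= max_lag <= T - 1`. Default
#'   `T - 1` (the full partition).
#' @param include_fixed include the time-independent covariate columns.
#' @param wave_effects add indicator columns for waves `2..T` (a
#'   wave-varying intercept); off by default, matching the single-intercept
#'   marginal model.
#' @return An object of class `partitioned_design`: list with `Z` (the
#'   `N*T x p` matrix, rows ordered subject-major then wave), `col_info`
#'   (data frame: `label`, `covariate`, `lag`, `type`), `row_index`
#'   (data frame: `subject`, `wave`), `max_lag`, `N`, `T`, `p`.
#' @export
build_partitioned_design <- function(data, max_lag = data$T - 1L,
                                     include_fixed = TRUE,
                                     wave_effects = FALSE) {
  N <- data$N; T <- data$T; J <- data$J
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag > T - 1L)
    stop(sprintf("max_lag must be in [0, %d]", T - 1L), call. = FALSE)

  cols <- list(rep(1, N * T))
  info <- data.frame(label = "(Intercept)", covariate = "(Intercept)",
                     lag = NA_integer_, type = "intercept",
                     stringsAsFactors = FALSE)

  if (wave_effects && T > 1L) {
    for (t in 2:T) {
      m <- matrix(0, N, T); m[, t] <- 1
      cols[[length(cols) + 1L]] <- as.vector(t(m))
      info <- rbind(info, data.frame(
        label = paste0("wave", t), covariate = paste0("wave", t),
        lag = NA_integer_, type = "wave", stringsAsFactors = FALSE))
    }
  }

  if (include_fixed && data$F > 0) {
    for (f in seq_len(data$F)) {
      cols[[length(cols) + 1L]] <- rep(data$x_fixed[, f], each = T)
      info <- rbind(info, data.frame(
        label = colnames(data$x_fixed)[f],
        covariate = colnames(data$x_fixed)[f],
        lag = NA_integer_, type = "fixed", stringsAsFactors = FALSE))
    }
  }

  for (j in seq_len(J)) {
    for (k in 0:max_lag) {
      m <- matrix(0, N, T)
      m[, (k + 1L):T] <- data$x_td[, seq_len(T - k), j]
      cols[[length(cols) + 1L]] <- as.vector(t(m))
      info <- rbind(info, data.frame(
        label = paste0(td_names(data)[j], ".lag", k),
        covariate = td_names(data)[j],
        lag = k, type = "td", stringsAsFactors = FALSE))
    }
  }

  Z <- do.call(cbind, cols)
  colnames(Z) <- info$label
  structure(
    list(Z = Z, col_info = info,
         row_index = data.frame(
           subject = rep(data$subject_ids, each = T),
           wave = rep(seq_len(T), times = N)),
         max_lag = max_lag, N = N, T = T, p = ncol(Z)),
    class = "partitioned_design")
}

#' @export
print.partitioned_design <- function(x, ...) {
  cat(sprintf("Partitioned design: %d rows x %d columns (max lag %d)\n",
              nrow(x$Z), x$p, x$max_lag))
  cat("  columns:", paste(x$col_info$label, collapse = ", "), "\n")
  invisible(x)
}

#' Keep a subset of design columns
#'
#' @param design a [build_partitioned_design()] result.
#' @param keep integer or logical index of columns to keep.
#' @return a `partitioned_design` restricted to those columns.
#' @export
subset_design <- function(design, keep) {
  design$Z <- design$Z[, keep, drop = FALSE]
  design$col_info <- design$col_info[keep, , drop = FALSE]
  rownames(design$col_info) <- NULL
  design$p <- ncol(design$Z)
  design
}

#' Marginal mean under the partitioned logistic model
#'
#' Row-wise inverse-logit of the linear predictor `Z %*% beta`.
#'
#' @param beta coefficient vector, length `p`.
#' @param design a [build_partitioned_design()] result.
#' @return numeric vector of fitted probabilities, one per design row.
#' @export
marginal_mean <- function(beta, design) {
  if (length(beta) != design$p)
    stop(sprintf("beta has length %d but the design has %d columns",
                 length(beta), design$p), call. = FALSE)
  stats::plogis(drop(design$Z %*% beta))
}

outcome_vector <- function(data) as.vector(t(data$y))
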