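# Small panels built in code for unit tests.

# 2 subjects x 4 waves, 1 binary time-dependent covariate, known values.
tiny_panel <- function() {
  y <- rbind(c(1, 0, 1, 1),
             c(0, 1, 1, 0))
  x <- array(0, c(2, 4, 1), dimnames = list(NULL, NULL, "x1"))
  x[1, , 1] <- c(1, 0, 1, 1)
  x[2, , 1] <- c(0, 1, 0, 1)
  panel_dataset(y, x, x_fixed = matrix(c(1, 0), ncol = 1,
                                       dimnames = list(NULL, "male")))
}

# Random balanced panel with continuous covariates for property tests.
random_panel <- function(N, T, J, F = 1L) {
  y <- matrix(rbinom(N * T, 1, 0.5), N, T)
  x <- array(rnorm(N * T * J), c(N, T, J),
             dimnames = list(NULL, NULL, paste0("x", seq_len(J))))
  xf <- if (F > 0) matrix(rnorm(N * F), N, F) else NULL
  panel_dataset(y, x, x_fixed = xf)
}

tiny_csv <- function(path, wave_labels = 1:4) {
  d <- tiny_panel()
  d$wave_labels <- wave_labels
  write_long_csv(d, path)
}
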