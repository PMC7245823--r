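test_that("long CSV reading validates shape and maps waves ordinally", {
  path <- withr::local_tempfile(fileext = ".csv")
  cfg <- tiny_csv(path, wave_labels = c(2005, 2008, 2011, 2014))

  d <- read_long_csv(path, cfg)
  expect_s3_class(d, "panel_dataset")
  expect_equal(c(d$N, d$T, d$J, d$F), c(2L, 4L, 1L, 1L))
  expect_equal(d$wave_labels, c(2005, 2008, 2011, 2014))

  # waves are used ordinally regardless of labels
  d2 <- read_long_csv(path, cfg)
  expect_equal(d2$y, d$y)

  # missing mapped column is a configuration error
  bad <- cfg; bad$outcome <- "nope"
  expect_error(read_long_csv(path, bad), "nope")

  # non-binary outcome is a data error
  df <- utils::read.csv(path)
  df$y[1] <- 2
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_long_csv(path2, cfg), "binary")
})

test_that("unbalanced subjects are rejected in strict mode, droppable otherwise", {
  path <- withr::local_tempfile(fileext = ".csv")
  cfg <- tiny_csv(path)
  df <- utils::read.csv(path)
  df <- df[!(df$id == 1 & df$wave == 3), ]  # subject 1 misses wave 3
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)

  expect_error(read_long_csv(path2, cfg), "unbalanced.*1")
  expect_message(d <- read_long_csv(path2, cfg, drop_incomplete = TRUE),
                 "dropping 1")
  expect_equal(d$N, 1L)
  expect_equal(d$subject_ids, 2)
})

test_that("writing and re-reading a panel is an exact round trip", {
  set.seed(11)
  d <- random_panel(N = 7, T = 3, J = 2, F = 2)
  d$y[] <- rbinom(21, 1, 0.4)
  path <- withr::local_tempfile(fileext = ".csv")
  cfg <- write_long_csv(d, path)
  d2 <- read_long_csv(path, cfg)
  expect_equal(d2$y, d$y)
  expect_equal(unname(d2$x_td), unname(d$x_td), tolerance = 1e-12)
  expect_equal(unname(d2$x_fixed), unname(d$x_fixed), tolerance = 1e-12)
})

test_that("the lower-triangular block matches the worked example", {
  d <- tiny_panel()  # subject 1 has x = (1, 0, 1, 1)
  des <- build_partitioned_design(d, max_lag = 3)
  block <- des$Z[1:4, paste0("x1.lag", 0:3)]
  expect_equal(unname(block),
               rbind(c(1, 0, 0, 0),
                     c(0, 1, 0, 0),
                     c(1, 0, 1, 0),
                     c(1, 1, 0, 1)))
  expect_true(all(des$Z[, "(Intercept)"] == 1))
  expect_equal(des$Z[1:4, "male"], rep(1, 4), ignore_attr = TRUE)
})

test_that("lag-k design entries equal x at wave t-k for t > k and 0 otherwise", {
  set.seed(42)
  for (rep in 1:10) {
    N <- sample(3:8, 1); T <- sample(2:5, 1); J <- sample(1:3, 1)
    d <- random_panel(N, T, J)
    max_lag <- sample(0:(T - 1), 1)
    des <- build_partitioned_design(d, max_lag = max_lag)
    expect_lte(des$p, 1 + d$F + J * T)
    expect_equal(des$p, 1 + d$F + J * (max_lag + 1))
    for (j in seq_len(J)) for (k in 0:max_lag) {
      col <- des$Z[, paste0("x", j, ".lag", k)]
      for (i in seq_len(N)) for (t in seq_len(T)) {
        expected <- if (t > k) unname(d$x_td[i, t - k, j]) else 0
        expect_identical(unname(col[(i - 1) * T + t]), expected)
      }
    }
  }
})

test_that("design construction is invariant to subject order up to row permutation", {
  set.seed(7)
  d <- random_panel(N = 6, T = 4, J = 2)
  perm <- sample(6)
  dp <- panel_dataset(d$y[perm, ], d$x_td[perm, , , drop = FALSE],
                      d$x_fixed[perm, , drop = FALSE],
                      subject_ids = d$subject_ids[perm])
  des <- build_partitioned_design(d)
  desp <- build_partitioned_design(dp)
  rows <- as.vector(t(matrix(seq_len(24), 6, 4, byrow = TRUE)[perm, ]))
  expect_equal(unname(desp$Z), unname(des$Z[rows, ]))
})

test_that("max_lag 0 reduces to a cross-sectional logistic design", {
  d <- tiny_panel()
  des <- build_partitioned_design(d, max_lag = 0)
  expect_equal(des$col_info$label, c("(Intercept)", "male", "x1.lag0"))
  expect_equal(des$Z[, "x1.lag0"], as.vector(t(d$x_td[, , 1])),
               ignore_attr = TRUE)
})

test_that("marginal means are the row-wise inverse logit", {
  d <- tiny_panel()
  des <- build_partitioned_design(d)
  expect_equal(marginal_mean(rep(0, des$p), des), rep(0.5, 8))
  b <- c(log(3), rep(0, des$p - 1))
  expect_equal(marginal_mean(b, des), rep(0.75, 8))
  set.seed(3)
  b <- rnorm(des$p)
  expect_equal(marginal_mean(b, des)[5],
               1 / (1 + exp(-sum(des$Z[5, ] * b))), tolerance = 1e-12)
  expect_error(marginal_mean(rep(0, des$p + 1), des), "length")
})

test_that("invalid panels are rejected by the constructor", {
  expect_error(panel_dataset(matrix(c(0, 2), 1), array(0, c(1, 2, 1))),
               "binary")
  expect_error(panel_dataset(matrix(0, 2, 2), array(0, c(3, 2, 1))),
               "dimensions")
  d <- tiny_panel()
  expect_error(build_partitioned_design(d, max_lag = 4), "max_lag")
  expect_error(build_partitioned_design(d, max_lag = -1), "max_lag")
})

test_that("single-wave slices behave as cross-sectional datasets", {
  d <- tiny_panel()
  s <- subset_waves(d, 2)
  expect_equal(s$T, 1L)
  expect_equal(s$y[, 1], d$y[, 2])
  des <- build_partitioned_design(s, max_lag = 0)
  expect_equal(nrow(des$Z), 2)
})
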