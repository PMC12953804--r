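test_that("noiseless trends are forecast exactly once differencing removes them", {
  x <- as.numeric(1:100)
  tr <- run_point_cv(x, one_step_folds(100), p_range = 1:2, d_range = 0:2,
                     q_range = 0:1)
  expect_lt(mae(tr$actual, tr$predicted), 1e-6)
  expect_true(all(tr$d >= 1))
})

test_that("one-step white-noise MAE approaches the folded-normal mean", {
  # E|N(0, sigma^2)| = sigma * sqrt(2/pi); the one-step forecast of white
  # noise converges to its mean
  maes <- vapply(1:20, function(s) {
    z <- generate_arma_series(n = 200, seed = 700 + s)
    tr <- run_point_cv(z, one_step_folds(200), p_range = 1, d_range = 0,
                       q_range = 0)
    mae(tr$actual, tr$predicted)
  }, numeric(1))
  expect_equal(mean(maes), sqrt(2 / pi), tolerance = 0.1)
})

test_that("constant training data degrades to logged missing predictions", {
  x <- c(rep(3, 60), rnorm(40))
  tr <- run_point_cv(x, one_step_folds(100, n_folds = 2), p_range = 1,
                     d_range = 0, q_range = 0)
  expect_true(any(is.na(tr$predicted)))
  expect_gt(nrow(attr(tr, "log")), 0)
})

test_that("traces are deterministic and chronologically coherent", {
  y <- generate_arma_series(ar = 0.7, n = 150, seed = 2)
  plan <- tss_folds(150)
  a <- run_point_cv(y, plan, p_range = 1:2, d_range = 0, q_range = 0:1)
  b <- run_point_cv(y, plan, p_range = 1:2, d_range = 0, q_range = 0:1)
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
  for (fd in unique(a$fold)) {
    expect_true(!is.unsorted(a$time_index[a$fold == fd], strictly = TRUE))
  }
  # per-fold metrics are available for dispersion reporting
  fm <- evaluate_trace(a, by_fold = TRUE)
  expect_equal(nrow(fm), length(unique(a$fold)))
})

test_that("blocked point prediction anchors on the allowed information set", {
  y <- generate_arma_series(ar = 0.7, n = 200, seed = 13)
  tr <- run_point_cv(y, blocked_folds(200), p_range = 1:2, d_range = 0,
                     q_range = 0)
  expect_equal(sum(!is.na(tr$predicted)), nrow(tr))
  expect_true(mae(tr$actual, tr$predicted) < 2 * sd(y))
})

test_that("interval prediction rejects the blocked scheme", {
  y <- rnorm(100)
  expect_error(run_interval_cv(y, method = "blocked"),
               "restricted to point prediction")
})

test_that("interval traces satisfy the bound and width invariants", {
  y <- generate_arma_series(ar = 0.6, n = 240, seed = 3)
  for (m in c("one_step", "tss")) {
    tr <- run_interval_cv(y, method = m, p_range = 1:2, d_range = 0,
                          q_range = 0:1)
    expect_true(all(tr$type == "interval"))
    expect_true(all(tr$lower <= tr$predicted & tr$predicted <= tr$upper))
    # widths are non-decreasing within each horizon-5 forecast block
    widths <- tr$upper - tr$lower
    blk <- (seq_len(nrow(tr)) - 1) %/% 5
    for (g in unique(blk)) {
      expect_true(all(diff(widths[blk == g]) >= -1e-12))
    }
  }
})

test_that("one-step interval blocks advance by the horizon without overlap", {
  y <- generate_arma_series(ar = 0.6, n = 200, seed = 4)
  tr <- run_interval_cv(y, method = "one_step", horizon = 5, p_range = 1,
                        d_range = 0, q_range = 0)
  expect_true(!any(duplicated(tr$time_index)))
  expect_equal(sort(unique(diff(sort(unique(tr$time_index))))), 1)
  expect_gte(min(tr$time_index), 101)
})

test_that("horizon-5 spread exceeds the one-step spread for the same model", {
  y <- generate_arma_series(ar = 0.7, n = 300, seed = 6)
  tr5 <- run_interval_cv(y, method = "one_step", horizon = 5, p_range = 1,
                         d_range = 0, q_range = 0)
  tr1 <- run_interval_cv(y, method = "one_step", horizon = 1, p_range = 1,
                         d_range = 0, q_range = 0)
  expect_gt(ci_spread(tr5), ci_spread(tr1))
})
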