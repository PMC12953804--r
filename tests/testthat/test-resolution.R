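test_that("resolution reduction averages non-overlapping windows", {
  expect_equal(reduce_resolution(as.numeric(1:10), 5)$values, c(3, 8))
  expect_equal(reduce_resolution(as.numeric(1:7), 1)$values, as.numeric(1:7))
  expect_error(reduce_resolution(1:100, 7), "must be one of")

  # window with >= 50% missing is itself missing
  x <- as.numeric(1:10)
  x[c(1, 2, 3)] <- NA
  out <- reduce_resolution(x, 5)
  expect_true(is.na(out$values[1]))
  expect_equal(out$values[2], 8)

  # trailing incomplete window dropped
  expect_length(reduce_resolution(as.numeric(1:12), 5)$values, 2)
})

test_that("complete reduction conserves the grand mean", {
  set.seed(4)
  x <- rnorm(600)
  for (res in c(5, 10, 30, 60)) {
    expect_equal(mean(reduce_resolution(x, res)$values), mean(x),
                 tolerance = 1e-9)
  }
})

test_that("short gaps interpolate linearly and long gaps split segments", {
  s <- handle_gaps(c(1, 2, NA, NA, 5, 6))
  expect_equal(s$values, as.numeric(1:6))
  expect_equal(nrow(s$segments), 1)

  s2 <- handle_gaps(c(1, 2, rep(NA, 6), 9, 10))
  expect_true(all(is.na(s2$values[3:8])))
  expect_equal(s2$segments$start, c(1, 9))
  expect_equal(s2$segments$end, c(2, 10))
  expect_equal(longest_segment(s2), c(1, 2))

  # a run of exactly five is removed, not interpolated
  s3 <- handle_gaps(c(1:4, rep(NA, 5), 10:13))
  expect_equal(nrow(s3$segments), 2)
  expect_true(all(is.na(s3$values[5:9])))

  # a run of four is interpolated
  s4 <- handle_gaps(c(0, rep(NA, 4), 10))
  expect_equal(s4$values, seq(0, 10, by = 2))
})

test_that("boundary missing runs are trimmed and all-missing input is empty", {
  s <- handle_gaps(c(NA, NA, 3, 4, 5, NA))
  expect_equal(s$segments$start, 3)
  expect_equal(s$segments$end, 5)
  expect_true(is.na(s$values[1]) && is.na(s$values[6]))

  s2 <- handle_gaps(rep(NA_real_, 8))
  expect_equal(nrow(s2$segments), 0)
  expect_length(longest_segment(s2), 0)
})

test_that("interpolated values never leave the flanking range", {
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(40)
    k <- sample(1:4, 1)
    start <- sample(5:30, 1)
    x[start:(start + k - 1)] <- NA
    filled <- handle_gaps(x)$values
    lo <- min(x[start - 1], x[start + k])
    hi <- max(x[start - 1], x[start + k])
    expect_true(all(filled[start:(start + k - 1)] >= lo - 1e-12 &
                      filled[start:(start + k - 1)] <= hi + 1e-12))
  }
})

test_that("differencing examples and exact inversion", {
  expect_equal(as.numeric(difference(c(1, 4, 9, 16), 1)), c(3, 5, 7))
  expect_equal(as.numeric(difference(c(1, 4, 9, 16), 2)), c(2, 2))
  expect_identical(difference(c(5, 1, 7), 0), c(5, 1, 7))
  expect_error(difference(c(1, 2), 2), "length")

  set.seed(3)
  for (d in 1:2) {
    x <- cumsum(rnorm(200))
    dx <- difference(x, d)
    expect_equal(undifference(dx), x, tolerance = 1e-12)
  }
})

test_that("ADF and KPSS agree with their textbook behaviour on clear cases", {
  set.seed(10)
  stationary <- as.numeric(arima.sim(list(ar = 0.3), 500))
  rw <- cumsum(rnorm(500))
  expect_true(adf_test(stationary)$adf_reject_unit_root)
  expect_false(kpss_test(stationary)$kpss_reject_stationarity)
  expect_true(kpss_test(rw)$kpss_reject_stationarity)

  expect_error(adf_test(rep(2, 100)), "zero variance")
  expect_error(kpss_test(rep(2, 100)), "zero variance")
  expect_error(adf_test(rnorm(10)), "at least 20")
  rep_tbl <- stationarity_report(stationary)
  expect_true(all(c("adf_statistic", "kpss_statistic") %in% names(rep_tbl)))
})

test_that("ACF/PACF match theory for an AR(1) process", {
  x <- generate_arma_series(ar = 0.7, n = 5000, seed = 6)
  ap <- acf_pacf(x, 10)
  expect_equal(ap$acf[1], 1)
  expect_true(all(abs(ap$acf[2:6] - 0.7^(1:5)) < 0.05))
  expect_true(all(abs(ap$pacf[3:11]) < 0.05)) # PACF cuts off after lag 1
  expect_equal(attr(ap, "band"), 1.96 / sqrt(5000))
  expect_equal(ap$acf, naive_acf(x, 10), tolerance = 1e-10)
  expect_error(acf_pacf(rep(1, 50), 5), "zero variance")
})
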