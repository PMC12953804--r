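test_that("10-s block means follow the non-overlapping frame rule", {
  out <- block_mean_10s(rep(10, 3000), 100)
  expect_equal(out$mean, c(10, 10, 10))
  expect_true(all(out$valid))

  # arithmetic-series oracle: frame means of a ramp
  ramp <- as.numeric(0:2999)
  expect_equal(block_mean_10s(ramp, 100)$mean, c(499.5, 1499.5, 2499.5))

  # trailing incomplete frame dropped: 25 s -> 2 frames
  expect_equal(nrow(block_mean_10s(numeric(2500), 100)), 2)
  expect_equal(nrow(block_mean_10s(numeric(0), 100)), 0)
})

test_that("frame validity follows the 50% unmasked-majority rule", {
  x <- rep(4, 2000)
  mask <- rep(FALSE, 2000)
  mask[1:501] <- TRUE # 501/1000 missing -> invalid
  mask[1001:1500] <- TRUE # exactly 50% present -> still valid
  out <- block_mean_10s(x, 100, mask)
  expect_equal(out$valid, c(FALSE, TRUE))
  expect_true(is.na(out$mean[1]))
  expect_equal(out$mean[2], 4)
})

test_that("AMP matches the least-squares sinusoid amplitude oracle", {
  t <- (0:999) / 100
  frame <- 5 * sin(2 * pi * 1.2 * t + 0.7)
  expect_equal(compute_amp(frame, 100), 5.0, tolerance = 0.01)
  expect_equal(compute_amp(frame, 100),
               unname(ls_sine_amp(frame, 1.2, 100)), tolerance = 0.01)

  expect_equal(compute_amp(numeric(1000), 100), 0)
  expect_equal(compute_amp(rep(7, 1000), 100), 0) # DC is outside the band

  # offset invariance: the cardiac band excludes 0 Hz
  expect_equal(compute_amp(frame + 120, 100), compute_amp(frame, 100),
               tolerance = 1e-9)
  expect_error(compute_amp(frame[1:900], 100), "10 s")
})

test_that("CPP is the MAP - ICP difference without clamping", {
  expect_equal(compute_cpp(87, 12), 75)
  expect_equal(compute_cpp(0, 0), 0)
  expect_equal(compute_cpp(80, 90), -10)
})

test_that("pearson matches the product-moment formula and handles degeneracy", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               naive_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_true(is.na(pearson(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson(1:4, 1:5), "equal length")
  # symmetry
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearson(x, y), pearson(y, x))
})

test_that("moving correlation uses trailing 30-frame windows on a minute stride", {
  x <- as.numeric(1:60)
  out <- moving_correlation_index(x, 2 * x + 1)
  expect_length(out, 10)
  expect_true(all(is.na(out[1:4]))) # fewer than 30 prior frames
  expect_equal(out[5:10], rep(1, 6))
  expect_equal(moving_correlation_index(x, -x)[5:10], rep(-1, 6))

  # a single invalid frame poisons exactly the windows overlapping it:
  # frame 31 sits in the windows ending at minutes 6..10, not minute 5
  x2 <- x; x2[31] <- NA
  out2 <- moving_correlation_index(x2, 2 * x + 1)
  expect_false(is.na(out2[5]))
  expect_true(all(is.na(out2[6:10])))
})

test_that("null moving-correlation dispersion matches the Fisher variance", {
  set.seed(14)
  idx <- moving_correlation_index(rnorm(10000), rnorm(10000))
  idx <- idx[!is.na(idx)]
  expect_lt(abs(mean(idx)), 0.02)
  expect_equal(sd(idx), 1 / sqrt(29), tolerance = 0.2)
})

test_that("derived minute records satisfy the row-wise invariants", {
  rec <- generate_patient_waveforms(sim_config(duration = 30, seed = 8))
  mr <- derive_minute_record(rec)
  expect_equal(nrow(mr), 30)
  expect_equal(mr$minute, 0:29)
  expect_equal(mr$CPP, mr$MAP - mr$ICP, tolerance = 1e-9)
  for (col in c("PRx", "PAx", "RAC", "RAP")) {
    v <- mr[[col]]
    expect_true(all(is.na(v[1:4])))
    expect_true(all(abs(v[!is.na(v)]) <= 1))
  }
  expect_true(all(mr$AMP[!is.na(mr$AMP)] >= 0))
})

test_that("constant records yield missing correlation indices", {
  cfg <- quiet_config(duration = 7, slow_waves = list(),
                      icp_slow_waves = list(), resp_amp = 0,
                      pulse_pressure = 0, icp_pulse_base = 0)
  mr <- derive_minute_record(generate_patient_waveforms(cfg))
  expect_true(all(is.na(mr$PRx)))
  expect_true(all(is.na(mr$RAP)))
})

test_that("a gap invalidates exactly the windows that overlap it", {
  rec <- generate_patient_waveforms(sim_config(duration = 20, seed = 9))
  # knock out minute 10 entirely (6 frames at 100 Hz)
  rec <- inject_missingness(rec, list(c(10 * 60 * 100 + 1, 6000)))
  mr <- derive_minute_record(rec)
  expect_true(is.na(mr$MAP[11]))
  expect_true(all(is.na(mr$PRx[11:15]))) # trailing windows cover minute 10
  expect_false(is.na(mr$PRx[16]))
  expect_false(is.na(mr$MAP[10]))
})

test_that("records shorter than six minutes are rejected", {
  rec <- generate_patient_waveforms(sim_config(duration = 5, seed = 1))
  expect_error(derive_minute_record(rec), "6 whole minutes")
})
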