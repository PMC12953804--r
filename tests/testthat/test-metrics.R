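test_that("metric worked examples", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  expect_equal(r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r2(c(1, 2, 3), c(2, 2, 2)), 0)
  expect_true(is.na(r2(c(2, 2, 2), c(1, 2, 3))))
  expect_true(is.na(mae(c(NA, NA), c(1, 2))))
  expect_error(mae(1:3, 1:4), "equal length")
})

test_that("missing pairs are dropped pairwise", {
  y <- c(1, NA, 3, 4)
  yhat <- c(2, 5, NA, 4)
  expect_equal(mae(y, yhat), mean(c(1, 0)))
  expect_equal(rmse(y, yhat), sqrt(mean(c(1, 0))))
})

test_that("r2 is shift-invariant and can be negative", {
  set.seed(5)
  y <- rnorm(50); yhat <- rnorm(50)
  expect_equal(r2(y, yhat), r2(y + 10, yhat + 10))
  expect_lt(r2(y, y + 5), 0)
})

test_that("ci_spread summarises interval widths", {
  tr <- tibble::tibble(lower = c(-1.96, -1.96), upper = c(1.96, 1.96),
                       type = "interval")
  expect_equal(ci_spread(tr), 3.92)
  tr2 <- tibble::tibble(lower = c(0, 1), upper = c(2, 5), type = "interval")
  expect_equal(ci_spread(tr2), 3)
  expect_equal(ci_spread(tr2, stat = "median"), 3)
  expect_true(is.na(ci_spread(tibble::tibble(lower = numeric(),
                                             upper = numeric()))))
})

test_that("cohort aggregation averages across patients with exclusions", {
  rows <- tibble::tibble(
    patient_id = c("A", "B"), signal = "MAP", resolution = 5L,
    method = "one_step", prediction_type = "point",
    mae = c(1, 3), rmse = c(2, 4), r2 = c(0.1, 0.3),
    ci_spread = NA_real_)
  s <- summarize_cohort(rows)
  expect_equal(s$mae_mean, 2)
  expect_equal(s$mae_sd, sd(c(1, 3)))
  expect_equal(s$n_patients, 2L)

  # single patient: summary equals its row, SD = 0
  s1 <- summarize_cohort(rows[1, ])
  expect_equal(s1$mae_mean, 1)
  expect_equal(s1$mae_sd, 0)

  # a patient missing one signal is excluded from that signal's cells only
  rows2 <- dplyr::bind_rows(
    rows,
    tibble::tibble(patient_id = c("A", "B"), signal = "PbtO2",
                   resolution = 5L, method = "one_step",
                   prediction_type = "point", mae = c(0.5, NA),
                   rmse = c(0.7, NA), r2 = c(0, NA), ci_spread = NA_real_))
  s2 <- summarize_cohort(rows2)
  pb <- s2[s2$signal == "PbtO2", ]
  expect_equal(pb$mae_mean, 0.5)
  expect_equal(pb$n_patients, 1L)

  # permutation invariance in patient order
  s3 <- summarize_cohort(rows[c(2, 1), ])
  expect_equal(s3$mae_mean, s$mae_mean)
  expect_equal(s3$mae_sd, s$mae_sd)

  expect_equal(nrow(summarize_cohort(rows[0, ])), 0)
})

test_that("summary tables pivot to the signals-by-resolutions layout", {
  rows <- tidyr::expand_grid(patient_id = c("A", "B"),
                             signal = c("MAP", "ICP"),
                             resolution = c(1L, 5L)) |>
    dplyr::mutate(method = "tss", prediction_type = "point",
                  mae = 1, rmse = 2, r2 = 0.5, ci_spread = NA_real_)
  tab <- summary_table(summarize_cohort(rows), "tss", "point")
  expect_equal(nrow(tab), 2)
  expect_true(all(c("r2_mean_1", "r2_mean_5", "rmse_mean_1",
                    "rmse_mean_5") %in% names(tab)))
  p <- plot_metric_heatmap(summarize_cohort(rows), "tss", "point")
  expect_s3_class(p, "ggplot")
})
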