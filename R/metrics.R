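#' Forecast-accuracy metrics
#'
#' Mean absolute error, root mean squared error and the coefficient of
#' determination between actual and predicted values. Pairs with a missing
#' member are dropped; when no valid pair remains the metric is `NA`. `r2`
#' is also `NA` when the actual values have zero variance (the
#' mean-reference denominator degenerates). Negative `r2` indicates a model
#' worse than predicting the mean.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return A single numeric value.
#' @name forecast_metrics
#' @examples
#' mae(c(1, 2, 3), c(2, 2, 2))  # 2/3
#' rmse(c(1, 2, 3), c(2, 2, 2)) # sqrt(2/3)
#' r2(c(1, 2, 3), c(2, 2, 2))   # 0
NULL

metric_pairs <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stopf("`actual` and `predicted` must have equal length")
  }
  ok <- !is.na(actual) & !is.na(predicted)
  list(y = actual[ok], yhat = predicted[ok])
}

#' @rdname forecast_metrics
#' @export
mae <- function(actual, predicted) {
  p <- metric_pairs(actual, predicted)
  if (!length(p$y)) return(NA_real_)
  mean(abs(p$y - p$yhat))
}

#' @rdname forecast_metrics
#' @export
rmse <- function(actual, predicted) {
  p <- metric_pairs(actual, predicted)
  if (!length(p$y)) return(NA_real_)
  sqrt(mean((p$y - p$yhat)^2))
}

#' @rdname forecast_metrics
#' @export
r2 <- function(actual, predicted) {
  p <- metric_pairs(actual, predicted)
  if (!length(p$y)) return(NA_real_)
  ss_tot <- sum((p$y - mean(p$y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((p$y - p$yhat)^2) / ss_tot
}

#' Mean prediction-interval spread of an interval trace
#'
#' The mean width `upper - lower` over all interval entries of a
#' prediction trace; the uncertainty summary reported alongside interval
#' forecasts. A median variant is available via `stat`.
#'
#' @param trace A prediction trace from [run_interval_cv()] (or any data
#'   frame with `lower` and `upper` columns).
#' @param stat `"mean"` (default) or `"median"`.
#' @return Mean (or median) interval width; `NA` for an empty trace.
#' @export
ci_spread <- function(trace, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!all(c("lower", "upper") %in% names(trace))) {
    stopf("`trace` must have `lower` and `upper` columns")
  }
  w <- trace$upper - trace$lower
  w <- w[!is.na(w)]
  if (!length(w)) return(NA_real_)
  if (stat == "mean") mean(w) else stats::median(w)
}

#' Metrics of one prediction trace
#'
#' Collapses a prediction trace into a one-row metric record (MAE, RMSE,
#' R-squared, CI spread and counts), optionally per fold.
#'
#' @param trace A prediction trace tibble.
#' @param by_fold If `TRUE`, one row per fold (supports fold-wise
#'   mean/SD reporting); otherwise one pooled row.
#' @return Tibble with columns `mae`, `rmse`, `r2`, `ci_spread`,
#'   `n_predictions` (plus `fold` when `by_fold`).
#' @export
evaluate_trace <- function(trace, by_fold = FALSE) {
  one <- function(tr) {
    tibble::tibble(
      mae = mae(tr$actual, tr$predicted),
      rmse = rmse(tr$actual, tr$predicted),
      r2 = r2(tr$actual, tr$predicted),
      ci_spread = if (any(tr$type == "interval")) ci_spread(tr) else NA_real_,
      n_predictions = sum(!is.na(tr$predicted)))
  }
  if (!by_fold) return(one(trace))
  trace |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Aggregate per-patient metric rows into a cohort summary
#'
#' Groups metric rows by (signal, resolution, method, prediction type) and
#' reports the mean and standard deviation (n - 1 denominator) of each
#' metric across patients, with the contributing patient count. Missing
#' metrics are excluded, never imputed.
#'
#' @param metric_rows Tibble with columns `patient_id`, `signal`,
#'   `resolution`, `method`, `prediction_type`, `mae`, `rmse`, `r2`,
#'   `ci_spread`.
#' @return A tibble with `*_mean` and `*_sd` columns per metric and
#'   `n_patients`.
#' @export
summarize_cohort <- function(metric_rows) {
  if (nrow(metric_rows) == 0L) {
    return(tibble::tibble(signal = character(), resolution = integer(),
                          method = character(), prediction_type = character(),
                          n_patients = integer()))
  }
  metric_rows |>
    dplyr::group_by(.data$signal, .data$resolution, .data$method,
                    .data$prediction_type) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("mae", "rmse", "r2", "ci_spread")),
                    list(mean = ~ if (all(is.na(.x))) NA_real_ else
                           mean(.x, na.rm = TRUE),
                         # SD over a single contributing patient is 0 by
                         # convention (no dispersion observed)
                         sd = ~ {
                           k <- sum(!is.na(.x))
                           if (k == 0L) NA_real_
                           else if (k == 1L) 0
                           else sd(.x, na.rm = TRUE)
                         })),
      n_patients = dplyr::n_distinct(.data$patient_id[!is.na(.data$mae)]),
      .groups = "drop")
}

#' Heatmap-shaped summary table for one method and prediction type
#'
#' Reshapes a cohort summary into the signals-by-resolutions table used to
#' report the resolution sweep: each cell pairs the cross-patient mean
#' R-squared with the mean RMSE.
#'
#' @param cohort_summary Output of [summarize_cohort()].
#' @param method One of `"one_step"`, `"blocked"`, `"tss"`.
#' @param prediction_type `"point"` or `"interval"`.
#' @return A tibble with one row per signal and paired
#'   `r2_mean_<resolution>` / `rmse_mean_<resolution>` columns.
#' @export
summary_table <- function(cohort_summary, method, prediction_type = "point") {
  cohort_summary |>
    dplyr::filter(.data$method == !!method,
                  .data$prediction_type == !!prediction_type) |>
    dplyr::select("signal", "resolution", "r2_mean", "rmse_mean") |>
    tidyr::pivot_wider(names_from = "resolution",
                       values_from = c("r2_mean", "rmse_mean"),
                       names_sep = "_")
}

#' Heatmap of cohort forecast performance
#'
#' ggplot2 tile plot of the signals-by-resolutions cohort summary: fill is
#' the cross-patient mean R-squared, cell labels are the mean RMSE.
#'
#' @param cohort_summary Output of [summarize_cohort()].
#' @param method,prediction_type Which slice to plot.
#' @return A ggplot object.
#' @export
plot_metric_heatmap <- function(cohort_summary, method = "one_step",
                                prediction_type = "point") {
  dat <- cohort_summary |>
    dplyr::filter(.data$method == !!method,
                  .data$prediction_type == !!prediction_type)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$resolution),
                                    y = .data$signal,
                                    fill = .data$r2_mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rmse_mean)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::labs(x = "temporal resolution (min)", y = NULL,
                  fill = expression(bar(R)^2),
                  title = sprintf("%s %s prediction", method,
                                  prediction_type)) +
    ggplot2::theme_minimal()
}
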