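# Cross-validated ARIMA prediction over a split plan.
#
# Leakage discipline: within every fold, the ARIMA order is selected on the
# training range only; forecasts for a test point are anchored on observed
# history strictly before it, restricted to the fold's allowed information
# set (for blocked folds the discarded gap points are excluded).

empty_trace <- function() {
  tibble::tibble(time_index = integer(), actual = numeric(),
                 predicted = numeric(), lower = numeric(), upper = numeric(),
                 fold = integer(), method = character(), type = character(),
                 p = integer(), d = integer(), q = integer())
}

#' Point-prediction cross-validation over a split plan
#'
#' Runs leakage-free one-step-ahead point prediction over every fold of a
#' split plan. Orders are selected per fold (AIC grid search on the fold's
#' training range). For one-step plans the coefficients are re-estimated at
#' every step as the training window expands; for blocked and expanding
#' (TSS) plans one fit per fold predicts the test range by iterated
#' one-step-ahead forecasts anchored on observed history. Fit failures
#' degrade to missing predictions and are logged, never thrown.
#'
#' @param values Numeric series (a contiguous segment after gap handling).
#' @param plan A `split_plan` covering `length(values)`.
#' @param p_range,d_range,q_range Order grid passed to [select_order()].
#' @param level Unused for point prediction (kept for symmetry).
#' @return A prediction-trace tibble: `time_index`, `actual`, `predicted`,
#'   `lower`/`upper` (`NA` for point traces), `fold`, `method`,
#'   `type = "point"`, and the order used (`p`, `d`, `q`). Attributes:
#'   `log` (tibble of failures), `train_seconds`, `test_seconds`.
#' @export
#' @examples
#' x <- generate_arma_series(ar = 0.7, n = 80, seed = 1)
#' tr <- run_point_cv(x, one_step_folds(80, n_folds = 2),
#'                    p_range = 1, d_range = 0, q_range = 0)
#' mae(tr$actual, tr$predicted)
run_point_cv <- function(values, plan, p_range = 1:10, d_range = 0:2,
                         q_range = 0:10, level = 0.95) {
  stopifnot(inherits(plan, "split_plan"))
  x <- as.numeric(values)
  if (length(x) != plan$n_obs) {
    stopf("plan was built for %d observations but series has %d",
          plan$n_obs, length(x))
  }
  log <- list()
  rows <- list()
  t_train <- 0; t_test <- 0
  for (b in seq_len(nrow(plan$folds))) {
    f <- plan$folds[b, ]
    train_idx <- f$train_start:f$train_end
    tic <- proc.time()[["elapsed"]]
    sel <- tryCatch(
      select_order(x[train_idx], p_range, d_range, q_range),
      error = function(e) e)
    t_train <- t_train + proc.time()[["elapsed"]] - tic
    if (inherits(sel, "error")) {
      log[[length(log) + 1L]] <- tibble::tibble(
        fold = f$fold, stage = "select_order",
        message = conditionMessage(sel))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        time_index = f$test_start:f$test_end,
        actual = x[f$test_start:f$test_end], predicted = NA_real_,
        lower = NA_real_, upper = NA_real_, fold = f$fold,
        method = plan$method, type = "point", p = NA_integer_,
        d = NA_integer_, q = NA_integer_)
      next
    }
    ord <- sel$order
    fit <- sel$fit
    test_idx <- f$test_start:f$test_end
    pred <- rep(NA_real_, length(test_idx))
    for (j in seq_along(test_idx)) {
      t <- test_idx[j]
      hist <- switch(plan$method,
        one_step = x[1:(t - 1L)],
        tss = x[1:(t - 1L)],
        # blocked: train block plus observed test values before t; the
        # discarded gap stays outside the information set
        blocked = c(x[train_idx],
                    if (t > f$test_start) x[f$test_start:(t - 1L)]))
      if (plan$method == "one_step") {
        # coefficients re-estimated at every step on the expanded window
        tic <- proc.time()[["elapsed"]]
        refit <- tryCatch(fit_arima(hist, ord, init = fit),
                          error = function(e) e)
        t_train <- t_train + proc.time()[["elapsed"]] - tic
        if (!inherits(refit, "error") && isTRUE(refit$converged)) {
          fit <- refit
        } else if (inherits(refit, "error")) {
          log[[length(log) + 1L]] <- tibble::tibble(
            fold = f$fold, stage = sprintf("refit@%d", t),
            message = conditionMessage(refit))
        }
      }
      tic <- proc.time()[["elapsed"]]
      fc <- tryCatch(arima_forecast(fit, history = hist, horizon = 1L,
                                    level = level),
                     error = function(e) e)
      t_test <- t_test + proc.time()[["elapsed"]] - tic
      if (!inherits(fc, "error")) pred[j] <- fc$point[1L] else {
        log[[length(log) + 1L]] <- tibble::tibble(
          fold = f$fold, stage = sprintf("forecast@%d", t),
          message = conditionMessage(fc))
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time_index = test_idx, actual = x[test_idx], predicted = pred,
      lower = NA_real_, upper = NA_real_, fold = f$fold,
      method = plan$method, type = "point", p = ord[["p"]],
      d = ord[["d"]], q = ord[["q"]])
  }
  out <- dplyr::bind_rows(c(list(empty_trace()), rows))
  attr(out, "log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(fold = integer(), stage = character(),
                   message = character())
  attr(out, "train_seconds") <- t_train
  attr(out, "test_seconds") <- t_test
  out
}

#' Interval-prediction cross-validation
#'
#' Multi-step forecasting with Gaussian prediction intervals under the
#' one-step (expanding window) or expanding/fixed (TSS) scheme. The blocked
#' scheme is rejected: it is restricted to point prediction because its
#' fixed non-overlapping blocks do not support stable interval estimation.
#'
#' For `method = "one_step"` the series beyond the initial training window
#' is covered by consecutive non-overlapping blocks of `horizon` points:
#' from the end of each expanding training window the model forecasts
#' `horizon` steps with intervals, then the window advances by `horizon`.
#' Blocks are grouped into `n_folds` folds; the order is selected once per
#' fold and coefficients are re-estimated per block. For `method = "tss"`
#' the model is fitted on each fold's training partitions and forecasts the
#' first `horizon` points of its test partition.
#'
#' @param values Numeric series.
#' @param method `"one_step"` or `"tss"`.
#' @param horizon Forecast interval length (default 5).
#' @param level Prediction-interval coverage (default 0.95).
#' @param n_folds Folds (one_step) / splits (tss); default 5.
#' @param initial_fraction Initial training share for one_step.
#' @param p_range,d_range,q_range Order grid.
#' @return A prediction-trace tibble as in [run_point_cv()] with
#'   `type = "interval"` and populated `lower`/`upper`.
#' @export
run_interval_cv <- function(values, method = c("one_step", "tss"),
                            horizon = 5L, level = 0.95, n_folds = 5L,
                            initial_fraction = 0.5, p_range = 1:10,
                            d_range = 0:2, q_range = 0:10) {
  if (identical(method, "blocked") || identical(method[1], "blocked")) {
    stopf("blocked cross-validation is restricted to point prediction; interval prediction supports one_step and tss only")
  }
  method <- match.arg(method)
  x <- as.numeric(values)
  n <- length(x)
  if (horizon < 1L) stopf("`horizon` must be >= 1")
  log <- list()
  rows <- list()
  t_train <- 0; t_test <- 0

  add_block <- function(fit, hist, start, fold, ord) {
    h <- min(horizon, n - start + 1L)
    tic <- proc.time()[["elapsed"]]
    fc <- tryCatch(arima_forecast(fit, history = hist, horizon = h,
                                  level = level),
                   error = function(e) e)
    t_test <<- t_test + proc.time()[["elapsed"]] - tic
    if (inherits(fc, "error")) {
      log[[length(log) + 1L]] <<- tibble::tibble(
        fold = fold, stage = sprintf("forecast@%d", start),
        message = conditionMessage(fc))
      return(invisible(NULL))
    }
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      time_index = start:(start + h - 1L), actual = x[start:(start + h - 1L)],
      predicted = fc$point, lower = fc$lower, upper = fc$upper, fold = fold,
      method = method, type = "interval", p = ord[["p"]], d = ord[["d"]],
      q = ord[["q"]])
  }

  if (method == "one_step") {
    first_test <- as.integer(ceiling(initial_fraction * n)) + 1L
    block_starts <- seq(first_test, n, by = horizon)
    block_starts <- block_starts[block_starts + horizon - 1L <= n]
    if (!length(block_starts)) {
      stopf("series too short for even one %d-step interval block", horizon)
    }
    n_folds_eff <- min(n_folds, length(block_starts))
    fold_of <- sort(rep_len(seq_len(n_folds_eff), length(block_starts)))
    fit <- NULL; ord <- NULL
    for (i in seq_along(block_starts)) {
      start <- block_starts[i]
      train <- x[1:(start - 1L)]
      new_fold <- i == 1L || fold_of[i] != fold_of[i - 1L]
      tic <- proc.time()[["elapsed"]]
      res <- tryCatch({
        if (new_fold) {
          sel <- select_order(train, p_range, d_range, q_range)
          list(fit = sel$fit, ord = sel$order)
        } else {
          list(fit = fit_arima(train, ord, init = fit), ord = ord)
        }
      }, error = function(e) e)
      t_train <- t_train + proc.time()[["elapsed"]] - tic
      if (inherits(res, "error")) {
        log[[length(log) + 1L]] <- tibble::tibble(
          fold = fold_of[i], stage = sprintf("fit@%d", start),
          message = conditionMessage(res))
        next
      }
      ord <- res$ord
      if (isTRUE(res$fit$converged)) fit <- res$fit
      if (is.null(fit)) next
      add_block(fit, train, start, fold_of[i], ord)
    }
  } else { # tss
    plan <- tss_folds(n, n_splits = n_folds)
    for (b in seq_len(nrow(plan$folds))) {
      f <- plan$folds[b, ]
      train <- x[f$train_start:f$train_end]
      tic <- proc.time()[["elapsed"]]
      sel <- tryCatch(select_order(train, p_range, d_range, q_range),
                      error = function(e) e)
      t_train <- t_train + proc.time()[["elapsed"]] - tic
      if (inherits(sel, "error")) {
        log[[length(log) + 1L]] <- tibble::tibble(
          fold = f$fold, stage = "select_order",
          message = conditionMessage(sel))
        next
      }
      h_start <- f$test_start
      add_block(sel$fit, train, h_start, f$fold, sel$order)
    }
  }
  out <- dplyr::bind_rows(c(list(empty_trace()), rows))
  attr(out, "log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(fold = integer(), stage = character(),
                   message = character())
  attr(out, "train_seconds") <- t_train
  attr(out, "test_seconds") <- t_test
  out
}
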