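# Split plans for the three time-series cross-validation schemes.
# Fold ranges are 1-based inclusive indices into the analysed series.

new_split_plan <- function(folds, method, n_obs, ...) {
  stopifnot(all(c("fold", "train_start", "train_end", "test_start",
                  "test_end") %in% names(folds)))
  # chronological integrity: every train index precedes every test index
  if (any(folds$train_end >= folds$test_start)) {
    stopf("internal error: train range must precede test range in every fold")
  }
  if (any(folds$test_end > n_obs) || any(folds$train_start < 1L)) {
    stopf("internal error: fold indices exceed series bounds")
  }
  # test ranges pairwise disjoint
  o <- order(folds$test_start)
  if (any(folds$test_start[o][-1L] <= folds$test_end[o][-nrow(folds)])) {
    stopf("internal error: test ranges overlap across folds")
  }
  structure(list(method = method, n_obs = as.integer(n_obs),
                 folds = tibble::as_tibble(folds), ...),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d folds over %d observations\n",
              x$method, nrow(x$folds), x$n_obs))
  print(x$folds)
  invisible(x)
}

#' One-step-ahead (expanding window) cross-validation plan
#'
#' The evaluation region is the final `1 - initial_fraction` share of the
#' series; every point in it is a single one-step test with all prior
#' observations as training data. Consecutive test points are grouped into
#' `n_folds` nearly equal folds for fold-wise dispersion reporting; each
#' fold's `train_start`/`train_end` record its initial training range
#' (training then expands point by point within the fold).
#'
#' @param n_obs Series length.
#' @param n_folds Number of reporting folds (default 5).
#' @param initial_fraction Share of the series reserved as the initial
#'   training window (default 0.5).
#' @return A `split_plan` with `method = "one_step"`.
#' @export
#' @examples
#' one_step_folds(100)$folds
one_step_folds <- function(n_obs, n_folds = 5L, initial_fraction = 0.5) {
  n_obs <- as.integer(n_obs)
  first_test <- as.integer(ceiling(initial_fraction * n_obs)) + 1L
  n_test <- n_obs - first_test + 1L
  if (n_test < n_folds) {
    stopf("evaluation region has %d points, fewer than n_folds = %d",
          max(n_test, 0L), n_folds)
  }
  sizes <- rep(n_test %/% n_folds, n_folds)
  extra <- n_test %% n_folds
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- first_test - 1L + cumsum(sizes)
  starts <- ends - sizes + 1L
  folds <- tibble::tibble(fold = seq_len(n_folds), train_start = 1L,
                          train_end = starts - 1L, test_start = starts,
                          test_end = ends)
  new_split_plan(folds, "one_step", n_obs,
                 initial_fraction = initial_fraction)
}

#' Blocked time-series cross-validation plan
#'
#' Splits the series into `n_folds` contiguous non-overlapping blocks (the
#' last block absorbs any remainder). Within each block the first
#' `floor(train_fraction * block)` points train, the next `gap` points are
#' discarded to avoid information leakage across the train/test boundary,
#' and the remainder is the test range.
#'
#' @param n_obs Series length.
#' @param n_folds Number of blocks (default 5).
#' @param train_fraction Within-block training share (default 0.7).
#' @param gap Discarded points between train and test (default 2).
#' @return A `split_plan` with `method = "blocked"`.
#' @export
#' @examples
#' blocked_folds(100)$folds
blocked_folds <- function(n_obs, n_folds = 5L, train_fraction = 0.7,
                          gap = 2L) {
  n_obs <- as.integer(n_obs); gap <- as.integer(gap)
  base <- n_obs %/% n_folds
  if (base < 1L) stopf("series of length %d cannot form %d blocks", n_obs,
                       n_folds)
  starts <- (seq_len(n_folds) - 1L) * base + 1L
  ends <- c(starts[-1L] - 1L, n_obs) # last block absorbs the remainder
  folds <- purrr::map(seq_len(n_folds), function(b) {
    size <- ends[b] - starts[b] + 1L
    n_train <- as.integer(floor(train_fraction * size))
    test_start <- starts[b] + n_train + gap
    if (n_train < 1L || test_start > ends[b]) {
      stopf("block %d (size %d) too small for train + gap (%d) + 1 test point",
            b, size, gap)
    }
    tibble::tibble(fold = b, train_start = starts[b],
                   train_end = starts[b] + n_train - 1L,
                   test_start = test_start, test_end = ends[b])
  }) |> dplyr::bind_rows()
  new_split_plan(folds, "blocked", n_obs, gap = gap,
                 train_fraction = train_fraction)
}

#' Expanding-train / fixed-test sequential split plan
#'
#' Divides the series into `n_splits + 1` sequential partitions of size
#' `floor(n_obs / (n_splits + 1))`. Fold `k` trains on the first `k`
#' partitions and tests on partition `k + 1`; any remainder attaches to
#' the final test fold.
#'
#' @param n_obs Series length (>= `2 * (n_splits + 1)`).
#' @param n_splits Number of splits (default 5).
#' @return A `split_plan` with `method = "tss"`.
#' @export
#' @examples
#' tss_folds(60)$folds
tss_folds <- function(n_obs, n_splits = 5L) {
  n_obs <- as.integer(n_obs); n_splits <- as.integer(n_splits)
  if (n_splits >= n_obs) stopf("`n_splits` must be smaller than `n_obs`")
  if (n_obs < 2L * (n_splits + 1L)) {
    stopf("need n_obs >= 2 * (n_splits + 1) = %d, got %d",
          2L * (n_splits + 1L), n_obs)
  }
  s <- n_obs %/% (n_splits + 1L)
  k <- seq_len(n_splits)
  folds <- tibble::tibble(
    fold = k,
    train_start = 1L,
    train_end = k * s,
    test_start = k * s + 1L,
    test_end = (k + 1L) * s
  )
  folds$test_end[n_splits] <- n_obs # remainder joins the final test fold
  new_split_plan(folds, "tss", n_obs, n_partitions = n_splits + 1L)
}

#' @describeIn one_step_folds Plot a split plan's train/gap/test layout.
#' @param object A `split_plan`.
#' @param ... Unused.
#' @export
autoplot.split_plan <- function(object, ...) {
  f <- object$folds
  seg <- dplyr::bind_rows(
    tibble::tibble(fold = f$fold, start = f$train_start, end = f$train_end,
                   part = "train"),
    tibble::tibble(fold = f$fold, start = f$test_start, end = f$test_end,
                   part = "test"))
  ggplot2::ggplot(seg, ggplot2::aes(xmin = .data$start - 0.5,
                                    xmax = .data$end + 0.5,
                                    ymin = .data$fold - 0.35,
                                    ymax = .data$fold + 0.35,
                                    fill = .data$part)) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_reverse(breaks = f$fold) +
    ggplot2::labs(x = "time index", y = "fold",
                  title = sprintf("%s cross-validation plan", object$method),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
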