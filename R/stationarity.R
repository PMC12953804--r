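#' Augmented Dickey--Fuller unit-root test
#'
#' Fits \eqn{\Delta y_t = \alpha + \gamma y_{t-1} + \sum_{i=1}^{k} \delta_i
#' \Delta y_{t-i} + \epsilon_t} by least squares (constant, no trend), with
#' the lag order `k` chosen by AIC over a common estimation sample up to
#' `max_lag`. The statistic is the t-ratio of \eqn{\gamma}; the null of a
#' unit root is rejected at 5% when the statistic falls below a
#' MacKinnon-style response-surface critical value.
#'
#' @param values Numeric series of length >= 20 with nonzero variance.
#' @param max_lag Maximum augmentation lag; default
#'   `floor(12 * (n/100)^0.25)` (Schwert rule).
#' @return One-row tibble: `adf_statistic`, `adf_critical_5pct`,
#'   `adf_reject_unit_root`, `lags_used`, `n_obs`.
#' @export
adf_test <- function(values, max_lag = NULL) {
  y <- as.numeric(values)
  n <- length(y)
  if (anyNA(y)) stopf("`values` must not contain missing data")
  if (n < 20L) stopf("ADF test needs at least 20 observations")
  if (var(y) == 0) stopf("`values` has zero variance")
  if (is.null(max_lag)) max_lag <- floor(12 * (n / 100)^0.25)
  max_lag <- min(max_lag, n - 10L)

  dy <- diff(y)
  adf_design <- function(k, t_idx) {
    X <- cbind(1, y[t_idx - 1L])
    if (k > 0L) {
      X <- cbind(X, vapply(seq_len(k), function(i) dy[t_idx - 1L - i],
                           numeric(length(t_idx))))
    }
    X
  }
  # lag order by AIC on a common estimation sample, then the final
  # regression refit on the full sample available for that lag
  t_common <- (max_lag + 2L):n # positions in y of the regressand Delta y_t
  best_k <- 0L; best_aic <- Inf
  for (k in 0:max_lag) {
    fit <- stats::lm.fit(adf_design(k, t_common), dy[t_common - 1L])
    nobs <- length(t_common)
    aic <- nobs * log(sum(fit$residuals^2) / nobs) + 2 * (k + 2)
    if (aic < best_aic) { best_aic <- aic; best_k <- k }
  }
  t_idx <- (best_k + 2L):n
  X <- adf_design(best_k, t_idx)
  fit <- stats::lm.fit(X, dy[t_idx - 1L])
  # t-ratio of gamma (column 2)
  nobs <- length(t_idx)
  dof <- nobs - ncol(X)
  sigma2 <- sum(fit$residuals^2) / dof
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se_gamma <- sqrt(sigma2 * XtX_inv[2L, 2L])
  stat <- fit$coefficients[2L] / se_gamma
  # MacKinnon (2010) response surface, constant-only model, 5% level
  cv5 <- -2.86154 - 2.8903 / nobs - 4.234 / nobs^2 - 40.04 / nobs^3
  tibble::tibble(
    adf_statistic = unname(stat),
    adf_critical_5pct = cv5,
    adf_reject_unit_root = unname(stat) < cv5,
    lags_used = best_k,
    n_obs = nobs
  )
}

#' KPSS level-stationarity test
#'
#' LM statistic on the partial sums of demeaned residuals, with the
#' long-run variance estimated by a Bartlett kernel of bandwidth
#' `floor(4 * (n/100)^(1/4))`. The null of level stationarity is rejected
#' at 5% when the statistic exceeds the tabulated critical value 0.463.
#'
#' @param values Numeric series of length >= 20 with nonzero variance.
#' @return One-row tibble: `kpss_statistic`, `kpss_critical_5pct`,
#'   `kpss_reject_stationarity`, `bandwidth`, `n_obs`.
#' @export
kpss_test <- function(values) {
  y <- as.numeric(values)
  n <- length(y)
  if (anyNA(y)) stopf("`values` must not contain missing data")
  if (n < 20L) stopf("KPSS test needs at least 20 observations")
  if (var(y) == 0) stopf("`values` has zero variance")
  e <- y - mean(y)
  s_t <- cumsum(e)
  bw <- floor(4 * (n / 100)^0.25)
  gamma0 <- sum(e^2) / n
  lrv <- gamma0
  for (l in seq_len(bw)) {
    gl <- sum(e[seq_len(n - l)] * e[(l + 1L):n]) / n
    lrv <- lrv + 2 * (1 - l / (bw + 1)) * gl
  }
  stat <- sum(s_t^2) / (n^2 * lrv)
  tibble::tibble(
    kpss_statistic = stat,
    kpss_critical_5pct = 0.463,
    kpss_reject_stationarity = stat > 0.463,
    bandwidth = bw,
    n_obs = n
  )
}

#' Stationarity diagnostics for one series
#'
#' Runs [adf_test()] and [kpss_test()] and combines both into a single
#' one-row report, the per-(signal, resolution) diagnostic emitted by the
#' benchmark pipeline.
#'
#' @inheritParams adf_test
#' @return One-row tibble combining both test reports.
#' @export
stationarity_report <- function(values, max_lag = NULL) {
  dplyr::bind_cols(
    adf_test(values, max_lag = max_lag),
    kpss_test(values) |> dplyr::select(-"n_obs")
  )
}

#' Autocorrelation and partial autocorrelation
#'
#' Normalised autocovariances (lag 0 = 1) and the partial autocorrelation
#' function, with the conventional `+/- 1.96/sqrt(n)` white-noise band,
#' used to judge residual whitening before and after ARIMA fitting.
#'
#' @param values Numeric series with nonzero variance.
#' @param n_lags Number of lags; `length(values)` must exceed
#'   `n_lags + 1`.
#' @return Tibble with columns `lag` (0..`n_lags`), `acf`, `pacf` (`NA` at
#'   lag 0) and attribute `band` = `1.96/sqrt(n)`.
#' @export
acf_pacf <- function(values, n_lags) {
  y <- as.numeric(values)
  n <- length(y)
  if (n <= n_lags + 1L) stopf("series too short for %d lags", n_lags)
  if (var(y) == 0) stopf("`values` has zero variance")
  a <- stats::acf(y, lag.max = n_lags, plot = FALSE, demean = TRUE)
  p <- stats::pacf(y, lag.max = n_lags, plot = FALSE)
  out <- tibble::tibble(
    lag = 0:n_lags,
    acf = as.numeric(a$acf),
    pacf = c(NA_real_, as.numeric(p$acf))
  )
  attr(out, "band") <- 1.96 / sqrt(n)
  out
}
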