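#' Psi weights of an ARIMA model
#'
#' Coefficients of the MA(infinity) representation used to propagate the
#' innovation variance into multi-step forecast uncertainty:
#' \eqn{\psi_0 = 1}, \eqn{\psi_j = \theta_j [j \le q] + \sum_{i=1}^{\min(j,p)}
#' \phi_i \psi_{j-i}} on the differenced scale; for `d > 0` the weights are
#' cumulatively summed `d` times to reach the original scale.
#'
#' @param fit An `arima_css` fit.
#' @param horizon Number of weights \eqn{\psi_0..\psi_{h-1}} to return.
#' @return Numeric vector of length `horizon`.
#' @export
#' @examples
#' m <- arima_fixed(arima_order(1, 0, 0), ar = 0.5)
#' psi_weights(m, 4) # 1, 0.5, 0.25, 0.125
psi_weights <- function(fit, horizon) {
  stopifnot(inherits(fit, "arima_css"), horizon >= 1)
  p <- fit$order[["p"]]; d <- fit$order[["d"]]; q <- fit$order[["q"]]
  psi <- numeric(horizon)
  psi[1L] <- 1
  for (j in seq_len(horizon - 1L)) {
    v <- if (j <= q) fit$ma[j] else 0
    for (i in seq_len(min(j, p))) v <- v + fit$ar[i] * psi[j - i + 1L]
    psi[j + 1L] <- v
  }
  if (d > 0) for (k in seq_len(d)) psi <- cumsum(psi)
  psi
}

#' Point and interval forecasts from an ARIMA fit
#'
#' Point forecasts follow the conditional-expectation recursion on the
#' differenced scale (future innovations set to zero, residuals of the
#' history entering the MA terms), then are integrated `d` times back to
#' the original scale. The h-step standard error is
#' \eqn{\sigma \sqrt{\sum_{j<h} \psi_j^2}} with original-scale psi weights,
#' and the bounds are Gaussian: point \eqn{\mp z_{(1+level)/2}} se.
#'
#' @param fit An `arima_css` fit (converged).
#' @param history Numeric series the forecast is anchored on; defaults to
#'   the series the model was fitted to. Must be at least
#'   `max(p, q) + d` long.
#' @param horizon Number of steps ahead (>= 1).
#' @param level Coverage probability of the prediction interval.
#' @return A tibble of class `neurocast_forecast` with columns `step`,
#'   `point`, `se`, `lower`, `upper`; `se` is non-decreasing in `step`.
#' @export
#' @examples
#' m <- arima_fixed(arima_order(1, 0, 0), ar = 0.5, series = c(0, 0, 2))
#' arima_forecast(m, horizon = 3)
arima_forecast <- function(fit, history = fit$series, horizon = 1L,
                           level = 0.95) {
  stopifnot(inherits(fit, "arima_css"))
  if (horizon < 1L) stopf("`horizon` must be >= 1")
  if (!isTRUE(fit$converged)) stopf("refusing to forecast from a non-converged fit")
  if (level <= 0 || level >= 1) stopf("`level` must be in (0, 1)")
  p <- fit$order[["p"]]; d <- fit$order[["d"]]; q <- fit$order[["q"]]
  x <- as.numeric(history)
  if (length(x) < max(p, q) + d) {
    stopf("history of length %d too short for ARIMA(%d,%d,%d)", length(x),
          p, d, q)
  }
  w <- if (d > 0) diff(x, differences = d) else x
  e <- css_residuals_cpp(w, fit$constant, fit$ar, fit$ma)
  nw <- length(w)
  wext <- c(w, numeric(horizon))
  eext <- c(e, numeric(horizon))
  for (j in seq_len(horizon)) {
    t <- nw + j
    v <- fit$constant
    for (i in seq_len(p)) v <- v + fit$ar[i] * wext[t - i]
    for (jj in seq_len(q)) v <- v + fit$ma[jj] * eext[t - jj]
    wext[t] <- v
  }
  wf <- wext[(nw + 1L):(nw + horizon)]

  point <- integrate_forecast(wf, x, d)
  psi <- psi_weights(fit, horizon)
  se <- sqrt(fit$sigma2) * sqrt(cumsum(psi^2))
  z <- qnorm((1 + level) / 2)
  out <- tibble::new_tibble(
    list(step = seq_len(horizon), point = point, se = se,
         lower = point - z * se, upper = point + z * se),
    nrow = horizon)
  class(out) <- c("neurocast_forecast", class(out))
  attr(out, "level") <- level
  out
}

# Integrate differenced-scale forecasts back to the original scale using
# the tails of the history.
integrate_forecast <- function(wf, x, d) {
  if (d == 0L) return(wf)
  tails <- numeric(d)
  xd <- x
  for (k in seq_len(d)) {
    tails[k] <- xd[length(xd)]
    xd <- diff(xd)
  }
  f <- wf
  for (k in d:1) f <- tails[k] + cumsum(f)
  f
}
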