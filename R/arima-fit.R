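# Durbin-Levinson map between partial autocorrelations and AR coefficients.
# Used to parameterise the optimiser so every iterate is stationary /
# invertible: unconstrained reals -> tanh -> partials in (-1, 1) -> coefs.
pacf_to_coef <- function(r) {
  p <- length(r)
  a <- numeric(p)
  for (k in seq_len(p)) {
    prev <- a[seq_len(k - 1L)]
    a[seq_len(k - 1L)] <- prev - r[k] * rev(prev)
    a[k] <- r[k]
  }
  a
}

coef_to_pacf <- function(a) {
  p <- length(a)
  r <- numeric(p)
  work <- a
  for (k in rev(seq_len(p))) {
    r[k] <- work[k]
    if (k > 1L) {
      denom <- 1 - work[k]^2
      if (denom < 1e-12) denom <- 1e-12
      prev <- work[seq_len(k - 1L)]
      work[seq_len(k - 1L)] <- (prev + work[k] * rev(prev)) / denom
    }
  }
  pmin(pmax(r, -0.999), 0.999)
}

unconstrained_to_ar <- function(u) pacf_to_coef(tanh(u))
# MA: theta such that 1 + sum(theta_j z^j) has roots outside the circle.
unconstrained_to_ma <- function(u) -pacf_to_coef(tanh(u))
ar_to_unconstrained <- function(phi) atanh(coef_to_pacf(phi))
ma_to_unconstrained <- function(theta) atanh(coef_to_pacf(-theta))

#' Validate an ARIMA order
#'
#' Orders follow the grid used throughout the pipeline: `p` in 1..10,
#' `d` in 0..2, `q` in 0..10.
#'
#' @param p,d,q Integer orders.
#' @return Named integer vector `c(p, d, q)`.
#' @export
arima_order <- function(p, d, q) {
  if (!p %in% 1:10) stopf("`p` must be in 1..10")
  if (!d %in% 0:2) stopf("`d` must be in 0..2")
  if (!q %in% 0:10) stopf("`q` must be in 0..10")
  c(p = as.integer(p), d = as.integer(d), q = as.integer(q))
}

#' Conditional-sum-of-squares Gaussian log-likelihood
#'
#' Computes residuals by the ARMA recursion
#' \eqn{e_t = y_t - c - \sum_i \phi_i y_{t-i} - \sum_j \theta_j e_{t-j}}
#' with residuals zero-initialised for \eqn{t \le \max(p, q)}, then the
#' Gaussian log-likelihood of the residual vector at the supplied
#' innovation variance.
#'
#' @param diffed Numeric vector (already differenced, if applicable).
#' @param constant Constant term `c`.
#' @param ar,ma Coefficient vectors \eqn{\phi}, \eqn{\theta}.
#' @param sigma2 Innovation variance (> 0).
#' @return Log-likelihood (scalar).
#' @export
css_loglik <- function(diffed, constant = 0, ar = numeric(),
                       ma = numeric(), sigma2 = 1) {
  if (sigma2 <= 0) stopf("`sigma2` must be > 0")
  e <- css_residuals(diffed, constant, ar, ma)
  sum(dnorm(e, sd = sqrt(sigma2), log = TRUE))
}

#' Conditional residuals of an ARMA recursion
#'
#' @inheritParams css_loglik
#' @return Residual vector (zeros for the first `max(p, q)` entries).
#' @export
css_residuals <- function(diffed, constant = 0, ar = numeric(),
                          ma = numeric()) {
  y <- as.numeric(diffed)
  if (max(length(ar), length(ma)) >= length(y)) {
    stopf("series shorter than the ARMA memory max(p, q)")
  }
  css_residuals_cpp(y, constant, as.numeric(ar), as.numeric(ma))
}

#' Fit an ARIMA model by conditional sum of squares
#'
#' Differences the series `d` times, then maximises the concentrated CSS
#' Gaussian likelihood over the constant and the ARMA coefficients, with
#' stationarity and invertibility enforced through a partial-autocorrelation
#' transform so every optimiser iterate is admissible. The constant is
#' estimated when `d = 0` and fixed to zero when `d >= 1` (a constant under
#' differencing would imply a deterministic polynomial trend). AIC counts
#' `k = p + q + 2` parameters (constant and innovation variance included).
#'
#' @param values Numeric series.
#' @param order `c(p, d, q)` as from [arima_order()].
#' @param init Optional warm start: a previous `arima_css` fit of the same
#'   order, or a list with `ar`, `ma`, `constant`.
#' @return An object of class `arima_css`: order, `constant`, `ar`, `ma`,
#'   `sigma2`, `loglik`, `aic`, `converged`, `n_used`, plus the series and
#'   residuals. Non-convergence is flagged, not thrown.
#' @seealso [select_order()], [arima_forecast()], [tidy.arima_css()]
#' @export
#' @examples
#' x <- generate_arma_series(ar = 0.6, n = 400, seed = 1)
#' fit <- fit_arima(x, arima_order(1, 0, 0))
#' tidy(fit)
fit_arima <- function(values, order, init = NULL) {
  order <- arima_order(order[1], order[2], order[3])
  p <- order[["p"]]; d <- order[["d"]]; q <- order[["q"]]
  x <- as.numeric(values)
  if (anyNA(x)) stopf("`values` must not contain missing data")
  if (length(x) <= p + q + d + 2) {
    stopf("series of length %d too short for ARIMA(%d,%d,%d): need > p+q+d+2 = %d",
          length(x), p, d, q, p + q + d + 2)
  }
  w <- if (d > 0) diff(x, differences = d) else x
  est_const <- d == 0L
  n_used <- length(w) - max(p, q)
  if (n_used < 3L) stopf("too few usable observations after conditioning")

  par0 <- c(if (est_const) 0 else NULL, numeric(p), numeric(q))
  if (!is.null(init)) {
    in_ar <- init$ar %||% numeric()
    in_ma <- init$ma %||% numeric()
    if (length(in_ar) == p && length(in_ma) == q) {
      par0 <- c(if (est_const) (init$constant %||% 0) else NULL,
                if (p) ar_to_unconstrained(in_ar) else NULL,
                if (q) ma_to_unconstrained(in_ma) else NULL)
      par0[!is.finite(par0)] <- 0
    }
  }
  if (var(x) == 0) stopf("series has zero variance; cannot fit ARMA")
  if (var(w) < 1e-20) {
    # differencing removed all variation (e.g. an exact polynomial trend):
    # the deterministic model with zero ARMA coefficients fits exactly
    cst <- if (est_const) mean(w) else 0
    rss <- sum((w - cst)^2)
    nw <- length(w)
    sigma2 <- max(rss / n_used, 1e-100) # keep the likelihood finite
    loglik <- -nw / 2 * (log(2 * pi * sigma2) + 1)
    return(structure(
      list(order = order, constant = cst, ar = numeric(p) + 0,
           ma = numeric(q) + 0, sigma2 = sigma2, loglik = loglik,
           aic = 2 * (p + q + 2) - 2 * loglik, converged = TRUE,
           n_used = n_used, series = x, diffed = w,
           residuals = w - cst),
      class = "arima_css"))
  }

  unpack <- function(par) {
    i <- 0L
    cst <- if (est_const) {par[1L]} else 0
    if (est_const) i <- 1L
    phi <- if (p) unconstrained_to_ar(par[(i + 1L):(i + p)]) else numeric()
    theta <- if (q) unconstrained_to_ma(par[(i + p + 1L):(i + p + q)]) else numeric()
    list(constant = cst, ar = phi, ma = theta)
  }
  objective <- function(par) {
    css_objective_cpp(par, w, p, q, est_const)
  }
  opt <- optim(par0, objective, method = "BFGS",
               control = list(reltol = 1e-8, maxit = 500))
  pr <- unpack(opt$par)
  rss <- css_rss_cpp(w, pr$constant, pr$ar, pr$ma)
  # sigma2 from the n_used conditional residuals; log-likelihood scaled to
  # the full differenced length so AIC stays comparable across orders that
  # condition away different numbers of points
  nw <- length(w)
  sigma2 <- rss / n_used
  loglik <- -nw / 2 * (log(2 * pi * sigma2) + 1)
  k <- p + q + 2
  aic <- 2 * k - 2 * loglik
  resid <- css_residuals_cpp(w, pr$constant, pr$ar, pr$ma)

  structure(
    list(order = order, constant = pr$constant, ar = pr$ar,
         ma = pr$ma, sigma2 = sigma2, loglik = loglik, aic = aic,
         converged = opt$convergence == 0L && is.finite(aic),
         n_used = n_used, series = x, diffed = w, residuals = resid),
    class = "arima_css"
  )
}

#' Construct an ARIMA model with fixed, known coefficients
#'
#' Builds an `arima_css` object directly from supplied coefficients without
#' estimation, e.g. to generate forecasts from a theoretical model.
#'
#' @param order `c(p, d, q)`.
#' @param ar,ma Coefficient vectors of lengths `p`, `q`.
#' @param constant Constant term (must be 0 when `d >= 1`).
#' @param sigma2 Innovation variance.
#' @param series Optional history attached to the fit for forecasting.
#' @return An `arima_css` object flagged as converged.
#' @export
#' @examples
#' m <- arima_fixed(arima_order(1, 0, 0), ar = 0.5, series = c(0, 1, 2))
#' arima_forecast(m, horizon = 3)$point # 1, 0.5, 0.25
arima_fixed <- function(order, ar = numeric(), ma = numeric(),
                        constant = 0, sigma2 = 1, series = NULL) {
  order <- arima_order(order[1], order[2], order[3])
  if (length(ar) != order["p"] || length(ma) != order["q"]) {
    stopf("`ar`/`ma` lengths must match the order (p = %d, q = %d)",
          order["p"], order["q"])
  }
  if (order["d"] > 0 && constant != 0) {
    stopf("`constant` must be 0 when d >= 1")
  }
  check_stationary(ar)
  check_invertible(ma)
  if (sigma2 <= 0) stopf("`sigma2` must be > 0")
  w <- NULL
  resid <- NULL
  if (!is.null(series)) {
    w <- if (order["d"] > 0) diff(series, differences = order["d"]) else series
    resid <- css_residuals_cpp(as.numeric(w), constant, as.numeric(ar),
                               as.numeric(ma))
  }
  structure(
    list(order = order, constant = constant, ar = as.numeric(ar),
         ma = as.numeric(ma), sigma2 = sigma2, loglik = NA_real_,
         aic = NA_real_, converged = TRUE,
         n_used = if (is.null(w)) 0L else length(w) - max(length(ar), length(ma)),
         series = series, diffed = w, residuals = resid),
    class = "arima_css"
  )
}

#' @export
print.arima_css <- function(x, ...) {
  cat(sprintf("ARIMA(%d,%d,%d) fit by conditional sum of squares\n",
              x$order["p"], x$order["d"], x$order["q"]))
  if (length(x$ar)) cat("  ar:   ", paste(signif(x$ar, 4), collapse = " "), "\n")
  if (length(x$ma)) cat("  ma:   ", paste(signif(x$ma, 4), collapse = " "), "\n")
  cat(sprintf("  constant %.4g, sigma^2 %.4g, logLik %.3f, AIC %.3f%s\n",
              x$constant, x$sigma2, x$loglik, x$aic,
              if (isTRUE(x$converged)) "" else "  [NOT converged]"))
  invisible(x)
}

#' Tidy an ARIMA fit
#'
#' @param x An `arima_css` fit.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`).
#' @export
tidy.arima_css <- function(x, ...) {
  terms <- c(if (x$order["d"] == 0) "constant",
             if (length(x$ar)) paste0("ar", seq_along(x$ar)),
             if (length(x$ma)) paste0("ma", seq_along(x$ma)))
  est <- c(if (x$order["d"] == 0) x$constant, x$ar, x$ma)
  tibble::tibble(term = terms %||% character(), estimate = est %||% numeric())
}

#' One-row summary of an ARIMA fit
#'
#' @param x An `arima_css` fit.
#' @param ... Unused.
#' @return Tibble: orders, `sigma2`, `loglik`, `aic`, `converged`,
#'   `n_used`.
#' @export
glance.arima_css <- function(x, ...) {
  tibble::tibble(p = x$order[["p"]], d = x$order[["d"]], q = x$order[["q"]],
                 sigma2 = x$sigma2, loglik = x$loglik, aic = x$aic,
                 converged = x$converged, n_used = x$n_used)
}

#' Serialise an ARIMA fit summary to JSON
#'
#' @param fit An `arima_css` fit.
#' @return JSON string with order, coefficients, variance, log-likelihood,
#'   AIC and convergence flag.
#' @export
arima_fit_json <- function(fit) {
  jsonlite::toJSON(list(
    order = unname(as.integer(fit$order)), constant = fit$constant,
    ar = fit$ar, ma = fit$ma, sigma2 = fit$sigma2, loglik = fit$loglik,
    aic = fit$aic, converged = fit$converged), auto_unbox = TRUE,
    digits = NA)
}
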