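#' Simulate an ARIMA process with known coefficients
#'
#' Generates a series whose d-times-differenced values follow the ARMA
#' recursion \deqn{w_t = \sum_i \phi_i w_{t-i} + \sum_j \theta_j e_{t-j} + e_t}
#' with zero constant and Gaussian innovations. Used to test estimators
#' against known ground truth. A burn-in of 500 samples is generated and
#' discarded so the output is free of initialisation transients.
#'
#' @param ar Numeric vector of AR coefficients \eqn{\phi_1..\phi_p} (may be
#'   empty). The AR polynomial must have all roots outside the unit circle.
#' @param ma Numeric vector of MA coefficients \eqn{\theta_1..\theta_q} (may
#'   be empty). The MA polynomial must be invertible.
#' @param d Integer differencing order in `0:2`; the simulated ARMA series is
#'   integrated (cumulatively summed) `d` times.
#' @param n Number of observations to return; must exceed
#'   `10 * (length(ar) + length(ma))`.
#' @param innovation_sd Standard deviation of the Gaussian innovations
#'   (0 allowed; gives the deterministic zero fixed point).
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- generate_arma_series(ar = 0.6, n = 500, seed = 1)
#' cor(x[-1], x[-length(x)]) # close to 0.6
generate_arma_series <- function(ar = numeric(), ma = numeric(), d = 0L,
                                 n, innovation_sd = 1, seed = 1L) {
  ar <- as.numeric(ar)
  ma <- as.numeric(ma)
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != floor(n)) {
    stopf("`n` must be a positive integer")
  }
  if (!d %in% 0:2) stopf("`d` must be 0, 1 or 2")
  if (!is.numeric(innovation_sd) || innovation_sd < 0) {
    stopf("`innovation_sd` must be >= 0")
  }
  if (n <= 10 * (length(ar) + length(ma))) {
    stopf("`n` must exceed 10 * (p + q) = %d", 10 * (length(ar) + length(ma)))
  }
  check_stationary(ar)
  check_invertible(ma)

  burn <- 500L
  n_arma <- n + burn
  e <- if (innovation_sd == 0) {
    numeric(n_arma)
  } else {
    with_seed(seed, rnorm(n_arma, sd = innovation_sd))
  }
  # MA part by one-sided convolution, AR part by the recursive filter.
  x <- if (length(ma)) {
    as.numeric(stats::filter(e, c(1, ma), method = "convolution",
                             sides = 1))
  } else {
    e
  }
  x[seq_along(ma)] <- e[seq_along(ma)] # drop NA head from the convolution
  if (length(ar)) {
    x <- as.numeric(stats::filter(x, ar, method = "recursive"))
  }
  x <- x[(burn + 1):n_arma]
  if (d > 0) for (k in seq_len(d)) x <- cumsum(x)
  x
}

# Stationarity: roots of 1 - sum(phi_i z^i) strictly outside the unit circle.
check_stationary <- function(ar, what = "AR") {
  if (!length(ar)) return(invisible(TRUE))
  roots <- polyroot(c(1, -ar))
  if (any(Mod(roots) <= 1 + 1e-8)) {
    stopf(paste0(
      "%s coefficients (%s) are non-stationary: polynomial root(s) on or ",
      "inside the unit circle (min modulus %.4f). Express unit roots via ",
      "the differencing order d instead."
    ), what, paste(signif(ar, 4), collapse = ", "), min(Mod(roots)))
  }
  invisible(TRUE)
}

# Invertibility: roots of 1 + sum(theta_j z^j) strictly outside the circle.
check_invertible <- function(ma) {
  if (!length(ma)) return(invisible(TRUE))
  roots <- polyroot(c(1, ma))
  if (any(Mod(roots) <= 1 + 1e-8)) {
    stopf(paste0(
      "MA coefficients (%s) are non-invertible: polynomial root(s) on or ",
      "inside the unit circle (min modulus %.4f)."
    ), paste(signif(ma, 4), collapse = ", "), min(Mod(roots)))
  }
  invisible(TRUE)
}
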