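# Independent brute-force oracles: direct transcriptions of the defining
# formulas, kept free of any package internals they are used to check.

naive_mae <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - yhat[i])
  s / length(y)
}

naive_rmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  sqrt(s / length(y))
}

naive_r2 <- function(y, yhat) {
  yb <- sum(y) / length(y)
  ss_res <- 0; ss_tot <- 0
  for (i in seq_along(y)) {
    ss_res <- ss_res + (y[i] - yhat[i])^2
    ss_tot <- ss_tot + (y[i] - yb)^2
  }
  1 - ss_res / ss_tot
}

naive_pearson <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sum((x - xb) * (y - yb)) /
    sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

naive_acf <- function(x, n_lags) {
  n <- length(x); xb <- mean(x)
  c0 <- sum((x - xb)^2) / n
  vapply(0:n_lags, function(k) {
    sum((x[seq_len(n - k)] - xb) * (x[(k + 1):n] - xb)) / n / c0
  }, numeric(1))
}

# Least-squares single-sinusoid amplitude at a known frequency.
ls_sine_amp <- function(x, freq, fs) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  b <- stats::lm.fit(cbind(1, X), x)$coefficients
  sqrt(b[2]^2 + b[3]^2)
}

# A quiet sim_config for fast derivation tests.
quiet_config <- function(...) {
  sim_config(map_drift_sd = 0, icp_drift_sd = 0, pbto2_drift_sd = 0,
             noise_sd = 0, ...)
}
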