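#' AIC grid search over ARIMA orders
#'
#' Fits every admissible order on the grid (default: `p` 1..10, `d` 0..2,
#' `q` 0..10) and returns the converged fit with the
#' lowest AIC. Ties (AIC equal to within 1e-9) are broken by smaller
#' `p + q`, then smaller `q`, then smaller `d`. Orders that fail to fit or
#' to converge are skipped and logged.
#'
#' @param values Numeric series.
#' @param p_range,d_range,q_range Integer vectors of candidate orders,
#'   within the printed bounds (`p` 1..10, `d` 0..2, `q` 0..10). Shrunken
#'   grids keep the search tractable on short series.
#' @return A list with `order` (named `c(p, d, q)`), `fit` (the winning
#'   `arima_css`), `candidates` (tibble of per-order AICs) and `skipped`
#'   (tibble of per-order failure reasons).
#' @export
#' @examples
#' x <- generate_arma_series(ar = c(1.2, -0.5), n = 300, seed = 4)
#' sel <- select_order(x, p_range = 1:3, d_range = 0, q_range = 0:1)
#' sel$order
select_order <- function(values, p_range = 1:10, d_range = 0:2,
                         q_range = 0:10) {
  if (!all(p_range %in% 1:10)) stopf("`p_range` must lie within 1..10")
  if (!all(d_range %in% 0:2)) stopf("`d_range` must lie within 0..2")
  if (!all(q_range %in% 0:10)) stopf("`q_range` must lie within 0..10")
  grid <- expand.grid(p = as.integer(p_range), d = as.integer(d_range),
                      q = as.integer(q_range))
  fits <- vector("list", nrow(grid))
  aics <- rep(NA_real_, nrow(grid))
  skipped <- list()
  for (i in seq_len(nrow(grid))) {
    o <- c(grid$p[i], grid$d[i], grid$q[i])
    res <- tryCatch(fit_arima(values, o), error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(p = o[1], d = o[2], q = o[3],
                       reason = conditionMessage(res))
      next
    }
    if (!isTRUE(res$converged)) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(p = o[1], d = o[2], q = o[3],
                       reason = "optimizer did not converge")
      next
    }
    fits[[i]] <- res
    aics[i] <- res$aic
  }
  ok <- which(!is.na(aics))
  if (!length(ok)) {
    log_tbl <- dplyr::bind_rows(skipped)
    stop(structure(
      class = c("neurocast_select_error", "error", "condition"),
      list(message = sprintf(
        "no ARIMA order on the grid could be fitted (%d failures)",
        nrow(log_tbl)),
        call = sys.call(-1), log = log_tbl)))
  }
  cand <- grid[ok, , drop = FALSE]
  cand$aic <- aics[ok]
  # minimum AIC with deterministic tie-breaks: p + q, then q, then d
  best_aic <- min(cand$aic)
  tied <- cand[cand$aic - best_aic < 1e-9, , drop = FALSE]
  tied <- tied[order(tied$p + tied$q, tied$q, tied$d), , drop = FALSE]
  win <- tied[1L, ]
  idx <- ok[which(cand$p == win$p & cand$d == win$d & cand$q == win$q)]
  list(order = c(p = win$p, d = win$d, q = win$q),
       fit = fits[[idx]],
       candidates = tibble::as_tibble(cand),
       skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
         tibble::tibble(p = integer(), d = integer(), q = integer(),
                        reason = character()))
}
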