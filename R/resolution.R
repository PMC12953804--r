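#' Reduce a minute-resolution signal to a lower temporal resolution
#'
#' Non-overlapping averaging of a minute-by-minute signal into windows of
#' `resolution` minutes, drawn from the supported ladder
#' ([resolution_ladder()]). A window's value is the mean of its non-missing
#' minutes and is valid only when at least 50% of the window's minutes are
#' present; a trailing incomplete window is dropped. Resolution 1 is the
#' identity.
#'
#' @param minute_values Numeric vector of minute values; `NA` marks missing.
#' @param resolution Window length in minutes, from the ladder.
#' @param signal_name Optional label carried on the result.
#' @return A `resolution_series` object: list with `signal_name`,
#'   `resolution`, `values` (numeric with `NA` for invalid windows) and
#'   `segments` (`NULL` until [handle_gaps()] is applied).
#' @export
#' @examples
#' reduce_resolution(1:10, 5)$values # 3, 8
reduce_resolution <- function(minute_values, resolution,
                              signal_name = NA_character_) {
  if (!resolution %in% resolution_ladder()) {
    stopf("`resolution` must be one of %s minutes",
          paste(resolution_ladder(), collapse = ", "))
  }
  k <- as.integer(resolution)
  x <- as.numeric(minute_values)
  if (k == 1L) {
    return(new_resolution_series(x, k, signal_name))
  }
  n_win <- length(x) %/% k
  if (n_win == 0L) return(new_resolution_series(numeric(), k, signal_name))
  m <- matrix(x[seq_len(n_win * k)], nrow = k)
  present <- colSums(!is.na(m))
  vals <- ifelse(present >= k / 2, colMeans(m, na.rm = TRUE), NA_real_)
  new_resolution_series(as.numeric(vals), k, signal_name)
}

new_resolution_series <- function(values, resolution, signal_name,
                                  segments = NULL) {
  structure(
    list(signal_name = signal_name, resolution = as.integer(resolution),
         values = values, segments = segments),
    class = "resolution_series"
  )
}

#' @export
print.resolution_series <- function(x, ...) {
  cat(sprintf("<resolution_series> %s @ %d min: %d points, %d missing%s\n",
              x$signal_name %||% "?", x$resolution, length(x$values),
              sum(is.na(x$values)),
              if (is.null(x$segments)) "" else
                sprintf(", %d segment(s)", nrow(x$segments))))
  invisible(x)
}

#' @export
as_tibble.resolution_series <- function(x, ...) {
  tibble::tibble(index = seq_along(x$values), value = x$values,
                 valid = !is.na(x$values))
}

#' Apply the short-gap interpolation / long-gap removal rule
#'
#' Missing runs of fewer than five consecutive points are filled by linear
#' interpolation between the flanking observed values; runs of five or more
#' are removed, splitting the series into contiguous segments. Leading and
#' trailing missing runs are trimmed (there is no flank to interpolate
#' from).
#'
#' @param series A `resolution_series` (or bare numeric vector with `NA`
#'   for missing).
#' @return A `resolution_series` whose `values` contain interpolated data
#'   (still `NA` on removed spans) and whose `segments` tibble lists the
#'   contiguous valid runs as 1-based inclusive `start`/`end` indices.
#' @export
#' @examples
#' s <- handle_gaps(c(1, 2, NA, NA, 5, 6))
#' s$values  # 1 2 3 4 5 6
#' s$segments
handle_gaps <- function(series) {
  if (is.numeric(series)) {
    series <- new_resolution_series(as.numeric(series), 1L, NA_character_)
  }
  if (!inherits(series, "resolution_series")) {
    stopf("`series` must be a resolution_series or numeric vector")
  }
  x <- series$values
  n <- length(x)
  if (n == 0L || all(is.na(x))) {
    series$segments <- tibble::tibble(segment = integer(), start = integer(),
                                      end = integer())
    return(series)
  }
  runs <- logical_runs(is.na(x))
  obs <- which(!is.na(x))
  first_obs <- obs[1L]; last_obs <- obs[length(obs)]
  for (i in seq_len(nrow(runs))) {
    if (!runs$value[i]) next
    s <- runs$start[i]; e <- runs$end[i]; len <- runs$length[i]
    interior <- s > first_obs && e < last_obs
    if (interior && len < 5L) {
      # linear fill between the flanking observed values
      x[s:e] <- approx(x = c(s - 1L, e + 1L), y = c(x[s - 1L], x[e + 1L]),
                       xout = s:e)$y
    }
    # len >= 5 (or a boundary run): stays NA -> removed span
  }
  seg_runs <- logical_runs(!is.na(x))
  segs <- seg_runs[seg_runs$value, , drop = FALSE]
  series$values <- x
  series$segments <- tibble::tibble(segment = seq_len(nrow(segs)),
                                    start = segs$start, end = segs$end)
  series
}

#' Longest contiguous segment of a gap-handled series
#'
#' Modeling proceeds on the longest contiguous segment when long-gap
#' removal splits a series, avoiding fabricated continuity across removed
#' spans. Earlier segments win ties.
#'
#' @param series A `resolution_series` processed by [handle_gaps()].
#' @return Numeric vector of the longest segment's values (may be empty).
#' @export
longest_segment <- function(series) {
  if (!inherits(series, "resolution_series") || is.null(series$segments)) {
    stopf("`series` must be a resolution_series processed by handle_gaps()")
  }
  segs <- series$segments
  if (nrow(segs) == 0L) return(numeric())
  len <- segs$end - segs$start + 1L
  i <- which.max(len)
  series$values[segs$start[i]:segs$end[i]]
}

#' Iterated first differences with exact inversion
#'
#' Applies first-order differencing `d` times; the initial values needed to
#' reverse the transform are stored as an attribute so
#' [undifference()] reproduces the input exactly.
#'
#' @param values Numeric vector of length greater than `d`.
#' @param d Differencing order in `0:2`.
#' @return Differenced vector of length `length(values) - d`, with
#'   attribute `initials` (the first `d` original values).
#' @export
#' @examples
#' difference(c(1, 4, 9, 16), 1) # 3 5 7
difference <- function(values, d) {
  if (!d %in% 0:2) stopf("`d` must be 0, 1 or 2")
  if (length(values) <= d) stopf("series length must exceed d = %d", d)
  if (d == 0L) return(values)
  out <- diff(values, differences = d)
  attr(out, "initials") <- values[seq_len(d)]
  attr(out, "d") <- as.integer(d)
  out
}

#' Invert iterated differencing
#'
#' @param diffed Output of [difference()], or any numeric vector.
#' @param d Differencing order used (taken from the attribute when absent).
#' @param initials The first `d` values of the original series (taken from
#'   the attribute when absent).
#' @return The reconstructed original series.
#' @export
undifference <- function(diffed, d = attr(diffed, "d"),
                         initials = attr(diffed, "initials")) {
  if (is.null(d) || d == 0L) return(as.numeric(diffed))
  if (length(initials) != d) {
    stopf("`initials` must supply exactly d = %d values", d)
  }
  as.numeric(stats::diffinv(as.numeric(diffed), differences = d,
                            xi = initials))
}
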