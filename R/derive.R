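#' Non-overlapping 10-s block means of a waveform channel
#'
#' Downsamples a uniform-rate signal with a 10-s non-overlapping moving
#' average, the standard pre-processing step that suppresses the cardiac and
#' respiratory components and exposes the slow vasogenic waves.
#'
#' @param signal Numeric vector sampled at `sampling_rate`.
#' @param sampling_rate Sampling rate in Hz; `10 * sampling_rate` must be a
#'   whole number of samples.
#' @param missing_mask Optional logical vector flagging missing samples.
#' @return A tibble with one row per complete 10-s frame: `frame`
#'   (1-based), `mean` (mean of the unmasked samples, `NA` when invalid)
#'   and `valid` (`TRUE` when at least 50% of the frame's samples are
#'   unmasked). A trailing incomplete frame is dropped.
#' @export
#' @examples
#' block_mean_10s(rep(10, 3000), 100)
block_mean_10s <- function(signal, sampling_rate, missing_mask = NULL) {
  check_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  frame_len <- sampling_rate * 10
  if (abs(frame_len - round(frame_len)) > 1e-9) {
    stopf("`sampling_rate` must give a whole number of samples per 10-s frame")
  }
  frame_len <- as.integer(round(frame_len))
  n <- length(signal)
  if (is.null(missing_mask)) missing_mask <- logical(n)
  if (length(missing_mask) != n) {
    stopf("`missing_mask` must match `signal` in length")
  }
  n_frames <- n %/% frame_len
  if (n_frames == 0L) {
    return(tibble::tibble(frame = integer(), mean = numeric(),
                          valid = logical()))
  }
  use <- seq_len(n_frames * frame_len)
  vals <- matrix(signal[use], nrow = frame_len)
  miss <- matrix(missing_mask[use], nrow = frame_len)
  vals[miss] <- NA_real_
  present <- frame_len - colSums(miss)
  valid <- present >= frame_len / 2
  means <- ifelse(valid, colMeans(vals, na.rm = TRUE), NA_real_)
  tibble::tibble(frame = seq_len(n_frames), mean = as.numeric(means),
                 valid = valid)
}

#' Pulse amplitude of a 10-s pressure frame
#'
#' Estimates AMP, the amplitude of the cardiac-frequency component of the
#' ICP pulse waveform, from one 10-s frame: the frame is tapered with a
#' periodic Hann window, transformed by DFT, and the largest-magnitude bin
#' in the cardiac band 0.67--3.0 Hz is converted back to pressure units by
#' undoing the window's coherent gain.
#'
#' @param frame Numeric vector of exactly `10 * sampling_rate` samples with
#'   no missing values (frames failing validity yield a missing AMP
#'   upstream).
#' @param sampling_rate Sampling rate in Hz.
#' @return Pulse amplitude in mmHg (>= 0). A constant frame returns 0: the
#'   cardiac band excludes DC.
#' @export
#' @examples
#' t <- (0:999) / 100
#' compute_amp(5 * sin(2 * pi * 1.2 * t), 100) # ~5
compute_amp <- function(frame, sampling_rate) {
  frame_len <- as.integer(round(sampling_rate * 10))
  if (length(frame) != frame_len) {
    stopf("`frame` must hold exactly 10 s of samples (%d), got %d",
          frame_len, length(frame))
  }
  if (anyNA(frame)) stopf("`frame` must not contain missing samples")
  n <- frame_len
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n)) # periodic Hann
  spec <- stats::fft((frame - mean(frame)) * w)
  freqs <- (seq_len(n) - 1) / 10 # bin width 0.1 Hz for a 10-s frame
  band <- which(freqs >= 0.67 & freqs <= 3.0)
  if (!length(band)) stopf("cardiac band empty below Nyquist; sampling_rate too low")
  mags <- Mod(spec[band])
  # amplitude A of a sinusoid at a bin: |X| = A * n * mean(w) / 2
  2 * max(mags) / (n * mean(w))
}

#' Cerebral perfusion pressure
#'
#' `CPP = MAP - ICP`, in mmHg. Negative values are permitted (physiologically
#' implausible but diagnostically informative).
#'
#' @param map_mean,icp_mean Mean arterial and intracranial pressure (mmHg);
#'   vectorised.
#' @return `map_mean - icp_mean`.
#' @export
#' @examples
#' compute_cpp(87, 12) # 75
compute_cpp <- function(map_mean, icp_mean) {
  map_mean - icp_mean
}

#' Pearson correlation with degenerate-input handling
#'
#' Product-moment correlation of two equal-length vectors. Zero variance in
#' either input yields `NA` (missing) rather than an error, matching the
#' pipeline's treatment of flat windows.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  if (length(x) < 3L) stopf("correlation needs at least 3 points")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Moving correlation index over 10-s frames
#'
#' Computes a cerebrovascular reactivity index: the Pearson correlation of
#' two 10-s mean series over a trailing window of 30 frames (5 min),
#' updated every minute (stride 6 frames). Minutes whose window extends
#' before the record, or contains any invalid frame, are missing.
#'
#' @param x,y Numeric vectors of 10-s means (`NA` marks invalid frames).
#' @return Numeric vector with one value per whole minute
#'   (`floor(length(x) / 6)` entries); `NA` where undefined.
#' @export
moving_correlation_index <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  n_minutes <- length(x) %/% 6L
  out <- rep(NA_real_, n_minutes)
  for (m in seq_len(n_minutes)) {
    end <- 6L * m
    if (end < 30L) next
    idx <- (end - 29L):end
    out[m] <- pearson(x[idx], y[idx])
  }
  out
}

#' Derive the minute-by-minute signal table from a waveform record
#'
#' Chains the full derivation: 10-s block means of ABP (-> MAP), ICP and
#' PbtO2; AMP per fully-observed 10-s ICP frame; CPP = MAP - ICP; the four
#' reactivity indices as trailing 30-frame moving correlations updated per
#' minute (PRx: ICP~MAP, PAx: AMP~MAP, RAC: AMP~CPP, RAP: AMP~ICP); and
#' minute means (6 frames, at least 4 valid) of the five magnitude signals.
#'
#' @param record A `waveform_record`.
#' @return A tibble with columns `minute` (0-based), `MAP`, `ICP`, `CPP`,
#'   `PbtO2`, `AMP`, `PRx`, `PAx`, `RAC`, `RAP`; one row per whole minute.
#'   Records without a PbtO2 channel carry an all-`NA` `PbtO2` column.
#' @export
#' @examples
#' rec <- generate_patient_waveforms(sim_config(duration = 10, seed = 2))
#' head(derive_minute_record(rec))
derive_minute_record <- function(record) {
  if (!inherits(record, "waveform_record")) {
    stopf("`record` must be a waveform_record")
  }
  fs <- record$sampling_rate
  frame_len <- as.integer(round(fs * 10))
  map_f <- block_mean_10s(record$abp, fs, record$abp_missing)
  icp_f <- block_mean_10s(record$icp, fs, record$icp_missing)
  n_frames <- nrow(map_f)
  n_minutes <- n_frames %/% 6L
  if (n_minutes < 6L) {
    stopf("record too short: need at least 6 whole minutes, got %d", n_minutes)
  }

  # AMP per frame, only where every sample of the frame is observed.
  amp_f <- rep(NA_real_, n_frames)
  for (k in seq_len(n_frames)) {
    idx <- ((k - 1L) * frame_len + 1L):(k * frame_len)
    if (!any(record$icp_missing[idx])) {
      amp_f[k] <- compute_amp(record$icp[idx], fs)
    }
  }

  map_v <- ifelse(map_f$valid, map_f$mean, NA_real_)
  icp_v <- ifelse(icp_f$valid, icp_f$mean, NA_real_)
  cpp_v <- compute_cpp(map_v, icp_v)

  pbt_v <- rep(NA_real_, n_frames)
  if (!is.null(record$pbto2)) {
    pbt_f <- block_mean_10s(record$pbto2, fs, record$pbto2_missing)
    pbt_v <- ifelse(pbt_f$valid, pbt_f$mean, NA_real_)
  }

  minute_mean <- function(v) {
    vapply(seq_len(n_minutes), function(m) {
      win <- v[((m - 1L) * 6L + 1L):(m * 6L)]
      if (sum(!is.na(win)) >= 4L) mean(win, na.rm = TRUE) else NA_real_
    }, numeric(1))
  }

  tibble::tibble(
    minute = seq_len(n_minutes) - 1L,
    MAP = minute_mean(map_v),
    ICP = minute_mean(icp_v),
    CPP = minute_mean(cpp_v),
    PbtO2 = minute_mean(pbt_v),
    AMP = minute_mean(amp_f),
    PRx = moving_correlation_index(icp_v, map_v)[seq_len(n_minutes)],
    PAx = moving_correlation_index(amp_f, map_v)[seq_len(n_minutes)],
    RAC = moving_correlation_index(amp_f, cpp_v)[seq_len(n_minutes)],
    RAP = moving_correlation_index(amp_f, icp_v)[seq_len(n_minutes)]
  )
}
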