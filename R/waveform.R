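#' Generate a synthetic patient waveform record
#'
#' Builds uniform-rate ABP, ICP and (optionally) PbtO2 traces from a
#' [sim_config()]. The construction is additive and fully seeded:
#'
#' * ABP = baseline + drift + slow vasogenic waves + respiratory wave +
#'   cardiac pulse (fundamental plus two harmonics) + white noise;
#' * ICP = baseline + drift + `g` x (MAP slow-wave component) + independent
#'   ICP slow wave + cardiac pulse whose amplitude is modulated by the
#'   normalised ICP slow-wave level + white noise;
#' * PbtO2 = baseline + drift + gain x (CPP slow-wave component lagged by
#'   `pbto2_lag` seconds) + white noise.
#'
#' @param config A [sim_config()].
#' @return A `waveform_record`: list with `patient_id`, `sampling_rate`,
#'   numeric channels `abp`, `icp`, `pbto2` (or `NULL`) and logical
#'   missingness masks `abp_missing`, `icp_missing`, `pbto2_missing`.
#'   All channels share length `duration * 60 * sampling_rate`.
#' @export
#' @examples
#' rec <- generate_patient_waveforms(sim_config(duration = 10, seed = 7))
#' length(rec$icp) / rec$sampling_rate / 60 # 10 minutes
generate_patient_waveforms <- function(config) {
  if (!inherits(config, "sim_config")) stopf("`config` must be a sim_config")
  fs <- config$sampling_rate
  n <- round(config$duration * 60 * fs)
  t <- (seq_len(n) - 1) / fs
  minutes <- ceiling(config$duration)

  with_seed(config$seed, {
    phase_of <- function(w) if (length(w) >= 3 && is.finite(w[3])) w[3] else runif(1, 0, 2 * pi)
    wave_sum <- function(waves) {
      out <- numeric(n)
      for (w in waves) out <- out + w[2] * sin(2 * pi * w[1] * t + phase_of(w))
      out
    }
    drift_of <- function(sd_per_min) {
      if (sd_per_min == 0 || minutes < 2) return(numeric(n))
      walk <- cumsum(c(0, rnorm(minutes, sd = sd_per_min)))
      approx(x = (0:minutes) * 60, y = walk, xout = t, rule = 2)$y
    }

    map_slow <- wave_sum(config$slow_waves)
    icp_own <- wave_sum(config$icp_slow_waves)
    phi_resp <- runif(1, 0, 2 * pi)
    phi_card <- runif(3, 0, 2 * pi)

    harm <- c(1, 0.3, 0.15)
    cardiac_abp <- numeric(n)
    for (k in 1:3) {
      cardiac_abp <- cardiac_abp + config$pulse_pressure * harm[k] *
        sin(2 * pi * k * config$cardiac_freq * t + phi_card[k])
    }

    map_drift <- drift_of(config$map_drift_sd)
    icp_drift <- drift_of(config$icp_drift_sd)

    abp <- config$map_baseline + map_drift + map_slow +
      config$resp_amp * sin(2 * pi * config$resp_freq * t + phi_resp) +
      cardiac_abp +
      (if (config$noise_sd > 0) rnorm(n, sd = config$noise_sd) else 0)

    icp_slow <- config$autoregulation_gain * map_slow + icp_own
    # Pulse amplitude rides on the slow-wave level (amplitude-pressure
    # coupling); normalised so the modulation is scale-free.
    slow_span <- max(abs(icp_slow))
    norm_slow <- if (slow_span > 0) icp_slow / slow_span else icp_slow
    pulse_amp <- pmax(config$icp_pulse_base *
                        (1 + config$amp_icp_coupling * norm_slow), 0.05)
    cardiac_icp <- pulse_amp * sin(2 * pi * config$cardiac_freq * t + phi_card[1]) +
      0.25 * pulse_amp * sin(2 * pi * 2 * config$cardiac_freq * t + phi_card[2])
    icp <- config$icp_baseline + icp_drift + icp_slow + cardiac_icp +
      (if (config$noise_sd > 0) rnorm(n, sd = config$noise_sd) else 0)

    pbto2 <- NULL
    if (is.finite(config$pbto2_baseline)) {
      cpp_slow <- (map_slow + map_drift) - (icp_slow + icp_drift)
      lag_n <- round(config$pbto2_lag * fs)
      lagged <- if (lag_n > 0 && lag_n < n) {
        c(rep(cpp_slow[1], lag_n), cpp_slow[seq_len(n - lag_n)])
      } else {
        cpp_slow
      }
      pbto2 <- config$pbto2_baseline + drift_of(config$pbto2_drift_sd) +
        config$pbto2_cpp_gain * lagged +
        (if (config$noise_sd > 0) rnorm(n, sd = config$noise_sd) else 0)
    }

    rec <- new_waveform_record(config$patient_id, fs, abp, icp, pbto2)
    if (length(config$missing_spec)) {
      gaps <- place_random_gaps(n, config$missing_spec)
      rec <- inject_missingness(rec, gaps)
    }
    rec
  })
}

new_waveform_record <- function(patient_id, sampling_rate, abp, icp,
                                pbto2 = NULL) {
  n <- length(abp)
  if (length(icp) != n || (!is.null(pbto2) && length(pbto2) != n)) {
    stopf("all channels of a waveform record must have equal length")
  }
  structure(
    list(patient_id = patient_id, sampling_rate = sampling_rate,
         abp = abp, icp = icp, pbto2 = pbto2,
         abp_missing = logical(n), icp_missing = logical(n),
         pbto2_missing = if (is.null(pbto2)) NULL else logical(n)),
    class = "waveform_record"
  )
}

# Draw non-overlapping gap positions for each (length, count) request.
# Assumes the seeded stream of the caller.
place_random_gaps <- function(n, missing_spec) {
  taken <- logical(n)
  out <- list()
  for (spec in missing_spec) {
    len <- as.integer(spec[1]); count <- as.integer(spec[2])
    for (i in seq_len(count)) {
      for (attempt in 1:100) {
        start <- sample.int(n - len + 1L, 1L)
        idx <- start:(start + len - 1L)
        if (!any(taken[idx])) {
          taken[idx] <- TRUE
          out[[length(out) + 1L]] <- c(start = start, length = len)
          break
        }
      }
    }
  }
  out
}

#' Flag samples of a waveform record as missing
#'
#' Marks sample runs as missing in every channel's mask. The underlying
#' values are preserved beneath the mask, so tests can compare derived
#' quantities against the unmasked truth.
#'
#' @param record A `waveform_record`.
#' @param gaps List of `c(start, length)` pairs (1-based sample indices), or
#'   a two-column matrix/data frame with columns `start` and `length`.
#' @return The record with updated missingness masks.
#' @export
inject_missingness <- function(record, gaps) {
  if (!inherits(record, "waveform_record")) {
    stopf("`record` must be a waveform_record")
  }
  if (is.data.frame(gaps) || is.matrix(gaps)) {
    gaps <- apply(as.matrix(gaps[, c("start", "length")]), 1L, identity,
                  simplify = FALSE)
  }
  n <- length(record$abp)
  mask <- logical(n)
  for (g in gaps) {
    start <- as.integer(g[[1]]); len <- as.integer(g[[2]])
    if (len < 1L || start < 1L || start + len - 1L > n) {
      stopf("gap (start %d, length %d) is out of record bounds [1, %d]",
            start, len, n)
    }
    idx <- start:(start + len - 1L)
    if (any(mask[idx])) stopf("overlapping gaps at samples %d..%d", start,
                              start + len - 1L)
    mask[idx] <- TRUE
  }
  record$abp_missing <- record$abp_missing | mask
  record$icp_missing <- record$icp_missing | mask
  if (!is.null(record$pbto2_missing)) {
    record$pbto2_missing <- record$pbto2_missing | mask
  }
  record
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf(
    "<waveform_record> %s: %d samples at %g Hz (%.1f min)%s, %d flagged missing\n",
    x$patient_id, length(x$abp), x$sampling_rate,
    length(x$abp) / x$sampling_rate / 60,
    if (is.null(x$pbto2)) ", no PbtO2" else "", sum(x$icp_missing)))
  invisible(x)
}

#' @export
as_tibble.waveform_record <- function(x, ...) {
  out <- tibble::tibble(
    time = (seq_along(x$abp) - 1) / x$sampling_rate,
    abp = x$abp, icp = x$icp,
    abp_missing = x$abp_missing, icp_missing = x$icp_missing)
  if (!is.null(x$pbto2)) {
    out$pbto2 <- x$pbto2
    out$pbto2_missing <- x$pbto2_missing
  }
  out
}

#' Simulate a cohort of synthetic patients
#'
#' Generates `n_patients` waveform records with per-patient seeds derived
#' from `seed`. By default patients alternate between impaired
#' (`autoregulation_gain = +1`) and intact (`-1`) cerebrovascular
#' reactivity, and a third of patients lack the PbtO2 channel (probe not
#' placed), mirroring the partial availability of brain oxygen monitoring.
#'
#' @param n_patients Number of patients.
#' @param duration Record length in minutes (shared).
#' @param seed Integer master seed.
#' @param ... Further overrides passed to every patient's [sim_config()].
#' @return Named list of `waveform_record`s.
#' @export
simulate_cohort <- function(n_patients, duration = 720, seed = 1L, ...) {
  stopifnot(n_patients >= 1)
  purrr::map(seq_len(n_patients), function(i) {
    cfg <- sim_config(
      patient_id = sprintf("P%03d", i),
      duration = duration,
      autoregulation_gain = if (i %% 2L == 1L) 1.0 else -1.0,
      pbto2_baseline = if (i %% 3L == 0L) NA_real_ else 25,
      seed = as.integer(seed) + 1013L * i,
      ...)
    generate_patient_waveforms(cfg)
  }) |>
    stats::setNames(sprintf("P%03d", seq_len(n_patients)))
}
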