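#' Configuration for a synthetic neuromonitoring patient
#'
#' Describes one synthetic patient record: uniform-rate arterial blood
#' pressure (ABP), intracranial pressure (ICP) and optional brain tissue
#' oxygen (PbtO2) traces built from a cardiac pulse, a respiratory
#' oscillation, slow vasogenic waves in the 0.005--0.05 Hz band, a signed
#' MAP-to-ICP autoregulation coupling, minute-scale random-walk drift and
#' additive Gaussian noise.
#'
#' The autoregulation gain `g` maps the MAP slow-wave component into ICP:
#' positive gain emulates impaired cerebrovascular reactivity (passive
#' pressure transmission, PRx > 0), negative gain emulates intact reactivity
#' (counter-regulation, PRx < 0). ICP additionally carries its own
#' independent slow wave so the imposed coupling is recoverable but not
#' degenerate.
#'
#' @param patient_id Character label for the record.
#' @param sampling_rate Sampling rate in Hz (default 100, the usual bedside
#'   ICP acquisition rate).
#' @param duration Record length in minutes.
#' @param map_baseline,icp_baseline Baseline MAP / ICP in mmHg (defaults 87
#'   and 12, typical adult TBI cohort medians).
#' @param cardiac_freq Cardiac frequency in Hz; must be a multiple of 0.1 Hz
#'   so a 10-s spectral frame holds a whole number of cycles (default 1.2,
#'   i.e. 72 bpm).
#' @param resp_freq,resp_amp Respiratory frequency (Hz) and ABP amplitude
#'   (mmHg).
#' @param slow_waves List of `c(freq, amp)` or `c(freq, amp, phase)` slow
#'   vasogenic components on MAP; frequencies must lie in \[0.005, 0.05\] Hz.
#'   Missing phases are drawn uniformly from the seeded stream.
#' @param icp_slow_waves Same structure; slow components private to ICP.
#' @param autoregulation_gain Signed dimensionless gain `g` coupling the MAP
#'   slow-wave component into ICP.
#' @param pulse_pressure Amplitude (mmHg) of the ABP cardiac fundamental.
#' @param icp_pulse_base Baseline amplitude (mmHg) of the ICP cardiac pulse.
#' @param amp_icp_coupling Dimensionless gain `a`: the ICP pulse amplitude is
#'   `icp_pulse_base * (1 + a * normalised ICP slow wave)`, emulating the
#'   amplitude--pressure relationship that AMP-based indices exploit.
#' @param pbto2_baseline Baseline PbtO2 in mmHg; `NA` omits the channel.
#' @param pbto2_cpp_gain Gain from the (lagged) CPP slow-wave into PbtO2.
#' @param pbto2_lag Lag in seconds of the PbtO2 response (default 20).
#' @param map_drift_sd,icp_drift_sd,pbto2_drift_sd Standard deviation
#'   (mmHg per sqrt-minute) of minute-scale random-walk baseline drift,
#'   linearly interpolated to sample resolution. Gives hour-scale averages
#'   realistic non-trivial dynamics.
#' @param noise_sd Additive white-noise standard deviation per channel
#'   (mmHg).
#' @param missing_spec List of `c(gap_length_samples, count)` pairs; gaps are
#'   placed at seeded random positions by [generate_patient_waveforms()].
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   records.
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_patient_waveforms()], [simulate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(duration = 30, autoregulation_gain = -1)
#' cfg$icp_baseline
sim_config <- function(patient_id = "P001",
                       sampling_rate = 100,
                       duration = 120,
                       map_baseline = 87,
                       icp_baseline = 12,
                       cardiac_freq = 1.2,
                       resp_freq = 0.25,
                       resp_amp = 2,
                       slow_waves = list(c(0.0083, 3), c(0.0222, 2),
                                         c(0.0455, 1)),
                       icp_slow_waves = list(c(0.012, 0.8)),
                       autoregulation_gain = 1.0,
                       pulse_pressure = 20,
                       icp_pulse_base = 2,
                       amp_icp_coupling = 0.5,
                       pbto2_baseline = 25,
                       pbto2_cpp_gain = 0.3,
                       pbto2_lag = 20,
                       map_drift_sd = 0.3,
                       icp_drift_sd = 0.15,
                       pbto2_drift_sd = 0.1,
                       noise_sd = 1,
                       missing_spec = list(),
                       seed = 1L) {
  check_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar_number(duration, "duration", positive = TRUE)
  check_scalar_number(cardiac_freq, "cardiac_freq", positive = TRUE)
  if (abs(cardiac_freq / 0.1 - round(cardiac_freq / 0.1)) > 1e-9) {
    stopf("`cardiac_freq` must be an integer multiple of 0.1 Hz so 10-s frames hold whole cycles")
  }
  nyquist <- sampling_rate / 2
  if (cardiac_freq >= nyquist || resp_freq >= nyquist) {
    stopf("cardiac and respiratory frequencies must be below Nyquist (%g Hz)", nyquist)
  }
  check_waves <- function(waves, name) {
    for (w in waves) {
      if (!is.numeric(w) || !length(w) %in% 2:3) {
        stopf("each `%s` component must be c(freq, amp) or c(freq, amp, phase)", name)
      }
      if (w[1] < 0.005 - 1e-12 || w[1] > 0.05 + 1e-12) {
        stopf("`%s` frequency %g Hz outside the slow vasogenic band [0.005, 0.05]", name, w[1])
      }
      if (w[2] < 0) stopf("`%s` amplitudes must be >= 0", name)
    }
  }
  check_waves(slow_waves, "slow_waves")
  check_waves(icp_slow_waves, "icp_slow_waves")
  for (nm in c("resp_amp", "pulse_pressure", "icp_pulse_base", "noise_sd",
               "map_drift_sd", "icp_drift_sd", "pbto2_drift_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) stopf("`%s` must be >= 0", nm)
  }
  if (!is.list(missing_spec)) stopf("`missing_spec` must be a list")
  structure(
    list(patient_id = as.character(patient_id),
         sampling_rate = sampling_rate, duration = duration,
         map_baseline = map_baseline, icp_baseline = icp_baseline,
         cardiac_freq = cardiac_freq, resp_freq = resp_freq,
         resp_amp = resp_amp, slow_waves = slow_waves,
         icp_slow_waves = icp_slow_waves,
         autoregulation_gain = autoregulation_gain,
         pulse_pressure = pulse_pressure, icp_pulse_base = icp_pulse_base,
         amp_icp_coupling = amp_icp_coupling,
         pbto2_baseline = pbto2_baseline, pbto2_cpp_gain = pbto2_cpp_gain,
         pbto2_lag = pbto2_lag, map_drift_sd = map_drift_sd,
         icp_drift_sd = icp_drift_sd, pbto2_drift_sd = pbto2_drift_sd,
         noise_sd = noise_sd, missing_spec = missing_spec,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> patient %s: %g min at %g Hz, MAP %g / ICP %g mmHg, g = %+g, seed %d\n",
    x$patient_id, x$duration, x$sampling_rate, x$map_baseline,
    x$icp_baseline, x$autoregulation_gain, x$seed))
  invisible(x)
}
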