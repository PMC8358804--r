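#' Configuration for the ABR waveform simulator
#'
#' Describes a click-evoked auditory brainstem response (ABR) recording
#' session as it looks *after* sweep averaging: an ascending series of
#' stimulus levels, a true hearing threshold, and a small set of biphasic
#' waves riding on Gaussian residual noise. The simulator emulates the
#' averaged record directly rather than the individual sweeps, which has
#' identical statistics at a fraction of the cost.
#'
#' Waves are Gabor-like transients (negative trough preceding the positive
#' peak) whose peak-to-peak amplitude grows linearly with level above
#' threshold and whose latency increases as level drops. Below threshold the
#' signal component is exactly zero, so the record is pure averaged noise.
#'
#' @param sampling_rate samples per ms (default 24.4, i.e. 24.4 kHz).
#' @param record_duration record length in ms from stimulus onset.
#' @param stimulus_levels ascending stimulus levels in dB SPL
#'   (default 10 to 90 dB in 10-dB steps).
#' @param true_threshold true threshold in dB SPL; levels below it contain
#'   no evoked signal. May sit one step above the grid (inaudible series).
#' @param conduction_delay acoustic travel delay to the tympanic membrane in
#'   ms (default 1.4, the closed-field tube delay); no wave energy occurs
#'   before it.
#' @param wave_latencies positive-peak latencies (ms) of each wave at 90 dB.
#' @param wave_rel_amp relative peak-to-peak amplitude of each wave.
#' @param latency_level_slope latency increase in ms per dB of level drop
#'   below 90 dB.
#' @param amplitude_growth peak-to-peak growth in uV per dB above
#'   `true_threshold - level_step` (so the wave is already present, one
#'   step's worth of amplitude, at threshold itself).
#' @param wave_freq_khz carrier frequency of the Gabor transient in kHz;
#'   the default 1 kHz sits mid-band of typical 0.5-3 kHz ABR filtering.
#' @param noise_sd standard deviation (uV) of the post-averaging residual
#'   noise, i.i.d. Gaussian per sample. Must be > 0.
#' @param seed RNG seed for reproducible records.
#' @return an object of class `abr_sim_config`.
#' @seealso [simulate_abr_series()]
#' @export
abr_sim_config <- function(sampling_rate = 24.4,
                           record_duration = 10,
                           stimulus_levels = seq(10, 90, by = 10),
                           true_threshold = 30,
                           conduction_delay = 1.4,
                           wave_latencies = c(1.9, 2.7, 3.5, 4.3),
                           wave_rel_amp = c(0.6, 1, 0.8, 0.5),
                           latency_level_slope = 0.006,
                           amplitude_growth = 0.15,
                           wave_freq_khz = 1,
                           noise_sd = 0.12,
                           seed = NULL) {
  check_number(sampling_rate, "sampling_rate", lower = 1)
  check_number(record_duration, "record_duration", lower = 1)
  check_number(conduction_delay, "conduction_delay", lower = 0)
  check_number(noise_sd, "noise_sd", lower = .Machine$double.eps)
  check_number(amplitude_growth, "amplitude_growth", lower = 0)
  if (length(stimulus_levels) < 2 || any(diff(stimulus_levels) <= 0))
    stop_eq("`stimulus_levels` must be strictly increasing with >= 2 levels")
  step <- diff(stimulus_levels)[1]
  lo <- min(stimulus_levels); hi <- max(stimulus_levels)
  check_number(true_threshold, "true_threshold",
               lower = lo - step, upper = hi + step)
  if (length(wave_latencies) != length(wave_rel_amp))
    stop_eq("`wave_latencies` and `wave_rel_amp` must have equal length")
  structure(list(
    sampling_rate = sampling_rate, record_duration = record_duration,
    stimulus_levels = as.numeric(stimulus_levels),
    true_threshold = true_threshold, conduction_delay = conduction_delay,
    wave_latencies = wave_latencies, wave_rel_amp = wave_rel_amp,
    latency_level_slope = latency_level_slope,
    amplitude_growth = amplitude_growth, wave_freq_khz = wave_freq_khz,
    noise_sd = noise_sd, level_step = step, seed = seed
  ), class = "abr_sim_config")
}

## Gabor-like biphasic transient: negative trough just before t0, positive
## peak just after, unit *peak-to-peak* amplitude.
gabor_wave <- function(t, t0, freq_khz, width_ms = 0.25) {
  u <- t - t0
  g <- exp(-u^2 / (2 * width_ms^2)) * sinpi(2 * freq_khz * u)
  ## normalize so max(g) - min(g) == 1 on a dense grid (precomputable but
  ## cheap enough to evaluate inline on the fine template below)
  g
}

gabor_p2p <- function(freq_khz, width_ms = 0.25) {
  u <- seq(-1.5, 1.5, by = 1e-3)
  g <- exp(-u^2 / (2 * width_ms^2)) * sinpi(2 * freq_khz * u)
  max(g) - min(g)
}

#' Simulate an averaged ABR level series with known ground truth
#'
#' Produces one averaged waveform per stimulus level. For levels below the
#' configured true threshold the record is pure Gaussian noise; at and above
#' it, biphasic waves appear inside the post-delay latency window, their
#' peak-to-peak amplitude growing with level and their latency shortening.
#'
#' @param config an [abr_sim_config()].
#' @return a list with
#'   \describe{
#'     \item{series}{an `abr_series`: waveforms per level on a shared time
#'       grid (see [abr_series()]).}
#'     \item{truth}{ground truth: `true_threshold`, and per-level wave
#'       latencies/amplitudes actually rendered (`NULL` rows below
#'       threshold).}
#'   }
#' @examples
#' sim <- simulate_abr_series(abr_sim_config(true_threshold = 30, seed = 1))
#' sapply(sim$series$waveforms, function(w) max(abs(w$voltage)))
#' @export
simulate_abr_series <- function(config) {
  if (!inherits(config, "abr_sim_config"))
    stop_eq("`config` must be an `abr_sim_config`")
  n <- ceiling(config$record_duration * config$sampling_rate)
  time <- (seq_len(n) - 1) / config$sampling_rate
  p2p_unit <- gabor_p2p(config$wave_freq_khz)
  with_seed(config$seed, {
    waves_truth <- vector("list", length(config$stimulus_levels))
    wfs <- vector("list", length(config$stimulus_levels))
    for (i in seq_along(config$stimulus_levels)) {
      level <- config$stimulus_levels[i]
      signal <- numeric(n)
      if (level >= config$true_threshold) {
        amp <- config$amplitude_growth *
          (level - config$true_threshold + config$level_step)
        lat <- config$wave_latencies +
          config$latency_level_slope * (90 - level)
        a <- amp * config$wave_rel_amp
        for (j in seq_along(lat)) {
          signal <- signal + (a[j] / p2p_unit) *
            gabor_wave(time, lat[j], config$wave_freq_khz)
        }
        ## no wave energy before the conduction delay
        signal[time < config$conduction_delay] <- 0
        waves_truth[[i]] <- data.frame(
          level_db = level, wave = seq_along(lat),
          latency_ms = lat, amplitude_uv = a)
      }
      v <- signal + stats::rnorm(n, 0, config$noise_sd)
      wfs[[i]] <- waveform(time, v, level)
    }
    series <- abr_series(wfs)
    truth <- list(
      true_threshold = config$true_threshold,
      waves = do.call(rbind, waves_truth))
    list(series = series, truth = truth)
  })
}
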