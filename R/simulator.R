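.calib_cache <- new.env(parent = emptyenv())

#' Synthetic beat shape
#'
#' The beat is defined in the velocity (VPG) domain as a sum of smooth
#' components and the PPG is its closed-form integral. The systolic bump is an
#' asymmetric Gaussian (rise width `sigma_rise`, fall width
#' `fall_ratio * sigma_rise`): its derivative gives an APG a-wave deeper than
#' the b-wave in the physiological ratio `|b|/|a| = 1/fall_ratio`. A small
#' dicrotic bump generates the c and d waves, and a broad negative decay lobe
#' returns the PPG to baseline (its area is fixed by the zero-net-area
#' constraint, so each beat starts and ends on the baseline). The VPG
#' full width at half maximum is approximately
#' `sqrt(2 log 2) * sigma_rise * (1 + fall_ratio)`, so `sigma_rise` is the
#' rise-steepness dial.
#'
#' @param sigma_rise Systolic rise width in seconds.
#' @param fall_ratio Systolic fall/rise width ratio (> 1 for a steep upstroke).
#' @param dicrotic_ratio Dicrotic bump velocity amplitude relative to systolic.
#' @param dicrotic_width Dicrotic bump width, seconds.
#' @param dicrotic_lag Dicrotic center minus systolic center, seconds
#'   (default scales mildly with `sigma_rise`).
#' @param decay_width Decay lobe width, seconds.
#' @param decay_lag Decay center minus systolic center, seconds.
#' @param amplitude Peak pulse height of the beat, arbitrary units.
#' @return An object of class `beat_shape`.
#' @export
beat_shape <- function(sigma_rise = 0.035, fall_ratio = 1.6,
                       dicrotic_ratio = 0.12, dicrotic_width = 0.05,
                       dicrotic_lag = 0.20 + 1.5 * sigma_rise,
                       decay_width = 0.12,
                       decay_lag = 0.40 + 2 * sigma_rise,
                       amplitude = 1) {
  stopifnot(sigma_rise > 0, fall_ratio > 0, dicrotic_width > 0,
            decay_width > 0, amplitude > 0,
            dicrotic_lag > 0, decay_lag > dicrotic_lag)
  shape <- structure(
    list(
      sigma_rise = sigma_rise, fall_ratio = fall_ratio,
      dicrotic_ratio = dicrotic_ratio, dicrotic_width = dicrotic_width,
      dicrotic_lag = dicrotic_lag, decay_width = decay_width,
      decay_lag = decay_lag, amplitude = amplitude,
      # systolic (VPG-peak) center measured from beat onset
      t_sys = 3.2 * sigma_rise + 0.01
    ),
    class = "beat_shape"
  )
  shape$unit_height <- shape_unit_height(shape)
  shape
}

# velocity-domain beat on a unit systolic amplitude
shape_velocity_unit <- function(t, s) {
  tc <- s$t_sys
  sr <- s$sigma_rise
  sf <- s$fall_ratio * sr
  td <- tc + s$decay_lag
  tdic <- tc + s$dicrotic_lag
  decay_amp <- ((sr + sf) / 2 + s$dicrotic_ratio * s$dicrotic_width) / s$decay_width
  sys <- ifelse(t < tc,
                exp(-(t - tc)^2 / (2 * sr^2)),
                exp(-(t - tc)^2 / (2 * sf^2)))
  sys +
    s$dicrotic_ratio * exp(-(t - tdic)^2 / (2 * s$dicrotic_width^2)) -
    decay_amp * exp(-(t - td)^2 / (2 * s$decay_width^2))
}

# closed-form integral of the unit velocity (the unit PPG beat)
shape_ppg_unit <- function(t, s) {
  tc <- s$t_sys
  sr <- s$sigma_rise
  sf <- s$fall_ratio * sr
  td <- tc + s$decay_lag
  tdic <- tc + s$dicrotic_lag
  decay_amp <- ((sr + sf) / 2 + s$dicrotic_ratio * s$dicrotic_width) / s$decay_width
  sq <- sqrt(2 * pi)
  sr * sq * stats::pnorm((pmin(t, tc) - tc) / sr) +
    sf * sq * (stats::pnorm((pmax(t, tc) - tc) / sf) - 0.5) +
    s$dicrotic_ratio * s$dicrotic_width * sq * stats::pnorm((t - tdic) / s$dicrotic_width) -
    decay_amp * s$decay_width * sq * stats::pnorm((t - td) / s$decay_width)
}

shape_unit_height <- function(s) {
  tg <- seq(0, s$t_sys + s$decay_lag + 4 * s$decay_width, by = 1e-3)
  max(shape_ppg_unit(tg, s))
}

# beat waveform (a.u.) at arbitrary times, scaled to the shape's amplitude
shape_ppg <- function(t, s) {
  s$amplitude / s$unit_height * shape_ppg_unit(t, s)
}

#' Sample one beat of a shape
#'
#' @param shape A [beat_shape()].
#' @param beat_period Beat period in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector of `round(beat_period * sampling_rate)` samples of
#'   the beat waveform on a zero baseline, peak height `shape$amplitude`.
#'   Deterministic in its arguments.
#' @export
beat_template <- function(shape, beat_period, sampling_rate) {
  stopifnot(inherits(shape, "beat_shape"), beat_period > 0, sampling_rate > 0)
  if (shape$t_sys + shape$dicrotic_lag >= beat_period) {
    stop("beat shape too wide for the requested period", call. = FALSE)
  }
  t <- seq(0, beat_period, by = 1 / sampling_rate)
  t <- t[-length(t)]
  shape_ppg(t, shape)
}

# beat shape used by the simulator: systolic geometry (which carries 1/FWHM
# and the a-wave) fixed in seconds, diastolic timing scaled with the mean beat
# period (diastole absorbs heart-period variation)
sim_beat_shape <- function(sigma_rise, fall_ratio, mean_period, amplitude = 1) {
  dic_lag <- 0.24 * mean_period + 1.2 * sigma_rise
  beat_shape(
    sigma_rise = sigma_rise, fall_ratio = fall_ratio,
    dicrotic_lag = dic_lag,
    decay_lag = max(0.45 * mean_period, dic_lag + 0.1 * mean_period),
    decay_width = 0.13 * mean_period,
    amplitude = amplitude
  )
}

# measure the pipeline inv FWHM of a noiseless single-channel record built
# from this shape (canonical conditions: 70 bpm, ~9 beats)
measure_shape_inv_fwhm <- function(sigma_rise, sampling_rate, fall_ratio,
                                   smoothing_window = 0.05,
                                   spec = filter_spec()) {
  period <- 60 / 70
  shape <- sim_beat_shape(sigma_rise, fall_ratio, mean_period = period)
  onsets <- 0.5 + period * (0:9)
  dur <- max(onsets) + 1.5
  t <- seq(0, dur, by = 1 / sampling_rate)
  x <- numeric(length(t))
  for (o in onsets) {
    idx <- which(t >= o & t <= o + 1.6)
    x[idx] <- x[idx] + shape_ppg(t[idx] - o, shape)
  }
  x <- 1000 * x + 2000
  ppg <- apply_bandpass(x, sampling_rate, spec)
  der <- derive_signals(ppg, sampling_rate, smoothing_window)
  beats <- segment_beats(der)
  if (beats$flagged) return(NA_real_)
  fid <- detect_fiducials(der, beats)
  stats::median(fid$inv_fwhm_vpg, na.rm = TRUE)
}

calibration_curve <- function(sampling_rate, fall_ratio,
                              smoothing_window = 0.05, spec = filter_spec()) {
  key <- sprintf("%g|%g|%g|%g|%g|%g", sampling_rate, fall_ratio,
                 smoothing_window, spec$low_cut, spec$high_cut, spec$order)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  sig <- exp(seq(log(0.009), log(0.165), length.out = 18))
  invf <- vapply(sig, measure_shape_inv_fwhm, numeric(1),
                 sampling_rate = sampling_rate, fall_ratio = fall_ratio,
                 smoothing_window = smoothing_window, spec = spec)
  ok <- is.finite(invf)
  sig <- sig[ok]; invf <- invf[ok]
  o <- order(invf)
  sig <- sig[o]; invf <- invf[o]
  keep <- c(TRUE, diff(invf) > 0)
  curve <- list(
    sigma = sig[keep], inv_fwhm = invf[keep],
    inverse = stats::splinefun(log(invf[keep]), log(sig[keep]), method = "hyman"),
    sampling_rate = sampling_rate, fall_ratio = fall_ratio,
    smoothing_window = smoothing_window, spec = spec
  )
  .calib_cache[[key]] <- curve
  curve
}

#' Calibrate a beat shape to a target 1/FWHM
#'
#' Finds the systolic rise width whose noiseless simulated beat, measured
#' through the full filtering/derivative/segmentation pipeline, yields the
#' requested `inv_fwhm_vpg`. The map from rise width to measured 1/FWHM is
#' monotone decreasing; it is tabulated once per condition (and cached),
#' inverted by monotone spline, and polished by secant steps until the
#' measured value is within 0.5% of the target.
#'
#' @param target_inv_fwhm Target 1/FWHM in 1/s (achievable range roughly
#'   2.5--18 1/s at the defaults; out-of-range targets raise an error naming
#'   the bounds).
#' @param sampling_rate Sampling rate in Hz for the calibration measurement.
#' @param fall_ratio Systolic asymmetry passed to [beat_shape()].
#' @param amplitude Amplitude of the returned shape.
#' @return A [beat_shape()] with attribute `achieved_inv_fwhm`.
#' @export
calibrate_shape <- function(target_inv_fwhm, sampling_rate = 1000,
                            fall_ratio = 1.6, amplitude = 1) {
  curve <- calibration_curve(sampling_rate, fall_ratio)
  lo <- min(curve$inv_fwhm); hi <- max(curve$inv_fwhm)
  if (target_inv_fwhm < lo || target_inv_fwhm > hi) {
    stop(sprintf(
      "target_inv_fwhm %.3g 1/s outside achievable range [%.3g, %.3g] 1/s",
      target_inv_fwhm, lo, hi
    ), call. = FALSE)
  }
  sigma <- exp(curve$inverse(log(target_inv_fwhm)))
  achieved <- measure_shape_inv_fwhm(sigma, sampling_rate, fall_ratio)
  for (iter in 1:4) {
    if (is.finite(achieved) && abs(achieved / target_inv_fwhm - 1) < 0.005) break
    # secant step on the log-log curve
    slope <- (curve$inverse(log(achieved) + 0.01) - curve$inverse(log(achieved) - 0.01)) / 0.02
    sigma <- exp(log(sigma) + slope * (log(target_inv_fwhm) - log(achieved)))
    achieved <- measure_shape_inv_fwhm(sigma, sampling_rate, fall_ratio)
  }
  shape <- beat_shape(sigma_rise = sigma, fall_ratio = fall_ratio,
                      amplitude = amplitude)
  attr(shape, "achieved_inv_fwhm") <- achieved
  shape
}

#' Simulation configuration
#'
#' Defaults describe a clean resting finger recording: 30 s at 1000 Hz (so
#' that millisecond-scale inter-channel delays are resolvable), 70 bpm with 3%
#' beat-to-beat variability, pulse amplitude 1000 a.u. on a 2000 a.u.
#' baseline, a small respiratory-scale drift, additive white noise of 1.5 a.u.
#' (SNR well above the 200 exclusion threshold), and no motion artifacts.
#'
#' @param duration Record length, seconds.
#' @param sampling_rate Hz.
#' @param heart_rate Beats per minute.
#' @param hrv_cv Coefficient of variation of the beat period (0--0.2).
#' @param target_inv_fwhm Target 1/FWHM of the VPG in 1/s (ground truth).
#' @param channel_delay Green-minus-near-infrared a-wave delay, seconds.
#' @param delay_jitter_sd Per-beat delay jitter SD, seconds.
#' @param amplitude Pulse height, a.u.
#' @param baseline_offset Additive DC level, a.u.
#' @param drift_amplitude,drift_period Sinusoidal baseline drift, a.u. / s.
#' @param noise_sd White-noise SD per channel, a.u.
#' @param motion_rate Motion-artifact events per minute (0 disables).
#' @param motion_magnitude RMS amplitude of a motion event, a.u.
#' @param include_red Also emit a red channel (scaled near-infrared pulse).
#' @param fall_ratio Beat-shape asymmetry (see [beat_shape()]).
#' @param seed Integer seed; mandatory so every record is reproducible.
#' @param metadata Metadata list for the emitted [waveform_record()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 30, sampling_rate = 1000, heart_rate = 70,
                       hrv_cv = 0.03, target_inv_fwhm = 8,
                       channel_delay = 0.02, delay_jitter_sd = 0.003,
                       amplitude = 1000, baseline_offset = 2000,
                       drift_amplitude = 3, drift_period = 12,
                       noise_sd = 1.5, motion_rate = 0, motion_magnitude = 0,
                       include_red = FALSE, fall_ratio = 1.6,
                       seed, metadata = list()) {
  if (missing(seed) || !is.finite(seed)) {
    stop("`seed` is mandatory in sim_config()", call. = FALSE)
  }
  stopifnot(duration > 0, sampling_rate > 0, heart_rate > 0,
            hrv_cv >= 0, hrv_cv <= 0.2, target_inv_fwhm > 0,
            delay_jitter_sd >= 0, amplitude > 0, noise_sd >= 0,
            motion_rate >= 0, motion_magnitude >= 0)
  structure(
    list(
      duration = duration, sampling_rate = sampling_rate,
      heart_rate = heart_rate, hrv_cv = hrv_cv,
      target_inv_fwhm = target_inv_fwhm, channel_delay = channel_delay,
      delay_jitter_sd = delay_jitter_sd, amplitude = amplitude,
      baseline_offset = baseline_offset, drift_amplitude = drift_amplitude,
      drift_period = drift_period, noise_sd = noise_sd,
      motion_rate = motion_rate, motion_magnitude = motion_magnitude,
      include_red = include_red, fall_ratio = fall_ratio,
      seed = as.integer(seed), metadata = metadata
    ),
    class = "sim_config"
  )
}

motion_artifacts <- function(n, sampling_rate, duration, rate, magnitude) {
  art <- numeric(n)
  n_ev <- stats::rpois(1, rate * duration / 60)
  if (n_ev == 0) return(art)
  for (k in seq_len(n_ev)) {
    start <- stats::runif(1, 0, duration)
    len <- round(stats::runif(1, 0.5, 1.5) * sampling_rate)
    i0 <- max(1L, round(start * sampling_rate))
    i1 <- min(n, i0 + len - 1L)
    m <- i1 - i0 + 1L
    if (m < 4) next
    rw <- cumsum(stats::rnorm(m))
    rw <- rw / max(sqrt(mean(rw^2)), .Machine$double.eps) * magnitude
    taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))
    art[i0:i1] <- art[i0:i1] + rw * taper
  }
  art
}

#' Simulate a dual-wavelength PPG record with ground truth
#'
#' The near-infrared channel is a concatenation of calibrated beats (periods
#' jittered per `hrv_cv`) plus baseline, drift and white noise; the green
#' channel is the same beat sequence with each beat time-shifted by its true
#' delay (a fractional-sample shift: the continuous beat model is evaluated at
#' shifted times), independently noised. Identical seeds give bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_record`: list with `record`
#'   (a [waveform_record()]) and `truth` (per-beat data frame with `onset`,
#'   `period` and `delay`, plus attributes `target_inv_fwhm`, `sigma_rise` and
#'   `achieved_inv_fwhm`).
#' @export
simulate_record <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cal <- calibrate_shape(config$target_inv_fwhm,
                         sampling_rate = config$sampling_rate,
                         fall_ratio = config$fall_ratio)
  mean_period <- 60 / config$heart_rate
  shape <- sim_beat_shape(cal$sigma_rise, config$fall_ratio, mean_period,
                          amplitude = config$amplitude)
  set.seed(config$seed)
  fs <- config$sampling_rate
  n_beats <- ceiling(config$duration / mean_period) + 2L
  periods <- stats::rnorm(n_beats, mean_period, config$hrv_cv * mean_period)
  periods <- pmin(pmax(periods, mean_period * (1 - 3 * max(config$hrv_cv, 0.01))),
                  mean_period * (1 + 3 * max(config$hrv_cv, 0.01)))
  onsets <- 0.3 + cumsum(c(0, periods[-n_beats]))
  keep <- onsets < config$duration
  onsets <- onsets[keep]
  periods <- periods[keep]
  delays <- config$channel_delay +
    stats::rnorm(length(onsets), 0, config$delay_jitter_sd)
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1) / fs
  tail_len <- shape$t_sys + shape$decay_lag + 4 * shape$decay_width
  nir <- numeric(n)
  green <- numeric(n)
  for (k in seq_along(onsets)) {
    idx <- which(t >= onsets[k] - 0.3 & t <= onsets[k] + tail_len + 0.3)
    nir[idx] <- nir[idx] + shape_ppg(t[idx] - onsets[k], shape)
    green[idx] <- green[idx] + shape_ppg(t[idx] - onsets[k] - delays[k], shape)
  }
  drift_phase <- stats::runif(1, 0, 2 * pi)
  drift <- config$drift_amplitude *
    sin(2 * pi * t / config$drift_period + drift_phase)
  base <- config$baseline_offset + drift
  motion <- if (config$motion_rate > 0 && config$motion_magnitude > 0) {
    motion_artifacts(n, fs, config$duration, config$motion_rate,
                     config$motion_magnitude)
  } else {
    numeric(n)
  }
  channels <- list(
    green = green + base + motion + stats::rnorm(n, 0, config$noise_sd)
  )
  if (config$include_red) {
    channels$red <- 0.4 * nir + base + motion + stats::rnorm(n, 0, config$noise_sd)
  }
  channels$nir <- nir + base + motion + stats::rnorm(n, 0, config$noise_sd)
  truth <- data.frame(
    beat = seq_along(onsets), onset = onsets, period = periods, delay = delays
  )
  attr(truth, "target_inv_fwhm") <- config$target_inv_fwhm
  attr(truth, "sigma_rise") <- shape$sigma_rise
  attr(truth, "achieved_inv_fwhm") <- attr(cal, "achieved_inv_fwhm")
  structure(
    list(
      record = waveform_record(channels, fs, metadata = config$metadata),
      truth = truth,
      config = config
    ),
    class = "sim_record"
  )
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf(
    "<sim_record> %d beats, target 1/FWHM %.3g 1/s, delay %.4g s, seed %d\n",
    nrow(x$truth), x$config$target_inv_fwhm, x$config$channel_delay,
    x$config$seed
  ))
  print(x$record)
  invisible(x)
}
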