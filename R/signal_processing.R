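#' Band-pass filter specification
#'
#' Cutoffs follow the acquisition protocol: the pulse band is isolated with a
#' 0.5--20 Hz band-pass. The realization is a Butterworth design applied
#' forward-backward (zero phase) so that inter-channel timing is untouched.
#'
#' @param low_cut Lower cutoff in Hz.
#' @param high_cut Higher cutoff in Hz.
#' @param order Butterworth order (per pass; forward-backward application
#'   doubles the effective order).
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single-pass.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 20, order = 2, zero_phase = TRUE) {
  if (!(low_cut > 0 && high_cut > low_cut)) {
    stop("need 0 < low_cut < high_cut", call. = FALSE)
  }
  structure(
    list(
      low_cut = low_cut, high_cut = high_cut,
      order = as.integer(order), zero_phase = isTRUE(zero_phase)
    ),
    class = "filter_spec"
  )
}

# reflect a signal anti-symmetrically at both ends; keeps low-frequency edge
# transients of the high-pass section away from the data
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  if (pad < 1) return(list(x = x, pad = 0L))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  list(x = c(head_pad, x, tail_pad), pad = as.integer(pad))
}

apply_bandpass <- function(x, sampling_rate, spec) {
  nyq <- sampling_rate / 2
  if (spec$high_cut >= nyq) {
    stop(sprintf(
      "high_cut (%g Hz) must be below the Nyquist frequency (%g Hz); raise sampling_rate or lower high_cut",
      spec$high_cut, nyq
    ), call. = FALSE)
  }
  bf <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq, type = "pass")
  # remove the mean first (the band-pass rejects DC anyway) and pad with ~3 s
  # (bounded by signal length) so the 0.5 Hz edge transient stays small
  x <- x - mean(x)
  p <- reflect_pad(x, round(3 * sampling_rate))
  y <- if (spec$zero_phase) {
    signal::filtfilt(bf, p$x)
  } else {
    as.numeric(signal::filter(bf, p$x))
  }
  y[(p$pad + 1):(p$pad + length(x))]
}

#' Band-pass filter every channel of a record
#'
#' All channels are filtered with identical coefficients and identical phase
#' behavior, so inter-channel timing (in particular the green-vs-near-infrared
#' a-wave delay) is preserved.
#'
#' @param record A [waveform_record()].
#' @param spec A [filter_spec()].
#' @return A `waveform_record` with filtered channels (same length as input).
#' @export
#' @examples
#' fs <- 200
#' t <- seq(0, 10, by = 1 / fs)
#' raw <- 1000 + 50 * sin(2 * pi * 1.2 * t)
#' rec <- waveform_record(list(green = raw, nir = raw), fs)
#' filt <- bandpass_filter(rec, filter_spec())
#' max(abs(mean(filt$channels$green))) < 1  # DC removed
bandpass_filter <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "waveform_record"), inherits(spec, "filter_spec"))
  record$channels <- lapply(record$channels, apply_bandpass,
    sampling_rate = record$sampling_rate, spec = spec
  )
  record
}

moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1L
  n <- length(x)
  if (w >= n) stop("moving-average window longer than signal", call. = FALSE)
  half <- (w - 1L) %/% 2L
  p <- reflect_pad(x, half)
  y <- stats::filter(p$x, rep(1 / w, w), sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Differentiate a signal and smooth with a centered moving average
#'
#' Central-difference derivative scaled to input-units per second, followed by
#' a centered moving average of odd sample count (reflection padding keeps the
#' output the same length as the input). Applying this to a filtered PPG gives
#' the velocity plethysmogram (VPG); applying it again gives the acceleration
#' plethysmogram (APG).
#'
#' @param x Numeric sample vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param window Moving-average window in seconds (default 50 ms; a window of
#'   one sample disables smoothing).
#' @return Numeric vector, same length as `x`, in input-units per second.
#' @export
differentiate_smooth <- function(x, sampling_rate, window = 0.05) {
  n <- length(x)
  w <- max(1L, round(window * sampling_rate))
  if (w >= n) stop("smoothing window longer than signal", call. = FALSE)
  if (n < 3) stop("signal too short to differentiate", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * sampling_rate / 2
  d[1] <- (x[2] - x[1]) * sampling_rate
  d[n] <- (x[n] - x[n - 1]) * sampling_rate
  moving_average(d, w)
}

#' Derive velocity and acceleration plethysmograms
#'
#' @param ppg Filtered PPG sample vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param window Moving-average window in seconds used after each
#'   differentiation.
#' @return An object of class `derived_signals` with elements `ppg`, `vpg`,
#'   `apg`, `sampling_rate` and `smoothing_window`.
#' @export
derive_signals <- function(ppg, sampling_rate, window = 0.05) {
  vpg <- differentiate_smooth(ppg, sampling_rate, window)
  apg <- differentiate_smooth(vpg, sampling_rate, window)
  structure(
    list(
      ppg = ppg, vpg = vpg, apg = apg,
      sampling_rate = sampling_rate, smoothing_window = window
    ),
    class = "derived_signals"
  )
}

#' @export
print.derived_signals <- function(x, ...) {
  cat(sprintf(
    "<derived_signals> %d samples @ %g Hz, smoothing window %g s\n",
    length(x$ppg), x$sampling_rate, x$smoothing_window
  ))
  invisible(x)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

#' Divide a record into beats
#'
#' Beat boundaries are the PPG minima delimiting cardiac cycles. Systolic
#' upstrokes are first anchored on VPG maxima (with an amplitude threshold and
#' a refractory period), then each anchor is traced backward to the preceding
#' PPG minimum. Boundary spacings outside the heart-rate bounds mark the
#' enclosed interval as invalid rather than raising an error.
#'
#' @param derived A [derive_signals()] result.
#' @param sampling_rate Sampling rate in Hz (defaults to the rate stored in
#'   `derived`).
#' @param hr_bounds Heart-rate bounds in beats per minute, `c(min, max)`.
#' @param refractory Minimum spacing between upstroke anchors, seconds.
#' @return An object of class `beat_index`: list with `boundaries` (sample
#'   indices of beat-delimiting PPG minima), `anchors` (VPG-maximum sample
#'   indices), `valid` (logical per inter-boundary interval), `beat_count`
#'   (number of valid beats) and `flagged` (`TRUE` when fewer than 2 beats were
#'   found).
#' @export
segment_beats <- function(derived, sampling_rate = derived$sampling_rate,
                          hr_bounds = c(30, 180), refractory = 0.3) {
  stopifnot(inherits(derived, "derived_signals"))
  vpg <- derived$vpg
  ppg <- derived$ppg
  empty <- structure(
    list(
      boundaries = integer(0), anchors = integer(0),
      valid = logical(0), beat_count = 0L, flagged = TRUE
    ),
    class = "beat_index"
  )
  cand <- local_maxima(vpg)
  cand <- cand[vpg[cand] > 0]
  if (length(cand) < 2) return(empty)
  thr <- 0.45 * as.numeric(stats::quantile(vpg, 0.98))
  cand <- cand[vpg[cand] >= thr]
  if (length(cand) < 2) return(empty)
  # enforce the refractory period, keeping the taller of competing anchors
  min_gap <- round(refractory * sampling_rate)
  keep <- logical(length(vpg))
  for (i in order(vpg[cand], decreasing = TRUE)) {
    idx <- cand[i]
    lo <- max(1L, idx - min_gap)
    hi <- min(length(keep), idx + min_gap)
    if (!any(keep[lo:hi])) keep[idx] <- TRUE
  }
  anchors <- which(keep)
  if (length(anchors) < 2) return(empty)
  # trace each upstroke back to the preceding PPG minimum
  back <- as.integer(round(0.6 * stats::median(diff(anchors))))
  boundaries <- vapply(anchors, function(a) {
    lo <- max(1L, a - back)
    lo + which.min(ppg[lo:a]) - 1L
  }, integer(1))
  boundaries <- sort(unique(boundaries))
  if (length(boundaries) < 2) return(empty)
  spacing <- diff(boundaries) / sampling_rate
  valid <- spacing >= 60 / hr_bounds[2] & spacing <= 60 / hr_bounds[1]
  structure(
    list(
      boundaries = boundaries, anchors = anchors, valid = valid,
      beat_count = sum(valid), flagged = sum(valid) < 2
    ),
    class = "beat_index"
  )
}

#' @export
print.beat_index <- function(x, ...) {
  cat(sprintf(
    "<beat_index> %d boundaries, %d valid beat(s)%s\n",
    length(x$boundaries), x$beat_count, if (x$flagged) " [flagged]" else ""
  ))
  invisible(x)
}

#' Slowly varying DC component of a raw channel
#'
#' Moving average of the *unfiltered* channel. The DC component rises when
#' pulsatile light absorption falls (e.g. when external pressure squeezes blood
#' out of the tissue under the sensor).
#'
#' @param raw_channel Unfiltered sample vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param window Averaging window in seconds (>= 1 s recommended so that the
#'   pulse itself is averaged out).
#' @return Numeric vector, same length as input.
#' @export
dc_component <- function(raw_channel, sampling_rate, window = 2) {
  w <- max(1L, round(window * sampling_rate))
  moving_average(raw_channel, w)
}
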