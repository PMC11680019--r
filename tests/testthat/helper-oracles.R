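# Independent oracles and small fixture builders used across the suite.

# Brute-force FWHM of a peaked signal: 16x spline resampling and exhaustive
# half-crossing search on the dense grid. Independent of fwhm_vpg()'s
# original-grid linear interpolation.
fwhm_bruteforce <- function(v, fs) {
  n <- length(v)
  dense <- stats::spline(seq_len(n), v, n = 16L * n)
  x <- dense$x
  y <- dense$y
  i <- which.max(y)
  half <- y[i] / 2
  li <- i
  while (li > 1 && y[li] > half) li <- li - 1
  ri <- i
  while (ri < length(y) && y[ri] > half) ri <- ri + 1
  if (y[li] > half || y[ri] > half) return(NA_real_)
  xl <- x[li] + (half - y[li]) / (y[li + 1] - y[li]) * (x[li + 1] - x[li])
  xr <- x[ri - 1] + (half - y[ri - 1]) / (y[ri] - y[ri - 1]) * (x[ri] - x[ri - 1])
  (xr - xl) / fs
}

# Textbook Welch statistic with Satterthwaite degrees of freedom.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# single-channel record holding a pure sinusoid (plus optional offset)
sine_record <- function(freq, fs = 1000, dur = 20, amp = 1, offset = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  waveform_record(list(green = offset + amp * sin(2 * pi * freq * t)), fs)
}

# a record made of exactly repeated beats (integer-sample period, no jitter)
tiled_beat_record <- function(n_beats = 40, period = 0.8, fs = 1000,
                              amplitude = 1000, offset = 2000,
                              sigma_rise = 0.04, noise_sd = 0, seed = 1) {
  set.seed(seed)
  shape <- beat_shape(sigma_rise = sigma_rise, amplitude = amplitude)
  beat <- beat_template(shape, period, fs)
  x <- rep(beat, n_beats) + offset
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  waveform_record(list(green = x), fs)
}

quick_sim <- function(seed, ...) {
  simulate_record(sim_config(seed = seed, ...))
}
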