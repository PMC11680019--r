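test_that("band-pass passes the pulse band and rejects DC and drift", {
  fs <- 1000
  # 5 Hz is well inside the 0.5-20 Hz band
  rec <- sine_record(5, fs = fs)
  out <- bandpass_filter(rec, filter_spec())$channels$green
  mid <- out[(5 * fs):(15 * fs)]
  gain <- (max(mid) - min(mid)) / 2
  expect_gte(gain, 0.95)
  expect_lte(gain, 1.0 + 1e-6)

  # DC is below the 0.5 Hz stop-band edge
  const <- waveform_record(list(green = rep(1000, 20 * fs)), fs)
  out_dc <- bandpass_filter(const, filter_spec())$channels$green
  expect_lt(max(abs(out_dc)), 1e-6 * 1000)

  # 0.05 Hz drift is deep in the stop band
  slow <- sine_record(0.05, fs = 200, dur = 80)
  out_slow <- bandpass_filter(slow, filter_spec())$channels$green
  mid_slow <- out_slow[(20 * 200):(60 * 200)]
  expect_lt((max(mid_slow) - min(mid_slow)) / 2, 0.1)

  # too-low sampling rate names the offending parameter
  low_fs <- waveform_record(list(green = sin(seq(0, 50, by = 1 / 30))), 30)
  expect_error(bandpass_filter(low_fs, filter_spec()), "high_cut")
})

test_that("differentiation recovers known derivatives", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  # ramp: derivative is the slope everywhere away from edges
  d_ramp <- differentiate_smooth(3 * t, fs, window = 0.05)
  interior <- d_ramp[100:(length(t) - 100)]
  expect_lt(max(abs(interior - 3)), 1e-9)

  # sinusoid: closed-form derivative, 1-sample window disables smoothing
  f <- 2
  d_sin <- differentiate_smooth(sin(2 * pi * f * t), fs, window = 1 / fs)
  truth <- 2 * pi * f * cos(2 * pi * f * t)
  err <- abs(d_sin - truth)[10:(length(t) - 10)]
  expect_lt(max(err), 0.01 * 2 * pi * f)

  expect_equal(differentiate_smooth(rep(7, 500), fs), rep(0, 500))
  expect_error(differentiate_smooth(rep(1, 20), fs, window = 0.5), "window")
})

test_that("differentiate_smooth is linear", {
  set.seed(42)
  fs <- 500
  for (i in 1:5) {
    x <- cumsum(rnorm(1000))
    y <- cumsum(rnorm(1000))
    a <- runif(1, -3, 3); b <- runif(1, -3, 3)
    lhs <- differentiate_smooth(a * x + b * y, fs)
    rhs <- a * differentiate_smooth(x, fs) + b * differentiate_smooth(y, fs)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("beat segmentation matches simulated beat counts and spacing", {
  sim <- quick_sim(seed = 11, duration = 10, heart_rate = 60, hrv_cv = 0,
                   noise_sd = 0, drift_amplitude = 0)
  der <- derive_signals(
    bandpass_filter(sim$record)$channels$nir, 1000
  )
  beats <- segment_beats(der)
  expect_false(beats$flagged)
  expect_true(beats$beat_count %in% c(9L, 10L))
  spacing <- diff(beats$boundaries)[beats$valid] / 1000
  # interior beats sit at the exact simulated period; the first and last
  # boundary can shift inside their flat valleys near the record edges
  interior <- spacing[2:(length(spacing) - 1)]
  expect_lt(max(abs(interior - 1.0)), 0.01)
  expect_lt(abs(median(spacing) - 1.0), 0.01)

  # a constant signal has no upstrokes: flagged, not an error
  const <- derive_signals(rep(0, 10000), 1000)
  flat <- segment_beats(const)
  expect_true(flat$flagged)
  expect_identical(flat$beat_count, 0L)

  # 75 bpm with 5% heart-rate variability: mean spacing ~ 0.8 s
  sim75 <- quick_sim(seed = 12, duration = 30, heart_rate = 75, hrv_cv = 0.05)
  der75 <- derive_signals(bandpass_filter(sim75$record)$channels$nir, 1000)
  b75 <- segment_beats(der75)
  mean_sp <- mean(diff(b75$boundaries)[b75$valid]) / 1000
  expect_lt(abs(mean_sp / 0.8 - 1), 0.02)
})

test_that("dc component tracks the slow baseline", {
  fs <- 200
  expect_equal(dc_component(rep(1000, 10 * fs), fs, window = 2),
               rep(1000, 10 * fs))

  # zero-mean 1.3 Hz pulse train averages out over a 2 s window
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  pulse <- sin(2 * pi * 1.3 * t) + 0.4 * sin(2 * pi * 2.6 * t)
  dc <- dc_component(1000 + 20 * (pulse - mean(pulse)), fs, window = 2)
  expect_lt(max(abs(dc - 1000)), 0.01 * 1000)

  # pressure-press step: transition completes within one window length
  step <- c(rep(1000, 15 * fs), rep(1200, 15 * fs))
  dcs <- dc_component(step, fs, window = 2)
  expect_lt(max(abs(dcs[1:(13 * fs)] - 1000)), 1)
  expect_lt(max(abs(dcs[(17 * fs):(30 * fs)] - 1200)), 1)

  # additivity in a constant offset
  x <- 1000 + 20 * pulse
  expect_equal(dc_component(x + 55, fs, 2), dc_component(x, fs, 2) + 55)
})

test_that("filtering and differentiation are channel-symmetric under time shifts", {
  sim <- quick_sim(seed = 13, duration = 24, noise_sd = 0, drift_amplitude = 0)
  x <- sim$record$channels$nir
  shift <- 12L
  rec <- waveform_record(
    list(green = x[1:(length(x) - shift)], nir = x[(1 + shift):length(x)]),
    1000
  )
  filt <- bandpass_filter(rec)
  n <- length(filt$channels$green)
  core <- (8000):(n - 8000)
  # the green channel leads nir by exactly `shift` samples after every stage
  expect_lt(max(abs(filt$channels$green[core + shift] - filt$channels$nir[core])),
            1e-6 * diff(range(filt$channels$nir)))
  dg <- derive_signals(filt$channels$green, 1000)
  dn <- derive_signals(filt$channels$nir, 1000)
  expect_lt(max(abs(dg$vpg[core + shift] - dn$vpg[core])),
            1e-6 * diff(range(dn$vpg)))
  expect_lt(max(abs(dg$apg[core + shift] - dn$apg[core])),
            1e-6 * diff(range(dn$apg)))
})
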