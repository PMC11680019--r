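test_that("baseline-corrected height S matches hand arithmetic and a brute-force max", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  # minima (0, 10) and (1, 14); narrow interior peak reaching 50 at t = 0.3,
  # riding on the tilted baseline so the tilt does not move the maximum
  beat <- 10 + 4 * t + 38.8 * exp(-(t - 0.3)^2 / (2 * 0.02^2))
  hs <- corrected_height_s(beat, fs)
  expect_true(hs$valid)
  expect_equal(hs$S, 50 - (10 + 0.3 * 4), tolerance = 1e-3)
  # brute-force oracle: max of (beat - line) over all samples
  line <- seq(beat[1], beat[length(beat)], length.out = length(beat))
  expect_equal(hs$S, max((beat - line)[2:(length(beat) - 1)]), tolerance = 1e-12)

  # flat baseline: zero-slope line
  flat <- 10 + 50 * exp(-(t - 0.4)^2 / (2 * 0.02^2)) * (t > 0 & t < 1)
  flat[c(1, length(flat))] <- 10
  expect_equal(corrected_height_s(flat, fs)$S, 50, tolerance = 1e-3)

  # adding a constant shifts the line identically
  expect_equal(corrected_height_s(beat + 123, fs)$S, hs$S, tolerance = 1e-12)
})

test_that("VPG half-width matches closed forms", {
  fs <- 1000
  # triangle: rise over [0, 0.1], fall over [0.1, 0.2] -> FWHM exactly 0.1 s
  t <- seq(0, 0.2, by = 1 / fs)
  tri <- 1 - abs(t - 0.1) / 0.1
  res <- fwhm_vpg(tri, fs)
  expect_true(res$valid)
  expect_equal(res$fwhm, 0.1, tolerance = 1e-3)
  expect_equal(res$inv_fwhm, 10, tolerance = 1e-2)

  # Gaussian: FWHM = 2 sqrt(2 ln 2) sigma
  tg <- seq(0, 0.5, by = 1 / fs)
  gauss <- exp(-(tg - 0.25)^2 / (2 * 0.05^2))
  expect_equal(fwhm_vpg(gauss, fs)$fwhm, 2 * sqrt(2 * log(2)) * 0.05,
               tolerance = 1e-4)

  # the diabetic group-mean 1/FWHM of 5.6 1/s corresponds to ~0.1786 s
  sigma <- 1 / (5.6 * 2 * sqrt(2 * log(2)))
  tw <- seq(0, 1, by = 1 / fs)
  wide <- exp(-(tw - 0.5)^2 / (2 * sigma^2))
  res56 <- fwhm_vpg(wide, fs)
  expect_equal(res56$fwhm, 1 / 5.6, tolerance = 1e-3)
  expect_equal(res56$inv_fwhm, 5.6, tolerance = 1e-2)

  # half level never crossed on one side -> invalid, no exception
  expect_false(fwhm_vpg(seq(0, 1, length.out = 100), fs)$valid)
})

test_that("APG wave detection finds well-separated components to sub-sample precision", {
  fs <- 1000
  t <- seq(0, 0.6, by = 1 / fs)
  centers <- c(0.05, 0.12, 0.20, 0.26, 0.33)
  amps <- c(1, -0.6, 0.2, -0.3, 0.15)
  apg <- rowSums(mapply(function(c, a) a * exp(-(t - c)^2 / (2 * 0.012^2)),
                        centers, amps))
  ap <- detect_apg_waves(apg, fs)
  expect_true(ap$valid)
  found <- c(ap$a[["time"]], ap$b[["time"]], ap$c[["time"]],
             ap$d[["time"]], ap$e[["time"]])
  expect_lt(max(abs(found - centers)), 0.002)
  expect_equal(ap$a[["amp"]], 1, tolerance = 0.01)

  # a pure-noise beat is flagged invalid, not an error
  set.seed(99)
  noise <- rnorm(600)
  expect_false(detect_apg_waves(noise, fs)$valid)
})

test_that("a-wave precedes the PPG maximum on simulated beats", {
  sim <- quick_sim(seed = 21, duration = 12, noise_sd = 0, drift_amplitude = 0)
  p <- process_record(sim$record)
  tab <- p$channels$green$beat_table
  ok <- tab[tab$apg_valid %in% TRUE, ]
  expect_gt(nrow(ok), 5)
  expect_true(all(ok$a_t < ok$t_ppg_max))
})

test_that("beat features follow the defining arithmetic and are scale invariant", {
  fid <- data.frame(
    valid = TRUE, S = 38.8, fwhm_vpg = 0.125,
    a_t = 0.05, a_amp = 1.0, b_t = 0.12, b_amp = -0.6,
    c_t = 0.20, c_amp = 0.2, d_t = 0.26, d_amp = -0.3,
    e_t = NA_real_, e_amp = NA_real_
  )
  bf <- beat_features(fid)
  expect_equal(bf$ab_time, 0.07)
  expect_equal(bf$inv_ab_time, 1 / 0.07, tolerance = 1e-6)  # ~14.29
  expect_equal(bf$norm_ab, 1.6)
  expect_equal(bf$norm_ad, 1.3)
  expect_equal(bf$ab_over_ad, 1.6 / 1.3)                    # ~1.2308
  expect_equal(beat_features(transform(fid, a_amp = 400))$a_over_S,
               400 / 38.8, tolerance = 1e-6)                # ~10.31

  # scaling the APG amplitudes by k > 0 leaves the normalized ratios unchanged
  k <- 7.3
  sc <- beat_features(transform(fid, a_amp = k * a_amp, b_amp = k * b_amp,
                                c_amp = k * c_amp, d_amp = k * d_amp))
  expect_equal(sc$norm_ab, bf$norm_ab, tolerance = 1e-12)
  expect_equal(sc$norm_ad, bf$norm_ad, tolerance = 1e-12)
  expect_equal(sc$ab_over_ad, bf$ab_over_ad, tolerance = 1e-12)

  # non-positive denominators drop the feature but keep the beat
  neg_s <- beat_features(transform(fid, S = -1))
  expect_true(is.na(neg_s$a_over_S))
  expect_true(is.na(neg_s$inv_S))
  expect_equal(neg_s$norm_ab, 1.6)
  neg_a <- beat_features(transform(fid, a_amp = -1))
  expect_true(is.na(neg_a$norm_ab))
})

test_that("channel delay pairs nearest peaks and respects the pairing window", {
  nir <- c(1.0, 2.0, 3.0, 4.0)
  # exact 12 ms shift
  ds <- channel_delay(nir + 0.012, nir)
  expect_equal(ds$delays, rep(0.012, 4), tolerance = 1e-12)
  expect_equal(ds$summary, 0.012)

  # identical channels: all zero
  expect_equal(channel_delay(nir, nir)$delays, rep(0, 4))

  # peaks beyond the window are dropped; no pairs flags the series
  far <- channel_delay(nir + 0.5, nir, pairing_window = 0.3)
  expect_true(far$flagged)
  expect_true(is.na(far$summary))

  # a missing green peak drops only that pair
  miss <- channel_delay(c(1.012, 3.012, 4.012), nir)
  expect_equal(length(miss$delays), 3)
})

test_that("record aggregation uses the median over valid beats", {
  tab <- beat_features(data.frame(
    valid = c(TRUE, TRUE, TRUE, FALSE),
    S = c(10, 11, 12, 99), fwhm_vpg = c(1 / 7, 1 / 8, 1 / 9, 1),
    a_t = 0.05, a_amp = 1, b_t = 0.12, b_amp = -0.6,
    c_t = NA_real_, c_amp = NA_real_, d_t = NA_real_, d_amp = NA_real_,
    e_t = NA_real_, e_amp = NA_real_
  ))
  agg <- aggregate_record(tab)
  expect_equal(agg$inv_fwhm_vpg, 8, tolerance = 1e-9)
  expect_identical(agg$n_beats, 3L)

  one <- aggregate_record(tab[2, ])
  expect_equal(one$inv_fwhm_vpg, 8, tolerance = 1e-9)
  expect_equal(one$S, 11)
})

test_that("aggregates recover constant ground truth from noisy beats", {
  sim <- quick_sim(seed = 22, duration = 40, heart_rate = 75,
                   target_inv_fwhm = 9, noise_sd = 2)
  p <- process_record(sim$record)
  expect_gte(p$features$n_beats, 40)
  expect_lt(abs(p$features$inv_fwhm_vpg / 9 - 1), 0.05)
})
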