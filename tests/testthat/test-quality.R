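test_that("template subtraction leaves no residual on exactly repeated beats", {
  rec <- tiled_beat_record(n_beats = 40, noise_sd = 0)
  p <- process_record(rec)
  nr <- noise_rms(rec$channels$green, p$channels$green$beats, 1000)
  expect_false(nr$flagged)
  S <- median(p$channels$green$beat_table$S, na.rm = TRUE)
  expect_lt(nr$noise_rms, 1e-9 * S)
})

test_that("injected white noise is recovered within 10%", {
  est <- vapply(1:3, function(s) {
    rec <- tiled_beat_record(n_beats = 40, noise_sd = 2, seed = 100 + s)
    p <- process_record(rec)
    noise_rms(rec$channels$green, p$channels$green$beats, 1000)$noise_rms
  }, numeric(1))
  expect_lt(abs(mean(est) / 2 - 1), 0.10)
})

test_that("noise estimate is invariant to a constant offset", {
  rec <- tiled_beat_record(n_beats = 35, noise_sd = 1.5, seed = 7)
  p <- process_record(rec)
  n1 <- noise_rms(rec$channels$green, p$channels$green$beats, 1000)$noise_rms
  n2 <- noise_rms(rec$channels$green + 500, p$channels$green$beats, 1000)$noise_rms
  expect_equal(n1, n2, tolerance = 1e-9)
})

test_that("fewer than 3 beats flags the noise estimate instead of erroring", {
  rec <- tiled_beat_record(n_beats = 40)
  short <- structure(list(anchors = c(100L, 900L), boundaries = c(1L, 801L),
                          valid = TRUE, beat_count = 1L, flagged = TRUE),
                     class = "beat_index")
  nr <- noise_rms(rec$channels$green, short, 1000)
  expect_true(nr$flagged)
  expect_true(is.na(nr$noise_rms))
})

test_that("SNR is the ratio of pulse height to noise RMS, capped at zero noise", {
  expect_equal(compute_snr(1000, 2)$snr, 500)
  capped <- compute_snr(1000, 0)
  expect_true(capped$capped)
  expect_equal(capped$snr, 1e6)
  expect_true(is.na(compute_snr(-1, 2)$snr))
})

test_that("exclusion rules fire exactly as stated, with a strict threshold", {
  cohort <- data.frame(
    record_id = paste0("r", 1:5),
    snr = c(150, 250, 300, 199, 1000),
    wrist_sbp = 120,
    inv_fwhm_vpg = 8, delay_green_nir = 0.02
  )
  res <- apply_exclusions(cohort)
  expect_equal(nrow(res$kept), 3)
  expect_equal(nrow(res$excluded), 2)
  expect_true(all(res$excluded$reasons == "snr_below_200"))
  expect_equal(unname(res$counts[["snr_below_200"]]), 2)

  # the boundary is strict: 199 excluded (S=398, noise=2), 200 kept, 201 kept
  edge <- data.frame(
    snr = c(compute_snr(398, 2)$snr, 200, compute_snr(402, 2)$snr),
    wrist_sbp = 120, inv_fwhm_vpg = 8, delay_green_nir = 0.02
  )
  res_edge <- apply_exclusions(edge)
  expect_equal(res_edge$kept$snr, c(200, 201))
  expect_equal(res_edge$excluded$snr, 199)

  # missing blood pressure excludes even at high SNR
  bp <- data.frame(snr = 500, wrist_sbp = NA_real_,
                   inv_fwhm_vpg = 8, delay_green_nir = 0.02)
  expect_equal(apply_exclusions(bp)$excluded$reasons, "missing_bp")

  # a record whose features could not be computed is excluded
  ff <- data.frame(snr = 500, wrist_sbp = 120,
                   inv_fwhm_vpg = NA_real_, delay_green_nir = 0.02)
  expect_equal(apply_exclusions(ff)$excluded$reasons, "feature_failure")
})

test_that("quality_report flags a processed record by the exclusion rules", {
  clean <- quick_sim(seed = 55, duration = 10,
                     metadata = list(wrist_sbp = 120, group = "control"))
  qr <- quality_report(process_record(clean$record))
  expect_false(qr$excluded)
  expect_equal(qr$reasons, "")

  noisy <- quick_sim(seed = 56, duration = 10, noise_sd = 12,
                     metadata = list(wrist_sbp = 120))
  qr2 <- quality_report(process_record(noisy$record))
  expect_true(qr2$excluded)
  expect_match(qr2$reasons, "snr_below_200")
})

test_that("SNR is invariant to amplitude scaling of the whole record", {
  sim <- quick_sim(seed = 31, duration = 20)
  p1 <- process_record(sim$record)
  scaled <- sim$record
  scaled$channels <- lapply(scaled$channels, function(x) 3.7 * x)
  p2 <- process_record(scaled)
  expect_equal(p2$qc$snr, p1$qc$snr, tolerance = 0.01)
})

test_that("measured noise RMS increases with injected noise", {
  meas <- vapply(c(0.5, 2, 6), function(s) {
    mean(vapply(1:3, function(k) {
      sim <- quick_sim(seed = 40 + k, duration = 20, noise_sd = s)
      p <- process_record(sim$record)
      p$qc$noise_rms
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meas) > 0))
})
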