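#' Noise RMS by ensemble-template subtraction
#'
#' The repeating pulse component is estimated as an ensemble-average beat
#' template and subtracted from every beat; the noise intensity is the RMS of
#' the residual. Beats are aligned in absolute time on their VPG-maximum
#' anchors (the steep systolic upstroke localizes far more precisely than the
#' flat PPG minima), and each beat is fitted with an offset, a linear trend,
#' the template, and the template derivative (absorbing sub-sample timing
#' jitter), after an integer-lag search; the residual standard deviation,
#' corrected for the fitted degrees of freedom, is pooled across beats. Two
#' alignment passes are run so the template itself is built from lag-corrected
#' beats.
#'
#' @param channel Sample vector (normally the raw, unfiltered channel, so that
#'   broad-band noise is counted at full power).
#' @param beats A [segment_beats()] result for this channel (from the filtered
#'   pipeline); its VPG anchors define the beat windows.
#' @param sampling_rate Sampling rate in Hz.
#' @param max_lag Integer-lag search half-width in samples.
#' @return List with `noise_rms` (a.u.), `n_beats` used, and `flagged`
#'   (`TRUE`, with `noise_rms = NA`, when fewer than 3 usable beats exist).
#' @export
noise_rms <- function(channel, beats, sampling_rate, max_lag = 8L) {
  bad <- list(noise_rms = NA_real_, n_beats = 0L, flagged = TRUE)
  if (!inherits(beats, "beat_index") || length(beats$anchors) < 3) return(bad)
  anchors <- beats$anchors
  period <- stats::median(diff(anchors))
  # window spans the systolic-dominant 60% of the beat around the upstroke:
  # late diastole near the next onset is excluded so that beat-period jitter
  # of neighboring beats does not count as noise
  pre <- as.integer(round(0.15 * period))
  post <- as.integer(round(0.45 * period))
  ok <- anchors - pre - max_lag >= 1 & anchors + post + max_lag <= length(channel)
  anchors <- anchors[ok]
  if (length(anchors) < 3) return(bad)
  w <- pre + post + 1L
  extract <- function(a, lag = 0L) channel[(a - pre + lag):(a + post + lag)]
  lags <- integer(length(anchors))
  tt <- seq_len(w) / sampling_rate
  resid_ss <- NULL
  resid_df <- NULL
  for (pass in 1:2) {
    mat <- vapply(seq_along(anchors),
                  function(i) extract(anchors[i], lags[i]), numeric(w))
    template <- rowMeans(mat)
    dtemplate <- differentiate_smooth(template, sampling_rate, window = 0)
    tc <- template - mean(template)
    resid_ss <- numeric(length(anchors))
    resid_df <- numeric(length(anchors))
    for (i in seq_along(anchors)) {
      # integer-lag search by maximizing correlation with the template
      best_lag <- lags[i]; best_cc <- -Inf
      for (lag in -max_lag:max_lag) {  # total lag bounded by max_lag
        y <- extract(anchors[i], lag)
        yc <- y - mean(y)
        cc <- sum(yc * tc) / max(sqrt(sum(yc^2)), .Machine$double.eps)
        if (is.finite(cc) && cc > best_cc) { best_cc <- cc; best_lag <- lag }
      }
      lags[i] <- best_lag
      y <- extract(anchors[i], lags[i])
      X <- cbind(1, tt, template, dtemplate)
      fit <- stats::lm.fit(X, y)
      resid_ss[i] <- sum(fit$residuals^2)
      resid_df[i] <- w - fit$rank
    }
  }
  list(
    noise_rms = sqrt(sum(resid_ss) / sum(resid_df)),
    n_beats = length(anchors),
    flagged = FALSE
  )
}

#' Signal-to-noise ratio of a PPG record
#'
#' The signal intensity is the pulse height S, the noise intensity is the
#' residual RMS after removing the repeating pulse component
#' ([noise_rms()]), and their ratio is the SNR.
#'
#' @param S Signal intensity (pulse height, a.u.).
#' @param noise Noise RMS (a.u.).
#' @param cap SNR value reported (with `capped = TRUE`) when the noise
#'   estimate is exactly zero.
#' @return List with `snr` and `capped`.
#' @export
compute_snr <- function(S, noise, cap = 1e6) {
  if (!is.finite(S) || !is.finite(noise) || S <= 0 || noise < 0) {
    return(list(snr = NA_real_, capped = FALSE))
  }
  if (noise == 0) return(list(snr = cap, capped = TRUE))
  list(snr = S / noise, capped = FALSE)
}

#' Apply the record-exclusion rules to a cohort table
#'
#' A record is excluded when any rule fires: its SNR (on any quality-control
#' channel present in the table) is strictly below the threshold, its wrist
#' systolic blood pressure is missing, or its key feature values could not be
#' calculated. A record whose SNR equals the threshold exactly is kept.
#'
#' @param cohort Data frame with one row per record; uses columns matching
#'   `snr_<channel>` (or a plain `snr` column), `wrist_sbp`, and the key
#'   feature columns.
#' @param snr_threshold Exclusion threshold (default 200).
#' @param key_features Feature columns that must be finite for the record to
#'   count as calculable.
#' @return List with `kept` and `excluded` data frames (the latter with a
#'   `reasons` column), and `counts`, the number of exclusions per reason.
#' @export
apply_exclusions <- function(cohort, snr_threshold = 200,
                             key_features = c("inv_fwhm_vpg", "delay_green_nir")) {
  stopifnot(is.data.frame(cohort))
  snr_cols <- grep("^snr(_|$)", names(cohort), value = TRUE)
  reasons <- vapply(seq_len(nrow(cohort)), function(i) {
    r <- character(0)
    if (length(snr_cols)) {
      snrs <- as.numeric(cohort[i, snr_cols])
      snrs <- snrs[is.finite(snrs)]  # absent channels are not analyzed
      if (length(snrs) && any(snrs < snr_threshold)) r <- c(r, "snr_below_200")
    }
    if ("wrist_sbp" %in% names(cohort) && !is.finite(cohort$wrist_sbp[i])) {
      r <- c(r, "missing_bp")
    }
    kf <- intersect(key_features, names(cohort))
    if (length(kf) && any(!is.finite(as.numeric(cohort[i, kf])))) {
      r <- c(r, "feature_failure")
    }
    paste(r, collapse = ";")
  }, character(1))
  excluded <- reasons != ""
  counts <- table(unlist(strsplit(reasons[excluded], ";")))
  ex <- cohort[excluded, , drop = FALSE]
  if (nrow(ex)) ex$reasons <- reasons[excluded]
  list(
    kept = cohort[!excluded, , drop = FALSE],
    excluded = ex,
    counts = counts
  )
}

#' Quality-control report for one processed record
#'
#' @param proc A [process_record()] result.
#' @param snr_threshold Exclusion threshold for the SNR rule.
#' @param key_features Features whose absence counts as a feature failure.
#' @return One-row data frame: per-channel S, noise RMS and SNR, plus
#'   `excluded` and `reasons`.
#' @export
quality_report <- function(proc, snr_threshold = 200,
                           key_features = c("inv_fwhm_vpg", "delay_green_nir")) {
  qc <- proc$qc
  row <- cbind(qc, proc$features[, intersect(key_features, names(proc$features)), drop = FALSE],
               wrist_sbp = proc$record$metadata$wrist_sbp)
  res <- apply_exclusions(row, snr_threshold, key_features)
  qc$excluded <- nrow(res$kept) == 0
  qc$reasons <- if (qc$excluded) res$excluded$reasons[1] else ""
  qc
}
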