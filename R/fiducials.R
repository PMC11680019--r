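#' Baseline-corrected pulse height S
#'
#' The two minima bounding the beat are connected by a straight line; the
#' height of the PPG above that line at its maximum is the pulse height S
#' (equivalently: the pulse maximum after a slope correction that makes the
#' minima-connecting line horizontal).
#'
#' @param ppg_beat PPG samples of one beat, first and last samples at the
#'   bounding minima.
#' @param sampling_rate Sampling rate in Hz (only used to report the time of
#'   the maximum).
#' @return List with `S` (a.u.), `t_max` (seconds from beat start) and `valid`
#'   (`FALSE` when no interior maximum exists or S is non-positive).
#' @export
#' @examples
#' # minima 10 and 14 one second apart, interior peak 50 at t = 0.3
#' fs <- 1000
#' t <- seq(0, 1, by = 1 / fs)
#' beat <- 10 + 4 * t + 40 * exp(-(t - 0.3)^2 / (2 * 0.03^2))
#' corrected_height_s(beat, fs)$S  # ~ 38.8
corrected_height_s <- function(ppg_beat, sampling_rate) {
  n <- length(ppg_beat)
  if (n < 3) return(list(S = NA_real_, t_max = NA_real_, valid = FALSE))
  line <- seq(ppg_beat[1], ppg_beat[n], length.out = n)
  resid <- ppg_beat - line
  i <- which.max(resid[2:(n - 1)]) + 1L
  s <- resid[i]
  list(
    S = s,
    t_max = (i - 1) / sampling_rate,
    valid = is.finite(s) && s > 0
  )
}

# 3-point parabolic interpolation around a sample extremum; returns the
# sub-sample offset (in samples, within [-0.5, 0.5]) and refined amplitude
parabolic_refine <- function(x, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(list(delta = 0, value = x[i]))
  y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
  denom <- y0 - 2 * y1 + y2
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * max(abs(c(y0, y1, y2)), 1)) {
    return(list(delta = 0, value = y1))
  }
  delta <- 0.5 * (y0 - y2) / denom
  delta <- max(-0.5, min(0.5, delta))
  list(delta = delta, value = y1 - 0.25 * (y0 - y2) * delta)
}

#' Full width at half maximum of the VPG systolic peak
#'
#' Locates the global VPG maximum within the beat and the two half-maximum
#' crossings bracketing it, each by linear interpolation between adjacent
#' samples.
#'
#' @param vpg_beat VPG samples of one beat.
#' @param sampling_rate Sampling rate in Hz.
#' @return List with `fwhm` (s), `inv_fwhm` (1/s), `t_peak` (s from beat
#'   start), `peak` (a.u./s) and `valid` (`FALSE` when the half level is not
#'   crossed on both sides within the beat).
#' @export
#' @examples
#' fs <- 1000
#' t <- seq(0, 0.5, by = 1 / fs)
#' v <- exp(-(t - 0.2)^2 / (2 * 0.05^2))
#' fwhm_vpg(v, fs)$fwhm  # ~ 2*sqrt(2*log(2))*0.05 = 0.1177
fwhm_vpg <- function(vpg_beat, sampling_rate) {
  bad <- list(fwhm = NA_real_, inv_fwhm = NA_real_, t_peak = NA_real_,
              peak = NA_real_, valid = FALSE)
  n <- length(vpg_beat)
  if (n < 5) return(bad)
  i <- which.max(vpg_beat)
  pk <- vpg_beat[i]
  if (!is.finite(pk) || pk <= 0) return(bad)
  ref <- parabolic_refine(vpg_beat, i)
  half <- ref$value / 2
  # left crossing
  li <- i
  while (li > 1 && vpg_beat[li] > half) li <- li - 1L
  if (vpg_beat[li] > half) return(bad)
  t_left <- li + (half - vpg_beat[li]) / (vpg_beat[li + 1] - vpg_beat[li])
  # right crossing
  ri <- i
  while (ri < n && vpg_beat[ri] > half) ri <- ri + 1L
  if (vpg_beat[ri] > half) return(bad)
  t_right <- (ri - 1) + (half - vpg_beat[ri - 1]) / (vpg_beat[ri] - vpg_beat[ri - 1])
  fwhm <- (t_right - t_left) / sampling_rate
  if (!is.finite(fwhm) || fwhm <= 0) return(bad)
  list(
    fwhm = fwhm, inv_fwhm = 1 / fwhm,
    t_peak = (i - 1 + ref$delta) / sampling_rate, peak = ref$value,
    valid = TRUE
  )
}

#' Detect APG a--e waves within one beat
#'
#' The a-wave is the global APG maximum inside the systolic-rise window; the
#' b-wave is the first local minimum after it. The later c (max), d (min) and
#' e (max) waves are searched within the first `cde_frac` of the beat and may
#' be absent. All peak times are refined to sub-sample precision by 3-point
#' parabolic interpolation. A beat is flagged invalid when a or b is missing,
#' the a-wave amplitude is not positive, or the a-b interval is outside
#' 10--450 ms (a physiologically implausible interval indicates a noise beat).
#'
#' @param apg_beat APG samples of one beat.
#' @param sampling_rate Sampling rate in Hz.
#' @param systolic_end End of the a-wave search window in seconds from beat
#'   start; defaults to 35% of the beat.
#' @param cde_frac Fraction of the beat searched for the c, d and e waves.
#' @return List with named elements `a`, `b`, `c`, `d`, `e` (each a
#'   `c(time, amplitude)` pair or `NULL`), plus `valid` and `reason`.
#' @export
detect_apg_waves <- function(apg_beat, sampling_rate, systolic_end = NULL,
                             cde_frac = 0.6) {
  n <- length(apg_beat)
  out <- list(a = NULL, b = NULL, c = NULL, d = NULL, e = NULL,
              valid = FALSE, reason = "")
  if (n < 7) { out$reason <- "beat_too_short"; return(out) }
  if (is.null(systolic_end)) systolic_end <- 0.35 * n / sampling_rate
  sys_n <- max(3L, min(n, ceiling(systolic_end * sampling_rate)))
  # the beat-delimiting PPG minimum is a sharp valley whose positive curvature
  # mimics an a-wave; skip the boundary region and demand a local maximum
  a_start <- max(0.03, 0.15 * systolic_end)
  maxs_all <- local_maxima(apg_beat)
  cand <- maxs_all[maxs_all <= sys_n & (maxs_all - 1) / sampling_rate >= a_start]
  if (!length(cand)) { out$reason <- "no_a_wave"; return(out) }
  ia <- cand[which.max(apg_beat[cand])]
  ra <- parabolic_refine(apg_beat, ia)
  a_t <- (ia - 1 + ra$delta) / sampling_rate
  a_amp <- ra$value
  if (!is.finite(a_amp) || a_amp <= 0) { out$reason <- "no_a_wave"; return(out) }
  out$a <- c(time = a_t, amp = a_amp)
  mins <- local_minima(apg_beat)
  ib <- mins[mins > ia]
  if (!length(ib)) { out$reason <- "no_b_wave"; return(out) }
  ib <- ib[1]
  rb <- parabolic_refine(apg_beat, ib)
  b_t <- (ib - 1 + rb$delta) / sampling_rate
  out$b <- c(time = b_t, amp = rb$value)
  ab <- b_t - a_t
  if (ab < 0.01 || ab > 0.45) { out$reason <- "implausible_ab_time"; return(out) }
  out$valid <- TRUE
  # c, d, e: alternating max/min/max after b, within the first cde_frac of beat
  lim <- floor(cde_frac * n)
  maxs <- maxs_all
  ic <- maxs[maxs > ib & maxs <= lim]
  if (length(ic)) {
    ic <- ic[1]
    rc <- parabolic_refine(apg_beat, ic)
    out$c <- c(time = (ic - 1 + rc$delta) / sampling_rate, amp = rc$value)
    id <- mins[mins > ic & mins <= lim]
    if (length(id)) {
      id <- id[1]
      rd <- parabolic_refine(apg_beat, id)
      out$d <- c(time = (id - 1 + rd$delta) / sampling_rate, amp = rd$value)
      ie <- maxs[maxs > id & maxs <= lim]
      if (length(ie)) {
        ie <- ie[1]
        re <- parabolic_refine(apg_beat, ie)
        out$e <- c(time = (ie - 1 + re$delta) / sampling_rate, amp = re$value)
      }
    }
  }
  out
}

#' Per-beat fiducials and features for one channel
#'
#' Runs [corrected_height_s()], [fwhm_vpg()] and [detect_apg_waves()] on every
#' valid beat of a segmented, derived channel and assembles the per-beat
#' feature table.
#'
#' @param derived A [derive_signals()] result for one channel.
#' @param beats A [segment_beats()] result on the same channel.
#' @return A data frame with one row per beat: boundary times, validity flag
#'   and reason, fiducial times/amplitudes (absolute times in seconds from the
#'   start of the record) and the feature columns described in
#'   [beat_features()].
#' @export
detect_fiducials <- function(derived, beats) {
  stopifnot(inherits(derived, "derived_signals"), inherits(beats, "beat_index"))
  fs <- derived$sampling_rate
  b <- beats$boundaries
  n_int <- length(b) - 1L
  rows <- vector("list", max(n_int, 0L))
  if (n_int >= 1) {
    for (k in seq_len(n_int)) {
      i0 <- b[k]; i1 <- b[k + 1]
      t_start <- (i0 - 1) / fs
      row <- data.frame(
        beat = k, t_start = t_start, t_end = (i1 - 1) / fs,
        valid = FALSE, reason = "spacing_out_of_bounds",
        apg_valid = FALSE, apg_reason = "",
        S = NA_real_, t_ppg_max = NA_real_,
        vpg_peak = NA_real_, t_vpg_max = NA_real_, fwhm_vpg = NA_real_,
        a_t = NA_real_, a_amp = NA_real_, b_t = NA_real_, b_amp = NA_real_,
        c_t = NA_real_, c_amp = NA_real_, d_t = NA_real_, d_amp = NA_real_,
        e_t = NA_real_, e_amp = NA_real_,
        stringsAsFactors = FALSE
      )
      if (beats$valid[k]) {
        seg <- i0:i1
        hs <- corrected_height_s(derived$ppg[seg], fs)
        fw <- fwhm_vpg(derived$vpg[seg], fs)
        if (!hs$valid) {
          row$reason <- "no_pulse_height"
        } else if (!fw$valid) {
          row$reason <- "no_vpg_half_width"
        } else {
          # beat usable for height/VPG features; APG fiducials are tracked
          # separately so that a missing a- or b-wave only skips the features
          # that need it
          row$valid <- TRUE
          row$reason <- ""
          row$S <- hs$S
          row$t_ppg_max <- t_start + hs$t_max
          row$vpg_peak <- fw$peak
          row$t_vpg_max <- t_start + fw$t_peak
          row$fwhm_vpg <- fw$fwhm
          ap <- detect_apg_waves(derived$apg[seg], fs,
                                 systolic_end = hs$t_max + 0.03)
          row$apg_valid <- ap$valid
          row$apg_reason <- ap$reason
          if (ap$valid) {
            row$a_t <- t_start + ap$a[["time"]]; row$a_amp <- ap$a[["amp"]]
            row$b_t <- t_start + ap$b[["time"]]; row$b_amp <- ap$b[["amp"]]
            if (!is.null(ap$c)) { row$c_t <- t_start + ap$c[["time"]]; row$c_amp <- ap$c[["amp"]] }
            if (!is.null(ap$d)) { row$d_t <- t_start + ap$d[["time"]]; row$d_amp <- ap$d[["amp"]] }
            if (!is.null(ap$e)) { row$e_t <- t_start + ap$e[["time"]]; row$e_amp <- ap$e[["amp"]] }
          }
        }
      }
      rows[[k]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  beat_features(out)
}

#' Compute per-beat features from detected fiducials
#'
#' Adds the feature columns to a per-beat fiducial table:
#' `inv_S = 1/S`, `a_over_S = a/S`, `inv_fwhm_vpg = 1/FWHM`,
#' `ab_time = t_b - t_a`, `inv_ab_time = 1/ab_time`,
#' `norm_ab = (a - b)/a` and `norm_ad = (a - d)/a` on the a-normalized APG,
#' and `ab_over_ad = norm_ab/norm_ad`. A feature whose denominator is missing
#' or non-positive is `NA`; the beat is retained for the other features.
#' Normalized amplitude ratios outside the plausible interval (0, 2] are
#' dropped as fiducial failures.
#'
#' @param fid Data frame of per-beat fiducials (see [detect_fiducials()]).
#' @return The input with feature columns appended.
#' @export
beat_features <- function(fid) {
  if (!nrow(fid)) {
    return(cbind(fid, data.frame(
      inv_S = numeric(0), a_over_S = numeric(0), inv_fwhm_vpg = numeric(0),
      ab_time = numeric(0), inv_ab_time = numeric(0), norm_ab = numeric(0),
      norm_ad = numeric(0), ab_over_ad = numeric(0)
    )[0, ]))
  }
  safe_div <- function(num, den) ifelse(is.finite(den) & den > 0, num / den, NA_real_)
  fid$inv_S <- safe_div(1, fid$S)
  fid$a_over_S <- safe_div(fid$a_amp, fid$S)
  fid$inv_fwhm_vpg <- safe_div(1, fid$fwhm_vpg)
  fid$ab_time <- fid$b_t - fid$a_t
  fid$inv_ab_time <- safe_div(1, fid$ab_time)
  fid$norm_ab <- safe_div(fid$a_amp - fid$b_amp, fid$a_amp)
  fid$norm_ad <- safe_div(fid$a_amp - fid$d_amp, fid$a_amp)
  in_range <- function(x) ifelse(!is.na(x) & (x <= 0 | x > 2), NA_real_, x)
  fid$norm_ab <- in_range(fid$norm_ab)
  fid$norm_ad <- in_range(fid$norm_ad)
  fid$ab_over_ad <- safe_div(fid$norm_ab, fid$norm_ad)
  fid
}

#' Green-vs-near-infrared a-wave peak delay
#'
#' For each near-infrared a-wave peak, the nearest green a-wave peak within
#' `pairing_window` seconds is paired (ties broken toward the earlier green
#' peak) and the delay `t_green - t_nir` computed; a positive delay means the
#' green a-wave lags the near-infrared one, i.e. the pulse arrives later in
#' the superficial capillary bed than in the deeper arterioles.
#'
#' @param green_a_times Green-channel a-wave peak times in seconds.
#' @param nir_a_times Near-infrared a-wave peak times in seconds (same time
#'   axis).
#' @param pairing_window Maximum |delay| for a pair, seconds.
#' @param summary_fun Aggregate for the per-record summary: `"median"`
#'   (default, robust to the large beat-to-beat variation of the delay) or
#'   `"mean"`.
#' @return An object of class `delay_series`: list with `delays` (seconds, one
#'   per pair), `pairs` (data frame of paired times), `summary` (aggregated
#'   delay) and `flagged` (`TRUE` when no pairs were found).
#' @export
channel_delay <- function(green_a_times, nir_a_times, pairing_window = 0.3,
                          summary_fun = c("median", "mean")) {
  summary_fun <- match.arg(summary_fun)
  g <- sort(green_a_times[is.finite(green_a_times)])
  nir <- sort(nir_a_times[is.finite(nir_a_times)])
  pairs <- list()
  for (tn in nir) {
    if (!length(g)) break
    dt <- g - tn
    ok <- abs(dt) <= pairing_window
    if (!any(ok)) next
    cand <- which(ok)
    best <- cand[order(abs(dt[cand]), g[cand])][1]  # tie -> earlier green peak
    pairs[[length(pairs) + 1]] <- data.frame(
      t_nir = tn, t_green = g[best], delay = dt[best]
    )
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(t_nir = numeric(0), t_green = numeric(0), delay = numeric(0))
  delays <- pairs$delay
  structure(
    list(
      delays = delays,
      pairs = pairs,
      summary = if (length(delays)) match.fun(summary_fun)(delays) else NA_real_,
      summary_fun = summary_fun,
      flagged = length(delays) == 0
    ),
    class = "delay_series"
  )
}

#' @export
print.delay_series <- function(x, ...) {
  cat(sprintf(
    "<delay_series> %d pair(s), %s delay %s s%s\n",
    length(x$delays), x$summary_fun,
    ifelse(is.na(x$summary), "NA", format(signif(x$summary, 4))),
    if (x$flagged) " [flagged]" else ""
  ))
  invisible(x)
}

#' Aggregate per-beat features into record-level features
#'
#' @param beat_tab Per-beat feature table from [detect_fiducials()].
#' @param delays Optional [channel_delay()] result for the record.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return One-row data frame with the record-level aggregate of each feature
#'   over valid beats (`S`, `inv_S`, `a`, `a_over_S`, `fwhm_vpg`,
#'   `inv_fwhm_vpg`, `ab_time`, `inv_ab_time`, `norm_ab`, `norm_ad`,
#'   `ab_over_ad`, `delay_green_nir`, `n_beats`).
#' @export
aggregate_record <- function(beat_tab, delays = NULL,
                             aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  agg <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else match.fun(aggregate)(x)
  }
  ok <- beat_tab[beat_tab$valid %in% TRUE, , drop = FALSE]
  data.frame(
    S = agg(ok$S),
    inv_S = agg(ok$inv_S),
    a = agg(ok$a_amp),
    a_over_S = agg(ok$a_over_S),
    fwhm_vpg = agg(ok$fwhm_vpg),
    inv_fwhm_vpg = agg(ok$inv_fwhm_vpg),
    ab_time = agg(ok$ab_time),
    inv_ab_time = agg(ok$inv_ab_time),
    norm_ab = agg(ok$norm_ab),
    norm_ad = agg(ok$norm_ad),
    ab_over_ad = agg(ok$ab_over_ad),
    delay_green_nir = if (is.null(delays)) NA_real_ else delays$summary,
    n_beats = nrow(ok)
  )
}
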