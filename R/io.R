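meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.yaml")
}

#' Write a waveform record to delimited text plus a metadata sidecar
#'
#' The waveform goes to a CSV with a `time` column and one column per channel;
#' the metadata (subject id, group, posture, cooled, wrist SBP, sampling rate,
#' t0) goes to a YAML sidecar next to it (`<stem>.meta.yaml`).
#'
#' @param record A [waveform_record()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  df <- data.frame(time = record_times(record))
  for (nm in intersect(c("green", "red", "nir"), names(record$channels))) {
    df[[nm]] <- record$channels[[nm]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- record$metadata
  meta$sampling_rate <- record$sampling_rate
  meta$t0 <- record$t0
  meta$wrist_sbp <- if (is.na(meta$wrist_sbp)) NULL else meta$wrist_sbp
  yaml::write_yaml(meta, meta_path(path))
  invisible(path)
}

#' Read a waveform record from delimited text
#'
#' Expects a CSV with a `time` column and at least one of the `green`, `red`,
#' `nir` channel columns, plus the YAML sidecar written by [write_record()]
#' (the sidecar is optional; without it the sampling rate is inferred from the
#' time column). Rejects non-monotone time and sampling jitter above 1%.
#'
#' @param path CSV path.
#' @return A [waveform_record()].
#' @export
read_record <- function(path) {
  df <- utils::read.csv(path)
  if (!"time" %in% names(df)) {
    stop("load error [", path, "]: missing 'time' column", call. = FALSE)
  }
  chans <- intersect(c("green", "red", "nir"), names(df))
  if (!length(chans)) {
    stop("load error [", path, "]: no channel column among green/red/nir",
         call. = FALSE)
  }
  dt <- diff(df$time)
  if (any(dt <= 0)) {
    stop("load error [", path, "]: time column is not strictly increasing",
         call. = FALSE)
  }
  dt_med <- stats::median(dt)
  if (max(abs(dt - dt_med)) > 0.01 * dt_med) {
    stop("load error [", path, "]: sampling jitter exceeds 1%; ",
         "irregularly sampled input is rejected (no resampling)", call. = FALSE)
  }
  meta <- list()
  fs <- 1 / dt_med
  t0 <- df$time[1]
  mp <- meta_path(path)
  if (file.exists(mp)) {
    side <- yaml::read_yaml(mp)
    if (!is.null(side$sampling_rate)) {
      if (abs(side$sampling_rate - fs) > 0.01 * fs) {
        stop("load error [", path, "]: sidecar sampling_rate (", side$sampling_rate,
             " Hz) disagrees with the time column (", signif(fs, 6), " Hz)",
             call. = FALSE)
      }
      fs <- side$sampling_rate
    }
    if (!is.null(side$t0)) t0 <- side$t0
    meta <- side[setdiff(names(side), c("sampling_rate", "t0"))]
  }
  waveform_record(
    channels = as.list(df[chans]),
    sampling_rate = fs, t0 = t0, metadata = meta
  )
}

#' Write a simulated cohort to a directory
#'
#' One CSV + sidecar per record, plus `ground_truth.csv` with the per-record
#' true parameters (including each record's seed).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$records)) {
    write_record(cohort$records[[i]]$record,
                 file.path(dir, paste0(cohort$truth$record_id[i], ".csv")))
  }
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
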