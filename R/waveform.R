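#' Multi-channel PPG waveform record
#'
#' The unit of acquisition: one or more simultaneously sampled PPG channels
#' (named among `"green"`, `"red"`, `"nir"`) with a common sampling rate and
#' per-record metadata.
#'
#' @param channels Named list of numeric sample vectors, all the same length
#'   (at least two seconds' worth of samples). Allowed names: `green`, `red`,
#'   `nir`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param metadata Named list; recognised fields are `subject_id`, `group`
#'   (`"diabetes"`, `"control"` or `"unknown"`), `posture` (`"navel"`,
#'   `"chest"`, `"forehead"` or `"other"`), `cooled` (logical) and `wrist_sbp`
#'   (mmHg, `NA` when the cuff measurement failed).
#'
#' @return An object of class `waveform_record`.
#' @export
#' @examples
#' fs <- 100
#' t <- seq(0, 5, by = 1 / fs)
#' rec <- waveform_record(
#'   channels = list(green = sin(2 * pi * 1.2 * t), nir = sin(2 * pi * 1.2 * t)),
#'   sampling_rate = fs
#' )
#' rec
waveform_record <- function(channels, sampling_rate, t0 = 0, metadata = list()) {
  stopifnot(is.list(channels), length(channels) >= 1)
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("`channels` must be a uniquely named list", call. = FALSE)
  }
  bad <- setdiff(nm, c("green", "red", "nir"))
  if (length(bad)) {
    stop("unknown channel name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  lens <- lengths(channels)
  if (length(unique(lens)) != 1) {
    stop("all channels must have the same length", call. = FALSE)
  }
  if (lens[[1]] < 2 * sampling_rate) {
    stop("channels must contain at least 2 seconds of samples", call. = FALSE)
  }
  channels <- lapply(channels, as.numeric)
  md <- normalize_metadata(metadata)
  structure(
    list(
      channels = channels,
      sampling_rate = as.numeric(sampling_rate),
      t0 = as.numeric(t0),
      metadata = md
    ),
    class = "waveform_record"
  )
}

normalize_metadata <- function(metadata) {
  md <- as.list(metadata)
  if (is.null(md$subject_id)) md$subject_id <- NA_character_
  md$subject_id <- as.character(md$subject_id)
  if (is.null(md$group) || is.na(md$group)) md$group <- "unknown"
  md$group <- match.arg(as.character(md$group), c("diabetes", "control", "unknown"))
  if (is.null(md$posture) || is.na(md$posture)) md$posture <- "other"
  md$posture <- match.arg(as.character(md$posture), c("navel", "chest", "forehead", "other"))
  if (is.null(md$cooled) || is.na(md$cooled)) md$cooled <- FALSE
  md$cooled <- isTRUE(as.logical(md$cooled))
  if (is.null(md$wrist_sbp)) md$wrist_sbp <- NA_real_
  md$wrist_sbp <- as.numeric(md$wrist_sbp)
  md
}

#' @export
print.waveform_record <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf(
    "<waveform_record> %d channel(s) [%s], %d samples @ %g Hz (%.1f s)\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    n, x$sampling_rate, n / x$sampling_rate
  ))
  cat(sprintf(
    "  subject: %s  group: %s  posture: %s  cooled: %s  wrist SBP: %s\n",
    x$metadata$subject_id, x$metadata$group, x$metadata$posture,
    x$metadata$cooled,
    ifelse(is.na(x$metadata$wrist_sbp), "NA", format(x$metadata$wrist_sbp))
  ))
  invisible(x)
}

#' Sample times of a waveform record
#'
#' @param record A [waveform_record()].
#' @return Numeric vector of sample times in seconds.
#' @export
record_times <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  record$t0 + (seq_along(record$channels[[1]]) - 1) / record$sampling_rate
}

#' Duration of a waveform record in seconds
#' @param record A [waveform_record()].
#' @return Length of the record in seconds.
#' @export
record_duration <- function(record) {
  length(record$channels[[1]]) / record$sampling_rate
}
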