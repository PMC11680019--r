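#' Default pipeline configuration
#'
#' One structured object holding every processing parameter: filter cutoffs
#' and realization, derivative smoothing window, heart-rate bounds and
#' refractory period for beat segmentation, a-wave pairing window, record
#' aggregation rule, SNR exclusion threshold and the channels it applies to,
#' the channel features are reported from, and the features whose absence
#' excludes a record.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @export
default_config <- function() {
  structure(
    list(
      filter = list(low_cut = 0.5, high_cut = 20, order = 2, zero_phase = TRUE),
      smoothing_window = 0.05,
      hr_bounds = c(30, 180),
      refractory = 0.3,
      pairing_window = 0.3,
      aggregate = "median",
      delay_summary = "median",
      snr_threshold = 200,
      qc_channels = c("green", "nir"),
      feature_channel = "green",
      key_features = c("inv_fwhm_vpg", "delay_green_nir"),
      seed = 1L
    ),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against the preconditions of the processing
#' operations and fills unset fields with defaults.
#'
#' @param config A list or `pipeline_config`.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(config = default_config()) {
  def <- default_config()
  cfg <- utils::modifyList(def, as.list(config))
  with(cfg, {
    if (!(filter$low_cut > 0 && filter$high_cut > filter$low_cut)) {
      stop("config error: need 0 < filter$low_cut < filter$high_cut", call. = FALSE)
    }
    if (smoothing_window < 0) stop("config error: smoothing_window < 0", call. = FALSE)
    if (!(length(hr_bounds) == 2 && hr_bounds[1] > 0 && hr_bounds[2] > hr_bounds[1])) {
      stop("config error: hr_bounds must be an increasing positive pair", call. = FALSE)
    }
    if (pairing_window <= 0) stop("config error: pairing_window <= 0", call. = FALSE)
    if (snr_threshold < 0) stop("config error: snr_threshold < 0", call. = FALSE)
  })
  cfg$aggregate <- match.arg(cfg$aggregate, c("median", "mean"))
  cfg$delay_summary <- match.arg(cfg$delay_summary, c("median", "mean"))
  cfg$feature_channel <- match.arg(cfg$feature_channel, c("green", "nir"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path File path.
#' @return `read_config()` returns a validated `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_config(config)), path)
  invisible(path)
}

config_filter_spec <- function(config) {
  filter_spec(config$filter$low_cut, config$filter$high_cut,
              config$filter$order, config$filter$zero_phase)
}
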