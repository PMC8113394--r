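#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG recording: a channels x samples
#' matrix of potentials in microvolts, the sampling rate, ordered channel
#' names, and the reference scheme.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one unique name per channel.
#' @param reference reference scheme, `"common"` or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names = NULL,
                      reference = c("common", "average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_names)) {
    channel_names <- rownames(data)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(nrow(data)))
    }
  }
  rec <- structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         reference = reference),
    class = "eeg_recording")
  validate_recording(rec)
}

#' @rdname recording
#' @param x object to validate.
#' @export
validate_recording <- function(x) {
  stopifnot(inherits(x, "eeg_recording"))
  if (!is.numeric(x$fs) || length(x$fs) != 1L || !is.finite(x$fs) || x$fs <= 0)
    stop("sampling rate `fs` must be a single positive number", call. = FALSE)
  if (nrow(x$data) < 2L)
    stop("a recording needs at least 2 channels", call. = FALSE)
  if (anyNA(x$data) || any(!is.finite(x$data)))
    stop("recording contains NaN/Inf values", call. = FALSE)
  if (length(x$channel_names) != nrow(x$data))
    stop("channel_names length (", length(x$channel_names),
         ") does not match channel count (", nrow(x$data), ")", call. = FALSE)
  if (anyDuplicated(x$channel_names))
    stop("channel names must be unique", call. = FALSE)
  if (!x$reference %in% c("common", "average"))
    stop("reference must be 'common' or 'average'", call. = FALSE)
  x
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(x) UseMethod("n_channels")
#' @export
n_channels.eeg_recording <- function(x) nrow(x$data)
#' @export
n_channels.eeg_epochs <- function(x) dim(x$epochs)[2L]

#' Epoched EEG
#'
#' Fixed-length, non-overlapping epochs cut from a continuous recording,
#' stored as an epoch x channel x sample array.
#'
#' @param epochs numeric array, epoch x channel x sample, microvolts.
#' @param fs sampling rate in Hz.
#' @param epoch_length_ms epoch duration in milliseconds; must correspond to
#'   an integer number of samples at `fs`.
#' @param channel_names character vector of channel names.
#' @param reference reference scheme carried over from the recording.
#' @return An object of class `eeg_epochs`.
#' @export
epoched_eeg <- function(epochs, fs, epoch_length_ms, channel_names = NULL,
                        reference = "common") {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3L)
  spe <- epoch_length_ms * fs / 1000
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_length_ms * fs / 1000 must be an integer sample count",
         call. = FALSE)
  if (dim(epochs)[3L] != round(spe))
    stop("epoch array sample dimension (", dim(epochs)[3L],
         ") does not match epoch_length_ms", call. = FALSE)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(epochs)[2L]))
  structure(
    list(epochs = epochs, fs = fs, epoch_length_ms = epoch_length_ms,
         channel_names = as.character(channel_names), reference = reference),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g ms @ %g Hz), %s reference\n",
              d[1L], d[2L], d[3L], x$epoch_length_ms, x$fs, x$reference))
  invisible(x)
}

#' Flatten epochs to a channels x samples matrix (epochs concatenated)
#' @noRd
epochs_to_matrix <- function(x) {
  d <- dim(x$epochs)
  m <- matrix(aperm(x$epochs, c(2L, 3L, 1L)), nrow = d[2L])
  rownames(m) <- x$channel_names
  m
}

#' Analysis configuration
#'
#' Bundle of pipeline parameters with validated defaults: 2-20 Hz band,
#' 2000 ms epochs, cluster search over q = 2..8, polarity-invariant
#' topographic matching, no temporal smoothing, family-wise alpha 0.05
#' Bonferroni-split over the four microstate classes.
#'
#' @param bandpass_low_hz,bandpass_high_hz band edges in Hz.
#' @param epoch_length_ms epoch duration in ms.
#' @param q_range inclusive integer range searched for the number of classes.
#' @param polarity_invariant disregard topography polarity when matching maps.
#' @param smoothing_min_ms minimum segment length enforced by label smoothing
#'   (0 disables smoothing).
#' @param alpha_family family-wise significance level.
#' @param n_comparisons number of comparisons the Bonferroni correction
#'   divides `alpha_family` by.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(bandpass_low_hz = 2, bandpass_high_hz = 20,
                            epoch_length_ms = 2000, q_range = 2:8,
                            polarity_invariant = TRUE, smoothing_min_ms = 0,
                            alpha_family = 0.05, n_comparisons = 4) {
  cfg <- structure(
    list(bandpass_low_hz = bandpass_low_hz, bandpass_high_hz = bandpass_high_hz,
         epoch_length_ms = epoch_length_ms, q_range = as.integer(q_range),
         polarity_invariant = isTRUE(polarity_invariant),
         smoothing_min_ms = smoothing_min_ms, alpha_family = alpha_family,
         n_comparisons = as.integer(n_comparisons)),
    class = "analysis_config")
  validate_analysis_config(cfg)
}

validate_analysis_config <- function(cfg) {
  with(cfg, {
    if (!(bandpass_low_hz > 0 && bandpass_low_hz < bandpass_high_hz))
      stop("need 0 < bandpass_low_hz < bandpass_high_hz", call. = FALSE)
    if (epoch_length_ms <= 0) stop("epoch_length_ms must be positive", call. = FALSE)
    if (length(q_range) < 1L || any(q_range < 2L) || any(q_range > 12L))
      stop("q_range must lie within [2, 12]", call. = FALSE)
    if (smoothing_min_ms < 0) stop("smoothing_min_ms must be >= 0", call. = FALSE)
    if (!(alpha_family > 0 && alpha_family < 1))
      stop("alpha_family must be in (0, 1)", call. = FALSE)
    if (n_comparisons < 1L) stop("n_comparisons must be >= 1", call. = FALSE)
  })
  cfg
}

config_schema_version <- "1"

#' Read / write an analysis configuration as YAML
#'
#' The YAML schema is versioned (`schema_version`); unknown keys are an error
#' so that misspelled options cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return `read_analysis_config` returns an `analysis_config`;
#'   `write_analysis_config` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version))
    stop("config file lacks schema_version", call. = FALSE)
  if (!identical(as.character(raw$schema_version), config_schema_version))
    stop("unsupported config schema_version: ", raw$schema_version, call. = FALSE)
  raw$schema_version <- NULL
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(raw$q_range)) raw$q_range <- raw$q_range[1L]:raw$q_range[length(raw$q_range)]
  do.call(analysis_config, raw)
}

#' @rdname read_analysis_config
#' @param cfg an `analysis_config`.
#' @export
write_analysis_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  out <- unclass(cfg)
  out$q_range <- c(min(out$q_range), max(out$q_range))
  yaml::write_yaml(c(list(schema_version = config_schema_version), out), path)
  invisible(path)
}
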