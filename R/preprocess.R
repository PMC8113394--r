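#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the net response is zero-phase and the stopband
#' attenuation is doubled. Filtering is applied to the continuous recording
#' before epoching to keep filter edge effects away from epoch boundaries.
#'
#' @param rec an [recording()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @return The filtered recording.
#' @export
bandpass <- function(rec, low = 2, high = 20) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high", call. = FALSE)
  if (high >= nyq) stop("high edge (", high, " Hz) must be below Nyquist (",
                        nyq, " Hz)", call. = FALSE)
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  out <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(bf, ch)))
  recording(out, fs = rec$fs, channel_names = rec$channel_names,
            reference = rec$reference)
}

#' Average re-reference
#'
#' Subtracts the instantaneous mean across channels at every sample, so each
#' sample's topography is zero-mean. Idempotent.
#'
#' @param rec an [recording()] (at least 2 channels).
#' @return The recording with `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  validate_recording(rec)
  out <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  recording(out, fs = rec$fs, channel_names = rec$channel_names,
            reference = "average")
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping, contiguous epochs starting at the first sample; a trailing
#' partial epoch is discarded, so the epoch count is
#' `floor(duration / epoch_length)`.
#'
#' @param rec an [recording()].
#' @param epoch_length_ms epoch duration in milliseconds.
#' @return An [epoched_eeg()] object.
#' @export
segment_epochs <- function(rec, epoch_length_ms = 2000) {
  validate_recording(rec)
  spe <- epoch_length_ms * rec$fs / 1000
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_length_ms does not correspond to an integer sample count at fs = ",
         rec$fs, call. = FALSE)
  spe <- as.integer(round(spe))
  n <- ncol(rec$data)
  n_epochs <- n %/% spe
  if (n_epochs < 1L)
    stop("recording (", n, " samples) is shorter than one epoch (", spe,
         " samples)", call. = FALSE)
  used <- rec$data[, seq_len(n_epochs * spe), drop = FALSE]
  arr <- aperm(array(used, dim = c(nrow(used), spe, n_epochs)), c(3L, 1L, 2L))
  epoched_eeg(arr, fs = rec$fs, epoch_length_ms = epoch_length_ms,
              channel_names = rec$channel_names, reference = rec$reference)
}

#' Global field power of a set of maps
#'
#' GFP at sample t is the uncorrected (population) standard deviation of the
#' average-referenced potential across the K channels:
#' `sqrt(mean((v - mean(v))^2))`. It is invariant to adding a constant to all
#' channels at a sample.
#'
#' @param x an [epoched_eeg()], [recording()], or channels x samples matrix.
#' @return An object of class `gfp_series`: per-sample GFP values (epochs
#'   concatenated), `fs`, epoch geometry and (after [find_gfp_peaks()]) peak
#'   indices.
#' @export
compute_gfp <- function(x) {
  if (inherits(x, "eeg_epochs")) {
    m <- epochs_to_matrix(x)
    spe <- dim(x$epochs)[3L]
    n_epochs <- dim(x$epochs)[1L]
    fs <- x$fs
  } else if (inherits(x, "eeg_recording")) {
    m <- x$data; spe <- ncol(m); n_epochs <- 1L; fs <- x$fs
  } else {
    m <- as.matrix(x); spe <- ncol(m); n_epochs <- 1L; fs <- NA_real_
  }
  if (anyNA(m)) stop("input contains NaN values", call. = FALSE)
  v <- gfp_of_maps(m)
  structure(list(values = v, fs = fs, n_epochs = n_epochs,
                 samples_per_epoch = spe, peak_indices = integer(0)),
            class = "gfp_series")
}

# columns are maps; population SD across channels
gfp_of_maps <- function(m) {
  mu <- colMeans(m)
  sqrt(pmax(colMeans(m^2) - mu^2, 0))
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d epochs x %d samples, %d peaks marked\n",
              x$n_epochs, x$samples_per_epoch, length(x$peak_indices)))
  invisible(x)
}

#' Locate GFP peaks
#'
#' Strict local maxima of the GFP series, evaluated within each epoch (peaks
#' never span or touch epoch boundaries). A plateau flanked by strictly lower
#' values reports its first sample. Topographies at GFP peaks have maximal
#' signal-to-noise and are the clustering input.
#'
#' @param gfp a `gfp_series` from [compute_gfp()].
#' @return The series with `peak_indices` filled (indices into the
#'   concatenated sample vector), invisibly also returned as an attribute-free
#'   integer vector via `$peak_indices`.
#' @export
find_gfp_peaks <- function(gfp) {
  stopifnot(inherits(gfp, "gfp_series"))
  spe <- gfp$samples_per_epoch
  if (spe < 3L) stop("epochs must hold at least 3 samples", call. = FALSE)
  peaks <- integer(0)
  for (e in seq_len(gfp$n_epochs)) {
    off <- (e - 1L) * spe
    v <- gfp$values[off + seq_len(spe)]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nr <- length(r$values)
    if (nr >= 3L) {
      is_peak <- c(FALSE, r$values[2:(nr - 1L)] > r$values[1:(nr - 2L)] &
                            r$values[2:(nr - 1L)] > r$values[3:nr], FALSE)
      peaks <- c(peaks, off + starts[is_peak])
    }
  }
  gfp$peak_indices <- peaks
  gfp
}
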