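#' Fit a microstate segmentation to resting-state EEG
#'
#' The package's central model fit. The continuous recording is band-pass
#' filtered (2-20 Hz by default), average re-referenced and cut into epochs;
#' topographies at GFP peaks are clustered by AAHC; the number of classes is
#' either fixed (`q`) or selected by the cross-validation criterion over
#' `config$q_range`; a four-class solution is canonically labeled MS1-MS4
#' against built-in normative maps; finally every sample is backfitted to its
#' best template (polarity-invariant spatial correlation) and the temporal
#' parameters computed.
#'
#' @param x an [recording()], an [epoched_eeg()] (taken as already
#'   preprocessed), or a channels x samples matrix (requires `fs`).
#' @param q fixed number of classes; `NULL` (default) selects by
#'   cross-validation.
#' @param config an [analysis_config()].
#' @param fs sampling rate, only when `x` is a bare matrix.
#' @param cluster_on cluster topographies at GFP peaks (default) or at every
#'   sample.
#' @param filter apply the band-pass filter (disable for pre-filtered data).
#' @return An object of class `microstates` with components `templates`
#'   (a [template_set()]), `diagnostics` (CV/GEV by q, when selected),
#'   `labels` (an [label_sequence()]), `metrics` (an `ms_metrics`), `gfp`,
#'   `gev` (explained variance of the backfit over all samples), `config`,
#'   and `call`.
#' @seealso [predict.microstates()], [simulate.microstates()],
#'   [summary.microstates()]
#' @examples
#' spec <- eeg_generator_spec(duration_s = 8, seed = 1)
#' fit <- microstates(simulate_recording(spec)$recording, q = 4)
#' fit
#' coef(fit)[, 1:4]
#' @export
microstates <- function(x, q = NULL, config = analysis_config(), fs = NULL,
                        cluster_on = c("peaks", "all"), filter = TRUE) {
  cluster_on <- match.arg(cluster_on)
  cl <- match.call()
  if (is.matrix(x) && !inherits(x, "eeg_recording")) {
    if (is.null(fs)) stop("fs is required for a bare matrix", call. = FALSE)
    x <- recording(x, fs = fs)
  }
  if (inherits(x, "eeg_recording")) {
    rec <- x
    if (filter) rec <- bandpass(rec, config$bandpass_low_hz,
                                config$bandpass_high_hz)
    rec <- rereference_average(rec)
    epochs <- segment_epochs(rec, config$epoch_length_ms)
  } else if (inherits(x, "eeg_epochs")) {
    epochs <- x
  } else stop("x must be a recording, epoched EEG, or matrix", call. = FALSE)

  gfp <- find_gfp_peaks(compute_gfp(epochs))
  m <- epochs_to_matrix(epochs)
  peak_idx <- if (cluster_on == "peaks") gfp$peak_indices else
    seq_len(ncol(m))
  if (length(peak_idx) < max(config$q_range, q))
    stop("too few GFP peaks (", length(peak_idx), ") for clustering",
         call. = FALSE)
  peak_maps <- t(m[, peak_idx, drop = FALSE])

  diagnostics <- NULL
  if (is.null(q)) {
    diagnostics <- select_cluster_number(peak_maps, config$q_range,
                                         channel_names = epochs$channel_names)
    templates <- diagnostics$templates
    q <- diagnostics$selected_q
  } else {
    templates <- aahc(peak_maps, q_target = q,
                      channel_names = epochs$channel_names)
  }
  if (q == 4L && all(epochs$channel_names %in% rownames(ten_twenty_positions)))
    templates <- canonical_order(templates, epochs$channel_names)

  labels <- label_timepoints(epochs, templates,
                             polarity_invariant = config$polarity_invariant)
  if (config$smoothing_min_ms > 0)
    labels <- smooth_labels(labels, config$smoothing_min_ms)
  metrics <- compute_metrics(labels)
  all_maps <- t(m)
  structure(list(templates = templates, diagnostics = diagnostics,
                 labels = labels, metrics = metrics, gfp = gfp,
                 gev = gev(all_maps, templates, assignment = pmax(labels$labels, 1L)),
                 gev_peaks = templates$gev,
                 q = q, config = config, fs = epochs$fs,
                 channel_names = epochs$channel_names,
                 n_epochs = dim(epochs$epochs)[1L],
                 samples_per_epoch = dim(epochs$epochs)[3L],
                 call = cl),
            class = "microstates")
}

#' @export
print.microstates <- function(x, ...) {
  cat("Microstate segmentation\n")
  cat(sprintf("  %d classes (%s), %d epochs x %d samples @ %g Hz\n",
              x$q, paste(x$templates$labels, collapse = ", "), x$n_epochs,
              x$samples_per_epoch, x$fs))
  cat(sprintf("  GEV: %.3f (all samples), %.3f (GFP peaks)\n",
              x$gev, x$gev_peaks))
  if (!is.null(x$diagnostics))
    cat(sprintf("  q selected by CV over {%s}\n",
                paste(names(x$diagnostics$cv_by_q), collapse = ", ")))
  invisible(x)
}

#' @export
summary.microstates <- function(object, ...) {
  structure(list(fit = object), class = "summary.microstates")
}

#' @export
print.summary.microstates <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$diagnostics)) print(x$fit$diagnostics)
  print(x$fit$metrics)
  invisible(x)
}

#' @export
coef.microstates <- function(object, ...) object$templates$maps

#' Backfit a fitted microstate model onto new EEG
#'
#' Applies the fit's preprocessing (filter, average reference, epoching) to
#' new data and labels every sample with the fitted templates.
#'
#' @param object a [microstates()] fit.
#' @param newdata an [recording()] or [epoched_eeg()] on the same montage;
#'   default: refit labels of the training data.
#' @param ... unused.
#' @return An [label_sequence()].
#' @export
predict.microstates <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  if (inherits(newdata, "eeg_recording")) {
    rec <- bandpass(newdata, object$config$bandpass_low_hz,
                    object$config$bandpass_high_hz)
    rec <- rereference_average(rec)
    newdata <- segment_epochs(rec, object$config$epoch_length_ms)
  }
  lab <- label_timepoints(newdata, object$templates,
                          polarity_invariant = object$config$polarity_invariant)
  if (object$config$smoothing_min_ms > 0)
    lab <- smooth_labels(lab, object$config$smoothing_min_ms)
  lab
}

#' Residual topographic amplitude of a microstate fit
#'
#' Per-sample fraction of GFP left unexplained by the assigned template:
#' `sqrt(1 - corr^2)` where `corr` is the spatial correlation between the
#' sample map and its template (0 for unassigned samples' entry is NA).
#'
#' @param object a [microstates()] fit.
#' @param ... unused.
#' @return numeric vector, one value per sample.
#' @export
residuals.microstates <- function(object, ...) {
  sim <- object$labels$similarity
  lab <- object$labels$labels
  out <- rep(NA_real_, length(lab))
  ok <- lab > 0L
  r <- sim[cbind(which(ok), lab[ok])]
  out[ok] <- sqrt(pmax(0, 1 - r^2))
  out
}

#' Simulate synthetic EEG from a fitted microstate model
#'
#' Uses the fitted template maps, mean durations and transition matrix as
#' the generating semi-Markov model and renders recordings with the
#' synthetic EEG generator.
#'
#' @param object a [microstates()] fit with `q >= 2`.
#' @param nsim number of recordings.
#' @param seed optional seed.
#' @param duration_s length of each simulated recording.
#' @param snr generator signal-to-noise ratio.
#' @param ... passed to [eeg_generator_spec()].
#' @return list of `nsim` results of [simulate_recording()].
#' @export
simulate.microstates <- function(object, nsim = 1, seed = NULL,
                                 duration_s = 10, snr = 2, ...) {
  if (!is.null(seed)) set.seed(seed)
  tm <- object$metrics$transitions
  rs <- rowSums(tm)
  tm[rs == 0, ] <- 1 / (object$q - 1)
  diag(tm) <- 0
  tm <- tm / rowSums(tm)
  dwell <- object$metrics$duration
  dwell[!is.finite(dwell)] <- mean(dwell, na.rm = TRUE)
  spec <- eeg_generator_spec(
    k = length(object$channel_names), q = object$q, fs = object$fs,
    duration_s = duration_s, mean_dwell_ms = unname(dwell),
    transition_matrix = unname(tm), snr = snr,
    templates = object$templates$maps, ...)
  replicate(nsim, simulate_recording(spec), simplify = FALSE)
}

#' Plot a microstate fit
#'
#' Two panels: the template maps as channel profiles, and the GFP trace of
#' the first epoch colored by the backfitted class.
#'
#' @param x a [microstates()] fit.
#' @param epoch which epoch to show in the GFP panel.
#' @param ... unused.
#' @export
plot.microstates <- function(x, epoch = 1L, ...) {
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(t(x$templates$maps), type = "l", lty = 1,
                    xlab = "channel", ylab = "normalized potential",
                    main = "template maps")
  graphics::legend("topright", legend = x$templates$labels, col = 1:x$q,
                   lty = 1, cex = 0.8, bty = "n")
  spe <- x$samples_per_epoch
  idx <- (epoch - 1L) * spe + seq_len(spe)
  tt <- (seq_len(spe) - 1L) / x$fs * 1000
  v <- x$gfp$values[idx]
  lab <- x$labels$labels[idx]
  graphics::plot(tt, v, type = "n", xlab = "time (ms)", ylab = "GFP (µV)",
                 main = sprintf("epoch %d GFP by class", epoch))
  for (cl in seq_len(x$q)) {
    vv <- v; vv[lab != cl] <- NA
    graphics::lines(tt, vv, col = cl)
  }
  invisible(x)
}

#' Wide per-subject table of microstate parameters
#'
#' One row per subject with the documented column order: `subject`,
#' `duration_MS1..4` (ms), `occurrence_MS1..4` (1/s), `coverage_MS1..4` (%),
#' then the 12 ordered transition probabilities `t_MS1_MS2..t_MS4_MS3`.
#'
#' @param fits named list of [microstates()] fits or `ms_metrics` objects.
#' @return data frame.
#' @export
metrics_table <- function(fits) {
  if (inherits(fits, "microstates") || inherits(fits, "ms_metrics"))
    fits <- list(fits)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("S", seq_along(fits))
  rows <- lapply(names(fits), function(id) {
    mt <- fits[[id]]
    if (inherits(mt, "microstates")) mt <- mt$metrics
    classes <- names(mt$duration)
    vals <- c(stats::setNames(mt$duration, paste0("duration_", classes)),
              stats::setNames(mt$occurrence, paste0("occurrence_", classes)),
              stats::setNames(mt$coverage, paste0("coverage_", classes)))
    tr <- mt$transitions
    for (i in classes) for (j in classes) if (i != j)
      vals[paste0("t_", i, "_", j)] <- tr[i, j]
    cbind(data.frame(subject = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  do.call(rbind, rows)
}
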