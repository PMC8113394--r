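#' Microstate label sequence
#'
#' Per-sample class labels for epoched EEG: integers `1..q` referencing
#' template rows, with `0` marking unassigned samples (zero GFP).
#'
#' @param labels integer vector, epochs concatenated.
#' @param fs sampling rate (Hz).
#' @param samples_per_epoch,n_epochs epoch geometry;
#'   `length(labels) == n_epochs * samples_per_epoch`.
#' @param q number of classes.
#' @param class_names optional class names (e.g. `"MS1".."MS4"`).
#' @param similarity optional samples x q matrix of polarity-invariant
#'   similarities, used by [smooth_labels()].
#' @return An object of class `ms_labels`.
#' @export
label_sequence <- function(labels, fs, samples_per_epoch,
                           n_epochs = length(labels) %/% samples_per_epoch,
                           q = max(labels, 1L), class_names = NULL,
                           similarity = NULL) {
  labels <- as.integer(labels)
  if (length(labels) != n_epochs * samples_per_epoch)
    stop("label length does not match epoch geometry", call. = FALSE)
  if (any(labels < 0L) || any(labels > q))
    stop("labels must lie in {0..q}", call. = FALSE)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(q))
  structure(list(labels = labels, fs = fs,
                 samples_per_epoch = as.integer(samples_per_epoch),
                 n_epochs = as.integer(n_epochs), q = as.integer(q),
                 class_names = class_names, similarity = similarity),
            class = "ms_labels")
}

#' @export
print.ms_labels <- function(x, ...) {
  cov <- round(100 * tabulate(x$labels, x$q) / max(1L, sum(x$labels > 0L)), 1)
  cat(sprintf("<ms_labels> %d epochs x %d samples @ %g Hz, q = %d (coverage %s)\n",
              x$n_epochs, x$samples_per_epoch, x$fs, x$q,
              paste0(x$class_names, " ", cov, "%", collapse = ", ")))
  invisible(x)
}

#' Backfit template maps onto every EEG sample
#'
#' Labels each sample with the template of maximal polarity-invariant spatial
#' correlation (equivalently, minimal global map dissimilarity). Ties break
#' toward the lower class index; zero-GFP samples get label 0.
#'
#' @param epochs an [epoched_eeg()] (average-referenced).
#' @param templates a [template_set()] for the same montage.
#' @param polarity_invariant disregard polarity (microstate convention).
#' @return An [label_sequence()] with the similarity matrix attached.
#' @export
label_timepoints <- function(epochs, templates, polarity_invariant = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(templates, "template_set"))
  if (dim(epochs$epochs)[2L] != ncol(templates$maps))
    stop("montage mismatch: epochs have ", dim(epochs$epochs)[2L],
         " channels, templates ", ncol(templates$maps), call. = FALSE)
  if (!is.null(templates$channel_names) &&
      !identical(epochs$channel_names, templates$channel_names))
    stop("montage mismatch: channel names differ", call. = FALSE)
  m <- epochs_to_matrix(epochs)                  # K x n
  vc <- sweep(m, 2L, colMeans(m), "-")
  ss <- colSums(vc^2)
  zero <- ss < 1e-300
  nv <- sqrt(ifelse(zero, 1, ss))
  sim <- crossprod(vc, t(templates$maps)) / nv   # n x q signed correlation
  if (polarity_invariant) sim <- abs(sim)
  lab <- max.col(sim, ties.method = "first")
  lab[zero] <- 0L
  sim[zero, ] <- 0
  label_sequence(lab, fs = epochs$fs,
                 samples_per_epoch = dim(epochs$epochs)[3L],
                 n_epochs = dim(epochs$epochs)[1L], q = templates$q,
                 class_names = templates$labels, similarity = sim)
}

# run-length encode the labels of one epoch
epoch_runs <- function(lab) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  data.frame(class = r$values, start = ends - r$lengths + 1L, end = ends,
             length = r$lengths)
}

#' Enforce a minimum microstate segment length
#'
#' Temporal smoothing of a label sequence: runs shorter than `min_ms` are
#' re-assigned sample-wise to the class of the neighboring run with higher
#' similarity at that sample, iterated until no short run remains. With
#' `min_ms = 0` the sequence is returned unchanged (the default analysis
#' applies no smoothing).
#'
#' @param labels an [label_sequence()]; must carry a similarity matrix (as
#'   produced by [label_timepoints()]) when `min_ms > 0`.
#' @param min_ms minimum segment duration in milliseconds.
#' @return The smoothed label sequence.
#' @export
smooth_labels <- function(labels, min_ms = 0) {
  stopifnot(inherits(labels, "ms_labels"), min_ms >= 0)
  if (min_ms == 0) return(labels)
  min_samples <- ceiling(min_ms * labels$fs / 1000)
  if (min_samples <= 1L) return(labels)
  sim <- labels$similarity
  if (is.null(sim))
    stop("smoothing needs the per-sample similarity matrix; ",
         "use the sequence returned by label_timepoints()", call. = FALSE)
  spe <- labels$samples_per_epoch
  lab <- labels$labels
  for (e in seq_len(labels$n_epochs)) {
    off <- (e - 1L) * spe
    seg <- lab[off + seq_len(spe)]
    repeat {
      runs <- epoch_runs(seg)
      short <- which(runs$length < min_samples & runs$class != 0L)
      if (length(short) == 0L || nrow(runs) == 1L) break
      i <- short[which.min(runs$length[short])]
      left <- if (i > 1L) runs$class[i - 1L] else NA_integer_
      right <- if (i < nrow(runs)) runs$class[i + 1L] else NA_integer_
      for (s in runs$start[i]:runs$end[i]) {
        cands <- stats::na.omit(c(left, right))
        cands <- cands[cands != 0L]
        if (length(cands) == 0L) { seg[s] <- 0L; next }
        sims <- vapply(cands, function(cl)
          if (cl == 0L) -Inf else sim[off + s, cl], 0)
        seg[s] <- cands[which.max(sims)]
      }
      if (all(seg == lab[off + seq_len(spe)])) break
      lab[off + seq_len(spe)] <- seg
    }
    lab[off + seq_len(spe)] <- seg
  }
  out <- labels
  out$labels <- lab
  out
}

#' Temporal microstate parameters from a label sequence
#'
#' Segments are maximal same-label runs within an epoch. Runs touching an
#' epoch's first or last sample are truncated by the epoch window, so they
#' are excluded from duration and occurrence (which need complete segments)
#' but still count toward coverage. Statistics are pooled over all epochs
#' (totals, not means of per-epoch means):
#' \itemize{
#'   \item duration: mean complete-run length per class, in ms;
#'   \item occurrence: complete runs per class / total labeled time, per s;
#'   \item coverage: percent of labeled samples per class (sums to 100);
#'   \item transitions: run-to-run conditional probabilities, see
#'     [transition_probabilities()].
#' }
#'
#' @param labels an [label_sequence()].
#' @return An object of class `ms_metrics` with fields `duration`,
#'   `occurrence`, `coverage` (named per class) and `transitions`.
#' @export
compute_metrics <- function(labels) {
  stopifnot(inherits(labels, "ms_labels"))
  q <- labels$q
  if (all(labels$labels == 0L)) stop("all samples unassigned", call. = FALSE)
  spe <- labels$samples_per_epoch
  total_run_len <- numeric(q); n_runs <- numeric(q)
  labeled <- numeric(q)
  for (e in seq_len(labels$n_epochs)) {
    seg <- labels$labels[(e - 1L) * spe + seq_len(spe)]
    runs <- epoch_runs(seg)
    complete <- runs$start > 1L & runs$end < spe & runs$class != 0L
    for (cl in unique(runs$class[complete])) {
      sel <- complete & runs$class == cl
      total_run_len[cl] <- total_run_len[cl] + sum(runs$length[sel])
      n_runs[cl] <- n_runs[cl] + sum(sel)
    }
    labeled <- labeled + tabulate(seg[seg != 0L], q)
  }
  total_labeled <- sum(labeled)
  duration <- ifelse(n_runs > 0, total_run_len / n_runs * 1000 / labels$fs,
                     NA_real_)
  occurrence <- n_runs / (total_labeled / labels$fs)
  coverage <- labeled / total_labeled * 100
  names(duration) <- names(occurrence) <- names(coverage) <- labels$class_names
  structure(list(duration = duration, occurrence = occurrence,
                 coverage = coverage,
                 transitions = transition_probabilities(labels),
                 n_complete_runs = stats::setNames(n_runs, labels$class_names),
                 fs = labels$fs),
            class = "ms_metrics")
}

#' @export
print.ms_metrics <- function(x, digits = 3, ...) {
  cat("<ms_metrics>\n")
  print(round(rbind(`duration (ms)` = x$duration,
                    `occurrence (1/s)` = x$occurrence,
                    `coverage (%)` = x$coverage), digits))
  cat("transition probabilities:\n")
  print(round(x$transitions, digits))
  invisible(x)
}

#' Run-to-run microstate transition probabilities
#'
#' Counts ordered transitions between consecutive segments (maximal runs) of
#' different classes within each epoch — never across epoch boundaries, and
#' an unassigned stretch breaks adjacency. Each row is normalized to the
#' conditional probability `P(next segment = j | current = i)`; rows with no
#' outgoing transitions are all-zero and flagged in the `"zero_rows"`
#' attribute.
#'
#' @param labels an [label_sequence()].
#' @return q x q matrix (zero diagonal) with attribute `zero_rows`.
#' @export
transition_probabilities <- function(labels) {
  stopifnot(inherits(labels, "ms_labels"))
  q <- labels$q
  counts <- matrix(0, q, q,
                   dimnames = list(labels$class_names, labels$class_names))
  spe <- labels$samples_per_epoch
  for (e in seq_len(labels$n_epochs)) {
    seg <- labels$labels[(e - 1L) * spe + seq_len(spe)]
    cls <- rle(seg)$values
    if (length(cls) < 2L) next
    from <- cls[-length(cls)]; to <- cls[-1L]
    ok <- from != 0L & to != 0L
    if (any(ok))
      counts <- counts + table(factor(from[ok], levels = seq_len(q)),
                               factor(to[ok], levels = seq_len(q)))
  }
  out_deg <- rowSums(counts)
  prob <- counts / ifelse(out_deg > 0, out_deg, 1)
  prob <- matrix(as.numeric(prob), q, q,
                 dimnames = list(labels$class_names, labels$class_names))
  attr(prob, "zero_rows") <- which(out_deg == 0)
  attr(prob, "n_transitions") <- sum(counts)
  prob
}
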