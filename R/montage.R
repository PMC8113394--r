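# Electrode geometry and idealized normative class topographies.
#
# Positions are schematic 2-D head coordinates (x: left -1 .. +1 right,
# y: posterior -1 .. +1 anterior) for the standard 10-20 set, enough to
# evaluate smooth normative maps on any montage built from these names.

ten_twenty_positions <- local({
  tab <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7  = c(-0.81, 0.59), F3  = c(-0.40, 0.52), Fz = c(0, 0.50),
    F4  = c(0.40, 0.52),  F8  = c(0.81, 0.59),
    FC1 = c(-0.22, 0.27), FC2 = c(0.22, 0.27),
    T7  = c(-1.00, 0.00), C3  = c(-0.50, 0.00), Cz = c(0, 0.00),
    C4  = c(0.50, 0.00),  T8  = c(1.00, 0.00),
    CP1 = c(-0.22, -0.27), CP2 = c(0.22, -0.27),
    P7  = c(-0.81, -0.59), P3 = c(-0.40, -0.52), Pz = c(0, -0.50),
    P4  = c(0.40, -0.52),  P8 = c(0.81, -0.59),
    O1  = c(-0.31, -0.95), O2 = c(0.31, -0.95), Oz = c(0, -1.00))
  colnames(tab) <- c("x", "y")
  tab
})

#' Schematic electrode positions for a montage
#'
#' Returns 2-D head coordinates for channels named after the 10-20 system;
#' unknown names are an error. For arbitrary channel counts (synthetic
#' montages) use [synthetic_montage()].
#'
#' @param channel_names character vector of electrode names.
#' @return numeric matrix with columns `x`, `y` and one row per channel.
#' @export
montage_positions <- function(channel_names) {
  idx <- match(channel_names, rownames(ten_twenty_positions))
  if (anyNA(idx))
    stop("no stored position for channel(s): ",
         paste(channel_names[is.na(idx)], collapse = ", "), call. = FALSE)
  ten_twenty_positions[idx, , drop = FALSE]
}

#' Default 19-channel montage
#' @return character vector of the classic 19 10-20 electrode names.
#' @export
montage_1020_19 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz", "C4",
    "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

#' Synthetic ring montage for arbitrary channel counts
#'
#' Places `k` electrodes on concentric rings inside the unit head disc; used
#' by the synthetic EEG generator when a named montage is not required.
#'
#' @param k number of channels (>= 2).
#' @return list with `channel_names` (`"ch1"...`) and a `positions` matrix.
#' @export
synthetic_montage <- function(k) {
  stopifnot(k >= 2L)
  n_rings <- max(1L, ceiling(k / 8))
  pos <- matrix(0, k, 2L, dimnames = list(NULL, c("x", "y")))
  i <- 1L
  for (ring in seq_len(n_rings)) {
    r <- ring / n_rings
    n_here <- if (ring < n_rings) min(8L, k - i + 1L) else k - i + 1L
    ang <- 2 * pi * (seq_len(n_here) - 1L) / n_here + 0.35 * ring
    pos[i:(i + n_here - 1L), ] <- cbind(r * cos(ang), r * sin(ang))
    i <- i + n_here
  }
  list(channel_names = paste0("ch", seq_len(k)), positions = pos)
}

# Idealized normative topographies for the four canonical classes, evaluated
# at electrode positions. Class MS1 (A): left-posterior vs right-anterior
# diagonal; MS2 (B): the mirrored diagonal; MS3 (C): anterior-posterior
# midline gradient; MS4 (D): fronto-central focal map. Rows centered
# (average reference) and unit L2 normalized.
canonical_reference_maps <- function(channel_names = NULL, positions = NULL) {
  if (is.null(positions)) positions <- montage_positions(channel_names)
  x <- positions[, "x"]; y <- positions[, "y"]
  g <- function(cx, cy, s = 0.55) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
  maps <- rbind(
    MS1 = g(0.6, 0.6) - g(-0.6, -0.6),    # right-anterior vs left-posterior
    MS2 = g(-0.6, 0.6) - g(0.6, -0.6),    # left-anterior vs right-posterior
    MS3 = g(0, 0.8) - g(0, -0.8),         # anterior vs posterior midline
    MS4 = g(0, 0.25, 0.45))               # fronto-central focal
  maps <- maps - rowMeans(maps)
  maps / sqrt(rowSums(maps^2))
}

#' Idealized class template maps for a montage
#'
#' The four normative topographies of [canonical_reference_maps()],
#' orthonormalized in class order (Gram-Schmidt), so the default synthetic
#' generator draws from four well-separated, zero-mean, unit-norm maps.
#'
#' @param channel_names electrode names with stored positions, or `NULL` if
#'   `positions` is given.
#' @param positions optional explicit position matrix (columns `x`, `y`).
#' @return 4 x K matrix, rows `MS1..MS4`.
#' @export
default_templates <- function(channel_names = montage_1020_19(),
                              positions = NULL) {
  maps <- canonical_reference_maps(channel_names, positions)
  for (i in seq_len(nrow(maps))) {
    v <- maps[i, ]
    if (i > 1L) {
      prev <- maps[seq_len(i - 1L), , drop = FALSE]
      v <- v - drop(crossprod(prev %*% v, prev))
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) stop("degenerate montage: templates not independent",
                        call. = FALSE)
    maps[i, ] <- v / nv
  }
  maps - rowMeans(maps)
}
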