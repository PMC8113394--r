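#' Specification for the synthetic microstate EEG generator
#'
#' Encodes the data-generating model the analysis assumes: the scalp
#' topography alternates among `q` quasi-stable template maps following a
#' semi-Markov sequence (geometric or gamma dwell times, mean
#' `mean_dwell_ms`), each map carried by an alpha-band amplitude oscillation,
#' plus spatially correlated 1/f noise. Defaults emulate eyes-closed resting
#' EEG: 4 classes, 80 ms mean dwell, 500 Hz, 60 s, 19-channel 10-20 montage
#' (a 64-channel synthetic-ring option mirrors denser caps).
#'
#' @param k number of channels (19 uses the named 10-20 montage).
#' @param q number of template classes.
#' @param fs sampling rate (Hz).
#' @param duration_s recording length (s).
#' @param mean_dwell_ms mean segment duration per class (scalar or length-q).
#' @param transition_matrix q x q row-stochastic matrix with zero diagonal;
#'   default uniform off-diagonal.
#' @param amplitude_uv peak amplitude of the template carrier (microvolts).
#' @param mod_freq_hz frequency of the alpha-band carrier oscillation.
#' @param snr ratio of mean template-signal GFP to mean noise GFP.
#' @param noise_corr_length spatial correlation length of the noise
#'   (head-radius units).
#' @param one_over_f_exponent temporal spectral exponent of the noise.
#' @param alpha_noise_prop proportion of noise power given to an additional
#'   8-12 Hz narrowband component (0 disables it).
#' @param dwell_dist `"geometric"` (memoryless, default) or `"gamma"`.
#' @param templates optional q x K matrix of generating maps; default
#'   [default_templates()] for the montage.
#' @param seed optional integer seed applied before generation.
#' @return list of class `eeg_generator_spec`.
#' @export
eeg_generator_spec <- function(k = 19L, q = 4L, fs = 500, duration_s = 60,
                               mean_dwell_ms = 80,
                               transition_matrix = NULL,
                               amplitude_uv = 10, mod_freq_hz = 10,
                               snr = 0.9, noise_corr_length = 0.6,
                               one_over_f_exponent = 1,
                               alpha_noise_prop = 0,
                               dwell_dist = c("geometric", "gamma"),
                               templates = NULL, seed = NULL) {
  dwell_dist <- match.arg(dwell_dist)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (q - 1), q, q)
    diag(transition_matrix) <- 0
  }
  tm <- as.matrix(transition_matrix)
  if (nrow(tm) != q || ncol(tm) != q || any(tm < 0) ||
      any(abs(diag(tm)) > 0) || any(abs(rowSums(tm) - 1) > 1e-9))
    stop("transition_matrix must be q x q, row-stochastic, zero diagonal",
         call. = FALSE)
  mean_dwell_ms <- rep_len(mean_dwell_ms, q)
  if (any(mean_dwell_ms <= 2000 / fs))
    stop("mean_dwell_ms must exceed 2 samples", call. = FALSE)
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (k == 19L) {
    channel_names <- montage_1020_19()
    positions <- montage_positions(channel_names)
  } else {
    sm <- synthetic_montage(k)
    channel_names <- sm$channel_names
    positions <- sm$positions
  }
  if (is.null(templates)) templates <- default_templates(positions = positions)[seq_len(min(q, 4L)), , drop = FALSE]
  if (nrow(templates) != q)
    stop("need one template per class (q = ", q, ")", call. = FALSE)
  structure(list(k = k, q = q, fs = fs, duration_s = duration_s,
                 mean_dwell_ms = mean_dwell_ms, transition_matrix = tm,
                 amplitude_uv = amplitude_uv, mod_freq_hz = mod_freq_hz,
                 snr = snr, noise_corr_length = noise_corr_length,
                 one_over_f_exponent = one_over_f_exponent,
                 alpha_noise_prop = alpha_noise_prop,
                 dwell_dist = dwell_dist,
                 templates = templates, channel_names = channel_names,
                 positions = positions, seed = seed),
            class = "eeg_generator_spec")
}

#' Draw a ground-truth microstate label sequence
#'
#' Semi-Markov generation: a dwell time is drawn for the current class
#' (geometric with the specified mean, or gamma), then the next class from
#' the transition matrix row. The realized per-class dwell means, counts and
#' transition counts are returned as ground truth.
#'
#' @param spec an [eeg_generator_spec()].
#' @return list with `labels` (an [label_sequence()] spanning the whole
#'   recording), `runs` (data frame of class/length), `realized` (per-class
#'   mean dwell ms, counts, empirical transition matrix).
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "eeg_generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$duration_s * spec$fs)
  dwell_samples <- spec$mean_dwell_ms * spec$fs / 1000
  draw_dwell <- function(cl) {
    if (spec$dwell_dist == "geometric")
      stats::rgeom(1L, 1 / dwell_samples[cl]) + 1L
    else
      max(1L, round(stats::rgamma(1L, shape = 4,
                                  scale = dwell_samples[cl] / 4)))
  }
  cls <- integer(0); lens <- integer(0)
  cur <- sample.int(spec$q, 1L)
  total <- 0L
  while (total < n) {
    d <- draw_dwell(cur)
    cls <- c(cls, cur); lens <- c(lens, d)
    total <- total + d
    cur <- sample.int(spec$q, 1L, prob = spec$transition_matrix[cur, ])
  }
  lens[length(lens)] <- lens[length(lens)] - (total - n)
  labels <- rep.int(cls, lens)
  runs <- data.frame(class = cls, length = lens)
  complete <- runs[-nrow(runs), , drop = FALSE]  # last run truncated
  realized_dwell <- vapply(seq_len(spec$q), function(cl) {
    v <- complete$length[complete$class == cl]
    if (length(v)) mean(v) * 1000 / spec$fs else NA_real_
  }, 0)
  tc <- matrix(0, spec$q, spec$q)
  if (nrow(runs) >= 2L) {
    from <- runs$class[-nrow(runs)]; to <- runs$class[-1L]
    tc <- unclass(table(factor(from, levels = 1:spec$q),
                        factor(to, levels = 1:spec$q)))
  }
  emp_tm <- tc / ifelse(rowSums(tc) > 0, rowSums(tc), 1)
  list(labels = label_sequence(labels, fs = spec$fs, samples_per_epoch = n,
                               n_epochs = 1L, q = spec$q,
                               class_names = paste0("MS", seq_len(spec$q))),
       runs = runs,
       realized = list(mean_dwell_ms = realized_dwell,
                       n_runs = tabulate(complete$class, spec$q),
                       transition_matrix = emp_tm,
                       transition_counts = tc))
}

# 1/f-shaped unit-variance noise, one row per source
shaped_noise <- function(n_src, n, fs, exponent, alpha_prop = 0) {
  freqs <- seq(0, fs, length.out = n + 1L)[1:n]
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  gain <- ifelse(freqs < 1e-9, 0, freqs^(-exponent / 2))
  out <- matrix(0, n_src, n)
  for (s in seq_len(n_src)) {
    spec_s <- stats::fft(stats::rnorm(n)) * gain
    x <- Re(stats::fft(spec_s, inverse = TRUE)) / n
    if (alpha_prop > 0) {
      band <- as.numeric(freqs >= 8 & freqs <= 12)
      spec_a <- stats::fft(stats::rnorm(n)) * band
      a <- Re(stats::fft(spec_a, inverse = TRUE)) / n
      x <- sqrt(1 - alpha_prop) * x / stats::sd(x) +
           sqrt(alpha_prop) * a / stats::sd(a)
    }
    out[s, ] <- x / stats::sd(x)
  }
  out
}

#' Render a label sequence into synthetic multichannel EEG
#'
#' Each sample's topography is the active class template scaled by an
#' alpha-band carrier (`amplitude_uv * sin(2 pi mod_freq_hz t + phase)`),
#' plus spatially correlated 1/f noise scaled so that the ratio of mean
#' template-signal GFP to mean noise GFP equals `snr`. The result is
#' average-referenced.
#'
#' @param sequence result of [generate_sequence()] (or an [label_sequence()]).
#' @param spec the [eeg_generator_spec()] used to draw the sequence.
#' @return list with `recording` (an [recording()]), `templates` (the
#'   ground-truth [template_set()]) and `labels`.
#' @export
generate_eeg <- function(sequence, spec) {
  stopifnot(inherits(spec, "eeg_generator_spec"))
  labels <- if (inherits(sequence, "ms_labels")) sequence else sequence$labels
  lab <- labels$labels
  n <- length(lab)
  tt <- (seq_len(n) - 1L) / spec$fs
  carrier <- spec$amplitude_uv * sin(2 * pi * spec$mod_freq_hz * tt +
                                     stats::runif(1L, 0, 2 * pi))
  tm <- spec$templates * sqrt(ncol(spec$templates))  # unit GFP rows
  sig <- t(tm[lab, , drop = FALSE]) * rep(carrier, each = spec$k)
  d2 <- as.matrix(stats::dist(spec$positions))^2
  cov_sp <- exp(-d2 / (2 * spec$noise_corr_length^2)) + diag(1e-6, spec$k)
  noise <- t(chol(cov_sp)) %*%
    shaped_noise(spec$k, n, spec$fs, spec$one_over_f_exponent,
                 spec$alpha_noise_prop)
  g_sig <- mean(gfp_of_maps(sig))
  g_noise <- mean(gfp_of_maps(noise))
  noise <- noise * g_sig / (spec$snr * g_noise)
  dat <- sig + noise
  dat <- sweep(dat, 2L, colMeans(dat), "-")
  rec <- recording(dat, fs = spec$fs, channel_names = spec$channel_names,
                   reference = "average")
  list(recording = rec,
       templates = template_set(spec$templates,
                                labels = paste0("MS", seq_len(spec$q)),
                                channel_names = spec$channel_names),
       labels = labels)
}

#' Convenience wrapper: one synthetic recording with ground truth
#' @param spec an [eeg_generator_spec()].
#' @return As [generate_eeg()], plus `sequence` with realized statistics.
#' @export
simulate_recording <- function(spec = eeg_generator_spec()) {
  sq <- generate_sequence(spec)
  out <- generate_eeg(sq, spec)
  out$sequence <- sq
  out
}
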