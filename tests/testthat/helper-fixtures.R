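# Small deterministic fixtures built in code.

# multichannel recording of superposed sinusoids (deterministic)
sine_recording <- function(k = 3, n = 2000, fs = 500, freq = 10, amp = 10) {
  tt <- (seq_len(n) - 1) / fs
  dat <- t(sapply(seq_len(k), function(ch)
    amp * sin(2 * pi * freq * tt + ch) + 0.5 * ch))
  recording(dat, fs = fs)
}

# epochs rendered noiselessly from templates and a per-sample label vector
noiseless_epochs <- function(templates, labels, fs = 500, amp = 5,
                             channel_names = NULL) {
  n <- length(labels)
  carrier <- amp * sin(2 * pi * 9.7 * (seq_len(n) - 1) / fs + 0.4)
  m <- t(templates[labels, , drop = FALSE]) * rep(carrier, each = ncol(templates))
  arr <- array(m, dim = c(nrow(m), n, 1L))
  arr <- aperm(arr, c(3L, 1L, 2L))
  epoched_eeg(arr, fs = fs, epoch_length_ms = n / fs * 1000,
              channel_names = channel_names)
}

# orthonormal zero-mean template rows for k channels (deterministic)
ortho_templates <- function(q, k, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(q * k), q, k)
  m <- m - rowMeans(m)
  for (i in seq_len(q)) {
    if (i > 1) {
      prev <- m[seq_len(i - 1), , drop = FALSE]
      m[i, ] <- m[i, ] - drop(crossprod(prev %*% m[i, ], prev))
    }
    m[i, ] <- m[i, ] / sqrt(sum(m[i, ]^2))
  }
  m
}

# independent brute-force Pearson correlation across channels
pearson_oracle <- function(u, v) {
  u <- u - mean(u); v <- v - mean(v)
  num <- sum(u * v)
  num / sqrt(sum(u^2) * sum(v^2))
}
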