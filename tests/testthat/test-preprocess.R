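test_that("band-pass keeps the passband and removes stopband and DC", {
  fs <- 500; n <- 5000
  tt <- (seq_len(n) - 1) / fs
  mid <- 1000:4000  # interior, away from filter edges
  in_band <- recording(rbind(10 * sin(2 * pi * 10 * tt),
                             10 * sin(2 * pi * 10 * tt + 1)), fs = fs)
  out <- bandpass(in_band, 2, 20)
  expect_equal(max(abs(out$data[1, mid])), 10, tolerance = 0.05)

  mains <- recording(rbind(10 * sin(2 * pi * 50 * tt),
                           10 * sin(2 * pi * 50 * tt + 1)), fs = fs)
  out <- bandpass(mains, 2, 20)
  expect_lt(max(abs(out$data[1, mid])), 1)   # >= 90% attenuation at 50 Hz

  dc <- recording(rbind(rep(7, n), rep(-3, n)), fs = fs)
  out <- bandpass(dc, 2, 20)
  expect_lt(abs(mean(out$data[, mid])), 1e-3)
  expect_lt(max(abs(out$data[, mid])), 1e-2)
})

test_that("band-pass meets the stated stopband attenuation at low/2 and 2*high", {
  fs <- 500; n <- 20000
  tt <- (seq_len(n) - 1) / fs
  mid <- 5000:15000
  for (f0 in c(1, 40)) {  # low/2 = 1 Hz, 2*high = 40 Hz
    rec <- recording(rbind(sin(2 * pi * f0 * tt), cos(2 * pi * f0 * tt)),
                     fs = fs)
    out <- bandpass(rec, 2, 20)
    gain <- max(abs(out$data[1, mid]))
    expect_lt(20 * log10(gain), -20)  # >= 20 dB down
  }
})

test_that("band-pass rejects an edge at or above Nyquist", {
  rec <- sine_recording(fs = 100)
  expect_error(bandpass(rec, 2, 50), "Nyquist")
  expect_error(bandpass(rec, 30, 20), "low < high")
})

test_that("average re-reference zeroes the channel mean and is idempotent", {
  rec <- recording(matrix(c(5, 5, 5, 5, 1, -1, 0, 0), nrow = 4), fs = 100)
  out <- rereference_average(rec)
  expect_equal(out$data[, 1], rep(0, 4))
  expect_equal(out$data[, 2], c(1, -1, 0, 0))
  expect_equal(out$reference, "average")
  twice <- rereference_average(out)
  expect_equal(twice$data, out$data)
  big <- sine_recording(k = 7, n = 500)
  reref <- rereference_average(big)
  expect_lt(max(abs(colMeans(reref$data))), 1e-9 * max(abs(reref$data)))
})

test_that("epoching yields 180 epochs from a 360 s recording at 500 Hz", {
  rec <- recording(matrix(rep(sin(1:180250), 2), nrow = 2, byrow = TRUE),
                   fs = 500)  # 360.5 s
  ep <- segment_epochs(rec, 2000)
  expect_equal(dim(ep$epochs), c(180L, 2L, 1000L))
  expect_equal(ep$epoch_length_ms, 2000)
})

test_that("epoching drops the trailing partial epoch and rejects short input", {
  fs <- 500
  rec <- recording(matrix(rnorm(2 * 1250), nrow = 2), fs = fs)  # 2500 ms
  ep <- segment_epochs(rec, 2000)
  expect_equal(dim(ep$epochs)[1], 1L)
  # conservation: n_epochs * spe <= total < (n_epochs + 1) * spe
  expect_true(1L * 1000L <= 1250 && 1250 < 2L * 1000L)
  expect_equal(ep$epochs[1, , ], rec$data[, 1:1000])
  short <- recording(matrix(rnorm(2 * 999), nrow = 2), fs = fs)  # 1998 ms
  expect_error(segment_epochs(short, 2000), "shorter")
})

test_that("GFP equals the population SD across channels", {
  expect_equal(compute_gfp(matrix(c(1, -1, 1, -1), ncol = 1))$values, 1)
  expect_equal(compute_gfp(matrix(rep(3.7, 4), ncol = 1))$values, 0)
  set.seed(11)
  m <- matrix(rnorm(8 * 50), nrow = 8)
  g <- compute_gfp(m)$values
  oracle <- apply(m, 2, function(v) {      # direct per-sample loop
    mu <- sum(v) / length(v)
    sqrt(sum((v - mu)^2) / length(v))
  })
  expect_equal(g, oracle, tolerance = 1e-12)
  # invariant to adding a constant to all channels at a sample
  shifted <- m + matrix(rep(rnorm(50), each = 8), nrow = 8)
  expect_equal(compute_gfp(shifted)$values, g, tolerance = 1e-12)
  expect_error(compute_gfp(matrix(c(1, NA), 2)), "NaN")
})

test_that("GFP peaks are strict interior local maxima with the plateau rule", {
  mk <- function(v) structure(list(values = v, fs = 100, n_epochs = 1L,
                                   samples_per_epoch = length(v),
                                   peak_indices = integer(0)),
                              class = "gfp_series")
  expect_equal(find_gfp_peaks(mk(c(0, 1, 0, 2, 0)))$peak_indices, c(2L, 4L))
  expect_equal(find_gfp_peaks(mk(c(1, 2, 3, 4, 5)))$peak_indices, integer(0))
  expect_equal(find_gfp_peaks(mk(c(0, 2, 2, 0)))$peak_indices, 2L)
  # epoch boundaries are never peaks and peaks never span epochs
  two <- structure(list(values = c(0, 1, 2, 1, 0, 5, 1, 0, 1, 0), fs = 100,
                        n_epochs = 2L, samples_per_epoch = 5L,
                        peak_indices = integer(0)), class = "gfp_series")
  expect_equal(find_gfp_peaks(two)$peak_indices, c(3L, 9L))
})

test_that("GFP peak finder matches a brute-force scan on random series", {
  set.seed(21)
  for (rep in 1:5) {
    v <- round(abs(rnorm(60)), 2)
    g <- structure(list(values = v, fs = 100, n_epochs = 1L,
                        samples_per_epoch = 60L, peak_indices = integer(0)),
                   class = "gfp_series")
    got <- find_gfp_peaks(g)$peak_indices
    oracle <- integer(0)  # first sample of any plateau with lower flanks
    i <- 2L
    while (i < 60L) {
      j <- i
      while (j < 60L && v[j + 1L] == v[i]) j <- j + 1L
      if (j < 60L && v[i - 1L] < v[i] && v[j + 1L] < v[i])
        oracle <- c(oracle, i)
      i <- j + 1L
    }
    expect_identical(got, oracle)
  }
})
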