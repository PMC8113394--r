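test_that("backfitting labels exact template data correctly with the tie rule", {
  gen <- ortho_templates(3, 10)
  ts <- template_set(gen)
  ep <- noiseless_epochs(gen, rep(2L, 50), fs = 500)
  lab <- label_timepoints(ep, ts)
  expect_true(all(lab$labels == 2L))
  # a map exactly equidistant between templates 1 and 2 goes to the lower index
  t1 <- c(1, -1, 0, 0) / sqrt(2)
  t2 <- c(0, 0, 1, -1) / sqrt(2)
  mix <- t1 + t2
  arr <- aperm(array(t(rbind(mix, mix, mix)), dim = c(4, 3, 1)), c(3, 1, 2))
  ep2 <- epoched_eeg(arr, fs = 500, epoch_length_ms = 6)
  lab2 <- label_timepoints(ep2, template_set(rbind(t1, t2)))
  expect_true(all(lab2$labels == 1L))
})

test_that("zero-GFP samples are unassigned and montages must match", {
  gen <- ortho_templates(2, 8)
  m <- t(gen[c(1, 2, 1), ])
  m[, 2] <- 0
  arr <- aperm(array(m, dim = c(8, 3, 1)), c(3, 1, 2))
  ep <- epoched_eeg(arr, fs = 500, epoch_length_ms = 6)
  lab <- label_timepoints(ep, template_set(gen))
  expect_equal(lab$labels, c(1L, 0L, 1L))
  expect_error(label_timepoints(ep, template_set(ortho_templates(2, 9))),
               "montage")
})

test_that("backfit labels equal a per-sample brute-force oracle", {
  set.seed(41)
  gen <- ortho_templates(4, 12)
  ts <- template_set(gen)
  m <- matrix(rnorm(12 * 100), 12, 100)
  arr <- aperm(array(m, dim = c(12, 100, 1)), c(3, 1, 2))
  ep <- epoched_eeg(arr, fs = 500, epoch_length_ms = 200)
  lab <- label_timepoints(ep, ts)
  oracle <- vapply(1:100, function(t) {
    sims <- vapply(1:4, function(j)
      abs(pearson_oracle(m[, t], gen[j, ])), 0)
    which.max(sims)
  }, 0L)
  expect_equal(lab$labels, oracle)
})

test_that("label smoothing removes short runs and is identity at min_ms 0", {
  gen <- ortho_templates(2, 8)
  lab_vec <- c(1, 1, 1, 2, 1, 1, 1)
  ep <- noiseless_epochs(gen, lab_vec, fs = 500)
  lab <- label_timepoints(ep, template_set(gen))
  expect_equal(lab$labels, lab_vec)         # sanity: flicker present
  expect_identical(smooth_labels(lab, 0)$labels, lab$labels)
  sm <- smooth_labels(lab, 4)               # 4 ms = 2 samples at 500 Hz
  expect_equal(sm$labels, rep(1L, 7))
})

test_that("after smoothing no interior run is shorter than the minimum", {
  set.seed(42)
  gen <- ortho_templates(3, 10)
  lab_vec <- rep(sample(1:3, 60, TRUE), times = sample(2:5, 60, TRUE))[1:120]
  ep <- noiseless_epochs(gen, lab_vec, fs = 500)
  lab <- label_timepoints(ep, template_set(gen))
  sm <- smooth_labels(lab, 4)               # 2 samples minimum
  runs <- rle(sm$labels)
  interior <- runs$lengths[seq_along(runs$lengths) %in%
                             2:(length(runs$lengths) - 1)]
  expect_true(all(interior >= 2))
})

test_that("metrics follow the hand-counted example and boundary rule", {
  lab <- label_sequence(c(1, 1, 2, 2, 2, 1), fs = 500, samples_per_epoch = 6,
                        q = 2)
  mt <- compute_metrics(lab)
  expect_equal(unname(mt$duration[2]), 6)        # one complete run of 3 samples
  expect_true(is.na(mt$duration[1]))             # class 1 only has boundary runs
  expect_equal(unname(mt$coverage), c(50, 50))
  # one class everywhere: full coverage but no complete run
  lab1 <- label_sequence(rep(1, 20), fs = 500, samples_per_epoch = 20, q = 2)
  mt1 <- compute_metrics(lab1)
  expect_equal(unname(mt1$coverage[1]), 100)
  expect_equal(unname(mt1$occurrence[1]), 0)
  expect_error(compute_metrics(label_sequence(rep(0, 5), fs = 500,
                                              samples_per_epoch = 5, q = 2)),
               "unassigned")
})

test_that("coverage sums to 100 and matches occurrence x duration on boundary-free sequences", {
  set.seed(43)
  # pad with class-0 at both ends so no class run touches an epoch boundary
  core <- rep(sample(1:4, 30, TRUE), times = sample(2:6, 30, TRUE))
  lab_vec <- c(0, core, 0)
  lab <- label_sequence(lab_vec, fs = 500, samples_per_epoch = length(lab_vec),
                        q = 4)
  mt <- compute_metrics(lab)
  expect_equal(sum(mt$coverage), 100, tolerance = 1e-9)
  ok <- mt$n_complete_runs > 0
  expect_equal(unname(mt$coverage[ok]),
               unname(mt$occurrence[ok] * mt$duration[ok] / 10),
               tolerance = 1e-9)
})

test_that("durations from a Markov generator match the analytic mean dwell", {
  spec <- eeg_generator_spec(duration_s = 60, seed = 44)
  sq <- generate_sequence(spec)
  # re-wrap the one long sequence into 2 s analysis epochs
  lab <- label_sequence(sq$labels$labels[1:30000], fs = 500,
                        samples_per_epoch = 1000, n_epochs = 30L, q = 4)
  mt <- compute_metrics(lab)
  pooled <- sum(mt$duration * mt$n_complete_runs) / sum(mt$n_complete_runs)
  expect_lt(abs(pooled - 80) / 80, 0.10)
})

test_that("transition probabilities follow hand counts and flag silent rows", {
  lab <- label_sequence(c(1, 2, 1, 2), fs = 500, samples_per_epoch = 4, q = 2)
  tp <- transition_probabilities(lab)
  expect_equal(tp["class1", "class2"], 1)
  expect_equal(tp["class2", "class1"], 1)
  lab2 <- label_sequence(c(1, 2, 1, 3), fs = 500, samples_per_epoch = 4, q = 3)
  tp2 <- transition_probabilities(lab2)
  expect_equal(unname(tp2[1, 2:3]), c(0.5, 0.5))
  expect_equal(attr(tp2, "zero_rows"), c(class3 = 3L))
  expect_true(all(abs(rowSums(tp2)[1:2] - 1) < 1e-12))
  # transitions are not counted across epoch boundaries
  lab3 <- label_sequence(c(1, 1, 2, 2), fs = 500, samples_per_epoch = 2, q = 2)
  expect_equal(sum(attr(transition_probabilities(lab3), "n_transitions")), 0)
})

test_that("empirical transition matrix converges to the generator matrix", {
  tm <- rbind(c(0, 0.7, 0.2, 0.1),
              c(0.3, 0, 0.5, 0.2),
              c(0.25, 0.25, 0, 0.5),
              c(0.4, 0.4, 0.2, 0))
  spec <- eeg_generator_spec(fs = 100, duration_s = 600, mean_dwell_ms = 50,
                             transition_matrix = tm, seed = 45)
  sq <- generate_sequence(spec)
  expect_gte(sum(sq$realized$transition_counts), 1e4)
  est <- transition_probabilities(sq$labels)
  expect_lt(max(abs(est - tm)), 0.05)
})
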