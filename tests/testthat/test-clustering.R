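test_that("spatial similarity matches the channel-wise Pearson oracle", {
  set.seed(31)
  u <- rnorm(10); v <- rnorm(10)
  u <- u - mean(u); v <- v - mean(v)
  expect_equal(spatial_similarity(u, v, polarity_invariant = FALSE),
               pearson_oracle(u, v), tolerance = 1e-12)
  expect_equal(spatial_similarity(u, u), 1)
  expect_equal(gmd(u, u), 0)
  expect_equal(spatial_similarity(u, -u, polarity_invariant = TRUE), 1)
  expect_equal(spatial_similarity(u, -u, polarity_invariant = FALSE), -1)
  expect_error(spatial_similarity(u, rep(0, 10)), "zero-GFP")
})

test_that("GMD and spatial correlation satisfy GMD^2 = 2(1 - corr)", {
  set.seed(32)
  for (i in 1:5) {
    u <- rnorm(12); v <- rnorm(12)
    u <- u - mean(u); v <- v - mean(v)
    # direct GMD oracle on GFP-normalized average-referenced maps
    gu <- sqrt(mean(u^2)); gv <- sqrt(mean(v^2))
    d_direct <- sqrt(mean((u / gu - v / gv)^2))
    r <- spatial_similarity(u, v, polarity_invariant = FALSE)
    expect_equal(d_direct, gmd(u, v), tolerance = 1e-12)
    expect_equal(d_direct^2 + 2 * r, 2, tolerance = 1e-12)
  }
})

test_that("AAHC at q = n keeps singletons with GEV 1", {
  set.seed(33)
  maps <- matrix(rnorm(5 * 8), 5, 8)
  ts <- aahc(maps, q_target = 5)
  expect_equal(ts$q, 5L)
  expect_equal(ts$gev, 1, tolerance = 1e-12)
  expect_equal(sort(unique(ts$assignment)), 1:5)
})

test_that("AAHC recovers orthogonal generators from noiseless sign-flipped copies", {
  gen <- ortho_templates(2, 10)
  maps <- rbind(gen[c(1, 2, 1, 2, 1, 2), ] * c(1, 1, -1, 1, 3, -2))
  ts <- aahc(maps, q_target = 2)
  sims <- abs(ts$maps %*% t(gen))
  expect_equal(unname(sort(apply(sims, 1, max))), c(1, 1), tolerance = 1e-9)
  expect_equal(ts$gev, 1, tolerance = 1e-9)
})

test_that("AAHC recovers 3 noisy generators and is order-invariant", {
  set.seed(34)
  gen <- ortho_templates(3, 12)
  idx <- rep(1:3, each = 10)
  maps <- gen[idx, ] * sample(c(-1, 1), 30, TRUE) * runif(30, 0.8, 1.2) +
    matrix(rnorm(30 * 12, sd = 0.03), 30, 12)
  ts <- aahc(maps, q_target = 3)
  sims <- abs(ts$maps %*% t(gen))
  best <- apply(sims, 1, which.max)
  expect_equal(sort(unname(best)), 1:3)                    # distinct generators
  expect_true(all(apply(sims, 1, max) >= 0.99))
  # permuting the input maps permutes labels only
  perm <- sample(30)
  ts2 <- aahc(maps[perm, ], q_target = 3)
  sims12 <- abs(ts$maps %*% t(ts2$maps))
  expect_true(all(apply(sims12, 1, max) > 0.999))
  expect_equal(ts$gev, ts2$gev, tolerance = 1e-6)
})

test_that("GEV is 1 on exact template data, 0 on orthogonal mislabels, and matches direct summation", {
  gen <- ortho_templates(2, 10)
  maps <- gen[c(1, 1, 2, 2), ] * c(2, -3, 1, 4)
  ts <- template_set(gen)
  expect_equal(gev(maps, ts, assignment = c(1, 1, 2, 2)), 1, tolerance = 1e-12)
  expect_equal(gev(maps, ts, assignment = c(2, 2, 1, 1)), 0, tolerance = 1e-12)

  set.seed(35)
  maps <- matrix(rnorm(50 * 10), 50, 10)
  lab <- sample(1:2, 50, TRUE)
  # term-by-term oracle
  num <- 0; den <- 0
  for (t in 1:50) {
    v <- maps[t, ] - mean(maps[t, ])
    g <- sqrt(mean(v^2))
    r <- pearson_oracle(v, gen[lab[t], ])
    num <- num + (g * r)^2
    den <- den + g^2
  }
  expect_equal(gev(maps, ts, assignment = lab), num / den, tolerance = 1e-12)
})

test_that("GEV and AAHC are invariant to global sign flips", {
  set.seed(36)
  gen <- ortho_templates(2, 10)
  maps <- gen[rep(1:2, 10), ] + matrix(rnorm(200, sd = 0.05), 20, 10)
  ts <- aahc(maps, 2)
  flip <- maps * sample(c(-1, 1), 20, TRUE)
  ts_f <- aahc(flip, 2)
  expect_equal(abs(ts$maps %*% t(ts_f$maps))[cbind(1:2, apply(
    abs(ts$maps %*% t(ts_f$maps)), 1, which.max))], c(1, 1), tolerance = 1e-9)
  expect_equal(gev(maps, ts), gev(flip, ts), tolerance = 1e-12)
})

test_that("CV criterion matches a hand-summed oracle and handles boundaries", {
  gen <- ortho_templates(2, 8)
  # noiseless: sigma2 = 0 so CV = 0
  exact <- gen[c(1, 2, 1), ] * c(2, 1, -1)
  ts <- template_set(gen)
  expect_equal(cv_criterion(exact, ts, assignment = c(1, 2, 1)), 0,
               tolerance = 1e-12)
  set.seed(37)
  maps <- matrix(rnorm(5 * 8), 5, 8)
  lab <- c(1, 2, 1, 2, 1)
  k <- 8; n <- 5; q <- 2
  s2 <- 0
  for (t in 1:n) {
    v <- maps[t, ] - mean(maps[t, ])
    s2 <- s2 + sum(v * v) - sum(v * ts$maps[lab[t], ])^2
  }
  s2 <- s2 / (n * (k - 1))
  expect_equal(cv_criterion(maps, ts, assignment = lab),
               s2 * ((k - 1) / (k - 1 - q))^2, tolerance = 1e-12)
  # q = K - 2 finite; q = K - 1 errors
  ts6 <- template_set(ortho_templates(6, 8))
  expect_true(is.finite(cv_criterion(maps, ts6)))
  ts7 <- template_set(ortho_templates(7, 8))
  expect_error(cv_criterion(maps, ts7), "undefined")
})

test_that("CV selects the generating class count and GEV grows with q", {
  set.seed(38)
  gen <- ortho_templates(4, 19)
  idx <- sample(1:4, 400, TRUE)
  maps <- gen[idx, ] * runif(400, 0.5, 1.5) +
    matrix(rnorm(400 * 19, sd = 0.05), 400, 19)
  d <- select_cluster_number(maps, 2:8)
  expect_equal(d$selected_q, 4L)
  expect_true(all(diff(d$gev_by_q) >= -1e-9))
  # single generator: CV increases with q, smallest q wins
  maps1 <- gen[rep(1, 200), ] * runif(200, 0.5, 1.5) +
    matrix(rnorm(200 * 19, sd = 0.3), 200, 19)
  d1 <- select_cluster_number(maps1, 2:6)
  expect_equal(d1$selected_q, 2L)
  expect_true(all(diff(d1$cv_by_q) > 0))
})

test_that("canonical ordering recovers permutations and matches the 4! oracle", {
  chn <- montage_1020_19()
  ref <- eegmicrostates:::canonical_reference_maps(chn)
  ts <- template_set(ref, channel_names = chn)
  out <- canonical_order(ts)
  expect_equal(out$labels, paste0("MS", 1:4))
  expect_equal(out$maps, ts$maps, ignore_attr = TRUE)
  shuf <- c(3, 1, 4, 2)
  out2 <- canonical_order(template_set(ref[shuf, ], channel_names = chn))
  expect_equal(unname(abs(diag(out2$maps %*% t(ref)))), rep(1, 4), tolerance = 1e-9)

  set.seed(39)
  rnd <- matrix(rnorm(4 * 19), 4, 19)
  out3 <- canonical_order(template_set(rnd, channel_names = chn))
  # exhaustive search oracle over all 24 permutations
  sims <- abs(template_set(rnd)$maps %*% t(ref))
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  sc <- apply(perms, 1, function(p) sum(sims[cbind(p, 1:4)]))
  best <- perms[which.max(sc), ]
  expect_equal(unname(out3$maps),
               unname(template_set(rnd)$maps[best, ]))
})

test_that("canonical ordering warns and labels 'other' when q != 4", {
  ts <- template_set(ortho_templates(3, 19), channel_names = montage_1020_19())
  expect_warning(out <- canonical_order(ts), "q = 4")
  expect_equal(out$labels, rep("other", 3))
})

test_that("group templates pool subjects polarity-invariantly", {
  chn <- montage_1020_19()
  base <- default_templates()
  subj <- lapply(1:6, function(i)
    template_set(base * sample(c(-1, 1), 4, TRUE), channel_names = chn))
  grp <- group_templates(subj)
  expect_equal(unname(abs(diag(grp$maps %*% t(base)))), rep(1, 4), tolerance = 1e-9)

  set.seed(40)
  noisy <- lapply(1:10, function(i) {
    m <- base + matrix(rnorm(4 * 19, sd = 0.05), 4, 19)
    template_set(m[sample(4), ], channel_names = chn)
  })
  grp2 <- group_templates(noisy)
  sims <- abs(grp2$maps %*% t(base))
  expect_true(all(apply(sims, 1, max) >= 0.98))
  expect_equal(sort(unname(apply(sims, 1, which.max))), 1:4)

  other <- template_set(ortho_templates(4, 12))
  expect_error(group_templates(list(subj[[1]], other)), "montage")
})
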