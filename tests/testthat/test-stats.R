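test_that("MPATS scoring spans 16-80 and validates items", {
  expect_equal(score_mpats(rep(1, 16))$total, 16)
  expect_equal(score_mpats(rep(5, 16))$total, 80)
  sc <- score_mpats(rbind(rep(2, 16), rep(3, 16)))
  expect_equal(sc$total, c(32, 48))
  expect_equal(sc$withdrawal_symptoms, c(12, 18))   # 6 items
  expect_equal(sc$social_comfort, c(6, 9))          # 3 items
  expect_equal(sc$withdrawal_symptoms + sc$salience_behavior +
                 sc$social_comfort + sc$mood_changes, sc$total)
  expect_error(score_mpats(c(rep(3, 15), 6)), "1, 5")
  expect_error(score_mpats(rep(3, 15)), "16 items")
})

test_that("Cronbach's alpha matches the variance formula and its limits", {
  x <- cbind(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6), c(0, 1, 2, 3, 4))
  expect_equal(cronbach_alpha(x), 1, tolerance = 1e-12)   # parallel items
  m <- rbind(c(1, 2, 4, 2), c(3, 3, 5, 1), c(2, 5, 3, 4), c(4, 1, 2, 5),
             c(5, 4, 1, 3))
  item_var <- sum(apply(m, 2, var))
  tot_var <- var(rowSums(m))
  expect_equal(cronbach_alpha(m),
               4 / 3 * (1 - item_var / tot_var), tolerance = 1e-12)
  # invariant to adding a constant to any item
  m2 <- m; m2[, 2] <- m2[, 2] + 100
  expect_equal(cronbach_alpha(m2), cronbach_alpha(m), tolerance = 1e-12)
  # independent items: alpha near 0 at large n
  set.seed(51)
  ind <- matrix(rnorm(5000 * 4), 5000, 4)
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero variance")
})

test_that("normality gate passes normal data and transforms skewed data", {
  set.seed(52)
  g <- normality_gate(rnorm(335))
  expect_equal(g$status, "normal")
  expect_false(g$transformed)

  decisions <- replicate(40, {
    x <- exp(rnorm(335))   # lognormal, sigma = 1: heavily right-skewed
    normality_gate(x)$status
  })
  expect_gte(mean(decisions == "non_normal"), 0.95)

  post_ok <- replicate(40, {
    x <- exp(rnorm(335))
    shapiro.test(normality_gate(x)$values)$p.value > 0.05
  })
  expect_gte(mean(post_ok), 0.90)
  expect_error(normality_gate(rep(1, 20)), "constant")
  expect_error(normality_gate(rnorm(5)), "n >= 8")
})

test_that("mildly non-normal data passes through untransformed", {
  # exact Beta(2, 2) quantiles: Shapiro rejects at n = 335, but
  # |skew| = 0 and |excess kurtosis| = 6/7 < 1
  x <- qbeta(ppoints(335), 2, 2)
  g <- normality_gate(x)
  expect_equal(g$status, "approximately_normal")
  expect_false(g$transformed)
  expect_identical(g$values, x)
})

test_that("residualization matches the normal-equations oracle and is orthogonal", {
  set.seed(54)
  n <- 80
  cov <- data.frame(age = rnorm(n, 20, 2), sex = rbinom(n, 1, 0.5))
  y <- 2 + 0.5 * cov$age - 1.2 * cov$sex + rnorm(n)
  r <- residualize(y, cov)
  x <- cbind(1, cov$age, cov$sex)
  oracle <- y - x %*% solve(t(x) %*% x, t(x) %*% y)
  expect_equal(r, drop(oracle), tolerance = 1e-10)
  expect_lt(max(abs(t(x) %*% r)) / sum(abs(y)), 1e-8)
  expect_equal(residualize(2 * cov$age, cov), rep(0, n), tolerance = 1e-10)
  z <- rnorm(n)
  expect_equal(residualize(z, cov), z - mean(z), tolerance = 0.5)
  expect_error(residualize(y, cbind(cov$age, cov$age)), "rank")
})

test_that("pearson p-values agree with a permutation oracle", {
  set.seed(55)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  ct <- pearson_r_p(x, y)
  expect_equal(ct$r, cor(x, y), tolerance = 1e-12)
  nperm <- 20000
  robs <- abs(ct$r)
  hits <- sum(replicate(nperm, abs(cor(x, sample(y))) >= robs))
  p_perm <- (hits + 1) / (nperm + 1)
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(ct$p - p_perm), 4 * se + 0.005)
  expect_equal(pearson_r_p(x, x)$r, 1)
  expect_error(pearson_r_p(x, rep(1, 30)), "constant")
})

test_that("correlation is invariant to affine rescaling", {
  set.seed(56)
  x <- rnorm(50); y <- rnorm(50)
  a <- pearson_r_p(x, y)
  b <- pearson_r_p(3 * x - 7, 0.2 * y + 11)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("residualize-then-correlate equals the closed-form partial correlation", {
  set.seed(57)
  n <- 120
  age <- rnorm(n, 20, 2); sex <- rbinom(n, 1, 0.5)
  x <- 0.3 * age + rnorm(n)
  y <- -0.2 * age + 0.5 * sex + rnorm(n)
  cov <- data.frame(age = age, sex = sex)
  r_resid <- cor(residualize(x, cov), residualize(y, cov))
  # closed form via the precision matrix of (x, y, age, sex)
  S <- cor(cbind(x, y, age, sex))
  P <- solve(S)
  r_partial <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(r_resid, r_partial, tolerance = 1e-10)
})

test_that("the correlation table uses the Bonferroni threshold and finds a planted effect", {
  link <- data.frame(score = "total", parameter = "duration_MS1", r = 0.35)
  spec <- cohort_generator_spec(n = 335, linkage = link, seed = 58)
  coh <- generate_cohort(spec)$cohort
  tab <- correlation_table(coh)
  expect_equal(attr(tab, "threshold"), 0.0125)
  expect_equal(nrow(tab), 5 * 24)
  expect_true(all(abs(tab$r) <= 1))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  cell <- tab[tab$predictor == "total" & tab$outcome == "duration_MS1", ]
  expect_true(cell$significant)
  expect_gt(cell$r, 0.2)
  expect_identical(tab$significant, tab$p < 0.0125)
})

test_that("a planted r = 0.2 total-duration link is detected in most cohorts", {
  link <- data.frame(score = "total", parameter = "duration_MS1", r = 0.2)
  hits <- vapply(1:10, function(i) {
    coh <- generate_cohort(cohort_generator_spec(n = 335, linkage = link,
                                                 seed = 580 + i))$cohort
    tab <- correlation_table(coh)
    tab$significant[tab$predictor == "total" & tab$outcome == "duration_MS1"]
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("the correlation table refuses undersized cohorts", {
  coh <- generate_cohort(cohort_generator_spec(n = 8, seed = 59))$cohort
  expect_error(correlation_table(coh), "10")
})
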