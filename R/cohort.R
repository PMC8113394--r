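# Synthetic questionnaire cohort generator: latent factor model for the 16
# Likert items, thresholded to 1..5, with configurable linkage between scale
# scores and microstate parameters.

# Effective attenuation of inter-item correlation when the latent normals
# are discretized into 5 equal-probability categories. The first-order slope
# is ~0.93 (see estimate_likert_attenuation()); the constant used here was
# calibrated by simulating the full item-generation model at large n so that
# the population alphas of the discretized items hit their targets, which
# also absorbs the weak nonlinearity of the attenuation.
likert5_attenuation <- 0.897

#' Calibrate latent loadings for target scale reliabilities
#'
#' Closed-form calibration for a one-loading-per-subscale factor model with
#' equal-probability 5-category thresholds: target alpha -> required observed
#' inter-item correlation (`rho = alpha / (m - alpha (m - 1))`) -> latent
#' correlation via the discretization attenuation factor -> loading
#' `lambda = sqrt(rho_latent)`. The uniform inter-factor correlation is then
#' solved so the 16-item total scale hits its target alpha.
#'
#' @param target_alphas named numeric: the four subscale alphas.
#' @param target_total_alpha target alpha of the full 16-item scale.
#' @param subscale_map item partition (default [mpats_subscales()]).
#' @param attenuation discretization attenuation factor.
#' @return list with `loadings` (per subscale) and `factor_cor` (uniform
#'   inter-factor correlation).
#' @export
calibrate_cohort_loadings <- function(
    target_alphas = c(withdrawal_symptoms = 0.80, salience_behavior = 0.70,
                      social_comfort = 0.82, mood_changes = 0.40),
    target_total_alpha = 0.87,
    subscale_map = mpats_subscales(),
    attenuation = likert5_attenuation) {
  m <- lengths(subscale_map)
  stopifnot(identical(names(target_alphas), names(subscale_map)))
  rho_obs <- target_alphas / (m - target_alphas * (m - 1))
  rho_lat <- pmin(0.99, rho_obs / attenuation)
  lambda <- sqrt(rho_lat)
  # total-scale alpha constrains the mean between-subscale item correlation
  n_items <- sum(m)
  rbar <- target_total_alpha / (n_items - target_total_alpha * (n_items - 1))
  within_pairs <- sum(choose(m, 2))
  total_pairs <- choose(n_items, 2)
  between_sum_obs <- rbar * total_pairs - sum(choose(m, 2) * rho_obs)
  loading_sums <- lambda * m
  cross <- sum(tcrossprod(loading_sums)[upper.tri(diag(length(m)))])
  phi <- (between_sum_obs / attenuation) / cross
  if (phi <= 0 || phi >= 1)
    stop("target total alpha infeasible for these subscale alphas",
         call. = FALSE)
  list(loadings = stats::setNames(lambda, names(subscale_map)),
       factor_cor = phi)
}

#' Specification for the synthetic questionnaire cohort generator
#'
#' Latent-factor model for the 16 MPATS items: four correlated standard
#' normal factors, one loading per subscale, items discretized to Likert 1-5
#' by equal-probability thresholds. Default loadings and inter-factor
#' correlation are calibrated (see [calibrate_cohort_loadings()]) so the
#' population reliabilities match the study sample values (total 0.87,
#' subscales 0.80 / 0.70 / 0.82 / 0.40). Microstate parameters are drawn
#' with realistic marginals and optional trait linkage.
#'
#' @param n number of subjects.
#' @param loadings per-subscale latent loadings.
#' @param factor_cor uniform inter-factor correlation.
#' @param thresholds latent cut points for categories 1..5.
#' @param linkage data frame with columns `score`, `parameter`, `r`: target
#'   population correlations between a score and a microstate parameter.
#' @param age_mean,age_sd,age_range age distribution (years, rounded).
#' @param p_female probability of sex code 1.
#' @param seed optional integer seed.
#' @return list of class `cohort_generator_spec`.
#' @export
cohort_generator_spec <- function(n = 335L,
                                  loadings = NULL, factor_cor = NULL,
                                  thresholds = stats::qnorm(c(.2, .4, .6, .8)),
                                  linkage = NULL,
                                  age_mean = 20, age_sd = 1.4,
                                  age_range = c(17, 26), p_female = 0.5,
                                  seed = NULL) {
  if (is.null(loadings) || is.null(factor_cor)) {
    cal <- calibrate_cohort_loadings()
    if (is.null(loadings)) loadings <- cal$loadings
    if (is.null(factor_cor)) factor_cor <- cal$factor_cor
  }
  if (any(loadings <= 0) || any(loadings >= 1))
    stop("loadings must lie in (0, 1)", call. = FALSE)
  if (factor_cor < 0 || factor_cor >= 1)
    stop("factor_cor must lie in [0, 1)", call. = FALSE)
  if (!is.null(linkage)) {
    stopifnot(all(c("score", "parameter", "r") %in% names(linkage)),
              all(abs(linkage$r) < 1))
  }
  structure(list(n = as.integer(n), loadings = loadings,
                 factor_cor = factor_cor, thresholds = thresholds,
                 linkage = linkage, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, p_female = p_female, seed = seed),
            class = "cohort_generator_spec")
}

# realistic marginal means/sds for the 24 microstate parameter columns
ms_parameter_marginals <- function() {
  classes <- paste0("MS", 1:4)
  means <- c(stats::setNames(c(78, 72, 80, 85), paste0("duration_", classes)),
             stats::setNames(c(3.4, 3.2, 3.5, 3.0), paste0("occurrence_", classes)),
             stats::setNames(c(24, 23, 27, 26), paste0("coverage_", classes)))
  sds <- c(rep(8, 4), rep(0.45, 4), rep(4, 4))
  names(sds) <- names(means)
  trans <- grep("^t_", ms_parameter_names(), value = TRUE)
  means <- c(means, stats::setNames(rep(1 / 3, 12), trans))
  sds <- c(sds, stats::setNames(rep(0.05, 12), trans))
  list(mean = means, sd = sds)
}

#' Generate a synthetic questionnaire cohort with microstate parameters
#'
#' Draws `n` subjects: correlated latent factors, item responses discretized
#' to Likert 1-5, subscale and total scores, age and sex covariates, and the
#' 24 microstate parameter columns. A `linkage` entry (score, parameter, r)
#' makes that parameter load on the standardized observed score with
#' population correlation `r`; all other parameters are independent of the
#' scores.
#'
#' @param spec a [cohort_generator_spec()].
#' @return list with `cohort` (data frame: `item1..item16`, the five score
#'   columns, `age`, `sex`, 24 parameter columns) and `truth` (the spec plus
#'   the realized generating values).
#' @export
generate_cohort <- function(spec = cohort_generator_spec()) {
  stopifnot(inherits(spec, "cohort_generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  sub <- mpats_subscales()
  n_fac <- length(sub)
  phi <- matrix(spec$factor_cor, n_fac, n_fac); diag(phi) <- 1
  fac <- matrix(stats::rnorm(n * n_fac), n) %*% chol(phi)
  items <- matrix(0L, n, 16L)
  for (j in seq_len(n_fac)) {
    lam <- spec$loadings[j]
    for (i in sub[[j]]) {
      latent <- lam * fac[, j] + sqrt(1 - lam^2) * stats::rnorm(n)
      items[, i] <- 1L + findInterval(latent, spec$thresholds)
    }
  }
  colnames(items) <- paste0("item", 1:16)
  scores <- score_mpats(items, sub)
  marg <- ms_parameter_marginals()
  params <- sapply(names(marg$mean), function(p)
    marg$mean[p] + marg$sd[p] * stats::rnorm(n))
  colnames(params) <- names(marg$mean)
  if (!is.null(spec$linkage)) {
    for (row in seq_len(nrow(spec$linkage))) {
      sc <- spec$linkage$score[row]
      pm <- spec$linkage$parameter[row]
      r <- spec$linkage$r[row]
      z <- scale(scores[[sc]])[, 1L]
      params[, pm] <- marg$mean[pm] +
        marg$sd[pm] * (r * z + sqrt(1 - r^2) * stats::rnorm(n))
    }
  }
  age <- round(pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                         spec$age_range[1L]), spec$age_range[2L]))
  sex <- stats::rbinom(n, 1L, spec$p_female)
  cohort <- cbind(as.data.frame(items), scores, age = age, sex = sex,
                  as.data.frame(params))
  list(cohort = cohort,
       truth = list(spec = spec,
                    population_alpha_total = 0.87,
                    linkage = spec$linkage))
}

#' Estimate the 5-category Likert discretization attenuation factor
#'
#' Simulation routine behind the fixed constant used by
#' [calibrate_cohort_loadings()]: draws bivariate normal pairs over a grid of
#' latent correlations, discretizes both margins with the given thresholds,
#' and regresses observed on latent correlation through the origin.
#'
#' @param thresholds latent cut points.
#' @param n draws per grid point.
#' @param seed RNG seed.
#' @return estimated attenuation slope.
#' @export
estimate_likert_attenuation <- function(thresholds = stats::qnorm(c(.2, .4, .6, .8)),
                                        n = 2e5, seed = 1L) {
  set.seed(seed)
  grid <- seq(0.1, 0.9, by = 0.2)
  obs <- vapply(grid, function(rho) {
    u <- stats::rnorm(n)
    v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
    stats::cor(1L + findInterval(u, thresholds), 1L + findInterval(v, thresholds))
  }, 0)
  sum(obs * grid) / sum(grid^2)
}
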