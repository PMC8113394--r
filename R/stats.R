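#' Default MPATS subscale structure
#'
#' Fixed partition of the 16 Likert items into the scale's four factors:
#' withdrawal symptoms (6 items), salience behavior (4), social comfort (3)
#' and mood changes (3).
#'
#' @return named list of integer item indices.
#' @export
mpats_subscales <- function() {
  list(withdrawal_symptoms = 1:6,
       salience_behavior = 7:10,
       social_comfort = 11:13,
       mood_changes = 14:16)
}

#' Score MPATS responses
#'
#' Each subscale score is the sum of its items; the total is the sum of all
#' 16 items (range 16-80, higher = stronger addiction tendency).
#'
#' @param items numeric vector of 16 item responses in 1..5, or a subjects x
#'   16 matrix/data frame.
#' @param subscale_map partition of items into subscales
#'   (default [mpats_subscales()]).
#' @return A one-row (or n-row) data frame with the four subscale scores and
#'   `total`.
#' @export
score_mpats <- function(items, subscale_map = mpats_subscales()) {
  m <- if (is.null(dim(items))) matrix(items, nrow = 1L) else as.matrix(items)
  if (ncol(m) != length(unlist(subscale_map)))
    stop("expected ", length(unlist(subscale_map)), " items, got ", ncol(m),
         call. = FALSE)
  idx <- sort(unlist(subscale_map))
  if (!identical(unname(idx), seq_len(ncol(m))))
    stop("subscale_map must partition the items exactly once each",
         call. = FALSE)
  if (anyNA(m) || any(m < 1) || any(m > 5))
    stop("item responses must lie in [1, 5]", call. = FALSE)
  out <- as.data.frame(lapply(subscale_map, function(ii)
    rowSums(m[, ii, drop = FALSE])))
  out$total <- rowSums(m)
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = m/(m-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param item_matrix subjects x items numeric matrix (>= 3 subjects,
#'   >= 2 items).
#' @return alpha coefficient (<= 1).
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  m <- ncol(x)
  if (m < 2L) stop("need at least 2 items", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 subjects", call. = FALSE)
  vt <- stats::var(rowSums(x))
  if (vt < 1e-300) stop("total score has zero variance", call. = FALSE)
  m / (m - 1) * (1 - sum(apply(x, 2L, stats::var)) / vt)
}

sample_skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / (mean(x^2))^1.5
}

sample_excess_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / (mean(x^2))^2 - 3
}

#' Rank-based inverse-normal transform
#' @param x numeric vector.
#' @return Blom-scored normal quantiles of the ranks of `x`.
#' @export
inverse_normal_transform <- function(x) {
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

#' Normality gate for a per-subject variable
#'
#' Shapiro-Wilk p > 0.05 passes as `"normal"`. Otherwise, if both |skewness|
#' and |excess kurtosis| are below 1, the distribution is treated as
#' `"approximately_normal"` and left untransformed; else it is `"non_normal"`
#' and a rank-based inverse-normal transform is applied before correlation.
#'
#' @param values numeric vector, n >= 8, non-constant.
#' @return list with `status`, `values` (possibly transformed),
#'   `transformed` flag, `shapiro_p`, `skewness`, `kurtosis`.
#' @export
normality_gate <- function(values) {
  if (length(values) < 8L) stop("need n >= 8", call. = FALSE)
  if (stats::sd(values) < 1e-300) stop("constant vector", call. = FALSE)
  p <- stats::shapiro.test(values)$p.value
  sk <- sample_skewness(values)
  ku <- sample_excess_kurtosis(values)
  if (p > 0.05) {
    status <- "normal"; out <- values; tr <- FALSE
  } else if (abs(sk) < 1 && abs(ku) < 1) {
    status <- "approximately_normal"; out <- values; tr <- FALSE
  } else {
    status <- "non_normal"; out <- inverse_normal_transform(values); tr <- TRUE
  }
  list(status = status, values = out, transformed = tr, shapiro_p = p,
       skewness = sk, kurtosis = ku)
}

#' Residualize a variable on age and sex
#'
#' Ordinary least-squares residuals of `values` on an intercept plus the
#' covariate columns; the residuals are orthogonal to the covariates, so
#' correlating two residualized variables equals their partial correlation
#' given the covariates.
#'
#' @param values numeric outcome vector.
#' @param covariates data frame or matrix of covariates (e.g. age and 0/1
#'   sex), full column rank.
#' @return numeric residual vector.
#' @export
residualize <- function(values, covariates) {
  x <- cbind(1, as.matrix(covariates))
  if (nrow(x) != length(values))
    stop("covariate rows do not match values length", call. = FALSE)
  if (qr(x)$rank < ncol(x)) stop("covariate matrix is rank deficient",
                                 call. = FALSE)
  if (length(values) <= ncol(x)) stop("too few observations", call. = FALSE)
  fit <- stats::lm.fit(x, values)
  unname(fit$residuals)
}

#' Pearson correlation with exact t-based p-value
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred two-sided to a
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r_p <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300)
    stop("constant input", call. = FALSE)
  r <- stats::cor(x, y)
  list(r = r, p = r_to_p(r, n), n = n)
}

# two-sided p for a Pearson r at sample size n
r_to_p <- function(r, n) {
  r <- min(1 - 1e-16, max(-1 + 1e-16, r))
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Covariate-adjusted correlation table of trait scores vs microstate metrics
#'
#' For every pair of an MPATS score (four subscales + total) and a
#' microstate parameter (duration, occurrence, coverage for each class, plus
#' the 12 ordered transition probabilities), both variables are residualized
#' on age and sex, passed through the [normality_gate()], and correlated with
#' [pearson_r_p()]. Cells are flagged `significant` at the Bonferroni
#' threshold `alpha_family / n_comparisons` (default 0.05 / 4 = 0.0125) and
#' `significant_01` at the study-wise 0.01 level.
#'
#' @param cohort a data frame with columns `age`, `sex`, the five score
#'   columns (`withdrawal_symptoms`, `salience_behavior`, `social_comfort`,
#'   `mood_changes`, `total`) and microstate parameter columns
#'   (`duration_MS1..4`, `occurrence_MS1..4`, `coverage_MS1..4`,
#'   `t_MS1_MS2..t_MS4_MS3`), one row per subject. Rows with any missing
#'   value are dropped (complete-case) and counted.
#' @param alpha_family family-wise significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 4, the four classes).
#' @return data frame of class `ms_correlations`: one row per (score,
#'   parameter) pair with `r`, `p`, `n`, `adjusted_for`, `significant`,
#'   `significant_01`; attributes `threshold`, `n_dropped`,
#'   `gate_status` (per-variable normality decisions).
#' @export
correlation_table <- function(cohort, alpha_family = 0.05, n_comparisons = 4) {
  scores <- c("withdrawal_symptoms", "salience_behavior", "social_comfort",
              "mood_changes", "total")
  params <- ms_parameter_names()
  need <- c("age", "sex", scores, intersect(params, names(cohort)))
  params <- intersect(params, names(cohort))
  if (length(params) == 0L) stop("no microstate parameter columns found",
                                 call. = FALSE)
  miss <- setdiff(c("age", "sex", scores), names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  cc <- stats::complete.cases(cohort[need])
  n_dropped <- sum(!cc)
  dat <- cohort[cc, need, drop = FALSE]
  if (nrow(dat) < 10L) stop("fewer than 10 complete cases", call. = FALSE)
  covars <- dat[c("age", "sex")]
  threshold <- alpha_family / n_comparisons

  vars <- c(scores, params)
  gate_status <- character(length(vars)); names(gate_status) <- vars
  adj <- list()
  for (v in vars) {
    res <- residualize(dat[[v]], covars)
    if (stats::sd(res) < 1e-12) {
      gate_status[v] <- "constant"; adj[[v]] <- NULL; next
    }
    g <- normality_gate(res)
    gate_status[v] <- g$status
    adj[[v]] <- g$values
  }
  rows <- list()
  for (s in scores) for (p in params) {
    if (is.null(adj[[s]]) || is.null(adj[[p]])) next
    ct <- pearson_r_p(adj[[s]], adj[[p]])
    rows[[length(rows) + 1L]] <- data.frame(
      predictor = s, outcome = p, r = ct$r, p = ct$p, n = ct$n,
      adjusted_for = "age+sex",
      significant = ct$p < threshold,
      significant_01 = ct$p <= 0.01,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ms_correlations", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "n_dropped") <- n_dropped
  attr(out, "gate_status") <- gate_status
  out
}

# canonical ordering of the 24 microstate parameter columns
ms_parameter_names <- function(classes = paste0("MS", 1:4)) {
  trans <- c()
  for (i in classes) for (j in classes) if (i != j)
    trans <- c(trans, paste0("t_", i, "_", j))
  c(paste0("duration_", classes), paste0("occurrence_", classes),
    paste0("coverage_", classes), trans)
}

#' @export
print.ms_correlations <- function(x, ...) {
  cat(sprintf("<ms_correlations> %d pairs, n = %d, Bonferroni threshold %.4g\n",
              nrow(x), x$n[1L], attr(x, "threshold")))
  sig <- x[x$significant, c("predictor", "outcome", "r", "p")]
  if (nrow(sig)) {
    cat("significant cells:\n")
    sig$r <- round(sig$r, 3); sig$p <- signif(sig$p, 3)
    print(sig, row.names = FALSE)
  } else cat("no significant cells\n")
  invisible(x)
}
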