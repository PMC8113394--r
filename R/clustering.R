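#' Set of microstate template maps
#'
#' @param maps q x K matrix; each row is centered (average-referenced) and
#'   unit L2 normalized on construction.
#' @param labels canonical class label per row (`"MS1".."MS4"` or `"other"`).
#' @param gev global explained variance fraction achieved by this set on the
#'   maps it was fitted to.
#' @param assignment optional integer vector assigning each fitted map to a
#'   template row.
#' @param channel_names channel names of the montage.
#' @return An object of class `template_set`.
#' @export
template_set <- function(maps, labels = NULL, gev = NA_real_,
                         assignment = NULL, channel_names = NULL) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < 1e-12)) stop("template row with zero norm", call. = FALSE)
  maps <- maps / nrm
  if (is.null(labels)) labels <- rep("other", nrow(maps))
  rownames(maps) <- labels
  structure(list(maps = maps, labels = labels, q = nrow(maps), gev = gev,
                 assignment = assignment, channel_names = channel_names),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> q = %d maps x %d channels [%s]%s\n",
              x$q, ncol(x$maps), paste(x$labels, collapse = ", "),
              if (is.na(x$gev)) "" else sprintf(", GEV = %.3f", x$gev)))
  invisible(x)
}

#' Polarity-invariant spatial similarity of two topographies
#'
#' The spatial Pearson correlation of two average-referenced maps across
#' channels; with `polarity_invariant = TRUE` (the microstate convention) its
#' absolute value. Global map dissimilarity follows as
#' `GMD = sqrt(2 * (1 - similarity))`.
#'
#' @param u,v numeric vectors (same length, K >= 2), average-referenced maps.
#' @param polarity_invariant disregard map polarity.
#' @return similarity in `[0, 1]` (invariant) or `[-1, 1]`.
#' @export
spatial_similarity <- function(u, v, polarity_invariant = TRUE) {
  stopifnot(length(u) == length(v), length(u) >= 2L)
  u <- u - mean(u); v <- v - mean(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-300 || nv < 1e-300)
    stop("similarity undefined for a zero-GFP map", call. = FALSE)
  r <- sum(u * v) / (nu * nv)
  r <- max(-1, min(1, r))
  if (polarity_invariant) abs(r) else r
}

#' Global map dissimilarity
#' @inheritParams spatial_similarity
#' @return GMD in `[0, 2]` (polarity-sensitive) or `[0, sqrt(2)]` when
#'   polarity is disregarded.
#' @export
gmd <- function(u, v, polarity_invariant = FALSE) {
  sqrt(2 * (1 - spatial_similarity(u, v, polarity_invariant)))
}

# Center map rows, compute per-map GFP and unit-normalized rows.
# maps: n x K, rows are topographies.
prep_maps <- function(maps) {
  maps <- as.matrix(maps)
  k <- ncol(maps)
  if (k < 3L) stop("need at least 3 channels", call. = FALSE)
  vc <- maps - rowMeans(maps)
  ss <- rowSums(vc^2)
  if (any(ss < 1e-300)) stop("zero-GFP map(s) in clustering input", call. = FALSE)
  list(vc = vc, gfp = sqrt(ss / k), vhat = vc / sqrt(ss), k = k, n = nrow(maps))
}

# Core AAHC pass: singleton initialization, repeated atomization of the
# cluster contributing least GEV, polarity-invariant reassignment of its
# members, centroids as the dominant eigenvector of the members'
# outer-product sum. Records a snapshot at every cluster count in `record_q`.
aahc_run <- function(maps, q_final, record_q = integer(0), channel_names = NULL) {
  p <- prep_maps(maps)
  n <- p$n; k <- p$k
  if (q_final < 1L || q_final > n)
    stop("q_target must lie in [1, number of maps] (got ", q_final,
         " for ", n, " maps)", call. = FALSE)
  record_q <- sort(unique(as.integer(record_q)), decreasing = TRUE)
  cl_assign <- seq_len(n)
  cent <- p$vhat                      # row per cluster id
  # outer products of the raw centered maps: centroids are GFP-weighted,
  # so low-amplitude (noise-dominated) members barely steer a cluster
  S <- lapply(seq_len(n), function(i) tcrossprod(p$vc[i, ]))
  a2 <- p$gfp^2                       # (gfp * |corr|)^2, corr = 1 for singletons
  contrib <- a2
  active <- rep(TRUE, n)
  denom <- sum(p$gfp^2)
  snapshots <- list()

  take_snapshot <- function(nc) {
    ids <- which(active)
    remap <- integer(n); remap[ids] <- seq_along(ids)
    template_set(cent[ids, , drop = FALSE],
                 gev = sum(a2) / denom,
                 assignment = remap[cl_assign],
                 channel_names = channel_names)
  }

  nc <- n
  repeat {
    if (length(record_q) && nc == record_q[1L]) {
      snapshots[[as.character(nc)]] <- take_snapshot(nc)
      record_q <- record_q[-1L]
    }
    if (nc <= q_final) break
    ids <- which(active)
    worst <- ids[which.min(contrib[ids])]
    members <- which(cl_assign == worst)
    active[worst] <- FALSE
    rem <- which(active)
    sims <- abs(p$vhat[members, , drop = FALSE] %*% t(cent[rem, , drop = FALSE]))
    new_cl <- rem[max.col(sims, ties.method = "first")]
    cl_assign[members] <- new_cl
    for (d in unique(new_cl)) {
      gained <- members[new_cl == d]
      S[[d]] <- S[[d]] + crossprod(p$vc[gained, , drop = FALSE])
      eg <- eigen(S[[d]], symmetric = TRUE)
      cent[d, ] <- eg$vectors[, 1L]
      mem_d <- which(cl_assign == d)
      cr <- drop(p$vhat[mem_d, , drop = FALSE] %*% cent[d, ])
      a2[mem_d] <- p$gfp[mem_d]^2 * cr^2
      contrib[d] <- sum(a2[mem_d])
    }
    nc <- nc - 1L
  }
  list(final = take_snapshot(nc), snapshots = snapshots)
}

#' Atomize-Agglomerate Hierarchical Clustering of topographies
#'
#' Bottom-up clustering of (GFP-peak) maps: every map starts as its own
#' cluster; the cluster contributing least global explained variance is
#' repeatedly dissolved ("atomized") and each of its members reassigned to
#' the remaining cluster of highest polarity-invariant spatial correlation,
#' until `q_target` clusters remain. Cluster centroids are the dominant
#' eigenvector of the members' outer-product sum, which handles polarity
#' invariance exactly.
#'
#' @param peak_maps n x K matrix, one topography per row (typically the maps
#'   at GFP peaks).
#' @param q_target number of clusters to keep (1 <= q_target <= n).
#' @param channel_names optional montage names stored on the result.
#' @return A [template_set()] with `gev` and per-map `assignment` filled.
#' @export
aahc <- function(peak_maps, q_target, channel_names = NULL) {
  aahc_run(peak_maps, q_final = q_target, channel_names = channel_names)$final
}

#' Global explained variance of labeled maps under a template set
#'
#' `GEV = sum_t (GFP_t * corr(v_t, T_L(t)))^2 / sum_t GFP_t^2`: the
#' GFP-weighted fraction of topographic variance captured by assigning each
#' map to its template. Invariant to sign flips of any map or template.
#'
#' @param maps n x K matrix of topographies (rows).
#' @param templates a [template_set()].
#' @param assignment integer vector assigning each map to a template row;
#'   defaults to the template set's stored assignment, else best match.
#' @return GEV fraction in `[0, 1]`.
#' @export
gev <- function(maps, templates, assignment = NULL) {
  maps <- as.matrix(maps)
  if (nrow(maps) == 0L) stop("empty map set", call. = FALSE)
  p <- prep_maps(maps)
  if (is.null(assignment)) assignment <- templates$assignment
  if (is.null(assignment))
    assignment <- max.col(abs(p$vhat %*% t(templates$maps)),
                          ties.method = "first")
  stopifnot(length(assignment) == nrow(maps))
  cr <- rowSums(p$vhat * templates$maps[assignment, , drop = FALSE])
  sum(p$gfp^2 * cr^2) / sum(p$gfp^2)
}

#' Cross-validation criterion for the number of microstate classes
#'
#' Predictive residual variance of the maps about their assigned templates,
#' inflated by a degrees-of-freedom penalty:
#' `CV = sigma2_hat * ((K - 1) / (K - 1 - q))^2`, with
#' `sigma2_hat = sum_t (v_t'v_t - (v_t'T_L(t))^2) / (n (K - 1))`.
#' Smaller is better; requires `q <= K - 2`.
#'
#' @inheritParams gev
#' @return positive scalar CV value.
#' @export
cv_criterion <- function(maps, templates, assignment = NULL) {
  maps <- as.matrix(maps)
  p <- prep_maps(maps)
  q <- templates$q; k <- p$k
  if (q > k - 2L)
    stop("CV penalty undefined for q >= K - 1 (q = ", q, ", K = ", k, ")",
         call. = FALSE)
  if (is.null(assignment)) assignment <- templates$assignment
  if (is.null(assignment))
    assignment <- max.col(abs(p$vhat %*% t(templates$maps)),
                          ties.method = "first")
  proj <- rowSums(p$vc * templates$maps[assignment, , drop = FALSE])
  sigma2 <- sum(rowSums(p$vc^2) - proj^2) / (p$n * (k - 1))
  sigma2 * ((k - 1) / (k - 1 - q))^2
}

#' Select the number of microstate classes by cross-validation
#'
#' Runs a single AAHC pass, snapshots the solution at every `q` in
#' `q_range`, and selects the `q` minimizing the CV criterion (ties broken
#' toward smaller `q`, i.e. parsimony).
#'
#' @param peak_maps n x K matrix of topographies (rows).
#' @param q_range integer candidate range, within `[2, K - 2]`.
#' @param channel_names optional montage names.
#' @return An object of class `cluster_diagnostics`: `cv_by_q`, `gev_by_q`,
#'   `selected_q`, and `templates` (the selected [template_set()]).
#' @export
select_cluster_number <- function(peak_maps, q_range = 2:8,
                                  channel_names = NULL) {
  q_range <- sort(unique(as.integer(q_range)))
  if (length(q_range) == 0L) stop("empty q_range", call. = FALSE)
  k <- ncol(as.matrix(peak_maps))
  if (min(q_range) < 2L || max(q_range) > k - 2L)
    stop("q_range must lie within [2, K - 2]", call. = FALSE)
  run <- aahc_run(peak_maps, q_final = min(q_range), record_q = q_range,
                  channel_names = channel_names)
  qs <- as.integer(names(run$snapshots))
  cv <- vapply(run$snapshots, function(ts)
    cv_criterion(peak_maps, ts), 0)
  gv <- vapply(run$snapshots, function(ts) ts$gev, 0)
  ord <- order(qs)
  qs <- qs[ord]; cv <- cv[ord]; gv <- gv[ord]
  names(cv) <- names(gv) <- qs
  sel <- qs[which.min(cv)]  # which.min returns the first (smallest q) on ties
  structure(list(cv_by_q = cv, gev_by_q = gv, selected_q = sel,
                 templates = run$snapshots[[as.character(sel)]]),
            class = "cluster_diagnostics")
}

#' @export
print.cluster_diagnostics <- function(x, ...) {
  cat("<cluster_diagnostics>\n")
  tab <- rbind(CV = x$cv_by_q, GEV = x$gev_by_q)
  print(signif(tab, 4))
  cat("selected q =", x$selected_q, "\n")
  invisible(x)
}

#' Assign canonical MS1-MS4 labels to a four-template set
#'
#' Matches the templates to built-in idealized normative topographies
#' (classes A/B/C/D of the microstate literature, here MS1-MS4) by the
#' one-to-one assignment over all 24 permutations that maximizes total
#' polarity-invariant similarity, then reorders the rows canonically.
#'
#' @param templates a [template_set()] with `q = 4`.
#' @param channel_names montage names (default: the set's stored names).
#' @param positions optional explicit electrode positions.
#' @return The relabeled, reordered template set. If `q != 4` the set is
#'   returned with labels `"other"` and a warning.
#' @export
canonical_order <- function(templates, channel_names = NULL, positions = NULL) {
  stopifnot(inherits(templates, "template_set"))
  if (templates$q != 4L) {
    warning("canonical MS1-MS4 labeling needs q = 4; labels set to 'other'")
    templates$labels <- rep("other", templates$q)
    rownames(templates$maps) <- templates$labels
    return(templates)
  }
  if (is.null(channel_names) && is.null(positions))
    channel_names <- templates$channel_names
  ref <- canonical_reference_maps(channel_names, positions)
  sim <- abs(templates$maps %*% t(ref))   # rows: templates, cols: MS1..4
  perms <- permutations_of(4L)
  scores <- vapply(seq_len(nrow(perms)), function(i)
    sum(sim[cbind(perms[i, ], 1:4)]), 0)
  best <- perms[which.max(scores), ]      # best[j] = template row for class j
  out <- templates
  out$maps <- templates$maps[best, , drop = FALSE]
  out$labels <- paste0("MS", 1:4)
  rownames(out$maps) <- out$labels
  if (!is.null(templates$assignment))
    out$assignment <- match(templates$assignment, best)
  out
}

# all permutations of 1..n (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- (1:n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Group-level template maps from per-subject template sets
#'
#' Second-level AAHC over the pooled subject templates, down to `q` group
#' maps (polarity-invariant, so sign-flipped subject maps pool correctly);
#' group maps are canonically MS1-MS4 ordered when `q = 4` and the montage
#' has stored positions.
#'
#' @param subject_templates list of [template_set()] objects sharing montage
#'   and `q`.
#' @param q number of group maps (default: the subjects' `q`).
#' @return A [template_set()] of group maps.
#' @export
group_templates <- function(subject_templates, q = NULL) {
  stopifnot(length(subject_templates) >= 1L)
  kset <- vapply(subject_templates, function(ts) ncol(ts$maps), 0L)
  if (length(unique(kset)) != 1L)
    stop("subjects have mismatched montages", call. = FALSE)
  chn <- subject_templates[[1L]]$channel_names
  for (ts in subject_templates) {
    if (!identical(ts$channel_names, chn))
      stop("subjects have mismatched montages", call. = FALSE)
  }
  if (is.null(q)) q <- subject_templates[[1L]]$q
  pooled <- do.call(rbind, lapply(subject_templates, function(ts) ts$maps))
  out <- aahc(pooled, q_target = q, channel_names = chn)
  if (q == 4L && !is.null(chn) &&
      all(chn %in% rownames(ten_twenty_positions)))
    out <- canonical_order(out, channel_names = chn)
  out
}
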