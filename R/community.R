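#' @title Community composition: dissimilarity, PERMANOVA, ordination,
#'   similarity networks
#' @description Pairwise Bray-Curtis dissimilarities among trap samples,
#'   a permutation test for group differences computed directly from the
#'   dissimilarity matrix, a low-dimensional embedding for visualisation,
#'   and the threshold-linked network of samples with similar sinking-cell
#'   communities.
#' @name community
NULL

#' Bray-Curtis dissimilarity between two flux vectors
#'
#' `sum(|x - y|) / sum(x + y)` over taxa: 0 for identical communities,
#' 1 for communities with no shared taxa. Fluxes enter untransformed by
#' default; callers wanting relative abundance or fourth-root transforms
#' apply them before calling (see [community_dissimilarity]).
#'
#' @param x,y Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("fluxes must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero communities")
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param M Samples x taxa matrix of non-negative fluxes with rownames;
#'   at least 2 samples and 2 taxa.
#' @param transform `"none"` (default, absolute fluxes), `"relative"`
#'   (rows scaled to sum 1), or `"fourth_root"`.
#' @return A symmetric matrix with zero diagonal and entries in \[0, 1\].
#' @export
community_dissimilarity <- function(M, transform = c("none", "relative", "fourth_root")) {
  transform <- match.arg(transform)
  M <- as.matrix(M)
  if (nrow(M) < 2 || ncol(M) < 2) stop("need at least 2 samples and 2 taxa")
  if (any(M < 0)) stop("fluxes must be non-negative")
  M <- switch(transform,
              none = M,
              relative = sweep(M, 1, rowSums(M), "/"),
              fourth_root = M^0.25)
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- bray_curtis(M[i, ], M[j, ])
    }
  }
  D
}

#' PERMANOVA pseudo-F and permutation p-value from a dissimilarity matrix
#'
#' One-way permutational multivariate analysis of variance computed
#' directly from squared dissimilarities (Anderson's partition):
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` sums the analogous
#' quantity within each group, and
#' `F = (SS_among / (a - 1)) / (SS_within / (n - a))`. Significance is
#' assessed by freely permuting the sample labels;
#' `p = (1 + #permutations with F* >= F_obs) / (1 + n_perm)`. With
#' `strata`, permutations are restricted within blocks (e.g. depth).
#'
#' @param D Square symmetric dissimilarity matrix, zero diagonal.
#' @param groups Group label per sample; >= 2 groups of >= 2 samples.
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param strata Optional blocking factor restricting permutations.
#' @return List with `pseudo_F`, `p_value`, `n_perm`, and the sums of
#'   squares `ss_among`, `ss_within`, `ss_total`.
#' @export
permanova <- function(D, groups, n_perm = 9999L, seed = 1L, strata = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(droplevels(groups)) < 2)) {
    stop("every group must contain at least 2 samples")
  }
  if (n_perm < 99) stop("n_perm must be at least 99")
  obs <- permanova_stat(D, groups)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- permute_labels(n, strata)
    Fb <- permanova_stat(D, groups[perm])$pseudo_F
    if (Fb >= obs$pseudo_F) ge <- ge + 1L
  }
  list(pseudo_F = obs$pseudo_F,
       p_value = (1 + ge) / (1 + n_perm),
       n_perm = as.integer(n_perm),
       ss_among = obs$ss_among, ss_within = obs$ss_within,
       ss_total = obs$ss_total)
}

# Anderson-style partition of squared dissimilarities.
permanova_stat <- function(D, groups) {
  n <- nrow(D)
  groups <- droplevels(as.factor(groups))
  a <- nlevels(groups)
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- D2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  denom <- ss_within / (n - a)
  pseudo_F <- if (denom <= .Machine$double.eps) {
    if (ss_among <= .Machine$double.eps) 0 else Inf
  } else {
    (ss_among / (a - 1)) / denom
  }
  list(pseudo_F = pseudo_F, ss_among = ss_among,
       ss_within = ss_within, ss_total = ss_total)
}

# Random permutation of 1:n, optionally within strata blocks.
permute_labels <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  strata <- as.factor(strata)
  perm <- seq_len(n)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' Exhaustive-permutation PERMANOVA p-value
#'
#' Enumerates all `n!` label orderings; practical only for tiny n and used
#' as an exact reference for the Monte-Carlo p-value.
#'
#' @inheritParams permanova
#' @return The exact permutation p-value
#'   `#\{orderings with F* >= F_obs\} / n!`.
#' @export
permanova_exact_p <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  groups <- as.factor(groups)
  obs <- permanova_stat(D, groups)$pseudo_F
  perms <- all_permutations(n)
  ge <- 0L
  for (k in seq_len(nrow(perms))) {
    Fb <- permanova_stat(D, groups[perms[k, ]])$pseudo_F
    if (Fb >= obs) ge <- ge + 1L
  }
  ge / nrow(perms)
}

# All permutations of 1:n as rows (n! x n), in lexicographic order.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (k in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(first, rest[sub[k, ]])
    }
  }
  out
}

#' Two-dimensional embedding of a dissimilarity matrix
#'
#' Metric multidimensional scaling by eigendecomposition (classical
#' scaling) followed by an optional nonmetric stress-minimising
#' refinement (Kruskal's method). Used for visualisation only.
#'
#' @param D Square symmetric dissimilarity matrix, n >= 3.
#' @param dims Embedding dimension (default 2).
#' @param refine Run the nonmetric refinement pass (default TRUE); falls
#'   back to the metric solution when the configuration is degenerate.
#' @return List with `points` (n x dims coordinate matrix) and `stress`
#'   (Kruskal stress-1, percent).
#' @export
mds_embed <- function(D, dims = 2L, refine = TRUE) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("embedding needs at least 3 samples")
  pts <- stats::cmdscale(D, k = dims)
  if (ncol(pts) < dims) {  # degenerate: pad with zeros
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  }
  stress <- kruskal_stress(D, pts)
  if (refine && all(D[upper.tri(D)] > 0)) {
    ref <- try(suppressWarnings(
      MASS::isoMDS(D, y = pts, k = dims, trace = FALSE)), silent = TRUE)
    if (!inherits(ref, "try-error") && is.finite(ref$stress)) {
      pts <- ref$points
      stress <- ref$stress
    }
  }
  rownames(pts) <- rownames(D)
  list(points = pts, stress = stress)
}

# Kruskal stress-1 (percent) of a configuration against target distances.
kruskal_stress <- function(D, pts) {
  d_emb <- as.matrix(stats::dist(pts))
  num <- sum((D[upper.tri(D)] - d_emb[upper.tri(d_emb)])^2)
  den <- sum(d_emb[upper.tri(d_emb)]^2)
  if (den == 0) return(0)
  100 * sqrt(num / den)
}

#' Threshold-linked community similarity network
#'
#' Links every pair of samples whose Bray-Curtis dissimilarity is
#' strictly below the threshold, then partitions samples into connected
#' components (sample clusters). Samples linking to no other sample form
#' singleton clusters. Cluster labels are deterministic: components are
#' numbered by their earliest deployment, then shallowest depth, of any
#' member (falling back to row order when metadata is absent).
#'
#' @param D Square symmetric dissimilarity matrix with sample rownames.
#' @param threshold Edge rule `D < threshold`, strict; in (0, 1\];
#'   default 0.25.
#' @param meta Optional data.frame with one row per sample (same order as
#'   `D`) containing `deployment` and `depth_m` columns used to order
#'   cluster labels.
#' @return List of class `community_network` with `edges` (data.frame
#'   `from`, `to`, `dissimilarity`), `membership` (integer cluster id per
#'   sample), `n_clusters`, and `threshold`.
#' @export
build_similarity_network <- function(D, threshold = 0.25, meta = NULL) {
  D <- as.matrix(D)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  n <- nrow(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  ut <- which(upper.tri(D) & D < threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[ut[, 1]], to = ids[ut[, 2]],
                      dissimilarity = D[ut], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- as.integer(igraph::components(g)$membership[ids])
  # deterministic relabelling: order components by earliest deployment,
  # then shallowest depth, of any member
  comp_ids <- sort(unique(comp))
  if (!is.null(meta) && all(c("deployment", "depth_m") %in% names(meta))) {
    key_dep <- vapply(comp_ids, function(k) min(meta$deployment[comp == k]), numeric(1))
    key_dz <- vapply(comp_ids, function(k) min(meta$depth_m[comp == k]), numeric(1))
    ord <- comp_ids[order(key_dep, key_dz, comp_ids)]
  } else {
    first_row <- vapply(comp_ids, function(k) min(which(comp == k)), integer(1))
    ord <- comp_ids[order(first_row)]
  }
  membership <- match(comp, ord)
  names(membership) <- ids
  structure(list(edges = edges, membership = membership,
                 n_clusters = length(unique(membership)),
                 threshold = threshold),
            class = "community_network")
}

#' @export
print.community_network <- function(x, ...) {
  cat(sprintf("<community_network> %d samples, %d edges, %d clusters (threshold %g)\n",
              length(x$membership), nrow(x$edges), x$n_clusters, x$threshold))
  invisible(x)
}

#' Mean relative composition per network cluster
#'
#' For each cluster of the similarity network, averages the relative
#' (row-normalised) taxon composition of its member samples. Taxa whose
#' mean share falls below `display_min` are pooled into an `"other"`
#' column; compositions sum to 1 per cluster.
#'
#' @param net A `community_network` from [build_similarity_network].
#' @param M Samples x taxa flux matrix (rownames matching the network).
#' @param display_min Minimum mean share for a taxon to be reported on
#'   its own (default 0.05); 0 disables pooling.
#' @return Matrix clusters x taxa (plus `"other"` when pooling occurs),
#'   rows summing to 1.
#' @export
network_cluster_composition <- function(net, M, display_min = 0.05) {
  stopifnot(inherits(net, "community_network"))
  M <- as.matrix(M)
  M <- M[names(net$membership), , drop = FALSE]
  rel <- sweep(M, 1, rowSums(M), "/")
  clusters <- sort(unique(net$membership))
  comp <- t(vapply(clusters, function(k) {
    colMeans(rel[net$membership == k, , drop = FALSE])
  }, numeric(ncol(M))))
  rownames(comp) <- paste0("cluster_", clusters)
  colnames(comp) <- colnames(M)
  if (display_min > 0) {
    minor <- colMeans(comp) < display_min & apply(comp, 2, max) < display_min
    if (any(minor)) {
      other <- rowSums(comp[, minor, drop = FALSE])
      comp <- cbind(comp[, !minor, drop = FALSE], other = other)
    }
  }
  comp
}
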