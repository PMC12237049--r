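#' @title Covariation of flux classes: rank correlation and PCA
#' @description Relates solitary-cell POC fluxes to detrital
#'   particle-class POC fluxes (aggregates, long fecal pellets, short
#'   ovoid pellets, salp pellets, large particles) via Spearman rank
#'   correlation with permutation p-values, and summarises covariability
#'   with a principal component analysis of min-max normalised fluxes.
#' @name covariation
NULL

#' Min-max normalisation of a flux variable to \[0, 1\]
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_normalize <- function(x) {
  if (anyNA(x)) stop("missing values not allowed")
  rng <- range(x)
  if (rng[2] <= rng[1]) stop("constant column cannot be min-max normalised")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' PCA loadings of flux variables on the first two components
#'
#' Each column of the flux feature table is min-max normalised to
#' \[0, 1\], then the covariance matrix of the normalised columns is
#' eigendecomposed. Loadings are unit-norm eigenvectors with a
#' deterministic sign convention: the largest-magnitude element of each
#' loading is positive. Constant columns are dropped with a warning. When
#' fewer than two eigenvalues are positive, only one component is
#' reported.
#'
#' @param X Samples x variables numeric matrix or data.frame
#'   (>= 3 samples, >= 2 variables), non-negative fluxes.
#' @param use_correlation Use the correlation rather than covariance
#'   matrix of the normalised columns (default FALSE).
#' @return List with `loadings` (variables x components), `eigenvalues`,
#'   `explained_variance` (shares summing to 1 over all components),
#'   `scores` (samples x components), and `n_components` (1 or 2).
#' @export
pca_first_two_loadings <- function(X, use_correlation = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (ncol(X) < 2) stop("need at least 2 variables")
  if (any(X < 0)) stop("fluxes must be non-negative")
  const <- apply(X, 2, function(col) diff(range(col)) <= 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    if (ncol(X) < 2) stop("fewer than 2 non-constant variables remain")
  }
  Z <- apply(X, 2, minmax_normalize)
  S <- if (use_correlation) stats::cor(Z) else stats::cov(Z)
  eig <- eigen(S, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12
  n_comp <- min(2L, sum(pos))
  load <- eig$vectors[, seq_len(n_comp), drop = FALSE]
  # sign convention: largest-magnitude element of each loading positive
  for (k in seq_len(n_comp)) {
    imax <- which.max(abs(load[, k]))
    if (load[imax, k] < 0) load[, k] <- -load[, k]
  }
  rownames(load) <- colnames(X)
  colnames(load) <- paste0("PC", seq_len(n_comp))
  scores <- scale(Z, center = TRUE, scale = FALSE) %*% load
  ev <- pmax(eig$values, 0)
  list(loadings = load,
       eigenvalues = eig$values,
       explained_variance = ev / sum(ev),
       scores = scores,
       n_components = n_comp)
}

#' Spearman rank correlation with permutation p-value
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). The
#' two-sided p-value is obtained by permuting one vector:
#' `p = (1 + #\{|rho*| >= |rho_obs|\}) / (1 + n_perm)`. For
#' `method = "asymptotic"` the t approximation is used instead.
#'
#' @param x,y Numeric vectors of equal length >= 4, neither constant.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param method `"permutation"` (default) or `"asymptotic"`.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_rho <- function(x, y, n_perm = 9999L, seed = 1L,
                         method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("constant input vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "asymptotic") {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    return(list(rho = rho, p_value = min(p, 1), n = n, method = method))
  }
  set.seed(seed)
  ge <- 0L
  tol <- 1e-12
  for (b in seq_len(n_perm)) {
    rb <- abs(stats::cor(rx, ry[sample.int(n)]))
    if (rb >= abs(rho) - tol) ge <- ge + 1L
  }
  list(rho = rho, p_value = (1 + ge) / (1 + n_perm), n = n,
       method = method)
}

#' Exhaustive-permutation Spearman p-value
#'
#' Enumerates all `n!` orderings of `y`; exact two-sided reference for
#' the Monte-Carlo p-value at tiny n.
#'
#' @inheritParams spearman_rho
#' @return Exact two-sided p-value.
#' @export
spearman_exact_p <- function(x, y) {
  n <- length(x)
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  rx <- rank(x)
  ry <- rank(y)
  rho <- abs(stats::cor(rx, ry))
  perms <- all_permutations(n)
  tol <- 1e-12
  ge <- 0L
  for (k in seq_len(nrow(perms))) {
    if (abs(stats::cor(rx, ry[perms[k, ]])) >= rho - tol) ge <- ge + 1L
  }
  ge / nrow(perms)
}
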