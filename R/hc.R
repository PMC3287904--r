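#' Higher Criticism configuration
#'
#' @param p_floor lower bound of the significance range searched by the
#'   HC maximization.  Order statistics below the floor are excluded
#'   from the maximization (the floor replaces the classical `1/L`
#'   lower bound, which is too coarse for genes with few SNPs).
#' @return list of class `hc_config`.
#' @export
hc_config <- function(p_floor = 1e-10) {
  stopifnot(is.numeric(p_floor), p_floor > 0, p_floor < 1)
  structure(list(p_floor = p_floor), class = "hc_config")
}

#' Higher Criticism statistic
#'
#' For ordered P-values `p_(1) <= ... <= p_(L)` the HC statistic is the
#' largest standardized difference between the observed and expected
#' fractions of significant tests,
#' `max_i sqrt(L) * (i/L - p_(i)) / sqrt(p_(i) * (1 - p_(i)))`,
#' maximized over the indices whose order statistic is at least
#' `p_floor`.  If every P-value lies below the floor (extremely strong
#' signal, or numerical underflow), the values are clamped to the floor
#' and the maximization runs over all indices.  `p_(i) = 1` contributes
#' the analytic limit of its term: 0 at `i = L`, `-Inf` otherwise.
#' Larger HC means more significant.
#'
#' @param pvalues numeric vector of P-values in `[0, 1]` (exact zeros
#'   are treated as lying below the floor).
#' @param cfg an [hc_config()].
#' @return the HC statistic (scalar).
#' @export
hc_statistic <- function(pvalues, cfg = hc_config()) {
  if (length(pvalues) == 0) stop("empty P-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("P-values must lie in [0, 1]")
  drop(.hc_cols(matrix(pvalues, ncol = 1), cfg$p_floor))
}

## Column-wise HC over an L x J matrix of P-values.  Shared by the
## scalar API and the batched permutation engine.
.hc_cols <- function(P, p_floor) {
  L <- nrow(P)
  Ps <- if (L == 1L) P else apply(P, 2, sort)
  Ps <- matrix(Ps, nrow = L)
  below <- Ps < p_floor
  all_below <- colSums(below) == L
  if (any(all_below)) Ps[, all_below] <- pmax(Ps[, all_below], p_floor)
  i_frac <- seq_len(L) / L
  num <- sqrt(L) * (i_frac - Ps)
  den <- sqrt(Ps * (1 - Ps))
  terms <- num / den
  ## analytic limit at p = 1: term -> 0 when i = L, -Inf below
  one <- Ps >= 1
  if (any(one)) {
    terms[one] <- -Inf
    top <- one[L, ]
    if (any(top)) terms[L, top] <- 0
  }
  terms[below & !matrix(all_below, L, ncol(P), byrow = TRUE)] <- -Inf
  apply(terms, 2, max)
}

#' Inverse-Cholesky whitening operator
#'
#' For a symmetric positive definite covariance `sigma = C C'` (lower
#' Cholesky factor `C`), returns `U = C^{-1}`: lower triangular with
#' positive diagonal and `U sigma U' = I`.
#'
#' @param sigma symmetric positive definite matrix.
#' @return lower-triangular whitening matrix `U`.
#' @export
cholesky_whitener <- function(sigma) {
  sigma <- as.matrix(sigma)
  R <- tryCatch(chol(sigma), error = function(e)
    stop("covariance is not positive definite"))
  forwardsolve(t(R), diag(nrow(sigma)))
}

#' Band-trim a lower-triangular matrix
#'
#' Keeps entry `(k, j)` iff `k - b + 1 <= j <= k`: the diagonal and the
#' `b - 1` nearest sub-diagonals survive; everything further below the
#' diagonal is zeroed.  `b = 1` keeps only the diagonal; `b >= L` is the
#' identity operation.
#'
#' @param U lower-triangular matrix.
#' @param b bandwidth, integer `>= 1`.
#' @return the trimmed matrix.
#' @export
band_trim <- function(U, b) {
  if (b < 1) stop("bandwidth must be >= 1")
  L <- nrow(U)
  k <- row(U); j <- col(U)
  U * (j >= k - b + 1 & j <= k)
}

#' Normalize matrix columns to unit Euclidean norm
#'
#' @param U matrix with no all-zero column.
#' @return matrix whose every column has L2 norm 1.
#' @export
column_normalize <- function(U) {
  nrm <- sqrt(colSums(U^2))
  if (any(nrm == 0)) stop("cannot normalize an all-zero column")
  sweep(U, 2, nrm, "/")
}

## Banded, column-normalized whitener used by the innovated HC scores.
## b = max(1, floor(log L)) with the natural log, L the gene's SNP count.
.ihc_bandwidth <- function(L) max(1L, as.integer(floor(log(L))))

.ihc_transform <- function(sigma, b = NULL) {
  L <- nrow(sigma)
  if (is.null(b)) b <- .ihc_bandwidth(L)
  column_normalize(band_trim(cholesky_whitener(sigma), b))
}

#' Innovated Higher Criticism score for a gene
#'
#' Whitens the jointly estimated coefficient vector with the banded,
#' column-normalized inverse Cholesky factor of its covariance
#' (`bandwidth b = max(1, floor(log L))`), converts the transformed
#' components to two-sided normal P-values and applies the HC
#' functional.  The banding exploits correlation that decays with SNP
#' distance, concentrating each transformed component on nearby SNPs.
#'
#' @param est a `joint_estimate` (from [joint_ols()] or
#'   [joint_logistic()]).
#' @param cfg an [hc_config()].
#' @param b optional bandwidth override.
#' @return the iHC statistic (larger = more significant).
#' @export
ihc_score <- function(est, cfg = hc_config(), b = NULL) {
  V <- .ihc_transform(est$sigma, b)
  z <- drop(V %*% est$beta)
  hc_statistic(2 * stats::pnorm(-abs(z)), cfg)
}

## Deterministic eigen-decomposition: eigenvalues descending, each
## eigenvector's sign fixed so its largest-magnitude entry is positive.
.eigen_whitener <- function(sigma, tol = 1e-12) {
  e <- eigen(sigma, symmetric = TRUE)
  if (any(e$values <= tol * max(e$values)))
    stop("covariance is numerically singular")
  Q <- e$vectors
  for (j in seq_len(ncol(Q))) {
    k <- which.max(abs(Q[, j]))
    if (Q[k, j] < 0) Q[, j] <- -Q[, j]
  }
  diag(1 / sqrt(e$values), nrow = length(e$values)) %*% t(Q)
}

#' Eigen-decomposition Higher Criticism score for a gene
#'
#' Whitens the coefficient vector exactly via the eigen-decomposition
#' `sigma = Q L Q'`: the transformed vector `Z = L^{-1/2} Q' beta` has
#' identity covariance, satisfying the independent-normality assumption
#' of the HC theory.  Components are converted to two-sided normal
#' P-values and scored with the HC functional.
#'
#' @inheritParams ihc_score
#' @return the eHC statistic (larger = more significant).
#' @export
ehc_score <- function(est, cfg = hc_config()) {
  W <- .eigen_whitener(est$sigma)
  z <- drop(W %*% est$beta)
  hc_statistic(2 * stats::pnorm(-abs(z)), cfg)
}

#' Correlation of marginal statistics across trait replicates
#'
#' Pearson correlation of per-SNP marginal statistics computed over
#' independent trait replicates (rows = replicates, columns = SNPs).
#' The estimate is projected to the nearest positive definite
#' correlation matrix by eigenvalue clipping when needed.
#'
#' @param stats replicates x SNPs matrix of marginal statistics.
#' @param clip smallest admissible eigenvalue before projection.
#' @return SNPs x SNPs positive definite correlation matrix with unit
#'   diagonal.
#' @export
estimate_stat_correlation_replicates <- function(stats, clip = 1e-6) {
  stats <- as.matrix(stats)
  if (nrow(stats) < 3)
    stop("need >= 3 replicates; use the genotype-based estimator instead")
  if (any(apply(stats, 2, stats::sd) == 0))
    stop("constant statistic column; cannot estimate correlation")
  .pd_correlation(stats::cor(stats), clip)
}

#' Correlation of marginal statistics approximated by genotype correlation
#'
#' Approximates the correlation between two SNPs' marginal statistics by
#' the Pearson correlation of their genotype columns.  The
#' approximation is exact only under the null, but needs no replicates.
#'
#' @param X genotype submatrix of a gene (individuals x SNPs).
#' @inheritParams estimate_stat_correlation_replicates
#' @return SNPs x SNPs positive definite correlation matrix.
#' @export
estimate_stat_correlation_genotype <- function(X, clip = 1e-6) {
  X <- as.matrix(X)
  if (any(apply(X, 2, stats::sd) == 0))
    stop("constant genotype column; clean the gene first")
  .pd_correlation(stats::cor(X), clip)
}

## Clip eigenvalues below `clip`, reconstruct, rescale to unit diagonal.
.pd_correlation <- function(C, clip = 1e-6) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  if (all(e$values >= clip)) {
    diag(C) <- 1
    return(C)
  }
  lam <- pmax(e$values, clip)
  C2 <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(C2))
  C2 <- C2 / outer(d, d)
  diag(C2) <- 1
  C2
}

#' Innovated Higher Criticism on marginal statistics
#'
#' Applies the banded-Cholesky whitening and HC scoring of [ihc_score()]
#' with the marginal statistic vector playing the role of the jointly
#' estimated coefficients and an estimated correlation matrix playing
#' the role of their covariance.  Because marginal statistics remain
#' stable for rare variants where joint (logistic) estimation breaks
#' down, this variant is robust in the rare-allele regime.
#'
#' @param stats marginal statistic vector (t or trend z), length L.
#' @param corr L x L positive definite correlation matrix, from
#'   [estimate_stat_correlation_replicates()] or
#'   [estimate_stat_correlation_genotype()].
#' @inheritParams ihc_score
#' @return the iHCM statistic (larger = more significant).
#' @export
ihcm_score <- function(stats, corr, cfg = hc_config(), b = NULL) {
  stats <- as.numeric(stats)
  corr <- as.matrix(corr)
  stopifnot(length(stats) == nrow(corr))
  V <- .ihc_transform(corr, b)
  z <- drop(V %*% stats)
  hc_statistic(2 * stats::pnorm(-abs(z)), cfg)
}
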