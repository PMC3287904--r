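#' Minimal P-value gene score
#'
#' The smallest marginal P-value among a gene's SNPs (equivalently, the
#' marginal statistic of largest magnitude).  Smaller means more
#' significant; cross-gene comparability comes from the permutation
#' calibration, which accounts for the number of SNPs tested.
#'
#' @param stats result of [marginal_stats()] (or any list with a
#'   `pvalue` vector).
#' @return the minimal P-value.
#' @export
minp_score <- function(stats) {
  p <- stats$pvalue
  if (length(p) == 0) stop("empty P-value vector")
  min(p)
}

#' Ridge regression configuration
#'
#' @param lambda_grid nonnegative penalty grid searched by generalized
#'   cross-validation; default `{0}` plus 101 log-spaced points in
#'   `[1e-3, 50]`.
#' @return list of class `ridge_config`.
#' @export
ridge_config <- function(lambda_grid = c(0, exp(seq(log(1e-3), log(50),
                                                    length.out = 101)))) {
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid >= 0))
  structure(list(lambda_grid = lambda_grid), class = "ridge_config")
}

## Ridge decomposition shared by fit / selection / scoring.  Genotype
## columns are standardized (zero-variance columns dropped: their
## coefficient is 0), the response centered, the intercept left
## unpenalized; the SVD of the standardized design makes the whole
## lambda grid cheap.
.ridge_prep <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  sv <- if (ncol(Xs) > 0) svd(Xs) else
    list(u = matrix(0, nrow(X), 0), d = numeric(0), v = matrix(0, 0, 0))
  list(mu = mu, sd = sdv, keep = keep, u = sv$u, d = sv$d, v = sv$v,
       n = nrow(X), p_all = ncol(X))
}

.ridge_solve <- function(prep, yc, lambda) {
  d <- prep$d
  shrink <- d / (d^2 + lambda)
  beta_s <- prep$v %*% (shrink * crossprod(prep$u, yc))
  drop(beta_s)
}

#' Fit ridge regression at a fixed penalty
#'
#' Minimizes `||y - alpha - X beta||^2 + lambda * ||beta||^2` in the
#' standardized-genotype basis (intercept unpenalized), and returns the
#' coefficients and fitted values on the original scale.  `lambda = 0`
#' on a full-rank design reproduces ordinary least squares.
#'
#' @param X genotype matrix of a gene (individuals x SNPs).
#' @param y phenotype vector; binary traits are treated numerically.
#' @param lambda penalty, `>= 0`.
#' @return list with `coefficients` (per input column; 0 for
#'   zero-variance columns), `intercept`, `fitted`, `ssr`.
#' @export
ridge_fit <- function(X, y, lambda) {
  stopifnot(lambda >= 0)
  y <- as.numeric(y)
  prep <- .ridge_prep(X)
  yc <- y - mean(y)
  beta_s <- .ridge_solve(prep, yc, lambda)
  beta <- numeric(prep$p_all)
  beta[prep$keep] <- beta_s / prep$sd[prep$keep]
  intercept <- mean(y) - sum(beta[prep$keep] * prep$mu[prep$keep])
  fitted <- intercept + drop(as.matrix(X) %*% beta)
  list(coefficients = beta, intercept = intercept, fitted = fitted,
       ssr = sum((y - fitted)^2))
}

## SSR and GCV over the whole lambda grid from one SVD.
## uy = U'yc, yss = ||yc||^2.  For each lambda the hat shrinkage is
## s_k = d_k^2 / (d_k^2 + lambda); SSR = yss - sum_k (2 s_k - s_k^2) uy_k^2
## and the effective df is 1 + sum_k s_k (intercept included).
.ridge_path <- function(prep, yc, grid) {
  uy2 <- drop(crossprod(prep$u, yc))^2
  yss <- sum(yc^2)
  d2 <- prep$d^2
  S <- outer(d2, grid, function(a, l) a / (a + l))   # k x G
  if (any(d2 == 0) && any(grid == 0)) S[d2 == 0, grid == 0] <- 0  # 0/0 guard
  ssr <- yss - colSums((2 * S - S^2) * uy2)
  ssr <- pmax(ssr, 0)
  df <- colSums(S) + 1
  gcv <- prep$n * ssr / (prep$n - df)^2
  list(ssr = ssr, gcv = gcv, df = df)
}

#' Select the ridge penalty by generalized cross-validation
#'
#' Returns the grid value minimizing the GCV criterion
#' `n * SSR(lambda) / (n - df(lambda))^2` with
#' `df = 1 + sum_k d_k^2/(d_k^2 + lambda)`; ties resolve to the
#' smallest lambda.  GCV is deterministic (no fold randomness), which
#' keeps permutation nulls reproducible.
#'
#' @inheritParams ridge_fit
#' @param cfg a [ridge_config()].
#' @return list with `lambda`, `gcv` (vector over the grid), `grid`.
#' @export
select_lambda <- function(X, y, cfg = ridge_config()) {
  prep <- .ridge_prep(X)
  y <- as.numeric(y)
  path <- .ridge_path(prep, y - mean(y), cfg$lambda_grid)
  list(lambda = cfg$lambda_grid[which.min(path$gcv)],
       gcv = path$gcv, grid = cfg$lambda_grid)
}

#' Ridge goodness-of-fit gene score
#'
#' The residual sum of squares of the ridge fit at the GCV-selected
#' penalty.  A smaller SSR means the gene's SNPs explain the trait
#' better, so smaller is more significant; the same least-squares
#' machinery is applied to binary traits (coded 0/1) for simplicity.
#'
#' @inheritParams select_lambda
#' @return list with `score` (the SSR), `lambda`.
#' @export
ridge_score <- function(X, y, cfg = ridge_config()) {
  prep <- .ridge_prep(X)
  y <- as.numeric(y)
  path <- .ridge_path(prep, y - mean(y), cfg$lambda_grid)
  i <- which.min(path$gcv)
  list(score = path$ssr[i], lambda = cfg$lambda_grid[i])
}
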