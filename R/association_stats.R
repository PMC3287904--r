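#' Marginal t statistic for a quantitative trait
#'
#' Simple linear regression of `y` on a single genotype column with an
#' intercept; the statistic is `slope / SE(slope)` on `n - 2` degrees of
#' freedom with a two-sided P-value.  A zero-variance genotype column
#' yields statistic 0 and P = 1 (gene cleaning normally removes such
#' columns before this is reached).
#'
#' @param x genotype column (numeric vector).
#' @param y quantitative phenotype vector of the same length.
#' @return list with `stat`, `pvalue`, `df`.
#' @export
marginal_t <- function(x, y) {
  n <- length(y)
  stopifnot(length(x) == n, n >= 3)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) return(list(stat = 0, pvalue = 1, df = n - 2L))
  yc <- y - mean(y)
  slope <- sum(xc * yc) / sxx
  sse <- sum((yc - slope * xc)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  list(stat = tval, pvalue = 2 * stats::pt(-abs(tval), df = n - 2),
       df = n - 2L)
}

#' Marginal trend (score) statistic for a binary trait
#'
#' Score test of single-covariate logistic regression with an intercept,
#' in the Armitage trend form
#' `z = sum((x - xbar) * (y - ybar)) / sqrt(ybar * (1 - ybar) * sum((x - xbar)^2))`,
#' asymptotically N(0, 1) under the null; the P-value is two-sided
#' normal.  The statistic flips sign under the allele-coding flip
#' `x -> 2 - x`.
#'
#' @param x genotype column.
#' @param y binary 0/1 phenotype vector.
#' @return list with `stat`, `pvalue`.
#' @export
marginal_z <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(y)) < 2) stop("phenotype has one class")
  ybar <- mean(y)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) return(list(stat = 0, pvalue = 1))
  z <- sum(xc * (y - ybar)) / sqrt(ybar * (1 - ybar) * sxx)
  list(stat = z, pvalue = 2 * stats::pnorm(-abs(z)))
}

#' Marginal statistics for every SNP in a gene
#'
#' Vectorized wrapper: t statistics (quantitative) or trend z statistics
#' (binary) for each column of a gene block.
#'
#' @param block a [gene_block()].
#' @param y a [phenotype()] vector.
#' @return list with `stat`, `pvalue` vectors and `df` (`NA` for binary
#'   traits).
#' @export
marginal_stats <- function(block, y) {
  trait <- attr(y, "trait_type")
  res <- .marginal_stat_matrix(block$X, matrix(as.numeric(y), ncol = 1), trait)
  list(stat = drop(res$stat), pvalue = drop(res$pvalue), df = res$df)
}

## Batched marginal statistics: X is n x L, Y is n x J (each column one
## response).  Quantitative: t = r * sqrt(n-2) / sqrt(1 - r^2) from the
## Pearson correlation r.  Binary: Armitage trend z per column pair.
## Returns L x J matrices of statistics and two-sided P-values.
.marginal_stat_matrix <- function(X, Y, trait_type) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  sx <- sqrt(colSums(Xc^2))
  cross <- crossprod(Xc, sweep(Y, 2, colMeans(Y)))  # L x J
  if (trait_type == "quantitative") {
    sy <- sqrt(colSums(sweep(Y, 2, colMeans(Y))^2))
    denom <- outer(sx, sy)
    r <- ifelse(denom > 0, cross / denom, 0)
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    list(stat = tstat, pvalue = 2 * stats::pt(-abs(tstat), df = n - 2),
         df = n - 2L)
  } else {
    ybar <- colMeans(Y)
    denom <- outer(sx, sqrt(ybar * (1 - ybar)))
    z <- ifelse(denom > 0, cross / denom, 0)
    list(stat = z, pvalue = 2 * stats::pnorm(-abs(z)), df = NA_integer_)
  }
}

#' Joint least-squares estimate of SNP effects in a gene
#'
#' Ordinary least squares of `y` on the gene's genotype columns plus an
#' intercept.  The coefficient covariance is the SNP block of
#' `(X'X)^{-1}` for the augmented design, with the residual variance
#' fixed at 1: the error scale is common to all genes for a given trait,
#' so it cancels in cross-gene comparison and the permutation null
#' absorbs it.
#'
#' @param block a [gene_block()] (cleaned: full column rank).
#' @param y quantitative phenotype vector.
#' @return object of class `joint_estimate`: list with `beta` (length
#'   L), `sigma` (L x L), `stabilized = FALSE`.
#' @export
joint_ols <- function(block, y) {
  X <- block$X
  n <- nrow(X)
  L <- ncol(X)
  if (n <= L + 1) stop("gene too large for joint estimation")
  Xt <- cbind(1, X)
  M <- chol2inv(chol(crossprod(Xt)))
  beta <- drop(M %*% crossprod(Xt, as.numeric(y)))
  structure(list(beta = beta[-1], sigma = M[-1, -1, drop = FALSE],
                 stabilized = FALSE),
            class = "joint_estimate")
}

#' Joint logistic (maximum likelihood) estimate of SNP effects
#'
#' Multicovariate logistic regression of a binary trait on the gene's
#' genotype columns with an intercept.  The covariance is the inverse
#' Fisher information (SNP block).  Rare variants frequently cause
#' separation; when the unpenalized fit diverges, the information matrix
#' is ridged with `epsilon` and the iteration repeated, and the result
#' is flagged `stabilized = TRUE`.  Genes that still fail are flagged
#' unusable for the joint-estimation scores.
#'
#' @param block a [gene_block()].
#' @param y binary 0/1 phenotype vector.
#' @param epsilon stabilization ridge added to the information matrix.
#' @param maxit maximum Newton iterations.
#' @return a `joint_estimate` (fields `beta`, `sigma`, `stabilized`), or
#'   `NULL` when estimation fails outright.
#' @export
joint_logistic <- function(block, y, epsilon = 1e-4, maxit = 50) {
  X <- block$X
  n <- nrow(X)
  L <- ncol(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("phenotype has one class")
  if (n <= L + 1) stop("gene too large for joint estimation")
  Xt <- cbind(1, X)

  fit <- .logistic_newton(Xt, y, ridge = 0, maxit = maxit)
  stabilized <- FALSE
  if (!fit$ok) {
    fit <- .logistic_newton(Xt, y, ridge = epsilon, maxit = maxit)
    stabilized <- TRUE
  }
  if (!fit$ok) return(NULL)
  structure(list(beta = fit$beta[-1], sigma = fit$cov[-1, -1, drop = FALSE],
                 stabilized = stabilized),
            class = "joint_estimate")
}

## Newton-Raphson for logistic regression with an optional ridge on the
## information matrix.  ok = FALSE on divergence (separation shows up as
## unbounded coefficients or a singular information matrix).
.logistic_newton <- function(Xt, y, ridge = 0, maxit = 50, tol = 1e-8) {
  p <- ncol(Xt)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  for (it in seq_len(maxit)) {
    eta <- drop(Xt %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(Xt * w, Xt) + diag(ridge, p)
    step <- tryCatch(solve(info, crossprod(Xt, y - mu)),
                     error = function(e) NULL)
    if (is.null(step)) return(list(ok = FALSE))
    beta <- beta + drop(step)
    if (max(abs(beta)) > 30 && ridge == 0) return(list(ok = FALSE))
    if (max(abs(step)) < tol) {
      covb <- tryCatch(solve(info), error = function(e) NULL)
      if (is.null(covb) || any(!is.finite(covb))) return(list(ok = FALSE))
      return(list(ok = TRUE, beta = beta, cov = covb))
    }
  }
  ## ridged fits that ran out of iterations are still usable when finite
  if (ridge > 0 && all(is.finite(beta))) {
    covb <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(covb) && all(is.finite(covb)))
      return(list(ok = TRUE, beta = beta, cov = covb))
  }
  list(ok = FALSE)
}
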