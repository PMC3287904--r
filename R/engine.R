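## Batched scoring engine
##
## Permutation calibration needs every method's statistic for every gene
## at thousands of shuffled responses.  Everything that depends only on
## the genotypes -- joint-design inverses, whitening operators, ridge
## SVDs, correlation matrices -- is computed once per gene; each batch of
## responses then reduces to a handful of matrix products per gene.

.method_ids <- c("minp", "ridge", "hc", "ihc", "ehc", "ihcm")

## Quantitative responses are standardized (mean 0, variance 1) before
## scoring.  Marginal t statistics are invariant; for the
## scale-dependent scores (ridge SSR, the sigma^2 = 1 joint-coefficient
## scores) this is what makes one replicate's permutation null valid
## for every replicate: a permutation never changes the response scale,
## but different replicates' noise draws do.
.standardize_y <- function(Y, trait_type) {
  if (trait_type != "quantitative") return(Y)
  mu <- colMeans(Y)
  s <- sqrt(colSums(sweep(Y, 2, mu)^2) / (nrow(Y) - 1))
  sweep(sweep(Y, 2, mu), 2, s, "/")
}

#' Significance orientation of each gene-scoring method
#'
#' @param method one of `"minp"`, `"ridge"`, `"hc"`, `"ihc"`, `"ehc"`,
#'   `"ihcm"`.
#' @return `"smaller_better"` (minP P-value, ridge SSR) or
#'   `"larger_better"` (HC-family statistics).
#' @export
method_orientation <- function(method) {
  method <- match.arg(method, .method_ids)
  if (method %in% c("minp", "ridge")) "smaller_better" else "larger_better"
}

## Per-gene precomputation.  `ihcm_corr` is the correlation matrix for
## the iHCM whitener (replicate- or genotype-estimated); NULL defers to
## the genotype estimator.
.prep_gene <- function(block, trait_type, methods,
                       ihcm_corr = NULL, ridge_cfg = ridge_config()) {
  prep <- list(testable = block$testable, L = ncol(block$X))
  if (!block$testable) return(prep)
  X <- block$X
  n <- nrow(X)
  L <- ncol(X)

  if (any(c("minp", "hc", "ihcm") %in% methods)) {
    prep$Xc <- sweep(X, 2, colMeans(X))
    prep$sx <- sqrt(colSums(prep$Xc^2))
  }
  if ("ridge" %in% methods) prep$ridge <- .ridge_prep(X)
  if (any(c("ihc", "ehc") %in% methods)) {
    joint <- if (n > L + 1) tryCatch({
      Xt <- cbind(1, X)
      M <- chol2inv(chol(crossprod(Xt)))
      sigma <- M[-1, -1, drop = FALSE]
      list(coef_op = (M %*% t(Xt))[-1, , drop = FALSE],   # L x n
           V_ihc = .ihc_transform(sigma),
           W_ehc = .eigen_whitener(sigma))
    }, error = function(e) NULL) else NULL
    if (is.null(joint)) {
      prep$joint_ok <- FALSE
    } else {
      prep[names(joint)] <- joint
      prep$X <- X
    }
  }
  if ("ihcm" %in% methods) {
    corr <- if (is.null(ihcm_corr))
      estimate_stat_correlation_genotype(X) else ihcm_corr
    prep$V_ihcm <- .ihc_transform(corr)
  }
  prep
}

## Score one gene against a response matrix Y (n x J).  `marg` carries
## the gene's precomputed marginal statistics/P-values (L x J).
## Returns a named list of length-J score vectors (NA where a method is
## unavailable for this gene).
.score_gene_cols <- function(prep, Y, trait_type, methods, marg,
                             hc_cfg, ridge_cfg) {
  J <- ncol(Y)
  out <- list()
  na_row <- rep(NA_real_, J)
  if (!prep$testable) {
    for (m in methods) out[[m]] <- na_row
    return(out)
  }
  if ("minp" %in% methods)
    out$minp <- apply(marg$pvalue, 2, min)
  if ("hc" %in% methods)
    out$hc <- .hc_cols(marg$pvalue, hc_cfg$p_floor)
  if ("ihcm" %in% methods) {
    Z <- prep$V_ihcm %*% marg$stat
    out$ihcm <- .hc_cols(2 * stats::pnorm(-abs(Z)), hc_cfg$p_floor)
  }
  if ("ridge" %in% methods) {
    Yc <- sweep(Y, 2, colMeans(Y))
    grid <- ridge_cfg$lambda_grid
    UY2 <- crossprod(prep$ridge$u, Yc)^2           # k x J
    yss <- colSums(Yc^2)
    d2 <- prep$ridge$d^2
    n <- prep$ridge$n
    G <- length(grid)
    gcv <- ssr <- matrix(0, G, J)
    for (g in seq_len(G)) {
      s <- d2 / (d2 + grid[g])
      if (grid[g] == 0) s[d2 == 0] <- 0
      ssr[g, ] <- pmax(yss - colSums((2 * s - s^2) * UY2), 0)
      gcv[g, ] <- n * ssr[g, ] / (n - (sum(s) + 1))^2
    }
    sel <- apply(gcv, 2, which.min)   # first = smallest lambda on ties
    out$ridge <- ssr[cbind(sel, seq_len(J))]
  }
  if (any(c("ihc", "ehc") %in% methods)) {
    if (isFALSE(prep$joint_ok)) {
      if ("ihc" %in% methods) out$ihc <- na_row
      if ("ehc" %in% methods) out$ehc <- na_row
    } else if (trait_type == "quantitative") {
      B <- prep$coef_op %*% Y                       # L x J
      if ("ihc" %in% methods) {
        Z <- prep$V_ihc %*% B
        out$ihc <- .hc_cols(2 * stats::pnorm(-abs(Z)), hc_cfg$p_floor)
      }
      if ("ehc" %in% methods) {
        Z <- prep$W_ehc %*% B
        out$ehc <- .hc_cols(2 * stats::pnorm(-abs(Z)), hc_cfg$p_floor)
      }
    } else {
      ihc_v <- ehc_v <- na_row
      blk <- list(X = prep$X, testable = TRUE)
      for (j in seq_len(J)) {
        est <- tryCatch(joint_logistic(blk, Y[, j]), error = function(e) NULL)
        if (is.null(est)) next
        if ("ihc" %in% methods)
          ihc_v[j] <- ihc_score(est, hc_cfg)
        if ("ehc" %in% methods)
          ehc_v[j] <- ehc_score(est, hc_cfg)
      }
      if ("ihc" %in% methods) out$ihc <- ihc_v
      if ("ehc" %in% methods) out$ehc <- ehc_v
    }
  }
  out[methods]
}

## Score every gene x every response column for the requested methods.
## blocks: list of cleaned gene_blocks; Y: n x J response matrix;
## ihcm_corrs: optional named list of per-gene correlation matrices.
## Returns a named list of I x J matrices (rownames = gene ids).
.score_genes_matrix <- function(blocks, Y, trait_type, methods,
                                ihcm_corrs = NULL,
                                hc_cfg = hc_config(),
                                ridge_cfg = ridge_config(),
                                preps = NULL) {
  methods <- match.arg(methods, .method_ids, several.ok = TRUE)
  Y <- .standardize_y(as.matrix(Y), trait_type)
  I <- length(blocks)
  J <- ncol(Y)
  if (is.null(preps))
    preps <- .prep_genes(blocks, trait_type, methods, ihcm_corrs, ridge_cfg)

  ## batched marginal statistics across all testable genes at once
  margs <- .marginal_by_gene(blocks, Y, trait_type, methods)

  out <- lapply(methods, function(m) {
    mat <- matrix(NA_real_, I, J,
                  dimnames = list(vapply(blocks, `[[`, "", "gene_id"), NULL))
    mat
  })
  names(out) <- methods
  for (i in seq_len(I)) {
    sc <- .score_gene_cols(preps[[i]], Y, trait_type, methods,
                           margs[[i]], hc_cfg, ridge_cfg)
    for (m in methods) out[[m]][i, ] <- sc[[m]]
  }
  out
}

.prep_genes <- function(blocks, trait_type, methods, ihcm_corrs = NULL,
                        ridge_cfg = ridge_config()) {
  lapply(seq_along(blocks), function(i) {
    corr <- if (!is.null(ihcm_corrs)) ihcm_corrs[[blocks[[i]]$gene_id]]
    .prep_gene(blocks[[i]], trait_type, methods, corr, ridge_cfg)
  })
}

## Marginal statistics for each gene (L_i x J), computed in one big
## cross-product over the concatenated genotype columns.
.marginal_by_gene <- function(blocks, Y, trait_type, methods) {
  need <- any(c("minp", "hc", "ihcm") %in% methods)
  if (!need) return(vector("list", length(blocks)))
  test_idx <- which(vapply(blocks, `[[`, TRUE, "testable"))
  if (length(test_idx) == 0) return(vector("list", length(blocks)))
  Xall <- do.call(cbind, lapply(blocks[test_idx], `[[`, "X"))
  res <- .marginal_stat_matrix(Xall, Y, trait_type)
  sizes <- vapply(blocks[test_idx], function(b) ncol(b$X), 0L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  margs <- vector("list", length(blocks))
  for (k in seq_along(test_idx)) {
    rows <- starts[k]:ends[k]
    margs[[test_idx[k]]] <- list(
      stat = res$stat[rows, , drop = FALSE],
      pvalue = res$pvalue[rows, , drop = FALSE])
  }
  margs
}
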