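#' Construct a gene block
#'
#' One gene's genotype submatrix, kept in genomic SNP order.  Blocks are
#' usually produced by [gene_blocks()] and cleaned with [clean_gene()]
#' before scoring.
#'
#' @param gene_id gene label.
#' @param X numeric matrix, individuals x SNPs (major-allele counts).
#' @param snp_ids SNP identifiers for the columns of `X`.
#' @param maf per-SNP minor allele frequencies.
#' @param removed_snp_ids SNPs deleted by cleaning, in deletion order.
#' @return object of class `gene_block` with a `testable` flag
#'   (`FALSE` when cleaning left no usable column, the `L = 0` sentinel).
#' @export
gene_block <- function(gene_id, X, snp_ids, maf,
                       removed_snp_ids = character()) {
  X <- as.matrix(X)
  obj <- list(gene_id = as.character(gene_id), X = X,
              snp_ids = as.character(snp_ids), maf = as.numeric(maf),
              removed_snp_ids = as.character(removed_snp_ids),
              testable = ncol(X) >= 1L)
  class(obj) <- "gene_block"
  obj
}

#' @export
print.gene_block <- function(x, ...) {
  cat(sprintf("gene_block %s: %d SNP(s), %d removed%s\n", x$gene_id,
              ncol(x$X), length(x$removed_snp_ids),
              if (x$testable) "" else " [untestable]"))
  invisible(x)
}

## Numerical rank with a relative singular-value cutoff.  Integer
## genotype data makes exact linear dependence the target, so the
## tolerance is tight (1e-10 of the largest singular value).
.num_rank <- function(X, tol = 1e-10) {
  if (ncol(X) == 0) return(0L)
  d <- svd(X, nu = 0, nv = 0)$d
  sum(d > tol * max(d, .Machine$double.eps))
}

#' Remove linearly dependent SNP columns from a gene
#'
#' While the genotype columns of a gene are linearly dependent, the
#' column with the smallest minor allele frequency *among those whose
#' removal leaves the column span unchanged* is deleted, and the rank is
#' recomputed.  Ties on MAF are broken toward the largest column index.
#' Zero-variance (monomorphic) columns are removed first: they are
#' collinear with the model intercept and carry no association
#' information.  The returned block has full column rank and the same
#' column space as the input; deletions are recorded in
#' `removed_snp_ids`.  A gene whose every column is constant is flagged
#' untestable (zero columns) and is skipped by the scoring methods.
#'
#' @param block a [gene_block()].
#' @param tol relative singular-value tolerance for rank detection.
#' @return a cleaned [gene_block()].
#' @export
clean_gene <- function(block, tol = 1e-10) {
  X <- block$X
  snp_ids <- block$snp_ids
  maf <- block$maf
  removed <- character()

  const <- apply(X, 2, function(v) max(v) == min(v))
  if (any(const)) {
    removed <- c(removed, snp_ids[const])
    X <- X[, !const, drop = FALSE]
    snp_ids <- snp_ids[!const]
    maf <- maf[!const]
  }
  if (ncol(X) == 0)
    return(gene_block(block$gene_id, X, snp_ids, maf, removed))

  ## rank is judged on the intercept-augmented design: downstream models
  ## all include an intercept, so a SNP set summing to a constant is as
  ## degenerate as a duplicated SNP
  aug_rank <- function(M) .num_rank(cbind(1, M), tol)
  r <- aug_rank(X)
  while (r < ncol(X) + 1L) {
    ## candidate order: smallest MAF first, largest column index on ties
    ord <- order(maf, -seq_along(maf))
    dropped <- FALSE
    for (j in ord) {
      if (aug_rank(X[, -j, drop = FALSE]) == r) {
        removed <- c(removed, snp_ids[j])
        X <- X[, -j, drop = FALSE]
        snp_ids <- snp_ids[-j]
        maf <- maf[-j]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break   # defensive; a deficient design always has a redundant column
    r <- aug_rank(X)
  }
  gene_block(block$gene_id, X, snp_ids, maf, removed)
}

#' Split a genotype matrix into per-gene blocks
#'
#' @param g a [genotype_matrix()].
#' @param clean apply [clean_gene()] to each block (default `TRUE`).
#' @return named list of [gene_block()] objects, one per gene, in order
#'   of first appearance.
#' @export
gene_blocks <- function(g, clean = TRUE) {
  genes <- unique(g$gene_ids)
  blocks <- lapply(genes, function(gid) {
    idx <- which(g$gene_ids == gid)
    gene_block(gid, g$values[, idx, drop = FALSE],
               g$snp_ids[idx], g$maf[idx])
  })
  names(blocks) <- genes
  if (clean) blocks <- lapply(blocks, clean_gene)
  blocks
}

#' Summarize a genotype dataset
#'
#' Computes the empirical quantiles of per-SNP MAF and of SNPs per gene,
#' and the distribution of absolute Pearson correlation between SNP
#' pairs located in the same gene at ordinal distance 1 (adjacent), 2
#' (separated by one SNP) and 3.  Genes with fewer than `d + 1` SNPs
#' contribute no pairs at distance `d`; pairs involving a zero-variance
#' column are skipped.
#'
#' @param g a [genotype_matrix()].
#' @return list with `maf_summary`, `snps_per_gene_summary` (both
#'   `summary()`-style), and `ld_by_distance`: a list with the vectors
#'   of |r| at distances 1-3 and their medians.
#' @export
summarize_dataset <- function(g) {
  snps_per_gene <- table(factor(g$gene_ids, levels = unique(g$gene_ids)))
  ld <- lapply(1:3, function(d) {
    out <- numeric(0)
    for (gid in unique(g$gene_ids)) {
      idx <- which(g$gene_ids == gid)
      L <- length(idx)
      if (L < d + 1) next
      X <- g$values[, idx, drop = FALSE]
      sds <- apply(X, 2, stats::sd)
      for (j in seq_len(L - d)) {
        if (sds[j] > 0 && sds[j + d] > 0)
          out <- c(out, abs(stats::cor(X[, j], X[, j + d])))
      }
    }
    out
  })
  names(ld) <- paste0("d", 1:3)
  list(maf_summary = summary(g$maf),
       snps_per_gene_summary = summary(as.numeric(snps_per_gene)),
       ld_by_distance = list(
         values = ld,
         median = vapply(ld, function(v)
           if (length(v)) stats::median(v) else NA_real_, 0)))
}
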