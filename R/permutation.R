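#' Build the shared permutation null for a set of genes
#'
#' Shuffles the response `J` times; within each permutation, the *same*
#' shuffled response is scored for every gene and every requested
#' method, so the cross-gene dependence induced by shared individuals
#' and overlapping LD is preserved under the null.  Genes flagged
#' untestable are carried as all-`NA` rows.  The shuffles are
#' Fisher-Yates permutations drawn from `seed`, so the null is
#' bit-reproducible.
#'
#' @param blocks list of cleaned [gene_block()]s.
#' @param y a [phenotype()] vector (the response being shuffled).
#' @param methods subset of `c("minp","ridge","hc","ihc","ehc","ihcm")`.
#' @param J number of permutations.
#' @param seed RNG seed for the shuffle sequence.
#' @param ihcm_corrs optional named list (by gene id) of correlation
#'   matrices for the iHCM whitener; default uses per-gene genotype
#'   correlation.
#' @param hc_cfg,ridge_cfg method configurations.
#' @return named list of `permutation_null` objects, one per method:
#'   each holds `S_star` (genes x J matrix), `method`, `orientation`,
#'   `seed`.
#' @export
build_null <- function(blocks, y, methods = .method_ids, J = 10000L,
                       seed = 1L, ihcm_corrs = NULL,
                       hc_cfg = hc_config(), ridge_cfg = ridge_config()) {
  stopifnot(J >= 1)
  trait_type <- attr(y, "trait_type")
  if (is.null(trait_type)) trait_type <- "quantitative"
  n <- length(y)
  set.seed(seed)
  Y <- vapply(seq_len(J), function(j) as.numeric(y)[sample.int(n)],
              numeric(n))
  mats <- .score_genes_matrix(blocks, Y, trait_type, methods,
                              ihcm_corrs, hc_cfg, ridge_cfg)
  out <- lapply(names(mats), function(m) {
    structure(list(S_star = mats[[m]], method = m,
                   orientation = method_orientation(m), seed = seed),
              class = "permutation_null")
  })
  names(out) <- names(mats)
  out
}

#' Empirical P-value of a gene statistic against its permutation null
#'
#' Add-one convention:
#' `(1 + #\{j : S*_ij at least as extreme as S_i\}) / (J + 1)`, where
#' "at least as extreme" respects the method's significance orientation
#' and includes ties.  The result is always in `(0, 1]`, never 0, which
#' keeps ranking well defined.
#'
#' @param S_i observed statistic for one gene.
#' @param null_row its J permutation statistics.
#' @param orientation `"larger_better"` or `"smaller_better"`.
#' @return empirical P-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(S_i, null_row,
                             orientation = c("larger_better",
                                             "smaller_better")) {
  orientation <- match.arg(orientation)
  null_row <- null_row[!is.na(null_row)]
  J <- length(null_row)
  if (J < 1) stop("empty permutation null")
  extreme <- if (orientation == "larger_better")
    sum(null_row >= S_i) else sum(null_row <= S_i)
  (1 + extreme) / (J + 1)
}

#' Permutation-normalized gene score
#'
#' Standardizes the observed statistic against its permutation null,
#' `(S_i - mean(S*_i)) / sd(S*_i)`, flipping the sign for
#' smaller-is-better methods so that a larger normalized score always
#' means more significant.  A degenerate null (zero variance) yields
#' `NA`; such genes are assigned the worst rank downstream.
#'
#' @inheritParams empirical_pvalue
#' @return normalized score (or `NA` for a degenerate null).
#' @export
normalized_score <- function(S_i, null_row,
                             orientation = c("larger_better",
                                             "smaller_better")) {
  orientation <- match.arg(orientation)
  null_row <- null_row[!is.na(null_row)]
  s <- stats::sd(null_row)
  if (!is.finite(s) || s == 0) return(NA_real_)
  z <- (S_i - mean(null_row)) / s
  if (orientation == "smaller_better") -z else z
}

#' Rank genes by significance
#'
#' Rank 1 is the most significant gene; ties get their average rank;
#' `NA` values (untestable genes, degenerate nulls) are assigned the
#' worst rank, equal to the number of genes.
#'
#' @param x numeric vector of per-gene values.
#' @param larger_better `TRUE` when larger values are more significant
#'   (normalized scores), `FALSE` for empirical P-values.
#' @return numeric vector of ranks.
#' @export
rank_genes <- function(x, larger_better = FALSE) {
  v <- if (larger_better) -x else x
  r <- rank(v, ties.method = "average", na.last = "keep")
  r[is.na(r)] <- length(x)
  r
}

#' Calibrate replicate scores against one shared permutation null
#'
#' Trait replicates overlay the same genotype panel, so their null
#' distributions coincide; the null built from permuting one replicate
#' calibrates all of them.  For each replicate, raw scores are turned
#' into empirical P-values, normalized scores, and ranks (ranked by
#' empirical P-value).
#'
#' @param null a `permutation_null` (one method).
#' @param score_matrix genes x replicates matrix of raw statistics for
#'   the same genes and method.
#' @return list of data frames (one per replicate) with columns
#'   `gene_id`, `raw_stat`, `emp_p`, `norm_score`, `rank`, `method`,
#'   `replicate_id`.
#' @export
share_null_across_replicates <- function(null, score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  if (nrow(score_matrix) != nrow(null$S_star))
    stop("gene sets of null and scores differ")
  lapply(seq_len(ncol(score_matrix)), function(r)
    gene_score_set(score_matrix[, r], null, replicate_id = r))
}

#' Score set for one replicate: empirical P-values, normalized scores, ranks
#'
#' @param raw named (or ordered) vector of raw gene statistics.
#' @param null the method's `permutation_null`.
#' @param replicate_id replicate label.
#' @return data frame, one row per gene.
#' @export
gene_score_set <- function(raw, null, replicate_id = 1L) {
  I <- nrow(null$S_star)
  stopifnot(length(raw) == I)
  emp <- norm <- rep(NA_real_, I)
  for (i in seq_len(I)) {
    row_i <- null$S_star[i, ]
    if (is.na(raw[i]) || all(is.na(row_i))) next
    emp[i] <- empirical_pvalue(raw[i], row_i, null$orientation)
    norm[i] <- normalized_score(raw[i], row_i, null$orientation)
  }
  data.frame(gene_id = rownames(null$S_star), raw_stat = as.numeric(raw),
             emp_p = emp, norm_score = norm,
             rank = rank_genes(emp, larger_better = FALSE),
             rank_norm = rank_genes(norm, larger_better = TRUE),
             method = null$method, replicate_id = as.integer(replicate_id),
             stringsAsFactors = FALSE)
}

#' Evaluate a method by the ranks of causative genes across replicates
#'
#' For each causative gene, the mean and standard deviation of its rank
#' over replicates; overall, the per-replicate average rank over all
#' causative genes is summarized by its mean and standard deviation.
#' Smaller mean rank indicates a method that places true genes closer
#' to the top.
#'
#' @param rank_matrix genes x replicates matrix of ranks (rownames =
#'   gene ids).
#' @param causative_genes character vector of true gene ids.
#' @return list with `per_gene` (data frame `gene_id`, `mean_rank`,
#'   `sd_rank`) and `overall` (named vector `mean`, `sd` of the
#'   replicate-wise causative average rank).
#' @export
evaluate_methods <- function(rank_matrix, causative_genes) {
  rank_matrix <- as.matrix(rank_matrix)
  if (length(causative_genes) == 0) stop("empty causative gene set")
  missing <- setdiff(causative_genes, rownames(rank_matrix))
  if (length(missing))
    stop("causative gene(s) absent from ranks: ",
         paste(missing, collapse = ", "))
  sub <- rank_matrix[causative_genes, , drop = FALSE]
  per_gene <- data.frame(
    gene_id = causative_genes,
    mean_rank = rowMeans(sub),
    sd_rank = if (ncol(sub) > 1) apply(sub, 1, stats::sd) else
      rep(0, nrow(sub)),
    stringsAsFactors = FALSE)
  rep_avg <- colMeans(sub)
  list(per_gene = per_gene,
       overall = c(mean = mean(rep_avg),
                   sd = if (length(rep_avg) > 1) stats::sd(rep_avg) else 0))
}
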