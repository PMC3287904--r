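#' Score every gene by the requested methods with permutation calibration
#'
#' The in-memory end-to-end run: cleans genes, computes raw statistics
#' for every trait replicate and method, builds one shared permutation
#' null by shuffling replicate 1's response (all replicates overlay the
#' same genotypes, so their null distributions coincide), and calibrates
#' each replicate's raw scores into empirical P-values, normalized
#' scores, and ranks.
#'
#' Methods needing the joint estimate (`ihc`, `ehc`) use least squares
#' for quantitative traits and logistic maximum likelihood for binary
#' traits; genes too large for joint estimation (`L >= n - 1` after
#' cleaning) or with failed logistic fits are reported `NA` for those
#' methods and ranked worst.  `ihcm` estimates its correlation matrix
#' across replicates when at least 3 replicates exist, otherwise it
#' falls back to genotype correlation with a message.
#'
#' @param geno a [genotype_matrix()] (or a pre-cleaned list of
#'   [gene_block()]s).
#' @param traits list of [phenotype()] replicates (same individuals).
#' @param methods subset of `c("minp","ridge","hc","ihc","ehc","ihcm")`.
#' @param J permutations for the shared null.
#' @param seed RNG seed for the shuffle sequence.
#' @param ihcm_correlation `"replicates"` or `"genotype"`.
#' @param p_floor HC significance-range floor.
#' @param ridge_cfg a [ridge_config()].
#' @return list with `scores` (long data frame over genes, methods,
#'   replicates), `raw` (per-method genes x replicates matrices),
#'   `null` (per-method `permutation_null`), `blocks`.
#' @export
score_dataset <- function(geno, traits,
                          methods = c("minp", "ridge", "hc", "ihc",
                                      "ehc", "ihcm"),
                          J = 10000L, seed = 1L,
                          ihcm_correlation = c("replicates", "genotype"),
                          p_floor = 1e-10, ridge_cfg = ridge_config()) {
  methods <- match.arg(methods, .method_ids, several.ok = TRUE)
  ihcm_correlation <- match.arg(ihcm_correlation)
  hc_cfg <- hc_config(p_floor)
  blocks <- if (inherits(geno, "genotype_matrix"))
    gene_blocks(geno) else geno
  trait_type <- attr(traits[[1]], "trait_type")
  n <- length(traits[[1]])
  Ymat <- vapply(traits, as.numeric, numeric(n))

  ihcm_corrs <- NULL
  if ("ihcm" %in% methods) {
    if (ihcm_correlation == "replicates" && length(traits) >= 3) {
      margs <- .marginal_by_gene(blocks, Ymat, trait_type, "ihcm")
      ihcm_corrs <- lapply(seq_along(blocks), function(i) {
        if (is.null(margs[[i]])) return(NULL)
        tryCatch(estimate_stat_correlation_replicates(t(margs[[i]]$stat)),
                 error = function(e)
                   estimate_stat_correlation_genotype(blocks[[i]]$X))
      })
      names(ihcm_corrs) <- vapply(blocks, `[[`, "", "gene_id")
    } else if (ihcm_correlation == "replicates") {
      message("fewer than 3 replicates: iHCM falls back to ",
              "genotype-based correlation")
    }
  }

  raw <- .score_genes_matrix(blocks, Ymat, trait_type, methods,
                             ihcm_corrs, hc_cfg, ridge_cfg)
  null <- build_null(blocks, traits[[1]], methods, J = J, seed = seed,
                     ihcm_corrs = ihcm_corrs, hc_cfg = hc_cfg,
                     ridge_cfg = ridge_cfg)
  scores <- do.call(rbind, unlist(lapply(methods, function(m)
    share_null_across_replicates(null[[m]], raw[[m]])),
    recursive = FALSE))
  rownames(scores) <- NULL
  list(scores = scores, raw = raw, null = null, blocks = blocks)
}

#' Run configuration for a file-based scoring run
#'
#' @param genotypes path to the genotype file.
#' @param gene_map path to the SNP-to-gene map TSV.
#' @param phenotypes character vector of phenotype TSV paths (one per
#'   replicate, in replicate order), or a directory containing them as
#'   `pheno*.tsv` files.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param format genotype dialect, `"table"` or `"vcf"`.
#' @param methods methods to run.
#' @param ihcm_correlation iHCM correlation estimator.
#' @param J permutations.
#' @param p_floor HC floor.
#' @param seed RNG seed.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(genotypes, gene_map, phenotypes,
                       trait_type = c("quantitative", "binary"),
                       format = c("table", "vcf"),
                       methods = c("minp", "ridge", "hc", "ihc", "ehc",
                                   "ihcm"),
                       ihcm_correlation = c("replicates", "genotype"),
                       J = 10000L, p_floor = 1e-10, seed = 1L,
                       out_dir = ".") {
  structure(list(genotypes = genotypes, gene_map = gene_map,
                 phenotypes = phenotypes,
                 trait_type = match.arg(trait_type),
                 format = match.arg(format),
                 methods = match.arg(methods, .method_ids,
                                     several.ok = TRUE),
                 ihcm_correlation = match.arg(ihcm_correlation),
                 J = as.integer(J), p_floor = p_floor,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Execute a file-based scoring run
#'
#' Loads the inputs named in the configuration, runs [score_dataset()],
#' and writes `scores.tsv` (long table: `gene_id method replicate_id
#' raw_stat emp_p norm_score rank rank_norm`), one
#' `summary_<method>.tsv` of per-gene mean/sd ranks, and a
#' `manifest.json` recording the configuration so the run can be
#' reproduced exactly.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the [score_dataset()] result.
#' @export
run_scoring <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  pheno_paths <- cfg$phenotypes
  if (length(pheno_paths) == 1 && dir.exists(pheno_paths))
    pheno_paths <- sort(list.files(pheno_paths,
                                   pattern = "^pheno.*\\.tsv$",
                                   full.names = TRUE))
  if (length(pheno_paths) == 0) stop("no phenotype file found")
  geno <- read_genotypes(cfg$genotypes, cfg$format, cfg$gene_map)
  traits <- lapply(seq_along(pheno_paths), function(r)
    read_phenotype(pheno_paths[r], cfg$trait_type, replicate_id = r))
  res <- score_dataset(geno, traits, methods = cfg$methods, J = cfg$J,
                       seed = cfg$seed,
                       ihcm_correlation = cfg$ihcm_correlation,
                       p_floor = cfg$p_floor)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$scores, file.path(cfg$out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in cfg$methods) {
    sub <- res$scores[res$scores$method == m, ]
    agg <- do.call(rbind, lapply(split(sub, sub$gene_id), function(d)
      data.frame(gene_id = d$gene_id[1], mean_rank = mean(d$rank),
                 sd_rank = if (nrow(d) > 1) stats::sd(d$rank) else 0,
                 mean_emp_p = mean(d$emp_p),
                 stringsAsFactors = FALSE)))
    agg <- agg[order(agg$mean_rank), ]
    utils::write.table(agg,
                       file.path(cfg$out_dir,
                                 sprintf("summary_%s.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- c(unclass(cfg),
                list(n_replicates = length(pheno_paths),
                     n_genes = length(res$blocks),
                     package_version =
                       as.character(utils::packageVersion("hcgene"))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Compare methods by causative-gene ranks
#'
#' For each method present in a scoring result, evaluates the ranks of
#' the causative genes (from the truth table) across replicates, once
#' for the empirical-P ranking and once for the normalized-score
#' ranking.  The method with the smallest overall mean rank is flagged
#' best in each table.
#'
#' @param scores the long score data frame from [score_dataset()] /
#'   `scores.tsv` (or a path to it).
#' @param truth the truth data frame (`gene_id`, `snp_id`, `beta`) or a
#'   path to `truth.tsv`.
#' @param out_dir optional directory; when given, writes
#'   `evaluation_emp_p.tsv`, `evaluation_norm.tsv` and a readable
#'   `evaluation.txt`.
#' @return list with `emp_p` and `norm` components; each holds a
#'   `table` (per-method overall mean/sd with `best` flag) and
#'   `per_gene` (per-method list of causative per-gene summaries).
#' @export
run_evaluation <- function(scores, truth, out_dir = NULL) {
  if (is.character(scores))
    scores <- utils::read.table(scores, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (is.character(truth))
    truth <- utils::read.table(truth, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  causative <- unique(truth$gene_id)
  methods <- unique(scores$method)
  eval_one <- function(rank_col) {
    per_gene <- list()
    rows <- lapply(methods, function(m) {
      sub <- scores[scores$method == m, ]
      rk <- do.call(cbind, lapply(split(sub, sub$replicate_id),
                                  function(d) {
                                    v <- d[[rank_col]]
                                    names(v) <- d$gene_id
                                    v
                                  }))
      ev <- evaluate_methods(rk, causative)
      per_gene[[m]] <<- ev$per_gene
      data.frame(method = m, mean_avg_rank = ev$overall["mean"],
                 sd_avg_rank = ev$overall["sd"], stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab$best <- tab$mean_avg_rank == min(tab$mean_avg_rank)
    list(table = tab, per_gene = per_gene)
  }
  out <- list(emp_p = eval_one("rank"), norm = eval_one("rank_norm"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out$emp_p$table,
                       file.path(out_dir, "evaluation_emp_p.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$norm$table,
                       file.path(out_dir, "evaluation_norm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    txt <- c("Causative-gene rank evaluation (smaller is better)",
             "", "Ranking by empirical P-value:",
             utils::capture.output(print(out$emp_p$table)),
             "", "Ranking by normalized score:",
             utils::capture.output(print(out$norm$table)))
    writeLines(txt, file.path(out_dir, "evaluation.txt"))
  }
  out
}
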