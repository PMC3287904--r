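#' Configuration for the synthetic genotype/trait simulator
#'
#' The generator emulates the regime of large exonic SNP panels: a
#' heavily right-skewed MAF spectrum dominated by rare variants, small
#' genes with a long right tail of SNP counts, and pairwise LD that
#' decays with the ordinal distance between SNPs.  Genotypes come from
#' a latent-Gaussian threshold model: two AR(1) latent haplotype
#' vectors per individual are thresholded at each SNP's MAF quantile,
#' so target MAF and LD decay are controlled independently.
#'
#' @param n_individuals number of individuals.
#' @param n_genes number of genes.
#' @param snps_per_gene `NULL` for the default right-skewed sampler
#'   (median 2), a single integer (every gene identical), or an integer
#'   vector of length `n_genes`.
#' @param snp_cap maximum SNPs per gene.
#' @param maf_range range of target MAFs (log-uniform draws).
#' @param maf_rare_frac fraction of SNPs drawn from the rare stratum
#'   below `maf_split`; the mixture reproduces the rare-dominated
#'   spectrum (median MAF of a few per-mille).
#' @param maf_split boundary between the rare and common strata.
#' @param ld_decay AR(1) parameter `rho` of the latent haplotype
#'   process; latent correlation at ordinal distance `d` is `rho^d`.
#' @param causal_genes number of causative genes.
#' @param causal_snps_per_gene causative SNPs within each causative
#'   gene.
#' @param causal_min_snps minimum SNP count of a causative gene.
#'   Causative genes in the exonic panels this generator emulates are
#'   predominantly multi-SNP genes, and the sparse-weak aggregation the
#'   HC-family methods exploit only exists when the causative SNPs sit
#'   among several non-causative ones; genes this small are the minP
#'   regime, not the HC regime.
#' @param causal_maf_range target MAF range for causative SNPs
#'   (rare but observable).
#' @param causal_adjacent place the causative SNPs of a gene at
#'   consecutive positions, so they sit in mutual LD (causative
#'   variants cluster within genes; adjacency gives the
#'   correlation-aware methods real structure to use).
#' @param effect_size per-minor-allele effect magnitude on the trait
#'   scale.
#' @param effect_sign `"random"` draws each causative SNP's effect
#'   direction independently (LD phase and effect direction are
#'   unrelated in real data); `"positive"` makes all effects
#'   risk-increasing on the minor allele.
#' @param trait_model `"linear-gaussian"`, `"liability-binary"` or
#'   `"logistic-binary"`.
#' @param prevalence case fraction for binary traits.
#' @param n_replicates trait replicates (genotypes fixed; only noise is
#'   redrawn).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 697L, n_genes = 200L,
                       snps_per_gene = NULL, snp_cap = 205L,
                       maf_range = c(7e-4, 0.5), maf_rare_frac = 0.8,
                       maf_split = 0.01, ld_decay = 0.8,
                       causal_genes = 5L, causal_snps_per_gene = 2L,
                       causal_min_snps = 10L,
                       causal_maf_range = c(0.005, 0.05),
                       causal_adjacent = TRUE,
                       effect_size = 0.5,
                       effect_sign = c("random", "positive"),
                       trait_model = c("linear-gaussian",
                                       "liability-binary",
                                       "logistic-binary"),
                       prevalence = 0.3, n_replicates = 50L, seed = 1L) {
  trait_model <- match.arg(trait_model)
  effect_sign <- match.arg(effect_sign)
  stopifnot(n_individuals >= 2, n_genes >= 1, ld_decay >= 0, ld_decay < 1,
            prevalence > 0, prevalence < 1, n_replicates >= 1,
            causal_genes >= 0, is.finite(effect_size))
  structure(as.list(environment()), class = "sim_config")
}

## Right-skewed SNPs-per-gene sampler: geometric bulk (median 2) plus a
## 10% heavy-tail component for the occasional large gene.
.sample_gene_sizes <- function(m, cap) {
  base <- 1L + stats::rgeom(m, 0.35)
  tail <- ifelse(stats::runif(m) < 0.1, stats::rgeom(m, 0.08), 0L)
  pmin(base + tail, cap)
}

## Two-stratum log-uniform MAF sampler.
.sample_mafs <- function(m, cfg) {
  rare <- stats::runif(m) < cfg$maf_rare_frac
  lo <- log(cfg$maf_range[1]); mid <- log(cfg$maf_split)
  hi <- log(cfg$maf_range[2])
  maf <- numeric(m)
  maf[rare] <- exp(stats::runif(sum(rare), lo, mid))
  maf[!rare] <- exp(stats::runif(sum(!rare), mid, hi))
  maf
}

## One latent AR(1) haplotype panel: n x L standard-normal matrix with
## column-to-column correlation rho.
.latent_haplotypes <- function(n, L, rho) {
  Z <- matrix(stats::rnorm(n * L), n, L)
  if (L > 1 && rho > 0) {
    for (j in 2:L) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
  }
  Z
}

#' Simulate an LD-structured genotype panel with known causative genes
#'
#' Per gene, target MAFs are drawn, two latent AR(1) haplotype vectors
#' per individual are thresholded at each SNP's MAF quantile to give
#' minor-allele indicators, and the genotype is stored in major-allele
#' coding (`2 - minor count`).  Monomorphic columns (no observed minor
#' allele, common for very rare target MAFs) are dropped, as real
#' variant panels only contain polymorphic sites; genes that lose every
#' SNP are dropped too.  Causative genes are chosen among genes with
#' enough SNPs; their causative SNPs get target MAFs redrawn from
#' `causal_maf_range` (rare but observable) and effect `effect_size`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]), `map` (SNP to
#'   gene data frame), `truth` (data frame `gene_id`, `snp_id`,
#'   `beta`), and `target_maf` (named vector of target MAFs for the
#'   retained SNPs).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  sizes <- if (is.null(cfg$snps_per_gene)) {
    .sample_gene_sizes(cfg$n_genes, cfg$snp_cap)
  } else if (length(cfg$snps_per_gene) == 1L) {
    rep(as.integer(cfg$snps_per_gene), cfg$n_genes)
  } else {
    stopifnot(length(cfg$snps_per_gene) == cfg$n_genes)
    as.integer(cfg$snps_per_gene)
  }
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))

  ## causative genes need room for their causative SNPs
  min_L <- max(cfg$causal_snps_per_gene, cfg$causal_min_snps, 1L)
  eligible <- which(sizes >= min_L)
  if (cfg$causal_genes > 0 && length(eligible) < cfg$causal_genes) {
    short <- setdiff(seq_len(cfg$n_genes), eligible)
    grow <- short[seq_len(cfg$causal_genes - length(eligible))]
    sizes[grow] <- min_L
    eligible <- which(sizes >= min_L)
  }
  causal_gene_idx <- if (cfg$causal_genes > 0)
    sort(sample(eligible, cfg$causal_genes)) else integer(0)

  cols <- list(); snp_ids <- character(0); gene_of <- character(0)
  target_maf <- numeric(0)
  truth <- data.frame(gene_id = character(0), snp_id = character(0),
                      beta = numeric(0), stringsAsFactors = FALSE)
  for (g in seq_len(cfg$n_genes)) {
    L <- sizes[g]
    maf <- .sample_mafs(L, cfg)
    ids <- sprintf("%s_snp%03d", gene_ids[g], seq_len(L))
    c_snp <- integer(0)
    if (g %in% causal_gene_idx) {
      k <- cfg$causal_snps_per_gene
      c_snp <- if (isTRUE(cfg$causal_adjacent) && L >= k) {
        start <- sample(seq_len(L - k + 1), 1)
        start:(start + k - 1)
      } else sort(sample(seq_len(L), k))
      maf[c_snp] <- exp(stats::runif(length(c_snp),
                                     log(cfg$causal_maf_range[1]),
                                     log(cfg$causal_maf_range[2])))
      sgn <- if (cfg$effect_sign == "random")
        sample(c(-1, 1), length(c_snp), replace = TRUE) else
        rep(1, length(c_snp))
      truth <- rbind(truth, data.frame(gene_id = gene_ids[g],
                                       snp_id = ids[c_snp],
                                       beta = sgn * cfg$effect_size,
                                       stringsAsFactors = FALSE))
    }
    thr <- stats::qnorm(maf)
    H1 <- .latent_haplotypes(n, L, cfg$ld_decay)
    H2 <- .latent_haplotypes(n, L, cfg$ld_decay)
    minor <- (sweep(H1, 2, thr, "<") * 1L) + (sweep(H2, 2, thr, "<") * 1L)
    cols[[g]] <- 2L - minor
    snp_ids <- c(snp_ids, ids)
    gene_of <- c(gene_of, rep(gene_ids[g], L))
    target_maf <- c(target_maf, maf)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- snp_ids

  ## code by the empirically major allele (observed frequency decides,
  ## as when loading real data) and keep polymorphic sites only
  X <- .recode_major(X)
  poly <- apply(X, 2, function(v) max(v) > min(v))
  X <- X[, poly, drop = FALSE]
  snp_ids <- snp_ids[poly]; gene_of <- gene_of[poly]
  target_maf <- target_maf[poly]
  truth <- truth[truth$snp_id %in% snp_ids, , drop = FALSE]

  map <- data.frame(snp_id = snp_ids, gene_id = gene_of,
                    position = stats::ave(seq_along(snp_ids), gene_of,
                                          FUN = seq_along),
                    stringsAsFactors = FALSE)
  g <- genotype_matrix(X, snp_ids, gene_of)
  names(target_maf) <- snp_ids
  list(genotypes = g, map = map, truth = truth, target_maf = target_maf,
       config = cfg)
}

#' Simulate trait replicates over a fixed genotype panel
#'
#' Quantitative traits: `y = sum_j beta_j * minor_count_j + N(0, 1)`
#' noise.  Liability-binary traits threshold the same latent trait at
#' its empirical `(1 - prevalence)` quantile; logistic-binary traits
#' draw Bernoulli outcomes with `logit(p) = logit(prevalence) +
#' genetic`.  All replicates share the genotypes and redraw only the
#' noise, mirroring study designs where many simulated trait replicates
#' overlay one genotype panel.
#'
#' @param sim result of [simulate_genotypes()].
#' @param n_replicates number of replicates (default from the config).
#' @param seed RNG seed (default `config seed + 1`).
#' @return list of [phenotype()] vectors, one per replicate.
#' @export
simulate_traits <- function(sim, n_replicates = NULL, seed = NULL) {
  cfg <- sim$config
  if (is.null(n_replicates)) n_replicates <- cfg$n_replicates
  if (is.null(seed)) seed <- cfg$seed + 1L
  set.seed(seed)
  n <- nrow(sim$genotypes$values)
  genetic <- numeric(n)
  if (nrow(sim$truth) > 0) {
    Xc <- sim$genotypes$values[, sim$truth$snp_id, drop = FALSE]
    genetic <- drop((2 - Xc) %*% sim$truth$beta)   # minor-allele counts
  }
  trait_type <- if (cfg$trait_model == "linear-gaussian")
    "quantitative" else "binary"
  lapply(seq_len(n_replicates), function(r) {
    noise <- stats::rnorm(n)
    y <- switch(cfg$trait_model,
      "linear-gaussian" = genetic + noise,
      "liability-binary" = {
        liab <- genetic + noise
        as.numeric(liab >= stats::quantile(liab, 1 - cfg$prevalence))
      },
      "logistic-binary" = {
        p <- stats::plogis(stats::qlogis(cfg$prevalence) + genetic)
        stats::rbinom(n, 1, p)
      })
    phenotype(y, trait_type, replicate_id = r)
  })
}

#' Write a ready-made synthetic dataset to disk
#'
#' Two presets.  `"tiny"`: 200 individuals, 50 genes of at most 10
#' SNPs, mostly common variants, 20 replicates -- scores in seconds and
#' is the default end-to-end test bed; two duplicate SNP columns are
#' planted so the cleaning step has real work to do.  `"gaw17-like"`:
#' 697 individuals, 500 genes, the rare-dominated MAF spectrum and 200
#' replicates -- the full study regime.  Files written: an allele-count
#' table, the SNP-to-gene map, one phenotype TSV per replicate, and a
#' `truth.tsv` (`gene_id snp_id beta`).
#'
#' @param preset `"tiny"` or `"gaw17-like"`.
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed.
#' @return invisibly, a list with the file paths and the in-memory
#'   simulation object.
#' @export
make_fixture <- function(preset = c("tiny", "gaw17-like"), out_dir,
                         seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (preset == "tiny") {
    sim_config(n_individuals = 200L, n_genes = 50L, snp_cap = 10L,
               maf_range = c(0.005, 0.5), maf_rare_frac = 0.5,
               maf_split = 0.05, ld_decay = 0.6, causal_genes = 5L,
               causal_snps_per_gene = 2L, causal_min_snps = 5L,
               causal_maf_range = c(0.05, 0.3),
               effect_size = 0.5, n_replicates = 20L, seed = seed)
  } else {
    sim_config(n_individuals = 697L, n_genes = 500L,
               n_replicates = 200L, seed = seed)
  }
  sim <- simulate_genotypes(cfg)
  if (preset == "tiny") sim <- .plant_duplicates(sim, k = 2L)
  traits <- simulate_traits(sim)

  paths <- list(
    genotypes = file.path(out_dir, "genotypes.tsv"),
    map = file.path(out_dir, "gene_map.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    phenotypes = file.path(out_dir,
                           sprintf("pheno_rep%03d.tsv",
                                   seq_along(traits))))
  write_allele_count_table(sim$genotypes, paths$genotypes)
  utils::write.table(sim$map, paths$map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (r in seq_along(traits)) {
    tab <- data.frame(sample = sim$genotypes$sample_ids,
                      value = as.numeric(traits[[r]]))
    utils::write.table(tab, paths$phenotypes[r], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(paths = paths, sim = sim, traits = traits,
                 trait_type = attr(traits[[1]], "trait_type")))
}

## Duplicate k SNP columns inside their genes (appended right after the
## original, same gene) so that cleaning has planted linear dependence
## to remove.
.plant_duplicates <- function(sim, k = 2L) {
  g <- sim$genotypes
  idx <- round(seq(1, ncol(g$values), length.out = k + 2))[2:(k + 1)]
  values <- g$values; snp_ids <- g$snp_ids; gene_ids <- g$gene_ids
  for (i in rev(sort(idx))) {
    values <- cbind(values[, 1:i, drop = FALSE],
                    values[, i, drop = FALSE],
                    if (i < ncol(values))
                      values[, (i + 1):ncol(values), drop = FALSE])
    snp_ids <- c(snp_ids[1:i], paste0(snp_ids[i], "_dup"),
                 if (i < length(snp_ids)) snp_ids[(i + 1):length(snp_ids)])
    gene_ids <- c(gene_ids[1:i], gene_ids[i],
                  if (i < length(gene_ids)) gene_ids[(i + 1):length(gene_ids)])
  }
  sim$genotypes <- genotype_matrix(values, snp_ids, gene_ids,
                                   g$sample_ids)
  sim$map <- data.frame(snp_id = snp_ids, gene_id = gene_ids,
                        position = stats::ave(seq_along(snp_ids), gene_ids,
                                              FUN = seq_along),
                        stringsAsFactors = FALSE)
  sim
}
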