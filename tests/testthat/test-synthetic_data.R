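test_that("genotype simulation is deterministic given the seed", {
  cfg <- sim_config(n_individuals = 100, n_genes = 10, seed = 61)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$genotypes$values, s2$genotypes$values)
  expect_identical(s1$truth, s2$truth)
  t1 <- simulate_traits(s1)
  t2 <- simulate_traits(s2)
  expect_identical(as.numeric(t1[[3]]), as.numeric(t2[[3]]))
})

test_that("LD decays with ordinal distance as the latent AR(1) dictates", {
  base <- list(n_individuals = 2000, n_genes = 30, snps_per_gene = 5L,
               maf_range = c(0.1, 0.5), maf_rare_frac = 0,
               causal_genes = 0L, seed = 62)
  s_ind <- simulate_genotypes(do.call(sim_config, c(base, ld_decay = 0)))
  med_ind <- summarize_dataset(s_ind$genotypes)$ld_by_distance$median
  expect_lt(med_ind["d1"], 0.08)        # independence: |r| near zero

  s_ld <- simulate_genotypes(do.call(sim_config, c(base, ld_decay = 0.8)))
  med_ld <- summarize_dataset(s_ld$genotypes)$ld_by_distance$median
  expect_gt(med_ld["d1"], med_ld["d2"])
  expect_gt(med_ld["d2"], med_ld["d3"])
})

test_that("empirical MAFs track their targets within binomial error", {
  cfg <- sim_config(n_individuals = 2000, n_genes = 40,
                    snps_per_gene = 3L, maf_range = c(0.01, 0.5),
                    maf_rare_frac = 0.5, maf_split = 0.05,
                    ld_decay = 0.5, causal_genes = 0L, seed = 63)
  sim <- simulate_genotypes(cfg)
  emp <- colSums(2L - sim$genotypes$values) / (2 * cfg$n_individuals)
  target <- sim$target_maf
  sdev <- sqrt(target * (1 - target) / (2 * cfg$n_individuals))
  frac_in <- mean(abs(emp - target) <= 3 * sdev)
  expect_gte(frac_in, 0.95)
})

test_that("null traits are independent of genotypes; planted signals dominate", {
  cfg0 <- sim_config(n_individuals = 300, n_genes = 10,
                     snps_per_gene = 4L, maf_range = c(0.05, 0.5),
                     maf_rare_frac = 0, causal_genes = 0L,
                     n_replicates = 5, seed = 64)
  sim0 <- simulate_genotypes(cfg0)
  tr0 <- simulate_traits(sim0)
  blocks <- gene_blocks(sim0$genotypes)
  stats <- unlist(lapply(blocks, function(b)
    marginal_stats(b, tr0[[1]])$stat))
  expect_lt(abs(mean(stats)), 0.3)

  # one common strong causal SNP attains the smallest marginal P
  cfg1 <- sim_config(n_individuals = 500, n_genes = 8, snps_per_gene = 5L,
                     maf_range = c(0.1, 0.5), maf_rare_frac = 0,
                     causal_genes = 1L, causal_snps_per_gene = 1L,
                     causal_min_snps = 1L, causal_maf_range = c(0.2, 0.3),
                     effect_size = 1, effect_sign = "positive",
                     n_replicates = 20, seed = 65)
  sim1 <- simulate_genotypes(cfg1)
  tr1 <- simulate_traits(sim1)
  hit <- vapply(tr1, function(y) {
    p <- vapply(seq_along(sim1$genotypes$snp_ids), function(j)
      marginal_t(sim1$genotypes$values[, j], as.numeric(y))$pvalue, 0)
    sim1$genotypes$snp_ids[which.min(p)] == sim1$truth$snp_id
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("binary traits honor the prevalence and liability thresholding", {
  cfg <- sim_config(n_individuals = 400, n_genes = 5, snps_per_gene = 3L,
                    maf_range = c(0.1, 0.5), maf_rare_frac = 0,
                    causal_genes = 0L, trait_model = "liability-binary",
                    prevalence = 0.3, n_replicates = 4, seed = 66)
  sim <- simulate_genotypes(cfg)
  tr <- simulate_traits(sim)
  expect_true(all(vapply(tr, function(y) all(y %in% c(0, 1)), TRUE)))
  expect_equal(mean(tr[[1]]), 0.3, tolerance = 0.01)
  expect_equal(attr(tr[[1]], "trait_type"), "binary")
})

test_that("tiny fixture is reproducible, parseable, and its planted duplicates clean away", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  fx1 <- make_fixture("tiny", d1, seed = 5)
  fx2 <- make_fixture("tiny", d2, seed = 5)
  expect_identical(readLines(fx1$paths$genotypes),
                   readLines(fx2$paths$genotypes))
  expect_identical(readLines(fx1$paths$truth), readLines(fx2$paths$truth))

  g <- read_genotypes(fx1$paths$genotypes, "table", fx1$paths$map)
  expect_identical(unname(g$values), unname(fx1$sim$genotypes$values))

  dup_ids <- grep("_dup$", g$snp_ids, value = TRUE)
  expect_length(dup_ids, 2)
  blocks <- gene_blocks(g)
  removed <- unlist(lapply(blocks, `[[`, "removed_snp_ids"))
  expect_true(all(dup_ids %in% removed))
  expect_true(all(vapply(blocks, function(b)
    hcgene:::.num_rank(b$X) == ncol(b$X), TRUE)))
})

test_that("gaw17-like panel reproduces the rare-variant regime", {
  cfg <- sim_config(n_genes = 500L, seed = 8)   # 697 individuals, rare MAF mix
  sim <- simulate_genotypes(cfg)
  expect_lt(median(sim$genotypes$maf), 0.02)
  expect_equal(nrow(sim$genotypes$values), 697)
  szs <- table(sim$genotypes$gene_ids)
  expect_lte(median(szs), 4)                    # small genes, right-skewed
  expect_gt(max(szs), median(szs))
})

test_that("gene scores are invariant under joint permutation of individuals", {
  set.seed(67)
  cfg <- sim_config(n_individuals = 120, n_genes = 6, snps_per_gene = 4L,
                    maf_range = c(0.1, 0.5), maf_rare_frac = 0,
                    causal_genes = 0L, n_replicates = 1, seed = 68)
  sim <- simulate_genotypes(cfg)
  y <- simulate_traits(sim)[[1]]
  blk <- gene_blocks(sim$genotypes)[[1]]
  perm <- sample(120)
  blk_p <- gene_block(blk$gene_id, blk$X[perm, ], blk$snp_ids, blk$maf)
  expect_equal(hc_statistic(marginal_stats(blk, y)$pvalue),
               hc_statistic(marginal_stats(blk_p,
                 phenotype(as.numeric(y)[perm], "quantitative"))$pvalue))
  expect_equal(ridge_score(blk$X, as.numeric(y))$score,
               ridge_score(blk_p$X, as.numeric(y)[perm])$score)
})
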