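test_that("MAF is the folded allele frequency", {
  expect_equal(compute_maf(matrix(2, 5, 1)), 0)
  expect_equal(compute_maf(matrix(c(2, 1, 1, 0), 4, 1)), 0.5)

  set.seed(4)
  x <- matrix(sample(0:2, 60, replace = TRUE), 20, 3)
  tally <- apply(x, 2, function(col) {
    f <- sum(col) / (2 * length(col))   # brute-force allele tally
    min(f, 1 - f)
  })
  expect_equal(compute_maf(x), tally)
})

test_that("major-allele recoding flips minor-coded columns and is MAF-invariant", {
  tmp <- tempfile(fileext = ".tsv")
  tab <- data.frame(sample = c("a", "b", "c"), snpA = c(0L, 0L, 1L))
  write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(snp_id = "snpA", gene_id = "g1", position = 1)
  g <- read_genotypes(tmp, "table", map)
  expect_equal(unname(g$values[, 1]), c(2L, 2L, 1L))
  expect_equal(unname(g$maf), 1 / 6)

  # coding involution: x -> 2 - x leaves the MAF unchanged
  x <- matrix(c(0L, 1L, 2L, 1L), 4, 1)
  expect_equal(compute_maf(x), compute_maf(2L - x))
})

test_that("biallelic VCF sites are read with ties broken toward REF", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t")), vcf)
  map <- data.frame(snp_id = "rs1", gene_id = "g1", position = 1)
  g <- read_genotypes(vcf, "vcf", map)
  # ALT frequency is exactly 0.5: REF wins the tie and is counted
  expect_equal(unname(g$values[, 1]), c(2L, 1L, 0L))

  multi <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("1", "100", "rs1", "A", "G,T", ".", ".", ".", "GT", "0/1",
          sep = "\t")), multi)
  expect_error(read_genotypes(multi, "vcf", map), "multi-allelic")
})

test_that("allele-count tables round-trip exactly", {
  set.seed(7)
  g <- genotype_matrix(matrix(sample(0:2, 40, replace = TRUE,
                                     prob = c(0.05, 0.15, 0.8)), 10, 4),
                       snp_ids = paste0("s", 1:4),
                       gene_ids = c("g1", "g1", "g2", "g2"))
  tmp <- tempfile(fileext = ".tsv")
  write_allele_count_table(g, tmp)
  map <- data.frame(snp_id = g$snp_ids, gene_id = g$gene_ids,
                    position = c(1, 2, 1, 2))
  g2 <- read_genotypes(tmp, "table", map)
  expect_identical(unname(g2$values), unname(g$values))
  expect_identical(g2$snp_ids, g$snp_ids)
})

test_that("cleaning removes dependent columns smallest-MAF-first, span preserved", {
  set.seed(21)
  # duplicated column: the rarer copy goes
  x1 <- rbinom(60, 2, 0.9)
  X <- cbind(a = x1, b = x1)
  blk <- gene_block("g", X, c("a", "b"), c(0.01, 0.10))
  cl <- clean_gene(blk)
  expect_identical(cl$removed_snp_ids, "a")
  expect_identical(cl$snp_ids, "b")

  # full-rank block is untouched
  b2 <- rand_block(50, 3, seed = 2)
  cl2 <- clean_gene(b2)
  expect_identical(cl2$snp_ids, b2$snp_ids)
  expect_length(cl2$removed_snp_ids, 0)

  # col3 = col1 + col2, col3 rarest -> col3 removed, span unchanged
  c1 <- rbinom(80, 1, 0.4); c2 <- rbinom(80, 1, 0.3)
  X3 <- cbind(s1 = c1, s2 = c2, s3 = c1 + c2)
  blk3 <- gene_block("g", X3, c("s1", "s2", "s3"), c(0.2, 0.3, 0.001))
  cl3 <- clean_gene(blk3)
  expect_identical(cl3$removed_snp_ids, "s3")
  fit <- lm.fit(cl3$X, X3[, "s3"])
  expect_lt(sqrt(sum(fit$residuals^2)), 1e-8)

  # idempotence
  expect_identical(clean_gene(cl3)$snp_ids, cl3$snp_ids)
})

test_that("all-constant genes become untestable sentinels", {
  blk <- gene_block("g", matrix(2L, 10, 2), c("a", "b"), c(0, 0))
  cl <- clean_gene(blk)
  expect_false(cl$testable)
  expect_equal(ncol(cl$X), 0)
  expect_setequal(cl$removed_snp_ids, c("a", "b"))
})

test_that("MAF ties during cleaning drop the largest column index", {
  x <- rbinom(40, 1, 0.5)
  X <- cbind(s1 = x, s2 = x)
  blk <- gene_block("g", X, c("s1", "s2"), c(0.1, 0.1))
  expect_identical(clean_gene(blk)$removed_snp_ids, "s2")
})

test_that("dataset summaries: within-gene correlation by ordinal distance", {
  # single-SNP gene contributes no pairs; duplicated adjacent pair has |r| = 1
  set.seed(3)
  x <- rbinom(30, 2, 0.6)
  g <- genotype_matrix(cbind(x, x, rbinom(30, 2, 0.5)),
                       snp_ids = c("a", "b", "c"),
                       gene_ids = c("g1", "g1", "g2"))
  s <- summarize_dataset(g)
  expect_equal(s$ld_by_distance$values$d1, 1)
  expect_length(s$ld_by_distance$values$d2, 0)

  # AR(1)-generated panel: median |r| decays from distance 1 to 3
  cfg <- sim_config(n_individuals = 800, n_genes = 40, snps_per_gene = 6L,
                    maf_range = c(0.1, 0.5), maf_rare_frac = 0,
                    ld_decay = 0.8, causal_genes = 0L, seed = 5)
  sim <- simulate_genotypes(cfg)
  med <- summarize_dataset(sim$genotypes)$ld_by_distance$median
  expect_gt(med["d1"], med["d3"])
})

test_that("missing genotypes are mean-imputed and all-missing columns dropped", {
  tmp <- tempfile(fileext = ".tsv")
  tab <- data.frame(sample = c("a", "b", "c", "d"),
                    s1 = c(2L, 2L, NA, 0L), s2 = c(NA, NA, NA, NA))
  write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(snp_id = c("s1", "s2"), gene_id = "g1",
                    position = 1:2)
  expect_warning(
    suppressMessages(g <- read_genotypes(tmp, "table", map)),
    "all-missing")
  expect_equal(ncol(g$values), 1)
  expect_false(anyNA(g$values))
  expect_equal(unname(g$values[3, 1]), 1L)  # round(mean(2,2,0)) = 1
})
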