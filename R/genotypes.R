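#' Construct a genotype matrix object
#'
#' Container for an individuals-by-SNPs matrix of major-allele counts
#' together with SNP identifiers, per-SNP gene labels and minor allele
#' frequencies.  Genotypes are coded 0/1/2 as the number of copies of the
#' *major* (more frequent) allele, so rare variants show up as values
#' below 2.  SNP order within a gene is genomic order; ordinal distance
#' between SNPs in the same gene is used for LD summaries and for the
#' banded whitening transform.
#'
#' @param values integer matrix, individuals x SNPs, entries in {0,1,2}.
#' @param snp_ids character vector of SNP identifiers (one per column).
#' @param gene_ids character vector of gene labels (one per column).
#' @param sample_ids optional individual identifiers (one per row).
#' @return An object of class `genotype_matrix` with fields `values`,
#'   `snp_ids`, `gene_ids`, `sample_ids` and `maf` (computed).
#' @export
genotype_matrix <- function(values, snp_ids, gene_ids, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (anyNA(values))
    stop("genotype matrix contains missing values; impute at read time")
  if (!all(values %in% 0:2))
    stop("genotype entries must be 0, 1 or 2 (major-allele counts)")
  if (length(snp_ids) != ncol(values))
    stop("snp_ids length must equal number of SNP columns")
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length must equal number of SNP columns")
  if (is.null(sample_ids))
    sample_ids <- sprintf("ind%04d", seq_len(nrow(values)))
  colnames(values) <- snp_ids
  rownames(values) <- sample_ids
  obj <- list(values = values,
              snp_ids = as.character(snp_ids),
              gene_ids = as.character(gene_ids),
              sample_ids = as.character(sample_ids),
              maf = compute_maf(values))
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs in %d genes\n",
              nrow(x$values), ncol(x$values), length(unique(x$gene_ids))))
  cat(sprintf("  MAF: median %.4g, max %.4g\n",
              stats::median(x$maf), max(x$maf)))
  invisible(x)
}

#' Minor allele frequency per SNP
#'
#' For a column coded as counts of one allele, the allele frequency is
#' `f = colSums(x) / (2n)`; the MAF is `min(f, 1 - f)`, always in
#' \[0, 0.5\].  The MAF is invariant to which allele the column counts.
#'
#' @param g a `genotype_matrix` or a numeric 0/1/2 matrix.
#' @return numeric vector of per-SNP minor allele frequencies.
#' @export
compute_maf <- function(g) {
  x <- if (inherits(g, "genotype_matrix")) g$values else as.matrix(g)
  f <- colSums(x) / (2 * nrow(x))
  pmin(f, 1 - f)
}

## Recode a 0/1/2 allele-count matrix so every column counts its MAJOR
## allele.  Columns whose counted-allele frequency is below 0.5 are
## flipped (x -> 2 - x); ties stay as given (first/REF allele wins).
.recode_major <- function(x) {
  f <- colSums(x) / (2 * nrow(x))
  flip <- f < 0.5
  if (any(flip)) x[, flip] <- 2L - x[, flip, drop = FALSE]
  x
}

## Mean-impute missing genotype calls per SNP column (rounded to the
## nearest valid count).  Returns the matrix and the imputed fraction.
.impute_mean <- function(x) {
  n_miss <- sum(is.na(x))
  if (n_miss > 0) {
    for (j in which(colSums(is.na(x)) > 0)) {
      m <- round(mean(x[, j], na.rm = TRUE))
      x[is.na(x[, j]), j] <- as.integer(max(0, min(2, m)))
    }
  }
  list(x = x, imputed_fraction = n_miss / length(x))
}

#' Read genotypes from a VCF or an allele-count table
#'
#' Two dialects are supported.  `"table"` is a tab-separated file with a
#' header row `sample snp1 snp2 ...` and one row of 0/1/2 allele counts
#' per individual.  `"vcf"` accepts biallelic records only (multi-allelic
#' sites raise an error naming the offending records) and converts the
#' GT field to ALT-allele dosages before recoding.  In either case
#' columns are recoded so the more frequent allele is the one counted
#' (ties are broken toward the REF / as-given allele), missing calls are
#' mean-imputed per SNP, and all-missing columns are dropped with a
#' warning.  Gene labels come from `gene_map` (see [read_gene_map()]);
#' SNPs absent from the map are dropped.  SNP order within each gene
#' follows the map's position column.
#'
#' @param path path to the genotype file.
#' @param format `"table"` or `"vcf"`.
#' @param gene_map data frame with columns `snp_id`, `gene_id`,
#'   `position`, or a path to such a TSV.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("table", "vcf"), gene_map) {
  format <- match.arg(format)
  if (is.character(gene_map)) gene_map <- read_gene_map(gene_map)
  if (format == "table") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("allele-count table needs a sample column and >= 1 SNP")
    sample_ids <- as.character(tab[[1]])
    x <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(x)) stop("allele-count table cells must be integers")
    snp_ids <- colnames(x)
  } else {
    parsed <- .read_vcf_dosage(path)
    x <- 2 - parsed$x   # count the REF allele so ties resolve toward REF
    snp_ids <- parsed$snp_ids
    sample_ids <- parsed$sample_ids
  }
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    warning(sprintf("dropping %d all-missing SNP column(s): %s",
                    sum(all_missing),
                    paste(snp_ids[all_missing], collapse = ", ")))
    x <- x[, !all_missing, drop = FALSE]
    snp_ids <- snp_ids[!all_missing]
  }
  imp <- .impute_mean(x)
  if (imp$imputed_fraction > 0)
    message(sprintf("imputed %.3f%% of genotype calls to per-SNP means",
                    100 * imp$imputed_fraction))
  x <- .recode_major(imp$x)
  keep <- match(gene_map$snp_id, snp_ids)
  if (all(is.na(keep))) stop("no SNP in the gene map matches the genotype file")
  ok <- !is.na(keep)
  genotype_matrix(x[, keep[ok], drop = FALSE],
                  snp_ids = gene_map$snp_id[ok],
                  gene_ids = gene_map$gene_id[ok],
                  sample_ids = sample_ids)
}

## Minimal biallelic-VCF GT reader.  vcfR is used when installed; a
## plain-text fallback parses uncompressed VCF directly so the reader
## has no hard dependency.
.read_vcf_dosage <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- rbind(vcfR::getFIX(v))   # keep matrix shape for 1-record files
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
      stop("multi-allelic VCF record(s) at: ",
           paste(sprintf("%s:%s", fix[multi, "CHROM"], fix[multi, "POS"]),
                 collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- matrix(gt, nrow = nrow(fix), dimnames = dimnames(gt))
    snp_ids <- fix[, "ID"]
    sample_ids <- colnames(gt)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
    body <- strsplit(lines[-1], "\t")
    sample_ids <- header[-(1:9)]
    alt <- vapply(body, `[[`, "", 5)
    multi <- grepl(",", alt, fixed = TRUE)
    if (any(multi))
      stop("multi-allelic VCF record(s) at: ",
           paste(vapply(body[multi], function(r) paste0(r[1], ":", r[2]), ""),
                 collapse = ", "))
    snp_ids <- vapply(body, `[[`, "", 3)
    gt <- t(vapply(body, function(r) sub(":.*", "", r[-(1:9)]),
                   character(length(sample_ids))))
    colnames(gt) <- sample_ids
  }
  dose <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (any(al == "." | al == "")) return(NA_real_)
      sum(al == "1")
    }, 0)
  }
  x <- t(apply(gt, 1, dose))
  rownames(x) <- snp_ids
  list(x = t(x), snp_ids = snp_ids, sample_ids = sample_ids)
}

#' Write an allele-count table
#'
#' Inverse of `read_genotypes(format = "table")`: a TSV with a header
#' `sample snp...` and one 0/1/2 row per individual, in the matrix's
#' (major-allele) coding.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @export
write_allele_count_table <- function(g, path) {
  tab <- data.frame(sample = g$sample_ids, g$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP-to-gene map
#'
#' Three-column TSV `snp_id gene_id position`; rows are sorted by gene
#' then position so that within-gene SNP order is genomic order.
#'
#' @param path path to the TSV.
#' @return data frame with columns `snp_id`, `gene_id`, `position`.
#' @export
read_gene_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("snp_id", "gene_id", "position")
  if (!all(need %in% names(m)))
    stop("gene map must have columns: ", paste(need, collapse = ", "))
  m[order(m$gene_id, m$position), need]
}

#' Read a phenotype vector
#'
#' Two-column TSV `sample value`.  Binary traits must contain only 0/1;
#' quantitative traits must have positive finite variance.
#'
#' @param path path to the TSV.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param replicate_id integer label attached to the result.
#' @return a `phenotype` object: numeric vector with attributes
#'   `trait_type`, `replicate_id` and names set to sample ids.
#' @export
read_phenotype <- function(path, trait_type = c("quantitative", "binary"),
                           replicate_id = 1L) {
  trait_type <- match.arg(trait_type)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  y <- as.numeric(tab[[2]])
  names(y) <- as.character(tab[[1]])
  phenotype(y, trait_type, replicate_id)
}

#' Construct a phenotype object
#'
#' @param values numeric vector (0/1 for binary traits).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param replicate_id integer replicate label.
#' @return numeric vector of class `phenotype`.
#' @export
phenotype <- function(values, trait_type = c("quantitative", "binary"),
                      replicate_id = 1L) {
  trait_type <- match.arg(trait_type)
  values <- as.numeric(values)
  if (anyNA(values)) stop("phenotype contains missing values")
  if (trait_type == "binary") {
    if (!all(values %in% c(0, 1))) stop("binary trait must be coded 0/1")
  } else {
    if (!is.finite(stats::var(values)) || stats::var(values) <= 0)
      stop("quantitative trait must have positive finite variance")
  }
  structure(values, trait_type = trait_type,
            replicate_id = as.integer(replicate_id), class = "phenotype")
}
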