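# Independent oracles and small fixture builders shared across tests.

# Exhaustive-loop Higher Criticism oracle: literal term-by-term
# evaluation of the standardized observed-minus-expected fraction,
# independent of the package's vectorized implementation.
hc_oracle <- function(p, floor = 1e-10) {
  L <- length(p)
  ps <- sort(p)
  if (all(ps < floor)) ps <- rep(floor, L)
  best <- -Inf
  for (i in seq_len(L)) {
    pi <- ps[i]
    if (pi < floor) next
    term <- if (pi >= 1) {
      if (i == L) 0 else -Inf
    } else {
      sqrt(L) * (i / L - pi) / sqrt(pi * (1 - pi))
    }
    if (term > best) best <- term
  }
  best
}

# Random symmetric positive definite matrix with unit-scale diagonal.
rand_pd <- function(L) {
  A <- matrix(rnorm(L * L), L)
  S <- crossprod(A) / L + diag(L) * 0.5
  S
}

# Random correlation matrix.
rand_corr <- function(L) {
  S <- rand_pd(L)
  d <- sqrt(diag(S))
  S / outer(d, d)
}

# Small genotype block with given MAF targets (common variants so every
# column is polymorphic).
rand_block <- function(n, L, gene_id = "g1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rbinom(n * L, 2, 0.7), n, L)
  while (any(apply(X, 2, function(v) max(v) == min(v))))
    X <- matrix(rbinom(n * L, 2, 0.7), n, L)
  gene_block(gene_id, X, sprintf("s%d", seq_len(L)), compute_maf(X))
}

# Null panel used by calibration tests: common-variant genes, no causal
# signal, quantitative trait replicates.
null_panel <- function(n_ind = 200, n_genes = 50, n_rep = 20, seed = 11) {
  cfg <- sim_config(n_individuals = n_ind, n_genes = n_genes,
                    snp_cap = 10L, maf_range = c(0.005, 0.5),
                    maf_rare_frac = 0.5, maf_split = 0.05,
                    ld_decay = 0.6, causal_genes = 0L,
                    n_replicates = n_rep, seed = seed)
  sim <- simulate_genotypes(cfg)
  list(sim = sim, traits = simulate_traits(sim))
}
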