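---
title: "Gene-based Higher Criticism scoring: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based Higher Criticism scoring: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A gene groups SNPs that are physically close, so their genotypes are
correlated (linkage disequilibrium, LD) and their causal effects — when
the gene is causal at all — tend to be sparse and weak: a couple of
variants with small population-level associations among many neutral
ones.  Single-SNP scans lose power in this regime, and naive
multivariate models are destabilized by rare alleles.  `hcgene` scores
each gene as a unit, with six methods spanning the design space from
"take the best SNP" to "whiten, then look at the whole distribution of
evidence":

* **minP** — the smallest marginal P-value in the gene (t test for
  quantitative traits, Armitage-type trend/score statistic for binary
  traits).  Smaller is more significant.
* **ridge** — the residual sum of squares of a ridge regression of the
  trait on all SNPs of the gene, at a penalty chosen by generalized
  cross-validation.  Smaller (better fit) is more significant.
* **HC** — the Higher Criticism statistic on the gene's ordered
  marginal P-values `p_(1) <= ... <= p_(L)`:

  `HC = max_i sqrt(L) * (i/L - p_(i)) / sqrt(p_(i) (1 - p_(i)))`,

  the largest standardized excess of observed small P-values over their
  null expectation.  HC is the classic detector of sparse, weak
  signals.
* **iHC** — HC after *innovation*: the SNP coefficients are estimated
  jointly (least squares for quantitative traits with the error
  variance fixed at 1, logistic maximum likelihood for binary traits),
  then multiplied by the banded, column-normalized inverse Cholesky
  factor of their covariance.  Banding (bandwidth `b = floor(log L)`,
  natural log, at least 1) exploits correlation that decays with SNP
  distance.
* **eHC** — HC after exact eigen-decomposition whitening
  `Z = Lambda^{-1/2} Q' beta_hat`, which gives `Z` identity covariance.
* **iHCM** — the iHC transform applied to the *marginal* statistics
  with an estimated correlation matrix in place of the joint
  covariance.  Marginal statistics stay stable for rare variants where
  joint logistic estimation separates, which is the point of this
  variant.

No method's raw statistic is comparable across genes (they differ in
`L` and LD), so all cross-gene statements go through a permutation
null.

## Permutation calibration and rank evaluation

The response is shuffled `J` times (default 10,000); in each
permutation the same shuffled response is scored for every gene and
method, preserving the cross-gene dependence of the null.  A gene's
observed statistic `S_i` is then summarized two ways:

* empirical P-value, add-one convention:
  `(1 + #{j : S*_ij at least as extreme as S_i}) / (J + 1)` — never 0,
  ties count as extreme, orientation respected per method;
* normalized score `(S_i - mean(S*_i)) / sd(S*_i)`, sign-flipped for
  smaller-is-better methods so larger always means more significant.

Trait replicates overlay one genotype panel, so one replicate's
permutation null calibrates all replicates.  This sharing is exact only
for statistics that are invariant to the response scale; ridge SSR and
the sigma^2 = 1 joint-coefficient scores are not.  The package
therefore standardizes each quantitative replicate to zero mean and
unit variance before scoring.  Within a replicate this is a monotone
rescaling (gene ranking unchanged, permutation null unchanged, since a
permutation never changes the scale); across replicates it removes the
sample-variance fluctuation that would otherwise shift every
scale-dependent score of a replicate against the shared null.  Without
it, the empirical P-values of the ridge score on a null panel are
grossly non-uniform (Kolmogorov–Smirnov distance near 0.9).

Methods are compared by the ranks of known causative genes: rank 1 is
most significant, ties get average ranks, untestable genes get the
worst rank.  For each method we report, per causative gene, the mean
and SD of its rank over replicates, and overall the mean and SD of the
replicate-wise average causative rank.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p_floor` | `1e-10` | lower end of the HC search range; replaces the classical `1/L` bound, which is useless for 2-SNP genes. Order statistics below the floor are excluded; if all lie below, they are clamped to the floor. |
| bandwidth `b` | `max(1, floor(log L))` | retained sub-diagonals of the whitener; `log` is natural, `L` is the gene's SNP count (the matrix being trimmed is `L x L`). For `L <= 7`, `b = 1` and the banded whitener collapses to the identity — small genes are scored as if independent. |
| ridge grid | `{0} + 101` log-spaced points in `[1e-3, 50]` | GCV is minimized over this grid; ties go to the smallest penalty. GCV (not fold CV) keeps the permutation engine deterministic. |
| logistic ridge `epsilon` | `1e-4` | stabilization added to the Fisher information when separation (common with rare variants) derails the unpenalized fit; affected genes are flagged `stabilized`. |
| `J` | 10,000 | permutations; tests and examples use 300–2,000 to keep runtimes in seconds-to-minutes. |
| iHCM correlation | replicates | Pearson correlation of the marginal statistics across trait replicates (needs >= 3; falls back to genotype correlation with a message). Replicate estimation removes each SNP's mean statistic, so causal mean-shifts do not contaminate the estimate. |

## Numerical choices

* Rank detection in cleaning uses singular values above `1e-10` of the
  largest: genotypes are integers, so exact dependence is the target.
  Rank is judged on the intercept-augmented design `[1, X]` — every
  downstream model contains an intercept, so SNPs summing to a constant
  are as degenerate as duplicates.  Monomorphic columns are removed
  first for the same reason.  Among removable columns, the smallest
  MAF goes first (ties: the largest column index), and removal never
  changes the span of the retained design.
* Eigen-decompositions sort eigenvalues descending and fix each
  eigenvector's sign so its largest-magnitude entry is positive; HC is
  not invariant to the basis chosen inside a degenerate eigenspace, so
  determinism requires pinning it.
* Estimated correlation matrices are projected to positive definiteness
  by clipping eigenvalues at `1e-6` and rescaling to a unit diagonal.
* Empirical P-values of `2*pnorm(-|Z|)` underflow to exact 0 around
  `|Z| > 38`; HC treats an exact 0 as lying below the floor rather
  than rejecting the input.
* At `p = 1` the HC term is taken at its analytic limit (0 for the last
  order statistic, `-Inf` otherwise).

## Design decisions on genuinely open points

* The literature's whitening step normalizes the *columns* of the
  banded matrix; we implement that literally.  Row normalization would
  give each transformed component unit variance, and the remark that
  bandwidth 1 leaves the whitener unchanged is inconsistent with the
  printed banding rule (bandwidth 1 keeps only the diagonal); both
  are left as-written, since the permutation null absorbs any variance
  distortion.
* The binary-trait marginal statistic is the logistic score test in
  Armitage trend form — asymptotically N(0,1) under the null, sign-
  equivariant under allele-coding flips.  Any N(0,1)-calibrated
  statistic would do, because the permutation null is the final
  arbiter.
* Binary traits are scored by the same least-squares ridge as
  quantitative ones (no logistic ridge), keeping the two trait types on
  one code path.
* All regressions include an intercept; genotype columns are not
  centered at load time, so omitting it would leak MAF into every
  statistic.

## The synthetic data generator

`simulate_genotypes()` emulates the regime of large exonic SNP panels:

* **MAF spectrum**: two-stratum log-uniform mixture, 80% in
  `[7e-4, 0.01]` and 20% in `[0.01, 0.5]`, giving a rare-dominated
  spectrum with a median of a few per-mille.  Simulated monomorphic
  columns are dropped (real panels contain only polymorphic sites),
  and columns are recoded to count the empirically major allele.
* **Gene sizes**: geometric bulk (median 2 SNPs) plus a 10% heavy-tail
  component, capped at 205.
* **LD**: two latent AR(1) Gaussian haplotype vectors per individual
  (`rho = 0.8` between adjacent SNPs), thresholded at each SNP's MAF
  quantile.  Target MAF and LD decay are controlled independently;
  observed genotype correlation decays with ordinal distance, strongly
  attenuated for rare variants — as in real data.
* **Causal architecture**: 5 causative genes with 2 causative SNPs
  each, adjacent (causative variants cluster, and adjacency gives the
  correlation-aware methods real structure), target MAF log-uniform in
  `[0.005, 0.05]`, effect 0.5 per minor allele with random sign (LD
  phase and effect direction are unrelated in real data).  Causative
  genes are drawn among genes with at least 10 SNPs: the sparse-weak
  aggregation that HC-type methods exploit requires causative SNPs
  embedded among several neutral ones, and the causative genes of the
  panels this generator emulates are predominantly multi-SNP genes.
* **Replicates** share the genotypes and redraw only trait noise;
  binary traits threshold the same latent liability at the prevalence
  quantile.

What the generator does **not** reproduce: real haplotype block
structure (the AR(1) latent process has no recombination hotspots),
covariates and population stratification, dosage uncertainty, and the
very-long-range LD of real rare haplotypes.  Passing tests on this
generator therefore demonstrate the statistical machinery — exact
whitening, calibrated nulls, reproducible ranks — not performance on
any particular real cohort.

## Known limitations

* iHC is consistently the weakest method on simulated panels (as it
  was reported to be on real exonic data): the sigma^2 = 1 joint
  covariance plus column normalization make its transformed components
  only loosely N(0,1), and rare variants inflate the joint estimates'
  variance.
* Whitening marginal statistics helps exactly where LD makes marginal
  signals partially cancel (effect signs opposing the LD phase); where
  LD reinforces them, plain HC and minP profit from the leakage and
  iHCM gives some of that back.  On panels with only two causative
  SNPs per gene, the within-gene maximum (minP) is near-optimal and
  the HC family has little room to aggregate; with several causative
  SNPs per gene the ordering flips and HC-type scores win.  Both
  regimes are exercised in the test suite.
* Replicate-based correlation estimation with few replicates (tens)
  injects noise into the whitener of every gene; the genotype-based
  estimator avoids that at the cost of being exact only under the
  null.

## Problem sizes used by the tests

Unit tests run on toy matrices (tens of individuals, `L <= 12`).  The
calibration checks use a 200-individual, 50-gene null panel with 20
replicates at `J = 2000`; the method-comparison checks use
697-individual, 200-gene panels with 50 replicates at `J = 1000` to
`2000`.  These sizes were chosen so the whole suite runs in a few
minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

## A minimal session

```{r example}
library(hcgene)

fx <- make_fixture("tiny", tempfile("fx"))          # writes TSVs + truth
res <- score_dataset(fx$sim$genotypes,
                     fx$traits, J = 2000, seed = 1)
head(res$scores)                                     # gene x method x replicate

ev <- run_evaluation(res$scores, fx$sim$truth)
ev$emp_p$table                                       # mean causative ranks
```
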