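test_that("HC statistic: closed cases and brute-force agreement", {
  L <- 10
  expect_equal(hc_statistic((1:L) / L), 0)        # observed = expected
  expect_equal(hc_statistic(0.5), 1)              # single term
  expect_equal(hc_statistic(c(0.01, 0.2, 0.5, 0.9)),
               2 * (0.25 - 0.01) / sqrt(0.01 * 0.99), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:100) {
    L <- sample(1:30, 1)
    p <- runif(L)
    expect_equal(hc_statistic(p), hc_oracle(p), tolerance = 1e-12)
  }
})

test_that("HC handles the floor and p = 1 limits", {
  # all P-values below the floor: clamped to the floor, max at i = L
  p <- rep(1e-14, 4)
  expect_equal(hc_statistic(p), hc_oracle(p), tolerance = 1e-12)
  expect_equal(hc_statistic(p),
               2 * (1 - 1e-10) / sqrt(1e-10 * (1 - 1e-10)),
               tolerance = 1e-6)
  # mixed: sub-floor entries are excluded from the maximization
  p2 <- c(1e-12, 0.4, 0.9)
  expect_equal(hc_statistic(p2), hc_oracle(p2), tolerance = 1e-12)
  expect_gt(hc_statistic(c(1e-9, 0.4, 0.9)), hc_statistic(p2))
  # p = 1 contributes its analytic limit
  expect_equal(hc_statistic(rep(1, 3)), 0)
  expect_error(hc_statistic(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(hc_statistic(numeric(0)), "empty")
})

test_that("HC is monotone: lowering one P-value never lowers HC", {
  set.seed(32)
  for (i in 1:50) {
    L <- sample(2:20, 1)
    p <- runif(L, min = 1e-9)
    j <- sample(L, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1, 0.1, 0.99)
    expect_gte(hc_statistic(p2), hc_statistic(p) - 1e-12)
  }
})

test_that("Cholesky whitener: closed forms and the whitening identity", {
  expect_equal(cholesky_whitener(diag(3)), diag(3))
  s <- c(2, 0.5, 9)
  expect_equal(cholesky_whitener(diag(s)), diag(1 / sqrt(s)))

  sigma <- matrix(c(1, 0.6, 0.6, 1), 2)
  U <- cholesky_whitener(sigma)
  expect_equal(U, matrix(c(1, -0.75, 0, 1.25), 2), tolerance = 1e-12)
  expect_equal(U %*% sigma %*% t(U), diag(2), tolerance = 1e-12)
  expect_error(cholesky_whitener(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("band trimming follows the k-b+1 <= j <= k index rule", {
  U <- matrix(0, 3, 3); U[lower.tri(U, diag = TRUE)] <- 1
  expect_equal(band_trim(U, 1), diag(3))
  expect_equal(band_trim(U, 3), U)
  expect_equal(band_trim(U, 2),
               matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 1), 3))
  expect_error(band_trim(U, 0), ">= 1")
})

test_that("column normalization yields exact unit columns", {
  expect_equal(column_normalize(diag(4)), diag(4))
  expect_equal(column_normalize(matrix(c(3, 4), 2)), matrix(c(0.6, 0.8), 2))
  set.seed(33)
  V <- column_normalize(matrix(rnorm(36), 6))
  expect_equal(colSums(V^2), rep(1, 6), tolerance = 1e-12)
  expect_error(column_normalize(matrix(c(1, 0, 0, 0), 2)), "zero column")
})

test_that("iHC reduces to HC of normal P-values under identity covariance", {
  set.seed(34)
  beta <- rnorm(5)
  est <- structure(list(beta = beta, sigma = diag(5)),
                   class = "joint_estimate")
  expect_equal(ihc_score(est), hc_statistic(2 * pnorm(-abs(beta))),
               tolerance = 1e-12)
  # L = 1 scalar reduction
  est1 <- structure(list(beta = 1.7, sigma = matrix(1)),
                    class = "joint_estimate")
  expect_equal(ihc_score(est1), hc_statistic(2 * pnorm(-1.7)),
               tolerance = 1e-12)
})

test_that("eHC whitens exactly and is deterministic", {
  est <- structure(list(beta = c(2, 3), sigma = diag(c(4, 1))),
                   class = "joint_estimate")
  # Z = (2/2, 3/1) = (1, 3)
  expect_equal(ehc_score(est), hc_statistic(2 * pnorm(-abs(c(1, 3)))),
               tolerance = 1e-12)

  set.seed(35)
  sigma <- rand_pd(4)
  W <- hcgene:::.eigen_whitener(sigma)
  expect_equal(W %*% sigma %*% t(W), diag(4), tolerance = 1e-8)

  # empirical covariance of Z over draws beta ~ N(0, sigma) is identity
  C <- t(chol(sigma))
  Zs <- W %*% (C %*% matrix(rnorm(4 * 10000), 4))
  expect_equal(unname(cov(t(Zs))), diag(4), tolerance = 0.08)
})

test_that("statistic-correlation estimators: closed cases and PD repair", {
  set.seed(36)
  S <- matrix(rnorm(200 * 3), 200, 3)
  S <- cbind(S, S[, 1])                       # duplicated column
  C <- estimate_stat_correlation_replicates(S)
  # duplicated columns: unit correlation up to the PD-repair clipping
  expect_equal(C[1, 4], 1, tolerance = 1e-5)
  expect_equal(diag(C), rep(1, 4))
  expect_true(all(abs(C[2, 3]) < 0.2))        # independent columns
  expect_error(estimate_stat_correlation_replicates(S[1:2, ]),
               ">= 3 replicates")

  X <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))  # orthogonal, centered
  expect_equal(estimate_stat_correlation_genotype(X), diag(2))

  # singular correlation becomes positive definite with unit diagonal
  A <- matrix(rnorm(30), 10, 3)
  A <- cbind(A, rowMeans(A))
  Cr <- hcgene:::.pd_correlation(cor(A))
  expect_gt(min(eigen(Cr, symmetric = TRUE)$values), 0)
  expect_equal(diag(Cr), rep(1, 4))
})

test_that("iHCM reduces to HC of marginal P-values when correlation is identity", {
  set.seed(37)
  stats <- rnorm(6)
  expect_equal(ihcm_score(stats, diag(6)),
               hc_statistic(2 * pnorm(-abs(stats))), tolerance = 1e-12)
  # bandwidth 1 on a unit-diagonal correlation also collapses to identity
  corr <- rand_corr(6)
  expect_equal(ihcm_score(stats, corr, b = 1),
               hc_statistic(2 * pnorm(-abs(stats))), tolerance = 1e-12)
  expect_equal(ihcm_score(stats[1], matrix(1)),
               hc_statistic(2 * pnorm(-abs(stats[1]))), tolerance = 1e-12)
})

test_that("iHCM exploits decorrelation where marginal signals cancel", {
  # adjacent equal-and-opposite signals in positive correlation: the
  # marginal means are attenuated by (1 - r) while whitening recovers
  # sqrt(1 - r^2); power at a fixed null quantile must be higher
  set.seed(38)
  L <- 10; r <- 0.5
  R <- r^abs(outer(1:L, 1:L, "-"))
  C <- t(chol(R))
  mu <- numeric(L); mu[5] <- 2.2; mu[6] <- -2.2
  mu_marg <- drop(R %*% mu)
  B <- 1500
  hc0 <- hc1 <- ih0 <- ih1 <- numeric(B)
  for (b in seq_len(B)) {
    z0 <- drop(C %*% rnorm(L)); z1 <- z0 + mu_marg
    hc0[b] <- hc_statistic(2 * pnorm(-abs(z0)))
    hc1[b] <- hc_statistic(2 * pnorm(-abs(z1)))
    ih0[b] <- ihcm_score(z0, R)
    ih1[b] <- ihcm_score(z1, R)
  }
  pow_hc <- mean(hc1 > quantile(hc0, 0.95))
  pow_ih <- mean(ih1 > quantile(ih0, 0.95))
  expect_gt(pow_ih, pow_hc)
})

test_that("bandwidth follows floor(log L) with a floor of 1", {
  expect_equal(hcgene:::.ihc_bandwidth(1), 1L)
  expect_equal(hcgene:::.ihc_bandwidth(7), 1L)   # ln 7 = 1.95
  expect_equal(hcgene:::.ihc_bandwidth(8), 2L)   # ln 8 = 2.08
  expect_equal(hcgene:::.ihc_bandwidth(55), 4L)  # ln 55 = 4.01
})
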