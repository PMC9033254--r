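test_that("variant filtering applies strict missingness and MAF boundaries", {
  ## 10 accessions, 6 SNPs: one at exactly 20% missing, one at MAF exactly
  ## 0.05 (1/20 alleles), one rare, three clean
  g <- matrix(0L, nrow = 10, ncol = 6)
  g[, 1] <- c(rep(NA, 2), rep(0L, 4), rep(2L, 4))        # missing = 0.20 -> out
  g[, 2] <- c(1L, rep(0L, 9))                            # MAF 0.05 -> out
  g[, 3] <- rep(0L, 10)                                  # monomorphic -> out
  g[, 4] <- c(rep(2L, 5), rep(0L, 5))                    # clean
  g[, 5] <- c(rep(2L, 2), rep(0L, 8))                    # MAF 0.2, clean
  g[, 6] <- c(NA, rep(2L, 4), rep(0L, 5))                # missing 0.1, clean
  vt <- make_vt(g)
  out <- filter_variants(vt)
  expect_equal(n_snps(out), 3L)
  expect_setequal(out$info$snp_id, c("s4", "s5", "s6"))
  expect_equal(attr(out, "n_removed"), 3L)
})

test_that("LD pruning keeps one of two identical columns, all independent ones", {
  set.seed(21)
  base <- sample(c(0L, 2L), 60, replace = TRUE)
  g <- cbind(base, base, sample(c(0L, 2L), 60, replace = TRUE),
             sample(c(0L, 2L), 60, replace = TRUE))
  vt <- make_vt(g)
  kept <- ld_prune(vt)
  expect_equal(sum(c("s1", "s2") %in% kept), 1L)
  expect_true(all(c("s3", "s4") %in% kept))

  ## hand-built 5-SNP window checked against the exhaustive r2 oracle
  set.seed(22)
  g5 <- matrix(sample(c(0L, 2L), 200, replace = TRUE), ncol = 5)
  g5[, 2] <- g5[, 1]; g5[, 2][1:3] <- 2L - g5[, 2][1:3]   # high r2 with s1
  vt5 <- make_vt(g5)
  kept5 <- ld_prune(vt5, window = 5, step = 5, r2_max = 0.1)
  r2 <- cor(g5)^2
  for (i in 1:4) for (j in (i + 1):5) {
    ki <- paste0("s", i) %in% kept5; kj <- paste0("s", j) %in% kept5
    if (ki && kj) expect_lte(r2[i, j], 0.1)
  }
  expect_false(all(c("s1", "s2") %in% kept5))
})

test_that("IBS kinship matches hand arithmetic and its invariants", {
  g <- rbind(a = c(0L, 2L, 0L), b = c(2L, 2L, 0L))
  K <- ibs_kinship(make_vt(g))
  expect_equal(K["a", "b"], (0 + 1 + 1) / 3)
  expect_equal(diag(K), c(a = 1, b = 1))
  g2 <- rbind(a = c(0L, 0L), b = c(2L, 2L))
  expect_equal(ibs_kinship(make_vt(g2))["a", "b"], 0)
  ## heterozygous dosage contributes half-identity
  g3 <- rbind(a = c(0L, 0L), b = c(1L, 1L))
  expect_equal(ibs_kinship(make_vt(g3))["a", "b"], 0.5)
})

test_that("kinship PCs separate simulated subpopulations and are deterministic", {
  cfg <- small_sim_config(seed = 31, missing_rate = 0)
  pop <- simulate_population(cfg)
  K <- ibs_kinship(pop$variants)
  pcs <- pca_covariates(K)
  lab <- as.numeric(pop$metadata$subpopulation == "Xian")
  expect_gt(abs(cor(pcs[, 1], lab)), 0.9)
  expect_identical(pcs, pca_covariates(K))
  expect_error(pca_covariates(K[1:3, 1:3], n_pc = 3), "n_pc")
})

test_that("spectral REML recovers heritability on block-structured kinship", {
  ## y simulated with h2 = 0.5 from a block kinship, n = 200, 20 replicates
  n <- 200
  blocks <- rep(1:20, each = 10)
  K <- outer(blocks, blocks, function(a, b) (a == b) * 0.9) + diag(n) * 0.1
  eK <- eigen(K, symmetric = TRUE)
  h2_hat <- vapply(1:20, function(r) {
    set.seed(400 + r)
    gvals <- eK$vectors %*% (sqrt(pmax(eK$values, 0)) * rnorm(n))
    y <- as.numeric(sqrt(0.5) * gvals / sd(gvals) + rnorm(n, 0, sqrt(0.5)))
    suppressWarnings(reml_fit(y, matrix(1, n, 1), K))$h2
  }, numeric(1))
  expect_gt(mean(h2_hat), 0.35)
  expect_lt(mean(h2_hat), 0.65)
  ## pure noise: negligible estimated heritability on average
  h2_null <- vapply(1:10, function(r) {
    set.seed(500 + r)
    suppressWarnings(reml_fit(rnorm(n), matrix(1, n, 1), K))$h2
  }, numeric(1))
  expect_lte(mean(h2_null), 0.15)
})

test_that("the restricted likelihood at the optimum dominates the whole grid", {
  set.seed(41)
  n <- 80
  K <- tcrossprod(matrix(rnorm(n * 30), n)) / 30
  K <- K / mean(diag(K)); diag(K) <- 1
  y <- rnorm(n) + 0.5 * K[, 1]
  fit <- suppressWarnings(reml_fit(y, matrix(1, n, 1), K))
  expect_true(all(fit$loglik >= fit$grid$rll - 1e-8))
})

test_that("with identity kinship the mixed-model scan equals OLS", {
  set.seed(51)
  n <- 60; m <- 40
  g <- matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE), n, m)
  vt <- make_vt(g)
  y <- rnorm(n) + 0.3 * g[, 5]
  X <- matrix(1, n, 1)
  fit <- suppressWarnings(reml_fit(y, X, diag(n)))
  scan <- association_scan(y, X, fit, vt)
  p_ols <- vapply(seq_len(m), function(j)
    summary(lm(y ~ g[, j]))$coefficients[2, 4], numeric(1))
  expect_equal(scan$p, p_ols, tolerance = 1e-8)
})

test_that("scan results are invariant to accession order and y shifts", {
  cfg <- small_sim_config(seed = 61, missing_rate = 0)
  pop <- simulate_population(cfg)
  vt <- filter_variants(pop$variants)
  K <- ibs_kinship(vt)
  set.seed(61)
  y <- rnorm(nrow(K)) + pop$variants$geno[, 10] * 0.3
  X <- cbind(1, pca_covariates(K))
  fit <- suppressWarnings(reml_fit(y, X, K))
  scan1 <- association_scan(y, X, fit, vt)
  ## shift y by a constant: identical p-values (intercept absorbs it)
  fit2 <- suppressWarnings(reml_fit(y + 100, X, K))
  scan2 <- association_scan(y + 100, X, fit2, vt)
  expect_equal(scan1$p, scan2$p, tolerance = 1e-6)
  ## permute accessions
  perm <- sample(nrow(K))
  vt_p <- subset_variants(vt, accessions = perm)
  fit3 <- suppressWarnings(reml_fit(y[perm], X[perm, , drop = FALSE],
                                    K[perm, perm]))
  scan3 <- association_scan(y[perm], X[perm, , drop = FALSE], fit3, vt_p)
  expect_equal(scan3$p, scan1$p, tolerance = 1e-6)
})

test_that("effective marker number: independent SNPs high, duplicated halves", {
  set.seed(71)
  n <- 150; m <- 120
  g <- matrix(sample(c(0L, 2L), n * m, replace = TRUE), n, m)
  vt <- make_vt(g)
  n_eff <- effective_marker_number(vt, window = 60)
  expect_gte(n_eff, 0.9 * m)
  expect_lte(n_eff, m)
  ## every SNP duplicated once -> about half the markers are independent
  g2 <- g[, rep(seq_len(60), each = 2)]
  vt2 <- make_vt(g2)
  n_eff2 <- effective_marker_number(vt2, window = 60)
  expect_lt(abs(n_eff2 - 60) / 60, 0.15)
})

test_that("significance threshold is the reciprocal effective marker count", {
  expect_equal(significance_threshold(500000), 2e-06)
  expect_equal(significance_threshold(1), 1)
  ## a 2.15e-06 threshold corresponds to about 465,000 effective markers
  expect_equal(1 / 2.15e-06, 465116, tolerance = 1e-4)
})

test_that("genomic-control lambda is calibrated on uniform p and monotone", {
  set.seed(81)
  p <- runif(10000)
  ql <- qq_lambda(p)
  expect_gt(ql$lambda, 0.9); expect_lt(ql$lambda, 1.1)
  expect_equal(nrow(ql$qq), 10000L)
  expect_gt(qq_lambda(p / 2)$lambda, ql$lambda)
})
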