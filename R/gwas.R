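## Mixed-linear-model association scan and its supporting statistics.
## The model is y = X b + g + e with cov(g) = sigma_g^2 K (identity-by-state
## kinship) and cov(e) = sigma_e^2 I; variance components are estimated once
## per trait on the null model by spectral REML and reused for every SNP
## (the EMMAX approximation), each SNP being tested by generalized least
## squares in the eigenbasis of K.

#' Filter SNPs on missingness and minor allele frequency
#'
#' Keeps SNPs with missing fraction strictly below `max_missing` and MAF
#' (computed on non-missing calls) strictly above `min_maf`.
#'
#' @param vt a [variant_table()].
#' @param max_missing missingness bound (exclusive), default 0.20.
#' @param min_maf MAF bound (exclusive), default 0.05.
#' @return Filtered `variant_table` with `attr(, "n_removed")`; an empty
#'   result is a warning, not an error.
#' @export
filter_variants <- function(vt, max_missing = 0.20, min_maf = 0.05) {
  st <- snp_stats(vt)
  keep <- !is.na(st$maf) & st$missing_rate < max_missing & st$maf > min_maf
  ag_msg("filter_variants: kept %d of %d SNPs", sum(keep), nrow(st))
  if (!any(keep)) warning("no SNPs survive the missingness/MAF filters")
  out <- subset_variants(vt, snps = which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Window-based LD pruning
#'
#' Greedy `indep-pairwise`-style pruning: within a sliding window of
#' `window` SNPs, one SNP of every pair with squared correlation above
#' `r2_max` is removed (the one with higher missingness; ties drop the later
#' position); the window then advances by `step` SNPs. Chromosomes are pruned
#' independently.
#'
#' @param vt a filtered [variant_table()].
#' @param window window size in SNPs (default 50).
#' @param step window step in SNPs (default 10).
#' @param r2_max r-squared threshold (default 0.1).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(vt, window = 50, step = 10, r2_max = 0.1) {
  info <- vt$info
  g <- vt$geno
  miss <- colSums(is.na(g))
  keep <- rep(TRUE, ncol(g))
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    start <- 1L
    repeat {
      w <- idx[seq(start, min(start + window - 1L, length(idx)))]
      w_live <- w[keep[w]]
      if (length(w_live) > 1) {
        r2 <- suppressWarnings(
          stats::cor(g[, w_live, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        r2[!is.finite(r2)] <- 0
        for (a in seq_len(length(w_live) - 1L)) {
          if (!keep[w_live[a]]) next
          for (b in seq((a + 1L), length(w_live))) {
            if (!keep[w_live[b]] || r2[a, b] <= r2_max) next
            drop <- if (miss[w_live[a]] > miss[w_live[b]]) w_live[a] else w_live[b]
            keep[drop] <- FALSE
            if (drop == w_live[a]) break
          }
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  info$snp_id[keep]
}

#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the mean over SNPs non-missing in both accessions of
#' `1 - |d_i - d_j| / 2`, so identical genotypes score 1 and opposite
#' homozygotes 0.
#'
#' @param vt a [variant_table()] (typically the LD-pruned subset).
#' @return Symmetric accession x accession matrix of class `matrix` with
#'   entries in `[0, 1]` and unit diagonal.
#' @export
ibs_kinship <- function(vt) {
  g <- vt$geno
  if (nrow(g) < 2) ag_stop("kinship needs at least 2 accessions",
                           "alkagerm_validation_error")
  A0 <- (!is.na(g) & g == 0L) + 0
  A1 <- (!is.na(g) & g == 1L) + 0
  A2 <- (!is.na(g) & g == 2L) + 0
  V <- (!is.na(g)) + 0
  shared <- tcrossprod(V)
  if (any(shared == 0))
    ag_stop("accession pair with zero shared genotyped SNPs",
            "alkagerm_validation_error")
  sim <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2) +
    0.5 * (tcrossprod(A0, A1) + tcrossprod(A1, A0) +
             tcrossprod(A1, A2) + tcrossprod(A2, A1))
  K <- sim / shared
  dimnames(K) <- list(rownames(g), rownames(g))
  K
}

#' Principal-component covariates from the kinship matrix
#'
#' Top eigenvectors of the double-centered kinship, eigenvalue-ordered, with
#' each vector's sign fixed so its largest-magnitude entry is positive.
#'
#' @param K kinship matrix.
#' @param n_pc number of components (default 3).
#' @return n x `n_pc` matrix of PC scores (columns `PC1` ...).
#' @export
pca_covariates <- function(K, n_pc = 3) {
  n <- nrow(K)
  if (n_pc >= n) ag_stop("n_pc must be smaller than the number of accessions",
                         "alkagerm_validation_error")
  C <- diag(n) - matrix(1 / n, n, n)
  Kc <- C %*% K %*% C
  eg <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  pcs <- eg$vectors[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {
    i_max <- which.max(abs(pcs[, j]))
    if (pcs[i_max, j] < 0) pcs[, j] <- -pcs[, j]
  }
  dimnames(pcs) <- list(rownames(K), paste0("PC", seq_len(n_pc)))
  pcs
}

#' Spectral REML fit of the polygenic null model
#'
#' Estimates the genetic and residual variance components of
#' `y = X b + g + e`, `cov(g) = sigma_g^2 K`, by profiling the restricted
#' log-likelihood over `log(delta)` (`delta = sigma_e^2 / sigma_g^2`) on a
#' 121-point grid from -10 to 10, refined by bounded scalar optimization. The
#' kinship is eigendecomposed once; the fit is exact given `delta`.
#'
#' @param y numeric trait vector (complete cases only).
#' @param X covariate matrix including the intercept column.
#' @param K kinship matrix aligned with `y`.
#' @return Object of class `reml_fit`: variance components `sigma_g2`,
#'   `sigma_e2`, their ratio `delta`, pseudo-heritability `h2`, restricted
#'   log-likelihood `loglik`, a `boundary` flag, and the eigendecomposition of
#'   `K` for reuse by [association_scan()].
#' @export
reml_fit <- function(y, X, K) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n)
  if (max(abs(K - t(K))) > 1e-8)
    ag_stop("kinship matrix must be symmetric", "alkagerm_validation_error")
  q <- qr(X)$rank
  if (n <= q + 1) ag_stop("too few observations for REML",
                          "alkagerm_validation_error")
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  SKS <- S %*% K %*% S
  eg <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(n - q)], 0)
  U <- eg$vectors[, seq_len(n - q), drop = FALSE]
  eta2 <- as.numeric(crossprod(U, y))^2
  nq <- n - q
  rll <- function(logdelta) {
    d <- exp(logdelta)
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(sum(eta2 / (lam + d)))) -
             sum(log(lam + d)))
  }
  grid <- seq(-10, 10, length.out = 121)
  vals <- vapply(grid, rll, numeric(1))
  i_best <- which.max(vals)
  lo <- grid[max(1, i_best - 1)]; hi <- grid[min(length(grid), i_best + 1)]
  opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  logdelta <- if (opt$objective >= vals[i_best]) opt$maximum else grid[i_best]
  delta <- exp(logdelta)
  sigma_g2 <- sum(eta2 / (lam + delta)) / nq
  sigma_e2 <- delta * sigma_g2
  boundary <- i_best %in% c(1L, length(grid))
  if (boundary)
    warning("REML optimum at the delta grid boundary; estimates may be degenerate")
  egK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
    h2 = 1 / (1 + delta), loglik = rll(logdelta), boundary = boundary,
    grid = data.frame(logdelta = grid, rll = vals),
    K_values = pmax(egK$values, 0), K_vectors = egK$vectors,
    n = n, rank_X = q
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "Spectral REML fit (n = %d)\n  sigma_g^2 = %.4g  sigma_e^2 = %.4g\n  delta = %.4g  pseudo-h2 = %.3f%s\n",
    x$n, x$sigma_g2, x$sigma_e2, x$delta, x$h2,
    if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) {
  c(sigma_g2 = object$sigma_g2, sigma_e2 = object$sigma_e2,
    delta = object$delta, h2 = object$h2)
}

#' EMMAX-style generalized-least-squares association scan
#'
#' With variance components fixed from [reml_fit()], rotates the phenotype,
#' covariates and each SNP dosage vector into the eigenbasis of the kinship,
#' weights by `1 / (lambda_i + delta)` and solves per-SNP generalized least
#' squares; the SNP effect is tested by a Wald t-test with
#' `df = n - rank(X) - 1`. Missing dosages are mean-imputed per SNP;
#' monomorphic SNPs are skipped (p = NA).
#'
#' @param y trait vector.
#' @param X covariate matrix including intercept.
#' @param vc a `reml_fit` for this trait (carries the kinship eigensystem).
#' @param vt a [variant_table()] aligned with `y`.
#' @param trait,panel labels stored in the result.
#' @return data.frame of class `assoc_scan` with columns `snp_id`, `chrom`,
#'   `pos`, `beta`, `se`, `p`, `maf`, `n`, plus `trait`/`panel` labels.
#' @export
association_scan <- function(y, X, vc, vt, trait = "trait", panel = "whole") {
  stopifnot(inherits(vc, "reml_fit"))
  n <- length(y)
  stopifnot(nrow(vt$geno) == n, nrow(X) == n)
  w <- 1 / (vc$K_values + vc$delta)
  Ut <- t(vc$K_vectors)
  sw <- sqrt(w)
  ys <- sw * (Ut %*% y)
  Xs <- sw * (Ut %*% X)
  G <- vt$geno
  ## per-SNP mean imputation
  mu <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G))
  if (length(na_idx)) G[na_idx] <- mu[((na_idx - 1) %/% n) + 1]
  Gs <- sw * (Ut %*% G)
  qrX <- qr(Xs)
  ry <- qr.resid(qrX, ys)
  RG <- qr.resid(qrX, Gs)
  gg <- colSums(RG^2)
  gy <- as.numeric(crossprod(RG, ry))
  df <- n - vc$rank_X - 1L
  beta <- gy / gg
  rss <- sum(ry^2) - beta^2 * gg
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 / gg)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  st <- snp_stats(vt)
  mono <- is.na(st$maf) | st$maf == 0 | gg < 1e-12
  if (any(mono)) {
    beta[mono] <- NA_real_; se[mono] <- NA_real_; p[mono] <- NA_real_
    ag_msg("association_scan: skipped %d monomorphic SNP(s)", sum(mono))
  }
  out <- data.frame(
    snp_id = vt$info$snp_id, chrom = vt$info$chrom, pos = vt$info$pos,
    beta = beta, se = se, p = p, maf = st$maf, n = n,
    trait = trait, panel = panel, stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' Effective number of independent markers
#'
#' simpleM-style estimator: within non-overlapping windows of `window` SNPs
#' per chromosome, the effective number is the smallest count of top
#' eigenvalues of the SNP correlation matrix capturing at least `capture` of
#' its trace; the genome-wide number is the sum over windows.
#'
#' @param vt a filtered [variant_table()].
#' @param window window size in SNPs (default 200).
#' @param capture trace fraction to capture (default 0.995).
#' @return Integer effective marker count (never exceeding the SNP count).
#' @export
effective_marker_number <- function(vt, window = 200, capture = 0.995) {
  info <- vt$info
  g <- vt$geno
  total <- 0L
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    starts <- seq(1L, length(idx), by = window)
    for (s in starts) {
      w <- idx[seq(s, min(s + window - 1L, length(idx)))]
      sub <- g[, w, drop = FALSE]
      mu <- colMeans(sub, na.rm = TRUE)
      nai <- which(is.na(sub))
      if (length(nai)) sub[nai] <- mu[((nai - 1) %/% nrow(sub)) + 1]
      sds <- apply(sub, 2, stats::sd)
      sub <- sub[, sds > 0, drop = FALSE]
      if (ncol(sub) == 0) next
      if (ncol(sub) == 1) { total <- total + 1L; next }
      ev <- eigen(stats::cor(sub), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      k <- which(cumsum(ev) >= capture * sum(ev))[1]
      total <- total + k
    }
  }
  min(total, n_snps(vt))
}

#' Bonferroni-style suggestive significance threshold
#'
#' @param n_eff effective number of independent markers (>= 1).
#' @return `1 / n_eff`.
#' @export
significance_threshold <- function(n_eff) {
  if (n_eff < 1) ag_stop("effective marker number must be >= 1",
                         "alkagerm_validation_error")
  1 / n_eff
}

#' Genomic-control inflation factor and QQ table
#'
#' `lambda_GC` is the median 1-df chi-square quantile of the observed
#' p-values divided by 0.4549 (the null median); the QQ table pairs sorted
#' observed with uniform-expected -log10 p.
#'
#' @param p vector of p-values (needs >= 100 non-missing).
#' @return List with `lambda` and `qq` (data.frame `expected`, `observed`).
#' @export
qq_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100)
    ag_stop("qq_lambda needs at least 100 p-values", "alkagerm_validation_error")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  m <- length(p)
  qq <- data.frame(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(sort(p))
  )
  list(lambda = lambda, qq = qq)
}
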