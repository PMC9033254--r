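## Pairwise linkage disequilibrium and confidence-interval block detection.
## Inbred genotypes are treated as haplotypes (allele = dosage / 2);
## heterozygous calls are excluded pairwise.

## Two-SNP haplotype counts (ref/alt coded 0/1) for inbred accessions.
hap_counts2 <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj) & gi != 1L & gj != 1L
  a <- gi[ok] / 2L
  b <- gj[ok] / 2L
  c(n00 = sum(a == 0 & b == 0), n01 = sum(a == 0 & b == 1),
    n10 = sum(a == 1 & b == 0), n11 = sum(a == 1 & b == 1))
}

ld_pair_from_counts <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(c(D = NA, Dprime = NA, r2 = NA))
  pA <- (cnt["n10"] + cnt["n11"]) / n   # alt freq at SNP 1
  pB <- (cnt["n01"] + cnt["n11"]) / n   # alt freq at SNP 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(c(D = NA, Dprime = NA, r2 = NA))
  D <- cnt["n11"] / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  c(D = unname(D),
    Dprime = unname(abs(D) / dmax),
    r2 = unname(D^2 / (pA * (1 - pA) * pB * (1 - pB))))
}

#' Pairwise LD statistics
#'
#' Haplotype-frequency-based D, D' and r-squared for every SNP pair in a
#' window, computed from inbred genotypes (haplotype = dosage / 2) on
#' pairwise-complete homozygous calls. Pairs involving a monomorphic SNP are
#' masked (NA).
#'
#' @param vt a [variant_table()] restricted to the window of interest
#'   (>= 2 SNPs).
#' @return List with symmetric matrices `r2` and `dprime` (diagonal 1).
#' @export
ld_statistics <- function(vt) {
  m <- n_snps(vt)
  if (m < 2) ag_stop("LD statistics need at least 2 SNPs",
                     "alkagerm_validation_error")
  g <- vt$geno
  r2 <- dp <- matrix(NA_real_, m, m, dimnames = list(vt$info$snp_id, vt$info$snp_id))
  diag(r2) <- diag(dp) <- 1
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      s <- ld_pair_from_counts(hap_counts2(g[, i], g[, j]))
      r2[i, j] <- r2[j, i] <- s["r2"]
      dp[i, j] <- dp[j, i] <- s["Dprime"]
    }
  }
  list(r2 = r2, dprime = dp)
}

## Posterior-style confidence bounds on |D'| for one pair: multinomial
## likelihood over a 101-point |D'| grid with allele frequencies fixed at
## their sample values; bounds are the 5th and 95th percentiles of the
## normalized likelihood (the approach popularized by Haploview).
dprime_ci <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(c(lo = NA, hi = NA))
  pA <- (cnt["n10"] + cnt["n11"]) / n
  pB <- (cnt["n01"] + cnt["n11"]) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(c(lo = NA, hi = NA))
  D_obs <- cnt["n11"] / n - pA * pB
  sgn <- if (D_obs >= 0) 1 else -1
  dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, length.out = 101)
  ll <- vapply(grid, function(dp) {
    D <- sgn * dp * dmax
    f11 <- pA * pB + D
    f10 <- pA * (1 - pB) - D
    f01 <- (1 - pA) * pB - D
    f00 <- (1 - pA) * (1 - pB) + D
    f <- pmax(c(f00, f01, f10, f11), 1e-12)
    sum(cnt * log(f[c(1, 2, 3, 4)]))
  }, numeric(1))
  lk <- exp(ll - max(ll))
  cum <- cumsum(lk) / sum(lk)
  c(lo = grid[which(cum >= 0.05)[1]], hi = grid[which(cum >= 0.95)[1]])
}

#' Detect the LD block containing an anchor SNP
#'
#' Confidence-interval block detection on D' bounds in the style of the
#' Gabriel criterion: a pair is in "strong LD" when the lower bound of its
#' |D'| interval is at least `strong_lo` and the upper bound at least
#' `strong_hi`; it shows "strong recombination" when the upper bound is below
#' `recomb_hi`. A contiguous SNP range is a block when its outermost pair is
#' in strong LD and at least `min_strong_frac` of its informative pairs are.
#' The widest such range containing the anchor is returned; with no qualifying
#' range the block degenerates to the anchor SNP alone.
#'
#' @param anchor_pos anchor SNP position (bp).
#' @param vt a [variant_table()] windowed around the anchor (e.g. +/- 300 kb).
#' @param strong_lo,strong_hi,recomb_hi D' confidence-bound parameters
#'   (defaults 0.70, 0.98, 0.90).
#' @param min_strong_frac minimum fraction of informative pairs in strong LD
#'   (default 0.95).
#' @param max_snps at most this many SNPs nearest the anchor enter the
#'   pairwise computation (default 80; keeps the quadratic cost bounded).
#' @return List of class `ld_block`: `chrom`, `start`, `end`, `n_snps`,
#'   `anchor_pos`.
#' @export
detect_ld_block <- function(anchor_pos, vt, strong_lo = 0.70, strong_hi = 0.98,
                            recomb_hi = 0.90, min_strong_frac = 0.95,
                            max_snps = 80) {
  info <- vt$info
  m <- nrow(info)
  ai <- which.min(abs(info$pos - anchor_pos))
  chrom <- info$chrom[ai]
  keep <- info$chrom == chrom
  idx <- which(keep)
  if (length(idx) > max_snps) {
    near <- order(abs(info$pos[idx] - info$pos[ai]))[seq_len(max_snps)]
    idx <- sort(idx[near])
  }
  g <- vt$geno
  k <- length(idx)
  if (k == 1)
    return(structure(list(chrom = chrom, start = info$pos[ai],
                          end = info$pos[ai], n_snps = 1L,
                          anchor_pos = info$pos[ai]), class = "ld_block"))
  ## pair classes: 1 strong, -1 recomb, 0 uninformative
  cls <- matrix(0L, k, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      ci <- dprime_ci(hap_counts2(g[, idx[a]], g[, idx[b]]))
      v <- if (anyNA(ci)) 0L
        else if (ci["lo"] >= strong_lo && ci["hi"] >= strong_hi) 1L
        else if (ci["hi"] < recomb_hi) -1L else 0L
      cls[a, b] <- cls[b, a] <- v
    }
  }
  a0 <- match(ai, idx)
  best <- c(a0, a0)
  for (s in seq_len(a0)) {
    for (e in seq(a0, k)) {
      if (e - s < 1) next
      if (cls[s, e] != 1L) next
      sub <- cls[s:e, s:e]
      inf <- sum(sub != 0L) / 2
      if (inf == 0) next
      if ((sum(sub == 1L) / 2) / inf >= min_strong_frac &&
          (e - s) > (best[2] - best[1]))
        best <- c(s, e)
    }
  }
  structure(list(chrom = chrom,
                 start = info$pos[idx[best[1]]],
                 end = info$pos[idx[best[2]]],
                 n_snps = best[2] - best[1] + 1L,
                 anchor_pos = info$pos[ai]),
            class = "ld_block")
}

#' @export
print.ld_block <- function(x, ...) {
  cat(sprintf("ld_block %s:%d-%d (%d bp, %d SNPs), anchor %d\n",
              x$chrom, x$start, x$end, x$end - x$start, x$n_snps, x$anchor_pos))
  invisible(x)
}
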