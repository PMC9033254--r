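# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms / direct definitions.

# Hudson FST estimator (ratio of averages) computed directly from two
# allele-frequency vectors with sample sizes; alleles counted at the
# accession level for inbred lines.
oracle_hudson_fst <- function(geno, subpop, pops = c("Xian", "Geng")) {
  g1 <- geno[subpop == pops[1], , drop = FALSE] / 2
  g2 <- geno[subpop == pops[2], , drop = FALSE] / 2
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colMeans(g1, na.rm = TRUE); p2 <- colMeans(g2, na.rm = TRUE)
  keep <- n1 > 1 & n2 > 1
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Whole-CDS translation oracle: substitute the alternate base at a genomic
# position and translate both CDS sequences with Biostrings.
oracle_snp_effect <- function(gene, genome, pos, ref, alt) {
  chrom_seq <- as.character(genome[[gene$chrom]])
  stopifnot(substr(chrom_seq, pos, pos) == ref)
  mutated <- chrom_seq
  substr(mutated, pos, pos) <- alt
  get_cds <- function(seq_chr) {
    segs <- gene$cds[order(gene$cds[, 1]), , drop = FALSE]
    s <- paste(vapply(seq_len(nrow(segs)), function(k)
      substr(seq_chr, segs[k, 1], segs[k, 2]), character(1)), collapse = "")
    d <- Biostrings::DNAString(s)
    if (gene$strand == "-") d <- Biostrings::reverseComplement(d)
    d
  }
  aa_ref <- as.character(Biostrings::translate(get_cds(chrom_seq),
                                               no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(get_cds(mutated),
                                               no.init.codon = TRUE))
  if (aa_ref == aa_alt) return("synonymous")
  d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])[1]
  alt_aa <- substr(aa_alt, d, d)
  ref_codon1 <- as.character(Biostrings::subseq(get_cds(chrom_seq), 1, 3))
  if (d == 1 && ref_codon1 == "ATG") "start_loss"
  else if (alt_aa == "*") "nonsense"
  else "missense"
}

# Independent Duncan letter oracle: computes the significance relation from
# the textbook definition (no step-down matrix reuse) and assembles letters
# by exhaustively finding maximal non-significant intervals of the ordered
# means.
oracle_duncan_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  k <- length(means)
  ns <- table(groups)[names(means)]
  fit <- stats::lm(values ~ groups)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  n_h <- k / sum(1 / ns)
  crit <- function(p) stats::qtukey((1 - alpha)^(p - 1), p, fit$df.residual) *
    sqrt(mse / n_h)
  # a range [i, j] is non-significant if its spread is below the critical
  # range for its span OR it is inside a larger non-significant range
  base_ns <- function(i, j) {
    if (mse <= .Machine$double.eps * max(abs(values), 1))
      return(means[i] == means[j])
    (means[i] - means[j]) <= crit(j - i + 1)
  }
  ns_mat <- matrix(FALSE, k, k)
  for (i in seq_len(k)) ns_mat[i, i] <- TRUE
  for (span in k:2) for (i in seq_len(k - span + 1)) {
    j <- i + span - 1
    direct <- base_ns(i, j)
    covered <- FALSE
    if (span < k) for (a in seq_len(k)) for (b in seq_len(k)) {
      if (b - a > span - 1 && a <= i && j <= b && ns_mat[a, b]) covered <- TRUE
    }
    ns_mat[i, j] <- ns_mat[j, i] <- direct || covered
  }
  # maximal intervals [i, j] with ns_mat[i, j]
  ivs <- list()
  for (i in seq_len(k)) for (j in i:k) {
    if (!ns_mat[i, j]) next
    maximal <- !(i > 1 && ns_mat[i - 1, j]) && !(j < k && ns_mat[i, j + 1])
    if (maximal) ivs[[length(ivs) + 1]] <- c(i, j)
  }
  ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 1))]
  lab <- rep("", k)
  for (li in seq_along(ivs))
    lab[ivs[[li]][1]:ivs[[li]][2]] <- paste0(lab[ivs[[li]][1]:ivs[[li]][2]],
                                             letters[li])
  stats::setNames(lab, names(means))
}

# Spearman rho by explicit rank computation (average ranks for ties).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
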