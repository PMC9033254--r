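## Gene-CDS-haplotype analysis: codon-aware effect classification of coding
## SNPs, haplotype construction over non-synonymous sites, subpopulation
## frequencies, favorable-haplotype identification and pyramiding.

#' Classify coding SNPs by codon effect
#'
#' Maps each SNP inside a gene's CDS to its codon (strand-aware: on the minus
#' strand the transcript allele is the reverse complement and offsets run
#' 3'->5' genomically) and translates the reference and alternate codons
#' under the standard genetic code.
#'
#' @param gene a [gene_model()].
#' @param genome reference `DNAStringSet` keyed by chromosome; the base at
#'   each SNP position must equal the SNP's reference allele.
#' @param vt a [variant_table()].
#' @return data.frame of class `cds_snp_effects`: `snp_id`, `gene_id`,
#'   `cds_offset` (1-based transcript position), `codon_index`,
#'   `pos_in_codon` (1-3), `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect` in `{synonymous, missense, nonsense, start_loss}`.
#' @export
classify_cds_snps <- function(gene, genome, vt) {
  info <- vt$info
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  code <- Biostrings::GENETIC_CODE
  cds_seq <- as.character(cds_sequence(gene, genome))
  segs <- gene$cds  # transcript order already
  ## genomic position -> 1-based transcript CDS offset
  to_cds <- function(pos) {
    off <- 0L
    for (k in seq_len(nrow(segs))) {
      s <- segs[k, 1]; e <- segs[k, 2]
      if (pos >= s && pos <= e) {
        within <- if (gene$strand == "+") pos - s else e - pos
        return(off + within + 1L)
      }
      off <- off + (e - s + 1L)
    }
    NA_integer_
  }
  sel <- info$chrom == gene$chrom &
    vapply(info$pos, function(p) !is.na(to_cds(p)), logical(1))
  if (!any(sel))
    return(structure(data.frame(), class = c("cds_snp_effects", "data.frame")))
  idx <- which(sel)
  rows <- lapply(idx, function(i) {
    cpos <- to_cds(info$pos[i])
    ref_t <- if (gene$strand == "+") info$ref[i] else comp[[info$ref[i]]]
    alt_t <- if (gene$strand == "+") info$alt[i] else comp[[info$alt[i]]]
    if (substr(cds_seq, cpos, cpos) != ref_t)
      ag_stop(sprintf("reference base does not match VCF ref allele at SNP %s",
                      info$snp_id[i]), "alkagerm_consistency_error")
    ci <- (cpos - 1L) %/% 3L + 1L
    pc <- (cpos - 1L) %% 3L + 1L
    ref_codon <- substr(cds_seq, (ci - 1L) * 3L + 1L, ci * 3L)
    alt_codon <- ref_codon
    substr(alt_codon, pc, pc) <- alt_t
    ref_aa <- code[[ref_codon]]
    alt_aa <- code[[alt_codon]]
    effect <- if (ref_aa == alt_aa) "synonymous"
      else if (ci == 1L && ref_codon == "ATG") "start_loss"
      else if (alt_aa == "*") "nonsense"
      else "missense"
    data.frame(snp_id = info$snp_id[i], gene_id = gene$gene_id,
               cds_offset = cpos, codon_index = ci, pos_in_codon = pc,
               ref_codon = ref_codon, alt_codon = alt_codon,
               ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$cds_offset), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("cds_snp_effects", "data.frame"))
}

#' Build gene-CDS haplotypes
#'
#' Haplotypes are defined by the allele vector over the gene's
#' non-synonymous CDS SNPs (missense, nonsense and start-loss sites);
#' synonymous SNPs are ignored, so accessions differing only at synonymous
#' sites merge into one haplotype. The panel being inbred, heterozygous calls
#' are treated as missing, and accessions missing any defining SNP are
#' excluded (counted). Haplotypes with at least `min_size` members are
#' labelled `Hap1`, `Hap2`, ... by descending size; smaller ones are pooled
#' as `rare` and excluded from phenotype tests.
#'
#' @param gene a [gene_model()].
#' @param effects `cds_snp_effects` for the gene ([classify_cds_snps()]).
#' @param vt a [variant_table()].
#' @param min_size minimum haplotype size entering tests (default 10).
#' @return Object of class `cds_haplotypes`: `gene_id`, `defining_snps`,
#'   `table` (haplotype, alleles, n), `assignment` (named haplotype label per
#'   retained accession, `"rare"` for pooled ones) and `n_excluded`.
#' @export
build_haplotypes <- function(gene, effects, vt, min_size = 10) {
  def <- effects$snp_id[effects$effect != "synonymous"]
  if (length(def) == 0) {
    ag_msg("build_haplotypes: %s has no non-synonymous CDS SNP", gene$gene_id)
    return(structure(list(gene_id = gene$gene_id, defining_snps = character(0),
                          table = data.frame(), assignment = character(0),
                          n_excluded = 0L), class = "cds_haplotypes"))
  }
  sub <- subset_variants(vt, snps = def)
  g <- sub$geno
  g[g == 1L] <- NA_integer_   # heterozygous -> missing (inbred panel)
  complete <- rowSums(is.na(g)) == 0
  n_excluded <- sum(!complete)
  g <- g[complete, , drop = FALSE]
  allele_mat <- matrix(sub$info$ref[col(g)], nrow(g), ncol(g))
  allele_mat[g == 2L] <- sub$info$alt[col(g)][g == 2L]
  key <- apply(allele_mat, 1L, paste, collapse = "/")
  cnt <- sort(table(key), decreasing = TRUE)
  lab <- stats::setNames(rep("rare", length(cnt)), names(cnt))
  big <- names(cnt)[cnt >= min_size]
  lab[big] <- paste0("Hap", seq_along(big))
  assignment <- stats::setNames(unname(lab[key]), rownames(g))
  tab <- data.frame(haplotype = unname(lab), alleles = names(cnt),
                    n = as.integer(cnt), stringsAsFactors = FALSE)
  structure(list(gene_id = gene$gene_id, defining_snps = sub$info$snp_id,
                 table = tab, assignment = assignment,
                 n_excluded = n_excluded),
            class = "cds_haplotypes")
}

#' @export
print.cds_haplotypes <- function(x, ...) {
  cat(sprintf("cds_haplotypes for %s: %d defining SNP(s), %d excluded accession(s)\n",
              x$gene_id, length(x$defining_snps), x$n_excluded))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Haplotype frequencies per subpopulation
#'
#' @param haps a `cds_haplotypes` object.
#' @param metadata accession metadata ([read_metadata()]).
#' @return data.frame: `haplotype`, `subpopulation`, `count`, `proportion`
#'   (within-subpopulation, over retained + rare haplotypes).
#' @export
haplotype_subpop_frequencies <- function(haps, metadata) {
  acc <- names(haps$assignment)
  sp <- metadata$subpopulation[match(acc, metadata$accession)]
  tab <- table(haplotype = haps$assignment, subpopulation = sp)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3] <- "count"
  tot <- stats::ave(df$count, df$subpopulation, FUN = sum)
  df$proportion <- ifelse(tot > 0, df$count / tot, NA_real_)
  df
}

#' Identify the favorable haplotype of a gene
#'
#' The favorable haplotype is the retained haplotype with the highest mean of
#' the chosen ratio trait (RGE by default, the trait most sensitive to alkali
#' stress); ties go to the larger haplotype, then the lower label index.
#'
#' @param haps a `cds_haplotypes` object.
#' @param trait_values named numeric vector (accession -> trait value).
#' @return Haplotype label (e.g. `"Hap2"`), with the per-haplotype means as
#'   `attr(, "means")`.
#' @export
favorable_haplotype <- function(haps, trait_values) {
  asg <- haps$assignment[haps$assignment != "rare"]
  if (!length(asg)) ag_stop("no retained haplotypes", "alkagerm_validation_error")
  vals <- trait_values[names(asg)]
  ok <- !is.na(vals)
  if (!any(ok)) ag_stop("all trait values missing", "alkagerm_validation_error")
  means <- tapply(vals[ok], asg[ok], mean)
  sizes <- table(asg)[names(means)]
  idx <- as.integer(sub("Hap", "", names(means)))
  o <- order(-means, -as.integer(sizes), idx)
  structure(names(means)[o[1]], means = means)
}

#' Pyramided haplotype-combination analysis
#'
#' Accessions are grouped by their favorable(+)/inferior(-) pattern over a
#' set of candidate genes (accessions lacking a haplotype assignment for any
#' gene are excluded); groups smaller than `min_group` are dropped. Retained
#' group means of the ratio trait are compared by one-way ANOVA with Fisher's
#' LSD letters, and the Spearman rank correlation between a group's count of
#' favorable haplotypes and its mean trait value is reported.
#'
#' @param hap_list named list of `cds_haplotypes` (one per gene).
#' @param favorable named character vector: favorable haplotype label per
#'   gene (names matching `hap_list`).
#' @param trait_values named numeric vector (accession -> trait, e.g. RGE).
#' @param min_group minimum combination size retained (default 15).
#' @param alpha level for the LSD letters (default 0.05).
#' @return Object of class `hap_combinations`: `table` (pattern, n,
#'   n_favorable, mean, letters), `lsd` (a `duncan_test` or `NULL` when fewer
#'   than 2 groups remain), `rho` (Spearman correlation across groups, NA
#'   when undefined) and `n_excluded`.
#' @export
combine_haplotypes <- function(hap_list, favorable, trait_values,
                               min_group = 15, alpha = 0.05) {
  genes <- names(hap_list)
  stopifnot(all(genes %in% names(favorable)))
  acc <- Reduce(intersect, lapply(hap_list, function(h) names(h$assignment)))
  n_universe <- length(unique(unlist(lapply(hap_list, function(h) names(h$assignment)))))
  flags <- vapply(genes, function(g) {
    ifelse(hap_list[[g]]$assignment[acc] == favorable[[g]], "+", "-")
  }, character(length(acc)))
  if (length(acc) == 1) flags <- matrix(flags, nrow = 1)
  pattern <- apply(flags, 1L, paste, collapse = "")
  names(pattern) <- acc
  cnt <- table(pattern)
  keep_pat <- names(cnt)[cnt >= min_group]
  sel <- pattern %in% keep_pat
  vals <- trait_values[acc]
  tab <- data.frame(
    pattern = names(cnt), n = as.integer(cnt),
    n_favorable = vapply(names(cnt), function(p)
      sum(strsplit(p, "")[[1]] == "+"), integer(1)),
    mean = as.numeric(tapply(vals, pattern, mean, na.rm = TRUE)[names(cnt)]),
    retained = names(cnt) %in% keep_pat,
    stringsAsFactors = FALSE
  )
  lsd <- NULL
  letters_col <- rep(NA_character_, nrow(tab))
  if (length(keep_pat) >= 2) {
    lsd <- lsd_test(vals[sel], pattern[sel], alpha = alpha)
    letters_col[match(lsd$table$group, tab$pattern)] <- lsd$table$letters
  }
  tab$letters <- letters_col
  ret <- tab[tab$retained, , drop = FALSE]
  rho <- if (nrow(ret) >= 3 && stats::sd(ret$n_favorable) > 0 &&
             stats::sd(ret$mean) > 0)
    stats::cor(ret$n_favorable, ret$mean, method = "spearman")
  else NA_real_
  tab <- tab[order(-tab$mean), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, lsd = lsd, rho = rho,
                 n_excluded = n_universe - length(acc)),
            class = "hap_combinations")
}

#' @export
print.hap_combinations <- function(x, ...) {
  cat(sprintf("hap_combinations: %d pattern(s), %d accession(s) excluded\n",
              nrow(x$table), x$n_excluded))
  print(x$table, row.names = FALSE)
  if (!is.na(x$rho))
    cat(sprintf("Spearman rho(favorable count, group mean) = %.3f\n", x$rho))
  invisible(x)
}

#' Relative expression fold change (2^-ddCt)
#'
#' qPCR fold change of a target gene against a reference gene and a control
#' condition: `dCt = Ct_target - Ct_reference` per condition,
#' `ddCt = dCt_treated - dCt_control`, fold change `2^-ddCt`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values.
#' @return Fold change (1 = no change).
#' @export
expression_fold_change <- function(ct_target_treated, ct_ref_treated,
                                   ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_treated), is.finite(ct_ref_treated),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
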