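## Clustering of significant SNPs into loci, cross-trait unification and
## candidate-gene selection.

#' Cluster significant SNPs into loci
#'
#' Greedy rule: repeatedly take the unassigned SNP with the lowest p-value as
#' the lead, absorb every unassigned significant SNP within `window` bp on
#' either side on the same chromosome, and continue until none remain. Locus
#' spans therefore never exceed `2 * window` (300 kb at the default).
#'
#' @param significant data.frame of already-thresholded association results
#'   (columns `snp_id`, `chrom`, `pos`, `p`; extra columns kept).
#' @param window merge half-width in bp (default 150000).
#' @return data.frame of class `locus_table`: `locus_id`, `chrom`, `lead_snp`,
#'   `lead_pos`, `lead_p`, `n_snps`, `span_bp`, `start`, `end`, `members`
#'   (comma-separated SNP ids).
#' @export
cluster_loci <- function(significant, window = 150000) {
  df <- as.data.frame(significant)
  if (nrow(df) == 0)
    return(structure(data.frame(), class = c("locus_table", "data.frame")))
  df <- df[!is.na(df$p), , drop = FALSE]
  assigned <- rep(FALSE, nrow(df))
  out <- list()
  while (!all(assigned)) {
    open <- which(!assigned)
    lead <- open[which.min(df$p[open])]
    memb <- open[df$chrom[open] == df$chrom[lead] &
                   abs(df$pos[open] - df$pos[lead]) <= window]
    assigned[memb] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      chrom = df$chrom[lead], lead_snp = df$snp_id[lead],
      lead_pos = df$pos[lead], lead_p = df$p[lead],
      n_snps = length(memb),
      span_bp = max(df$pos[memb]) - min(df$pos[memb]),
      start = min(df$pos[memb]), end = max(df$pos[memb]),
      members = paste(df$snp_id[memb], collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$lead_pos), , drop = FALSE]
  res$locus_id <- sprintf("locus%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  structure(res[, c("locus_id", setdiff(names(res), "locus_id"))],
            class = c("locus_table", "data.frame"))
}

#' Unify per-trait loci across traits and panels
#'
#' Loci found for different traits/panels whose lead SNPs lie within `window`
#' bp on the same chromosome are unified into one locus; each unified locus
#' lists its (trait, panel) associations and their count.
#'
#' @param locus_list named list of `locus_table`s; names are
#'   `"trait|panel"` labels, or supply data.frames carrying `trait`/`panel`
#'   columns.
#' @param window lead-SNP merge distance in bp (default 150000).
#' @return data.frame: `locus_id`, `chrom`, `lead_snp`, `lead_pos`, `lead_p`,
#'   `n_leads`, `n_associations`, `traits` (comma-separated `trait:panel`),
#'   `n_traits` (distinct traits).
#' @export
merge_across_traits <- function(locus_list, window = 150000) {
  rows <- list()
  for (nm in names(locus_list)) {
    lt <- locus_list[[nm]]
    if (nrow(lt) == 0) next
    lab <- strsplit(nm, "|", fixed = TRUE)[[1]]
    lt$trait <- lt$trait %||% lab[1]
    lt$panel <- if (length(lab) > 1) lab[2] else (lt$panel %||% "whole")
    rows[[length(rows) + 1L]] <- lt
  }
  if (!length(rows)) return(data.frame())
  all_loci <- do.call(rbind, rows)
  assigned <- rep(FALSE, nrow(all_loci))
  out <- list()
  while (!all(assigned)) {
    open <- which(!assigned)
    lead <- open[which.min(all_loci$lead_p[open])]
    memb <- open[all_loci$chrom[open] == all_loci$chrom[lead] &
                   abs(all_loci$lead_pos[open] - all_loci$lead_pos[lead]) <= window]
    assigned[memb] <- TRUE
    tp <- paste(all_loci$trait[memb], all_loci$panel[memb], sep = ":")
    out[[length(out) + 1L]] <- data.frame(
      chrom = all_loci$chrom[lead], lead_snp = all_loci$lead_snp[lead],
      lead_pos = all_loci$lead_pos[lead], lead_p = all_loci$lead_p[lead],
      n_leads = length(unique(all_loci$lead_snp[memb])),
      n_associations = length(unique(tp)),
      traits = paste(sort(unique(tp)), collapse = ","),
      n_traits = length(unique(all_loci$trait[memb])),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$lead_pos), , drop = FALSE]
  res$locus_id <- sprintf("ulocus%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("locus_id", setdiff(names(res), "locus_id"))]
}

#' Assign a SNP to a gene
#'
#' A SNP inside a gene span (1-based inclusive) is assigned to that gene; an
#' intergenic SNP is assigned to the downstream gene, interpreted as the next
#' gene in ascending genomic coordinates. A SNP beyond the last gene on its
#' chromosome gets `NA`.
#'
#' @param pos SNP position (bp).
#' @param chrom SNP chromosome.
#' @param genes list of [gene_model()] objects.
#' @return Gene id or `NA_character_`.
#' @export
annotate_snp_gene <- function(pos, chrom, genes) {
  on_chr <- Filter(function(g) g$chrom == chrom, genes)
  if (!length(on_chr)) return(NA_character_)
  starts <- unname(vapply(on_chr, function(g) g$span[1], numeric(1)))
  ends <- unname(vapply(on_chr, function(g) g$span[2], numeric(1)))
  ids <- unname(vapply(on_chr, function(g) g$gene_id, character(1)))
  inside <- which(pos >= starts & pos <= ends)
  if (length(inside)) return(ids[inside[1]])
  after <- which(starts > pos)
  if (!length(after)) {
    ag_msg("annotate_snp_gene: %s:%d beyond the last gene", chrom, pos)
    return(NA_character_)
  }
  ids[after[which.min(starts[after])]]
}

#' Select candidate genes by three criteria
#'
#' A gene is shortlisted when it meets at least one of: (1) it carries a
#' significant SNP and has a stress-related functional annotation; (2) it
#' carries SNPs significantly associated with more than `crit2_traits_gt`
#' distinct traits; (3) for some trait, the most significant SNP falls in the
#' gene and `p < 0.05 / n_eff`.
#'
#' @param significant data.frame of significant associations (columns
#'   `snp_id`, `chrom`, `pos`, `p`, `trait`; `panel` optional).
#' @param genes list of [gene_model()] objects.
#' @param annotations annotation table ([read_annotations()]) or `NULL`
#'   (disables criterion 1 with a warning).
#' @param n_eff effective marker number for criterion 3.
#' @param crit2_traits_gt criterion-2 threshold: strictly more than this many
#'   distinct traits (default 3).
#' @return data.frame of class `candidate_table`: `gene_id`, `criteria`
#'   (e.g. `"1,3"`), `best_snp`, `best_p`, `n_traits`, `annotation`.
#' @export
select_candidate_genes <- function(significant, genes, annotations, n_eff,
                                   crit2_traits_gt = 3) {
  df <- as.data.frame(significant)
  if (nrow(df) == 0)
    return(structure(data.frame(), class = c("candidate_table", "data.frame")))
  df$gene_id <- vapply(seq_len(nrow(df)), function(i)
    annotate_snp_gene(df$pos[i], df$chrom[i], genes), character(1))
  df <- df[!is.na(df$gene_id), , drop = FALSE]
  crit <- list()
  add <- function(gid, k) crit[[gid]] <<- union(crit[[gid]], k)
  if (is.null(annotations)) {
    warning("no annotation table: criterion 1 disabled")
  } else {
    stress <- annotations$gene_id[annotations$stress_related %in% TRUE]
    for (gid in intersect(unique(df$gene_id), stress)) add(gid, 1L)
  }
  traits_per_gene <- tapply(df$trait, df$gene_id, function(x) length(unique(x)))
  for (gid in names(traits_per_gene))
    if (traits_per_gene[[gid]] > crit2_traits_gt) add(gid, 2L)
  thr3 <- 0.05 / n_eff
  for (tr in unique(df$trait)) {
    sub <- df[df$trait == tr, , drop = FALSE]
    best <- which.min(sub$p)
    if (sub$p[best] < thr3) add(sub$gene_id[best], 3L)
  }
  if (!length(crit))
    return(structure(data.frame(), class = c("candidate_table", "data.frame")))
  gids <- names(crit)
  rows <- lapply(gids, function(gid) {
    sub <- df[df$gene_id == gid, , drop = FALSE]
    b <- which.min(sub$p)
    ann_txt <- if (!is.null(annotations)) {
      i <- match(gid, annotations$gene_id)
      if (is.na(i)) NA_character_ else annotations$functional_annotation[i]
    } else NA_character_
    data.frame(gene_id = gid,
               criteria = paste(sort(crit[[gid]]), collapse = ","),
               best_snp = sub$snp_id[b], best_p = sub$p[b],
               n_traits = length(unique(sub$trait)),
               annotation = ann_txt, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$best_p), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("candidate_table", "data.frame"))
}
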