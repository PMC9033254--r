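#' SNP genotype table
#'
#' A `variant_table` holds biallelic SNP genotypes for a panel of (largely
#' inbred) accessions as alternate-allele dosages. It is the common genotype
#' container consumed by the kinship, association-scan, LD and haplotype code.
#'
#' @param info data.frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt` (single nucleotides).
#' @param geno integer matrix, accessions x SNPs, entries in `{0, 1, 2, NA}`
#'   counting alternate alleles. Row names are accession ids, column names SNP
#'   ids.
#' @return An object of class `variant_table`: a list with elements `info` and
#'   `geno`, sorted by chromosome then position.
#' @export
variant_table <- function(info, geno) {
  stopifnot(is.data.frame(info), is.matrix(geno))
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(info)))
    ag_stop(paste("variant info must have columns:", paste(need, collapse = ", ")),
            "alkagerm_format_error")
  if (nrow(info) != ncol(geno))
    ag_stop("geno must have one column per SNP", "alkagerm_format_error")
  if (!all(info$ref %in% c("A", "C", "G", "T")) ||
      !all(info$alt %in% c("A", "C", "G", "T")))
    ag_stop("alleles must be single nucleotides A/C/G/T", "alkagerm_format_error")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) ag_stop("dosages must be 0, 1, 2 or NA", "alkagerm_format_error")
  storage.mode(geno) <- "integer"
  colnames(geno) <- info$snp_id
  ## canonical order: chromosome, then strictly increasing position
  o <- order(info$chrom, info$pos)
  info <- info[o, , drop = FALSE]
  geno <- geno[, o, drop = FALSE]
  rownames(info) <- NULL
  dup <- stats::ave(info$pos, info$chrom, FUN = function(p) c(0, diff(p)) == 0 & seq_along(p) > 1)
  if (any(dup == 1))
    ag_stop("positions must be strictly increasing within a chromosome",
            "alkagerm_format_error")
  structure(list(info = info, geno = geno), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d SNPs x %d accessions on %d chromosome(s)\n",
              nrow(x$info), nrow(x$geno), length(unique(x$info$chrom))))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$geno), nrow(x$info))

n_accessions <- function(vt) nrow(vt$geno)
n_snps <- function(vt) nrow(vt$info)

#' Subset a variant table
#'
#' @param vt a [variant_table()].
#' @param snps SNP ids or column indices (optional).
#' @param accessions accession ids or row indices (optional).
#' @return A `variant_table` restricted to the requested SNPs/accessions.
#' @export
subset_variants <- function(vt, snps = NULL, accessions = NULL) {
  info <- vt$info
  geno <- vt$geno
  if (!is.null(snps)) {
    idx <- if (is.character(snps)) match(snps, info$snp_id) else snps
    if (anyNA(idx)) ag_stop("unknown SNP id in subset", "alkagerm_lookup_error")
    info <- info[idx, , drop = FALSE]
    geno <- geno[, idx, drop = FALSE]
  }
  if (!is.null(accessions)) {
    idx <- if (is.character(accessions)) match(accessions, rownames(geno)) else accessions
    if (anyNA(idx))
      ag_stop(sprintf("accession(s) not present: %s",
                      paste(setdiff(accessions, rownames(vt$geno)), collapse = ", ")),
              "alkagerm_lookup_error")
    geno <- geno[idx, , drop = FALSE]
  }
  variant_table(info, geno)
}

#' Per-SNP minor allele frequency and missingness
#'
#' Frequencies are computed on non-missing calls only.
#'
#' @param vt a [variant_table()].
#' @return data.frame with `snp_id`, `maf`, `missing_rate`, `alt_freq`.
#' @export
snp_stats <- function(vt) {
  g <- vt$geno
  n_called <- colSums(!is.na(g))
  alt_freq <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  alt_freq[n_called == 0] <- NA_real_
  data.frame(
    snp_id = vt$info$snp_id,
    alt_freq = alt_freq,
    maf = pmin(alt_freq, 1 - alt_freq),
    missing_rate = colSums(is.na(g)) / nrow(g),
    stringsAsFactors = FALSE
  )
}
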