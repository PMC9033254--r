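#' Read biallelic SNP genotypes from a VCF file
#'
#' Loads a VCF 4.x file (via \pkg{vcfR}) and converts diploid GT calls to
#' alternate-allele dosages. Only biallelic SNP records are kept; indels and
#' multi-allelic records are skipped (never split) and counted. Half-calls and
#' non-diploid genotypes become missing.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param sample_subset optional character vector of sample ids to keep; an
#'   unknown id is an error naming the id.
#' @return A [variant_table()]. The number of skipped non-biallelic-SNP records
#'   is available as `attr(, "n_skipped")`.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path))
    ag_stop(sprintf("VCF file not found: %s", path), "alkagerm_io_error")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  is_snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    ag_msg("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skipped)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) ag_stop("VCF has no GT field", "alkagerm_format_error")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  if (!is.null(sample_subset)) {
    missing_ids <- setdiff(sample_subset, colnames(gt))
    if (length(missing_ids))
      ag_stop(sprintf("sample id(s) not present in VCF: %s",
                      paste(missing_ids, collapse = ", ")),
              "alkagerm_lookup_error")
    gt <- gt[, sample_subset, drop = FALSE]
  }
  geno <- t(gt_to_dosage(gt))
  ids <- fix$ID
  auto <- is.na(ids) | ids == "." | ids == ""
  ids[auto] <- paste0("rs_", fix$CHROM[auto], "_", fix$POS[auto])
  info <- data.frame(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = toupper(fix$REF), alt = toupper(fix$ALT), stringsAsFactors = FALSE
  )
  vt <- variant_table(info, geno)
  attr(vt, "n_skipped") <- n_skipped
  vt
}

## GT string matrix (SNPs x samples) -> integer dosage matrix.
## "0/0"->0, "0/1"/"1/0"->1, "1/1"->2; anything with ".", or not two alleles
## from {0,1}, -> NA. Accepts phased separators.
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  d[norm == "0/0"] <- 0L
  d[norm == "0/1" | norm == "1/0"] <- 1L
  d[norm == "1/1"] <- 2L
  d
}

#' Write a variant table as a VCF file
#'
#' Emits a minimal VCF 4.2 file with unphased diploid GT calls (`0/0`, `0/1`,
#' `1/1`, missing as `./.`). Round-trips losslessly through [read_vcf()].
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  samples <- rownames(vt$geno)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=alkagerm",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_snps(vt), ncol = length(samples))
  ok <- !is.na(t(vt$geno))
  gt[ok] <- code[t(vt$geno)[ok] + 1L]
  body <- paste(
    vt$info$chrom, vt$info$pos, vt$info$snp_id, vt$info$ref, vt$info$alt,
    ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
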