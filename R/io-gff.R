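#' Gene model with CDS segments
#'
#' @param gene_id gene identifier (e.g. `LOC_Os01g12000`).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds two-column matrix of 1-based inclusive `(start, end)` CDS
#'   segments in genomic coordinates. Stored ordered 5'->3' in transcript
#'   orientation (ascending start for `+`, descending for `-`).
#' @param span optional gene span `(start, end)`; defaults to the CDS extent.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds, span = NULL) {
  stopifnot(strand %in% c("+", "-"))
  cds <- matrix(as.integer(cds), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  if (any(cds[, 2] < cds[, 1]))
    ag_stop(sprintf("gene %s: CDS segment end before start", gene_id),
            "alkagerm_format_error")
  o <- order(cds[, 1], decreasing = (strand == "-"))
  cds <- cds[o, , drop = FALSE]
  ## non-overlap check in genomic order
  g <- cds[order(cds[, 1]), , drop = FALSE]
  if (nrow(g) > 1 && any(g[-1, 1] <= g[-nrow(g), 2]))
    ag_stop(sprintf("gene %s: overlapping CDS segments", gene_id),
            "alkagerm_format_error")
  len <- sum(cds[, 2] - cds[, 1] + 1L)
  if (len %% 3L != 0L)
    ag_stop(sprintf("gene %s: CDS length %d not divisible by 3", gene_id, len),
            "alkagerm_cds_error")
  span <- as.integer(span %||% c(min(cds[, 1]), max(cds[, 2])))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, span = span, cds_length = len),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d (%s), %d CDS segment(s), %d bp CDS\n",
              x$gene_id, x$chrom, x$span[1], x$span[2], x$strand,
              nrow(x$cds), x$cds_length))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features (via \pkg{rtracklayer}) into a list of
#' [gene_model()] objects, one per gene. When a gene has several mRNAs the
#' first is used. CDS phase is ignored, but the total CDS length of each gene
#' must be divisible by 3.
#'
#' @param path GFF3 file path.
#' @return Named list of `gene_model` objects (possibly empty).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path))
    ag_stop(sprintf("GFF3 file not found: %s", path), "alkagerm_io_error")
  if (length(readLines(path, n = 50, warn = FALSE)) == 0) return(list())
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(list())
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  out <- list()
  for (i in seq_along(genes)) {
    gid <- genes$ID[i]
    if (is.null(gid) || is.na(gid)) gid <- genes$Name[i]
    mrna <- gr[typ == "mRNA" & vapply(gr$Parent, function(p) gid %in% p, logical(1))]
    if (length(mrna) == 0) next
    tid <- mrna$ID[1]
    cds <- gr[typ == "CDS" & vapply(gr$Parent, function(p) tid %in% p, logical(1))]
    if (length(cds) == 0) next
    out[[gid]] <- gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(genes))[i],
      strand = as.character(GenomicRanges::strand(genes))[i],
      cds = cbind(GenomicRanges::start(cds), GenomicRanges::end(cds)),
      span = c(GenomicRanges::start(genes)[i], GenomicRanges::end(genes)[i])
    )
  }
  out
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features (1-based inclusive coordinates per the
#' GFF3 standard) readable by [read_gff3()].
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    gid <- g$gene_id
    lines <- c(lines,
      paste(g$chrom, "alkagerm", "gene", g$span[1], g$span[2], ".", g$strand,
            ".", sprintf("ID=%s;Name=%s", gid, gid), sep = "\t"),
      paste(g$chrom, "alkagerm", "mRNA", g$span[1], g$span[2], ".", g$strand,
            ".", sprintf("ID=%s.1;Parent=%s", gid, gid), sep = "\t"))
    cds <- g$cds[order(g$cds[, 1]), , drop = FALSE]
    for (k in seq_len(nrow(cds))) {
      lines <- c(lines,
        paste(g$chrom, "alkagerm", "CDS", cds[k, 1], cds[k, 2], ".", g$strand,
              "0", sprintf("ID=%s.1.cds;Parent=%s.1", gid, gid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract the CDS nucleotide sequence of a gene
#'
#' Returns the coding sequence in transcript orientation: segments are
#' concatenated 5'->3' and reverse-complemented for minus-strand genes.
#'
#' @param gene a [gene_model()].
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @return A `DNAString` of length `gene$cds_length`.
#' @export
cds_sequence <- function(gene, genome) {
  chrom_seq <- genome[[gene$chrom]]
  if (is.null(chrom_seq))
    ag_stop(sprintf("chromosome %s absent from reference", gene$chrom),
            "alkagerm_lookup_error")
  segs <- gene$cds[order(gene$cds[, 1]), , drop = FALSE]
  parts <- lapply(seq_len(nrow(segs)), function(k)
    Biostrings::subseq(chrom_seq, segs[k, 1], segs[k, 2]))
  s <- do.call(Biostrings::xscat, parts)
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}
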