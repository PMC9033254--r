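# Programmatic fixtures shared across test files.

# A tiny hand-written VCF (3 samples, 2 SNPs + 1 indel record).
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("chr1", "100", "snpA", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", "indel1", "A", "AT", ".", "PASS", ".", "GT",
          "0/0", "0/0", "1/1", sep = "\t"),
    paste("chr1", "300", "snpB", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "./.", "0/1", sep = "\t")
  ), path)
  path
}

# Small variant table built in code (n accessions x m SNPs, inbred unless
# dosages given).
make_vt <- function(dosages, pos = NULL, chrom = "chr1",
                    ref = NULL, alt = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("acc%03d", seq_len(nrow(dosages)))
  variant_table(
    data.frame(snp_id = sprintf("s%d", seq_len(m)), chrom = chrom, pos = pos,
               ref = ref, alt = alt, stringsAsFactors = FALSE),
    dosages
  )
}

# One germination-counts replicate row as used by the trait operations.
make_gc_row <- function(counts, n0 = 20, accession = "a1",
                        condition = "stress", replicate = 1,
                        rl = NA_real_, sl = NA_real_) {
  stopifnot(length(counts) == 7)
  df <- data.frame(accession = accession, condition = condition,
                   replicate = replicate, total_seeds = n0,
                   stringsAsFactors = FALSE)
  df[paste0("d", 1:7)] <- as.list(as.integer(counts))
  df$root_length_cm <- rl
  df$shoot_length_cm <- sl
  class(df) <- c("germination_counts", "data.frame")
  df
}

# Small, fast simulation configuration for end-to-end tests.
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_accessions = 120, n_snps = 600, n_chromosomes = 3,
               n_genes = 8, snp_spacing = 400, ld_block_len = 8000,
               causal_genes = data.frame(gene = 1, effect = 1.2),
               missing_rate = 0.01, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
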