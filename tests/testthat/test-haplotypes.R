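toy_genome <- function(chr_seq) Biostrings::DNAStringSet(c(chr1 = chr_seq))

test_that("plus-strand codon effects follow the genetic code", {
  ## CDS 11..19, codons: ATG GGA AAA; SNPs at third position of codon 2
  ## (GGA->GGG synonymous) and second of codon 3 (AAA->AGA missense)
  seqs <- paste0(strrep("T", 10), "ATGGGAAAA", strrep("T", 10))
  gene <- gene_model("g+", "chr1", "+", cbind(11L, 19L))
  vt <- make_vt(matrix(c(0L, 2L, 0L, 2L), 2, 2), pos = c(16L, 18L),
                ref = c("A", "A"), alt = c("G", "G"))
  eff <- classify_cds_snps(gene, toy_genome(seqs), vt)
  expect_equal(eff$effect, c("synonymous", "missense"))
  expect_equal(eff$pos_in_codon, c(3L, 2L))
  expect_equal(eff$ref_aa, c("G", "K"))
  expect_equal(eff$alt_aa, c("G", "R"))
})

test_that("minus-strand genomic C>T gives transcript G>A, GAA>AAA missense", {
  ## transcript GAA TTT TAA; genomic slice 10..18 is its reverse complement
  tx <- "GAATTTTAA"
  genomic <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  seqs <- paste0(strrep("C", 9), genomic, strrep("C", 10))
  gene <- gene_model("g-", "chr1", "-", cbind(10L, 18L))
  vt <- make_vt(matrix(c(0L, 2L), 2, 1), pos = 18L, ref = "C", alt = "T")
  eff <- classify_cds_snps(gene, toy_genome(seqs), vt)
  expect_equal(eff$pos_in_codon, 1L)
  expect_equal(eff$ref_codon, "GAA")
  expect_equal(eff$alt_codon, "AAA")
  expect_equal(eff$effect, "missense")
  ## and the whole-CDS translation oracle agrees
  expect_equal(oracle_snp_effect(gene, toy_genome(seqs), 18L, "C", "T"),
               "missense")
})

test_that("classification agrees with whole-CDS translation on random SNPs", {
  cfg <- small_sim_config(seed = 161)
  pop <- simulate_population(cfg)
  gm <- simulate_gene_models(cfg, pop$variants, pop$metadata)
  info <- pop$variants$info
  checked <- 0L
  for (gene in gm$genes) {
    eff <- classify_cds_snps(gene, gm$genome, pop$variants)
    for (i in seq_len(nrow(eff))) {
      j <- match(eff$snp_id[i], info$snp_id)
      expect_equal(eff$effect[i],
                   oracle_snp_effect(gene, gm$genome, info$pos[j],
                                     info$ref[j], info$alt[j]),
                   info = eff$snp_id[i])
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("mismatching reference base is an error naming the SNP", {
  seqs <- paste0(strrep("T", 10), "ATGGGAAAA", strrep("T", 10))
  gene <- gene_model("g+", "chr1", "+", cbind(11L, 19L))
  vt <- make_vt(matrix(0L, 2, 1), pos = 16L, ref = "C", alt = "G")
  expect_error(classify_cds_snps(gene, toy_genome(seqs), vt), "s1")
})

test_that("haplotypes are keyed on non-synonymous alleles only", {
  ## 30 accessions, 2 non-synonymous SNPs + 1 synonymous:
  ## patterns (0,0) x15, (2,2) x12, (0,2) x3 -> Hap1 15, Hap2 12, rare 3
  seqs <- paste0(strrep("T", 10), "ATGGGAAAAGCA", strrep("T", 10))
  gene <- gene_model("g", "chr1", "+", cbind(11L, 22L))
  pat <- rbind(matrix(rep(c(0L, 0L), 15), ncol = 2, byrow = TRUE),
               matrix(rep(c(2L, 2L), 12), ncol = 2, byrow = TRUE),
               matrix(rep(c(0L, 2L), 3), ncol = 2, byrow = TRUE))
  syn <- sample(c(0L, 2L), 30, replace = TRUE)
  g <- cbind(pat[, 1], syn, pat[, 2])
  vt <- make_vt(g, pos = c(17L, 16L, 18L), ref = c("A", "A", "A"),
                alt = c("C", "G", "G"))
  eff <- classify_cds_snps(gene, toy_genome(seqs), vt)
  expect_equal(sum(eff$effect == "synonymous"), 1L)
  h <- build_haplotypes(gene, eff, vt, min_size = 10)
  expect_equal(h$table$haplotype, c("Hap1", "Hap2", "rare"))
  expect_equal(h$table$n, c(15L, 12L, 3L))
  ## two accessions differing only at the synonymous SNP share a haplotype
  expect_equal(length(h$defining_snps), 2L)
})

test_that("synonymous-only variation merges everyone into one haplotype", {
  seqs <- paste0(strrep("T", 10), "ATGGGAAAA", strrep("T", 10))
  gene <- gene_model("g", "chr1", "+", cbind(11L, 19L))
  vt <- make_vt(matrix(sample(c(0L, 2L), 40, TRUE), 40, 1), pos = 16L,
                ref = "A", alt = "G")   # GGA->GGG synonymous
  eff <- classify_cds_snps(gene, toy_genome(seqs), vt)
  h <- build_haplotypes(gene, eff, vt)
  expect_equal(length(h$defining_snps), 0L)
  expect_equal(nrow(h$table), 0L)
})

test_that("heterozygous and missing defining genotypes exclude the accession", {
  seqs <- paste0(strrep("T", 10), "ATGAAAAAA", strrep("T", 10))
  gene <- gene_model("g", "chr1", "+", cbind(11L, 19L))
  g <- matrix(c(0L, 2L, 1L, NA, rep(0L, 20)), ncol = 1)
  vt <- make_vt(g, pos = 15L, ref = "A", alt = "G")  # AAA->AGA missense
  eff <- classify_cds_snps(gene, toy_genome(seqs), vt)
  h <- build_haplotypes(gene, eff, vt, min_size = 2)
  expect_equal(h$n_excluded, 2L)
  expect_equal(sum(h$table$n), 22L)
})

test_that("subpopulation frequencies count members and sum to one", {
  h <- structure(list(
    gene_id = "g", defining_snps = "s1",
    table = data.frame(haplotype = c("Hap1", "Hap2"), alleles = c("A", "G"),
                       n = c(4L, 3L)),
    assignment = setNames(c(rep("Hap1", 4), rep("Hap2", 3)),
                          sprintf("a%d", 1:7)),
    n_excluded = 0L), class = "cds_haplotypes")
  meta <- data.frame(accession = sprintf("a%d", 1:7),
                     subpopulation = c(rep("Xian", 4), rep("Geng", 3)))
  fr <- haplotype_subpop_frequencies(h, meta)
  expect_equal(fr$proportion[fr$haplotype == "Hap1" & fr$subpopulation == "Xian"], 1)
  expect_equal(fr$count[fr$haplotype == "Hap1" & fr$subpopulation == "Geng"], 0L)
  sums <- tapply(fr$proportion, fr$subpopulation, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("favorable haplotype maximizes mean RGE with size tie-break", {
  h <- structure(list(
    gene_id = "g", defining_snps = "s1",
    table = data.frame(),
    assignment = setNames(c(rep("Hap1", 40), rep("Hap2", 20)),
                          sprintf("a%d", 1:60)),
    n_excluded = 0L), class = "cds_haplotypes")
  tv <- setNames(c(rep(0.30, 40), rep(0.18, 20)), sprintf("a%d", 1:60))
  expect_equal(as.character(favorable_haplotype(h, tv)), "Hap1")
  ## exact tie: larger haplotype wins
  tv2 <- setNames(rep(0.25, 60), sprintf("a%d", 1:60))
  expect_equal(as.character(favorable_haplotype(h, tv2)), "Hap1")
})

test_that("combination analysis drops rare patterns and orders by mean", {
  set.seed(171)
  acc <- sprintf("a%03d", 1:100)
  mk_h <- function(assign) structure(
    list(gene_id = "g", defining_snps = "s", table = data.frame(),
         assignment = assign, n_excluded = 0L), class = "cds_haplotypes")
  a1 <- setNames(rep(c("Hap1", "Hap2"), c(55, 45)), acc)
  a2 <- setNames(rep(c("Hap1", "Hap2", "Hap1"), c(40, 46, 14)), acc)
  hl <- list(g1 = mk_h(a1), g2 = mk_h(a2))
  fav <- c(g1 = "Hap1", g2 = "Hap2")
  nfav <- (a1 == "Hap1") + (a2 == "Hap2")
  tv <- setNames(0.1 + 0.1 * nfav + rnorm(100, 0, 0.02), acc)
  cmb <- combine_haplotypes(hl, fav, tv, min_group = 15)
  ret <- cmb$table[cmb$table$retained, ]
  expect_true(all(ret$n >= 15))
  ## the 14-member pattern (+ then Hap1 on g2) is dropped
  expect_true(any(!cmb$table$retained & cmb$table$n == 14))
  expect_gt(cmb$rho, 0)
  expect_false(is.unsorted(rev(ret$mean)))
})

test_that("qPCR fold change follows 2^-ddCt", {
  expect_equal(expression_fold_change(5 + 1, 1, 3 + 1, 1), 0.25)
  expect_equal(expression_fold_change(2, 2, 2, 2), 1)
  expect_equal(expression_fold_change(20, 21, 20, 20), 2)
})
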