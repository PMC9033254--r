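test_that("inbred construction: no missingness at rate 0, dosages in {0, 2}", {
  cfg <- small_sim_config(missing_rate = 0)
  pop <- simulate_population(cfg)
  expect_false(anyNA(pop$variants$geno))
  expect_true(all(pop$variants$geno %in% c(0L, 2L)))
  expect_equal(nrow(pop$variants$geno), 120L)
})

test_that("Hudson FST over SNPs recovers the Balding-Nichols parameter", {
  ## fst 0.3, 200 accessions, 2000 SNPs; estimator computed by the
  ## independent brute-force oracle
  cfg <- sim_config(n_accessions = 200, n_snps = 2000, n_chromosomes = 2,
                    snp_spacing = 400, fst = 0.3, missing_rate = 0,
                    n_genes = 2, causal_genes = data.frame(), seed = 7)
  pop <- simulate_population(cfg)
  fst_hat <- oracle_hudson_fst(pop$variants$geno, pop$metadata$subpopulation)
  expect_lt(abs(fst_hat - 0.3), 0.08)
})

test_that("the generator is deterministic: same seed gives identical VCF bytes", {
  cfg <- small_sim_config(seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  expect_identical(readLines(file.path(d1, "genotypes.vcf")),
                   readLines(file.path(d2, "genotypes.vcf")))
  expect_identical(readLines(file.path(d1, "phenotypes.tsv")),
                   readLines(file.path(d2, "phenotypes.tsv")))
  expect_identical(readLines(file.path(d1, "genes.gff3")),
                   readLines(file.path(d2, "genes.gff3")))
})

test_that("gene models are consistent with the emitted reference", {
  cfg <- small_sim_config(seed = 2)
  pop <- simulate_population(cfg)
  gm <- simulate_gene_models(cfg, pop$variants, pop$metadata)
  ## FASTA base at every SNP position equals the ref allele
  info <- pop$variants$info
  for (ch in unique(info$chrom)) {
    seqs <- as.character(gm$genome[[ch]])
    sel <- info$chrom == ch
    got <- vapply(info$pos[sel], function(p) substr(seqs, p, p), character(1))
    expect_equal(got, info$ref[sel])
  }
  ## both strands represented; CDS lengths divisible by 3
  strands <- vapply(gm$genes, function(g) g$strand, character(1))
  expect_setequal(unique(strands), c("+", "-"))
  expect_true(all(vapply(gm$genes, function(g) g$cds_length %% 3, numeric(1)) == 0))
  ## minus-strand CDS sequence is the reverse complement of the genomic slice
  neg <- gm$genes[[which(strands == "-")[1]]]
  s <- cds_sequence(neg, gm$genome)
  fwd <- Biostrings::subseq(gm$genome[[neg$chrom]], neg$span[1], neg$span[2])
  expect_equal(as.character(s),
               as.character(Biostrings::reverseComplement(fwd)))
})

test_that("planted causal SNPs are verified non-synonymous by translation", {
  cfg <- small_sim_config(seed = 3)
  pop <- simulate_population(cfg)
  gm <- simulate_gene_models(cfg, pop$variants, pop$metadata)
  expect_equal(nrow(gm$causal), 1L)
  info <- pop$variants$info
  i <- match(gm$causal$snp_id, info$snp_id)
  gene <- gm$genes[[gm$causal$gene_id]]
  eff <- oracle_snp_effect(gene, gm$genome, info$pos[i], info$ref[i], info$alt[i])
  expect_equal(eff, "missense")
  ## reference CDS translates cleanly: starts with M, single terminal stop
  aa <- as.character(Biostrings::translate(cds_sequence(gene, gm$genome)))
  expect_equal(substr(aa, 1, 1), "M")
  expect_equal(gregexpr("\\*", aa)[[1]], nchar(aa), ignore_attr = TRUE)
})

test_that("null germination model: stress and control rates indistinguishable", {
  cfg <- sim_config(n_accessions = 200, n_snps = 300, n_chromosomes = 2,
                    n_genes = 2, causal_genes = data.frame(),
                    delta_stress = 0, gamma_tolerance = 0,
                    day_sdlog = c(control = 0.2, stress = 0.2),
                    subpop_latent_shift = 0, missing_rate = 0, seed = 9)
  pop <- simulate_population(cfg)
  truth <- build_sim_truth(cfg, pop$variants, pop$metadata, data.frame())
  ph <- simulate_germination(cfg, truth)
  tt <- compute_trait_table(ph)
  expect_gt(t.test(tt$GRS, tt$GRC)$p.value, 0.01)
})

test_that("tolerant accessions germinate relatively better under stress", {
  ## positive tolerance slope: Spearman correlation between the latent value
  ## and RGR is positive across accessions, in every one of 20 replicates
  hits <- vapply(1:20, function(r) {
    cfg <- sim_config(n_accessions = 100, n_snps = 200, n_chromosomes = 1,
                      n_genes = 1, causal_genes = data.frame(),
                      missing_rate = 0, seed = 100 + r)
    pop <- simulate_population(cfg)
    truth <- build_sim_truth(cfg, pop$variants, pop$metadata, data.frame())
    ph <- simulate_germination(cfg, truth)
    tt <- compute_trait_table(ph)
    cor(truth$latent[tt$accession], tt$RGR, method = "spearman",
        use = "pairwise.complete.obs")
  }, numeric(1))
  expect_true(all(hits > 0))
})

test_that("all-germinating control config yields control GR of exactly 1", {
  cfg <- sim_config(n_accessions = 40, n_snps = 100, n_chromosomes = 1,
                    n_genes = 1, causal_genes = data.frame(),
                    viability = 1.0, mu_control = 3,
                    day_sdlog = c(control = 0.05, stress = 0.05),
                    missing_rate = 0, seed = 13)
  pop <- simulate_population(cfg)
  truth <- build_sim_truth(cfg, pop$variants, pop$metadata, data.frame())
  ph <- simulate_germination(cfg, truth)
  ctl <- ph[ph$condition == "control", ]
  expect_true(all(rowSums(ctl[paste0("d", 1:7)]) == ctl$total_seeds))
})

test_that("truth round trip: the tolerant haplotype has the higher mean RGE", {
  ## planted effect >= 1 SD, checked over replicates
  ok <- vapply(1:5, function(r) {
    cfg <- small_sim_config(seed = 300 + r)
    ds <- simulate_dataset(cfg)
    tt <- compute_trait_table(ds$phenotypes)
    tv <- setNames(tt$RGE, tt$accession)
    g <- attr(ds$variants, "geno_complete")[, ds$causal$snp_id[1]]
    tol <- ds$causal$tolerant_allele[1] ==
      ds$variants$info$alt[match(ds$causal$snp_id[1], ds$variants$info$snp_id)]
    carrier <- if (tol) g == 2 else g == 0
    mean(tv[carrier], na.rm = TRUE) > mean(tv[!carrier], na.rm = TRUE)
  }, logical(1))
  expect_true(all(ok))
})
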