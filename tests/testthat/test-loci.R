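sig_df <- function(pos, p, chrom = "chr1") {
  data.frame(snp_id = sprintf("s%d", seq_along(pos)), chrom = chrom,
             pos = pos, p = p, stringsAsFactors = FALSE)
}

test_that("locus clustering follows the greedy lowest-p lead rule", {
  ## single SNP
  one <- cluster_loci(sig_df(1e5, 1e-8))
  expect_equal(nrow(one), 1L)
  expect_equal(one$lead_snp, "s1")

  ## 100 kb (1e-8), 150 kb (1e-7), 500 kb (1e-9): the 500-kb SNP leads its
  ## own locus; the 100-kb SNP absorbs the 150-kb one
  res <- cluster_loci(sig_df(c(1e5, 1.5e5, 5e5), c(1e-8, 1e-7, 1e-9)))
  expect_equal(nrow(res), 2L)
  solo <- res[res$lead_pos == 5e5, ]
  expect_equal(solo$n_snps, 1L)
  pair <- res[res$lead_pos == 1e5, ]
  expect_equal(pair$n_snps, 2L)
  expect_match(pair$members, "s2")

  ## two SNPs 400 kb apart -> two loci
  far <- cluster_loci(sig_df(c(1e5, 5e5), c(1e-8, 1e-8)))
  expect_equal(nrow(far), 2L)
})

test_that("every significant SNP lands in exactly one locus, spans <= 300 kb", {
  set.seed(91)
  df <- sig_df(sort(sample.int(3e6, 80)), runif(80, 1e-12, 1e-6))
  res <- cluster_loci(df)
  members <- unlist(strsplit(res$members, ","))
  expect_setequal(members, df$snp_id)
  expect_equal(length(members), nrow(df))
  expect_true(all(res$span_bp <= 3e5))
  ## leads carry the minimum p of their members
  for (i in seq_len(nrow(res))) {
    ms <- strsplit(res$members[i], ",")[[1]]
    expect_equal(res$lead_p[i], min(df$p[df$snp_id %in% ms]))
  }
})

test_that("cross-trait unification merges nearby leads and counts associations", {
  lt1 <- cluster_loci(sig_df(1e5, 1e-8))
  lt2 <- cluster_loci(sig_df(1e5, 1e-9))
  uni <- merge_across_traits(list("GRS|whole" = lt1, "RGR|whole" = lt2))
  expect_equal(nrow(uni), 1L)
  expect_equal(uni$n_associations, 2L)
  expect_equal(uni$n_traits, 2L)

  lt3 <- cluster_loci(sig_df(3.1e5, 1e-7))   # 210 kb away -> separate
  uni2 <- merge_across_traits(list("GRS|whole" = lt1, "MGTS|Xian" = lt3))
  expect_equal(nrow(uni2), 2L)
})

test_that("SNP-to-gene assignment: inside, downstream, boundary", {
  genes <- list(
    A = gene_model("A", "chr1", "+", cbind(5000L, 6999L + 1L)),
    B = gene_model("B", "chr1", "-", cbind(14000L, 15999L + 1L))
  )
  expect_equal(annotate_snp_gene(6000, "chr1", genes), "A")
  expect_equal(annotate_snp_gene(11000, "chr1", genes), "B")  # downstream
  expect_equal(annotate_snp_gene(5000, "chr1", genes), "A")   # start inclusive
  expect_true(is.na(annotate_snp_gene(2e6, "chr1", genes)))
  expect_true(is.na(annotate_snp_gene(6000, "chr9", genes)))
})

test_that("candidate-gene criteria: provenance, strict >3 traits, top-SNP rule", {
  genes <- list(
    A = gene_model("A", "chr1", "+", cbind(1000L, 1998L)),
    B = gene_model("B", "chr1", "+", cbind(50000L, 50998L)),
    C = gene_model("C", "chr1", "+", cbind(90000L, 90998L))
  )
  ann <- data.frame(gene_id = c("A", "B", "C"),
                    functional_annotation = c("stress thing", "x", "y"),
                    stress_related = c(TRUE, FALSE, FALSE))
  mk <- function(pos, p, trait) data.frame(
    snp_id = sprintf("r%d", seq_along(pos)), chrom = "chr1", pos = pos,
    p = p, trait = trait, stringsAsFactors = FALSE)
  ## A: stress-annotated with one significant SNP -> criterion 1
  ## B: significant for exactly 3 traits -> NOT via criterion 2
  ## C: significant for 4 traits -> criterion 2
  sig <- rbind(
    mk(1500, 1e-7, "GRS"),
    mk(rep(50500, 3), rep(1e-7, 3), c("GRS", "RGR", "RVI")),
    mk(rep(90500, 4), rep(2e-7, 4), c("GRS", "RGR", "RVI", "RGE"))
  )
  res <- select_candidate_genes(sig, genes, ann, n_eff = 1e4)
  expect_true("A" %in% res$gene_id)
  expect_match(res$criteria[res$gene_id == "C"], "2")
  expect_false("B" %in% res$gene_id[grepl("2", res$criteria)])
  ## criterion 3: minimum-p SNP per trait, below 0.05 / n_eff = 5e-6
  expect_true(grepl("3", res$criteria[res$gene_id == "A"]))
  ## monotonicity: removing the annotation table never adds genes
  res_noann <- suppressWarnings(
    select_candidate_genes(sig, genes, NULL, n_eff = 1e4))
  expect_true(all(res_noann$gene_id %in% res$gene_id))
})

test_that("planted causal gene is recovered as a candidate end to end", {
  cfg <- small_sim_config(seed = 77, missing_rate = 0)
  ds <- simulate_dataset(cfg)
  tt <- compute_trait_table(ds$phenotypes)
  vt <- filter_variants(ds$variants)
  K <- ibs_kinship(subset_variants(vt, snps = ld_prune(vt)))
  pcs <- pca_covariates(K)
  y <- tt$RGE[match(rownames(vt$geno), tt$accession)]
  X <- cbind(1, pcs)
  fit <- suppressWarnings(reml_fit(y, X, K))
  scan <- association_scan(y, X, fit, vt, trait = "RGE")
  n_eff <- effective_marker_number(vt)
  sig <- scan[!is.na(scan$p) & scan$p < significance_threshold(n_eff), ]
  cand <- select_candidate_genes(sig, ds$genes, ds$annotations, n_eff)
  expect_true(ds$causal$gene_id[1] %in% cand$gene_id)
})

test_that("pairwise LD statistics match the haplotype-count definitions", {
  ## duplicated column: r2 = 1, D' = 1
  set.seed(101)
  a <- sample(c(0L, 2L), 100, replace = TRUE)
  vt <- make_vt(cbind(a, a))
  ld <- ld_statistics(vt)
  expect_equal(ld$r2[1, 2], 1)
  expect_equal(ld$dprime[1, 2], 1)
  ## independent SNPs at large n: r2 near 0
  set.seed(102)
  vt2 <- make_vt(cbind(sample(c(0L, 2L), 2000, TRUE),
                       sample(c(0L, 2L), 2000, TRUE)))
  expect_lt(ld_statistics(vt2)$r2[1, 2], 0.01)
  ## hand counts (50, 0, 0, 50): D' = 1, r2 = 1; balanced (25 each): 0, 0
  g_coupled <- cbind(c(rep(0L, 50), rep(2L, 50)), c(rep(0L, 50), rep(2L, 50)))
  ldc <- ld_statistics(make_vt(g_coupled))
  expect_equal(unname(ldc$dprime[1, 2]), 1)
  g_bal <- cbind(rep(c(0L, 0L, 2L, 2L), 25), rep(c(0L, 2L, 0L, 2L), 25))
  ldb <- ld_statistics(make_vt(g_bal))
  expect_equal(unname(ldb$r2[1, 2]), 0)
  expect_equal(unname(ldb$dprime[1, 2]), 0)
})

test_that("LD block detection honours generator truth and always holds the anchor", {
  ## two founder-copied blocks with an abrupt recombination break
  set.seed(111)
  n <- 150
  founders1 <- matrix(sample(0:1, 4 * 10, TRUE), 4)
  founders2 <- matrix(sample(0:1, 4 * 10, TRUE), 4)
  f1 <- sample(1:4, n, TRUE); f2 <- sample(1:4, n, TRUE)
  g <- cbind(2L * founders1[f1, ], 2L * founders2[f2, ])
  pos <- c(seq(1000, 10000, length.out = 10),
           seq(11000, 20000, length.out = 10))
  vt <- make_vt(g, pos = as.integer(pos))
  blk <- detect_ld_block(5000, vt)
  expect_gte(blk$start, 1000); expect_lte(blk$end, 11000)
  expect_true(blk$start <= blk$anchor_pos && blk$anchor_pos <= blk$end)
  ## single SNP: degenerate block
  blk1 <- detect_ld_block(100, make_vt(matrix(c(0L, 2L, 0L, 2L), 4, 1)))
  expect_equal(blk1$n_snps, 1L)
  expect_equal(blk1$start, blk1$end)
})
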