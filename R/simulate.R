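#' Configuration for the synthetic alkali-tolerance dataset
#'
#' Defines the study conditions the generator emulates: a rice diversity panel
#' of two differentiated inbred subpopulations (Xian-majority, as in a
#' 278:125-style panel), LD-blocked genotypes built from founder-haplotype
#' mosaics, single-exon gene models carrying coding SNPs, and a
#' germination-day phenotype model in which planted causal haplotypes shift
#' stress-condition germination through a latent tolerance value.
#'
#' @param n_accessions number of accessions in the panel.
#' @param subpop_fractions named proportions over subpopulations (sum to 1).
#' @param n_chromosomes,n_snps genome shape; SNPs are split evenly over
#'   chromosomes.
#' @param snp_spacing mean SNP spacing in bp (chromosome length is derived).
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param ld_block_len haplotype copy-block length in bp: LD is created by
#'   copying founder haplotypes in blocks of this length.
#' @param n_founders founder haplotypes per subpopulation.
#' @param block_switch_prob probability that an accession switches founder at
#'   a block boundary (1 = independent blocks).
#' @param n_genes number of single-exon gene models to place.
#' @param gene_cds_length CDS length in bp (divisible by 3).
#' @param causal_genes data.frame with columns `gene` (index among placed
#'   genes) and `effect` (latent-tolerance shift per founder allele, in SD
#'   units); each causal gene gets one non-synonymous coding SNP.
#' @param mu_control mean germination day under control.
#' @param delta_stress additive delay of the stress mean day (days).
#' @param gamma_tolerance days of stress delay removed per latent-tolerance SD.
#' @param day_sdlog log-scale dispersion of the germination-day distribution,
#'   named vector for `control` and `stress`.
#' @param viability probability a seed is viable at all.
#' @param subpop_latent_shift latent-tolerance gap between Xian and Geng (SD
#'   units; Xian is the more tolerant).
#' @param latent_noise_sd SD of the non-genetic latent-tolerance noise.
#' @param root_control_mean,root_control_sd,shoot_control_mean,shoot_control_sd
#'   replicate-level length model under control (cm).
#' @param root_stress_base,root_stress_slope,shoot_stress_base,shoot_stress_slope
#'   stress lengths are `base + slope * latent + noise` (cm).
#' @param length_noise_sd replicate-level length noise under stress (cm).
#' @param n_replicates,seeds_per_dish assay layout (3 dishes of 20 seeds).
#' @param missing_rate genotype missingness injected after simulation.
#' @param seed master RNG seed; the same configuration reproduces the dataset
#'   byte-identically.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 400,
                       subpop_fractions = c(Xian = 0.65, Geng = 0.35),
                       n_chromosomes = 12,
                       n_snps = 20000,
                       snp_spacing = 600,
                       fst = 0.3,
                       ld_block_len = 12000,
                       n_founders = 24,
                       block_switch_prob = 0.8,
                       n_genes = 40,
                       gene_cds_length = 999,
                       causal_genes = data.frame(gene = 1, effect = 1.0),
                       mu_control = 3.8,
                       delta_stress = 2.5,
                       gamma_tolerance = 1.2,
                       day_sdlog = c(control = 0.20, stress = 0.35),
                       viability = 0.97,
                       subpop_latent_shift = 0.8,
                       latent_noise_sd = 0.7,
                       root_control_mean = 6.9, root_control_sd = 0.5,
                       shoot_control_mean = 5.3, shoot_control_sd = 0.3,
                       root_stress_base = 1.6, root_stress_slope = 0.6,
                       shoot_stress_base = 3.9, shoot_stress_slope = 0.7,
                       length_noise_sd = 0.3,
                       n_replicates = 3, seeds_per_dish = 20,
                       missing_rate = 0.02,
                       seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(subpop_fractions) - 1) > 1e-8)
    ag_stop("subpop_fractions must sum to 1", "alkagerm_config_error")
  if (!(fst > 0 && fst < 1))
    ag_stop("fst must be in (0, 1)", "alkagerm_config_error")
  if (gene_cds_length %% 3 != 0)
    ag_stop("gene_cds_length must be divisible by 3", "alkagerm_config_error")
  if (nrow(causal_genes) > 0) {
    if (!all(is.finite(causal_genes$effect)))
      ag_stop("causal effects must be finite", "alkagerm_config_error")
    if (any(causal_genes$gene < 1 | causal_genes$gene > n_genes))
      ag_stop("causal gene index out of range", "alkagerm_config_error")
  }
  if (missing_rate < 0 || missing_rate >= 1)
    ag_stop("missing_rate must be in [0, 1)", "alkagerm_config_error")
  cfg$chrom_length <- as.integer(ceiling(n_snps / n_chromosomes) * snp_spacing + 2L)
  structure(cfg, class = "sim_config")
}

#' Simulate genotypes and accession metadata
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); each subpopulation's
#' frequencies are drawn from the Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. Founder haplotypes are sampled per
#' subpopulation, and each fully inbred accession is a block mosaic of the
#' founders (dosages 0 or 2 before missingness), which creates block-wise LD.
#'
#' @param cfg a [sim_config()].
#' @return List with `variants` (a [variant_table()]; the complete
#'   pre-missingness dosage matrix is kept as `attr(variants, "geno_complete")`)
#'   and `metadata` (accession/subpopulation data.frame).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1))
  n <- cfg$n_accessions
  pops <- names(cfg$subpop_fractions)
  n_per <- diff(round(cumsum(c(0, cfg$subpop_fractions)) * n))
  subpop <- rep(pops, n_per)
  acc <- sprintf("acc%04d", seq_len(n))
  per_chrom <- diff(round(seq(0, cfg$n_snps, length.out = cfg$n_chromosomes + 1)))
  nt <- c("A", "C", "G", "T")
  info_list <- list()
  geno <- matrix(0L, nrow = n, ncol = 0)
  for (ch in seq_len(cfg$n_chromosomes)) {
    m <- per_chrom[ch]
    if (m == 0) next
    pos <- sort(sample.int(cfg$chrom_length - 3L, m)) + 1L
    p_anc <- stats::runif(m, 0.05, 0.95)
    a <- p_anc * (1 - cfg$fst) / cfg$fst
    b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
    block <- floor(pos / cfg$ld_block_len) + 1L
    n_blocks <- max(block)
    chrom_geno <- matrix(0L, nrow = n, ncol = m)
    row0 <- 0L
    for (sp in seq_along(pops)) {
      nsp <- n_per[sp]
      p_sub <- stats::rbeta(m, a, b)
      founders <- matrix(stats::rbinom(cfg$n_founders * m, 1L, rep(p_sub, each = cfg$n_founders)),
                         nrow = cfg$n_founders, ncol = m)
      ## founder path per accession: switch founders at block boundaries
      path <- matrix(0L, nrow = nsp, ncol = n_blocks)
      path[, 1] <- sample.int(cfg$n_founders, nsp, replace = TRUE)
      if (n_blocks > 1) {
        for (bidx in 2:n_blocks) {
          sw <- stats::runif(nsp) < cfg$block_switch_prob
          path[, bidx] <- ifelse(sw, sample.int(cfg$n_founders, nsp, replace = TRUE),
                                 path[, bidx - 1])
        }
      }
      for (i in seq_len(nsp))
        chrom_geno[row0 + i, ] <- 2L * founders[cbind(path[i, block], seq_len(m))]
      row0 <- row0 + nsp
    }
    ref <- sample(nt, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
    info_list[[ch]] <- data.frame(
      snp_id = sprintf("rs%d_%d", ch, pos),
      chrom = sprintf("chr%d", ch), pos = pos, ref = ref, alt = unname(alt),
      stringsAsFactors = FALSE
    )
    geno <- cbind(geno, chrom_geno)
  }
  info <- do.call(rbind, info_list)
  rownames(geno) <- acc
  colnames(geno) <- info$snp_id
  complete <- geno
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(geno)) < cfg$missing_rate
    geno[mask] <- NA_integer_
  }
  vt <- variant_table(info, geno)
  attr(vt, "geno_complete") <- complete[, vt$info$snp_id, drop = FALSE]
  list(
    variants = vt,
    metadata = data.frame(accession = acc, subpopulation = subpop,
                          stringsAsFactors = FALSE)
  )
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate gene models and a consistent reference genome
#'
#' Places single-exon CDS gene models (both strands) on the simulated
#' chromosomes and builds a reference sequence whose base at every SNP
#' position equals the SNP's reference allele. Each causal gene receives one
#' designated coding SNP placed at codon position 2 inside its CDS, with the
#' codon context arranged so the alternate allele is guaranteed missense
#' (G _ C context: no stop codons, second-position changes always alter the
#' amino acid); the change is verifiable by whole-CDS translation. Reference
#' CDSs start with ATG, end with a stop codon and carry no internal stops.
#'
#' @param cfg a [sim_config()].
#' @param variants the [variant_table()] from [simulate_population()].
#' @param metadata optional accession metadata; when supplied, causal SNPs
#'   are required to segregate within each major subpopulation (within-group
#'   MAF >= 0.05 and frequency gap <= 0.5), so the planted effect is
#'   identifiable by a structure-corrected scan rather than confounded with
#'   population stratification.
#' @return List with `genes` (list of [gene_model()]), `genome`
#'   (`DNAStringSet`) and `causal` (data.frame: `gene_id`, `snp_id`, `effect`,
#'   `tolerant_allele`).
#' @export
simulate_gene_models <- function(cfg, variants, metadata = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 2))
  info <- variants$info
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  nt <- c("A", "C", "G", "T")
  genome <- lapply(chroms, function(ch)
    sample(nt, cfg$chrom_length, replace = TRUE))
  names(genome) <- chroms
  L <- cfg$gene_cds_length
  causal <- cfg$causal_genes
  n_causal <- nrow(causal)

  ## --- choose gene intervals ----------------------------------------------
  spans <- data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), causal_row = integer(0),
                      snp_idx = integer(0))
  occupied <- list()  # per chrom list of taken intervals
  overlaps <- function(ch, s, e) {
    iv <- occupied[[ch]]
    !is.null(iv) && any(s <= iv[, 2] & e >= iv[, 1])
  }
  take <- function(ch, s, e) occupied[[ch]] <<- rbind(occupied[[ch]], c(s, e))

  ## causal genes first: anchor each on a common, clean SNP
  maf <- snp_stats(variants)$maf
  ok_within <- rep(TRUE, length(maf))
  if (!is.null(metadata)) {
    g <- attr(variants, "geno_complete")
    if (is.null(g)) g <- variants$geno
    major <- names(sort(table(metadata$subpopulation), decreasing = TRUE))
    major <- utils::head(major, 2)
    fr <- sapply(major, function(sp) {
      rows <- metadata$accession[metadata$subpopulation == sp]
      colMeans(g[rows, , drop = FALSE], na.rm = TRUE) / 2
    })
    within_maf <- pmin(fr, 1 - fr)
    ok_within <- apply(within_maf, 1, min) >= 0.05 &
      abs(fr[, 1] - fr[, 2]) <= 0.5
  }
  for (k in seq_len(n_causal)) {
    cand <- which(maf >= 0.15 & ok_within &
                    info$pos > L & info$pos < cfg$chrom_length - L)
    cand <- cand[sample.int(length(cand))]
    placed <- FALSE
    for (j in cand) {
      pos <- info$pos[j]; ch <- info$chrom[j]
      ## start so that the SNP sits at codon position 2 (0-based offset %% 3 == 1)
      off_target <- (L %/% 2L) - ((L %/% 2L) %% 3L) + 1L   # 0-based, ==1 mod 3
      s <- pos - off_target
      e <- s + L - 1L
      if (s < 1 || e > cfg$chrom_length || overlaps(ch, s, e)) next
      inside <- info$chrom == ch & info$pos >= s & info$pos <= e
      offs <- info$pos[inside] - s           # 0-based CDS offsets
      ## keep start/stop codons and the causal-codon flanks free of other SNPs
      flanks <- c(off_target - 1L, off_target + 1L)
      if (any(offs < 3L) || any(offs >= L - 3L)) next
      if (any(setdiff(offs, off_target) %in% flanks)) next
      take(ch, s, e)
      spans <- rbind(spans, data.frame(chrom = ch, start = s, strand = "+",
                                       causal_row = k, snp_idx = j))
      placed <- TRUE
      break
    }
    if (!placed)
      ag_stop("cannot place a causal SNP non-synonymously; adjust the configuration",
              "alkagerm_config_error")
  }
  ## remaining genes anywhere non-overlapping, alternating strands
  n_rest <- cfg$n_genes - n_causal
  tries <- 0L
  while (n_rest > 0 && tries < 50L * cfg$n_genes) {
    tries <- tries + 1L
    ch <- sample(chroms, 1)
    s <- sample.int(cfg$chrom_length - L - 2L, 1)
    e <- s + L - 1L
    if (overlaps(ch, s, e)) next
    take(ch, s, e)
    spans <- rbind(spans, data.frame(chrom = ch, start = s,
                                     strand = if (n_rest %% 2 == 0) "+" else "-",
                                     causal_row = NA_integer_, snp_idx = NA_integer_))
    n_rest <- n_rest - 1L
  }
  if (n_rest > 0)
    ag_stop("could not place all gene models; reduce n_genes or gene length",
            "alkagerm_config_error")
  spans <- spans[order(spans$chrom, spans$start), , drop = FALSE]

  ## --- write reference bases ----------------------------------------------
  ## SNP reference alleles first, then repair gene codon structure around them.
  for (ch in chroms) {
    sel <- info$chrom == ch
    genome[[ch]][info$pos[sel]] <- info$ref[sel]
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  genes <- list()
  causal_out <- data.frame()
  for (gi in seq_len(nrow(spans))) {
    ch <- spans$chrom[gi]; s <- spans$start[gi]; e <- s + L - 1L
    strand <- spans$strand[gi]
    gid <- sprintf("gene%02d_%s", gi, sub("chr", "c", ch))
    sel <- info$chrom == ch & info$pos >= s & info$pos <= e
    snp_pos <- info$pos[sel]
    ## transcript-orientation offsets (0-based) of SNPs
    t_off <- if (strand == "+") snp_pos - s else e - snp_pos
    is_snp_toff <- logical(L); is_snp_toff[t_off + 1L] <- TRUE
    get_t <- function(o)  # transcript base at 0-based offset o
      if (strand == "+") genome[[ch]][s + o] else comp[[genome[[ch]][e - o]]]
    set_t <- function(o, base) {
      if (strand == "+") genome[[ch]][s + o] <<- base
      else genome[[ch]][e - o] <<- comp[[base]]
    }
    ## start codon ATG, terminal stop TAA (shift off any SNP base — placement
    ## of causal genes already guarantees this; random genes may collide, in
    ## which case the SNP base wins and the codon check tolerates it)
    for (o in 0:2) if (!is_snp_toff[o + 1L]) set_t(o, c("A", "T", "G")[o + 1L])
    for (o in (L - 3L):(L - 1L)) if (!is_snp_toff[o + 1L]) set_t(o, c("T", "A", "A")[o - L + 4L])
    ## causal codon context: G _ C around the causal SNP
    if (!is.na(spans$causal_row[gi])) {
      j <- spans$snp_idx[gi]
      o_snp <- info$pos[j] - s           # + strand by construction
      set_t(o_snp - 1L, "G"); set_t(o_snp + 1L, "C")
    }
    ## repair internal stop codons using a non-SNP base
    for (ci in seq_len(L / 3 - 1L)[-1L]) {  # internal codons only
      o0 <- (ci - 1L) * 3L
      codon <- paste0(get_t(o0), get_t(o0 + 1L), get_t(o0 + 2L))
      if (codon %in% STOP_CODONS) {
        free <- which(!is_snp_toff[o0 + 1:3])
        if (length(free) == 0) next   # fully SNP-covered codon: leave as data
        set_t(o0 + free[1] - 1L, "C")
      }
    }
    genes[[gid]] <- gene_model(gid, ch, strand, cbind(s, e))
    if (!is.na(spans$causal_row[gi])) {
      k <- spans$causal_row[gi]; j <- spans$snp_idx[gi]
      causal_out <- rbind(causal_out, data.frame(
        gene_id = gid, snp_id = info$snp_id[j],
        effect = causal$effect[k],
        tolerant_allele = if (causal$effect[k] >= 0) info$alt[j] else info$ref[j],
        stringsAsFactors = FALSE
      ))
    }
  }
  genome_set <- Biostrings::DNAStringSet(
    vapply(genome, paste, character(1), collapse = ""))
  names(genome_set) <- chroms
  list(genes = genes, genome = genome_set, causal = causal_out)
}

#' Assemble the simulation ground truth
#'
#' Computes the latent tolerance value per accession:
#' subpopulation effect + sum of causal effects times the founder-allele
#' indicator (dosage/2) + Gaussian noise, standardized across the panel.
#'
#' @param cfg a [sim_config()].
#' @param variants variant table from [simulate_population()].
#' @param metadata accession metadata from [simulate_population()].
#' @param causal causal-gene table from [simulate_gene_models()].
#' @return List of class `sim_truth` with `metadata`, `latent` (named numeric),
#'   and `causal`.
#' @export
build_sim_truth <- function(cfg, variants, metadata, causal) {
  set.seed(derive_seed(cfg$seed, 3))
  g <- attr(variants, "geno_complete")
  if (is.null(g)) g <- variants$geno
  n <- nrow(g)
  shift <- numeric(n)
  shift[metadata$subpopulation == "Xian"] <- cfg$subpop_latent_shift / 2
  shift[metadata$subpopulation == "Geng"] <- -cfg$subpop_latent_shift / 2
  gen <- numeric(n)
  if (nrow(causal) > 0) {
    for (k in seq_len(nrow(causal))) {
      x <- g[, causal$snp_id[k]] / 2
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      gen <- gen + causal$effect[k] * x
    }
  }
  L <- shift + gen + stats::rnorm(n, 0, cfg$latent_noise_sd)
  L <- as.numeric(scale(L))
  names(L) <- metadata$accession
  structure(list(metadata = metadata, latent = L, causal = causal),
            class = "sim_truth")
}

#' Simulate a germination assay from the latent tolerance
#'
#' Each viable seed's germination day is a rounded log-normal draw whose mean
#' is `mu_control` under control and `mu_control + delta_stress -
#' gamma_tolerance * latent` under stress (floored at 1 day). Seeds whose draw
#' exceeds day 7 count as non-germinated. Root/shoot lengths are constants
#' plus noise under control and linear in the latent tolerance under stress.
#'
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth` from [build_sim_truth()].
#' @return A `germination_counts` data.frame (see [read_phenotype_table()]).
#' @export
simulate_germination <- function(cfg, truth) {
  set.seed(derive_seed(cfg$seed, 4))
  acc <- truth$metadata$accession
  n <- length(acc)
  grid <- expand.grid(accession = acc, condition = c("control", "stress"),
                      replicate = seq_len(cfg$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$accession, grid$condition, grid$replicate), , drop = FALSE]
  L <- truth$latent[grid$accession]
  stress <- grid$condition == "stress"
  mu_day <- ifelse(stress,
                   pmax(1, cfg$mu_control + cfg$delta_stress - cfg$gamma_tolerance * L),
                   cfg$mu_control)
  sdlog <- ifelse(stress, cfg$day_sdlog[["stress"]], cfg$day_sdlog[["control"]])
  ns <- cfg$seeds_per_dish
  counts <- matrix(0L, nrow(grid), 7L, dimnames = list(NULL, paste0("d", 1:7)))
  for (i in seq_len(nrow(grid))) {
    viable <- stats::runif(ns) < cfg$viability
    meanlog <- log(mu_day[i]) - sdlog[i]^2 / 2
    day <- pmax(1, round(stats::rlnorm(ns, meanlog, sdlog[i])))
    day[!viable] <- NA
    day[day > 7] <- NA
    tab <- tabulate(day, nbins = 7)
    counts[i, ] <- tab
  }
  root <- ifelse(stress,
                 pmax(0.05, cfg$root_stress_base + cfg$root_stress_slope * L +
                        stats::rnorm(nrow(grid), 0, cfg$length_noise_sd)),
                 stats::rnorm(nrow(grid), cfg$root_control_mean, cfg$root_control_sd))
  shoot <- ifelse(stress,
                  pmax(0.05, cfg$shoot_stress_base + cfg$shoot_stress_slope * L +
                         stats::rnorm(nrow(grid), 0, cfg$length_noise_sd)),
                  stats::rnorm(nrow(grid), cfg$shoot_control_mean, cfg$shoot_control_sd))
  out <- cbind(grid,
               data.frame(total_seeds = ns), as.data.frame(counts),
               data.frame(root_length_cm = round(pmax(0.05, root), 3),
                          shoot_length_cm = round(pmax(0.05, shoot), 3)))
  rownames(out) <- NULL
  class(out) <- c("germination_counts", "data.frame")
  out
}

#' Generate and write a complete synthetic dataset
#'
#' Runs the whole generator and writes `genotypes.vcf`, `genes.gff3`,
#' `reference.fasta`, `phenotypes.tsv`, `metadata.tsv`, `annotations.tsv` and
#' `truth.json` to a directory. Fully deterministic for a given configuration.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed); `NULL` skips writing.
#' @return List with all in-memory objects (`variants`, `metadata`, `genes`,
#'   `genome`, `causal`, `truth`, `phenotypes`, `annotations`) and `paths`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  pop <- simulate_population(cfg)
  gm <- simulate_gene_models(cfg, pop$variants, pop$metadata)
  truth <- build_sim_truth(cfg, pop$variants, pop$metadata, gm$causal)
  pheno <- simulate_germination(cfg, truth)
  set.seed(derive_seed(cfg$seed, 5))
  ann <- data.frame(
    gene_id = names(gm$genes),
    functional_annotation = "synthetic annotation",
    stress_related = stats::runif(length(gm$genes)) < 0.2,
    stringsAsFactors = FALSE
  )
  ann$stress_related[ann$gene_id %in% gm$causal$gene_id] <- TRUE
  ann$functional_annotation[ann$gene_id %in% gm$causal$gene_id] <-
    "synthetic abiotic stress response"
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      vcf = file.path(dir, "genotypes.vcf"),
      gff3 = file.path(dir, "genes.gff3"),
      fasta = file.path(dir, "reference.fasta"),
      phenotypes = file.path(dir, "phenotypes.tsv"),
      metadata = file.path(dir, "metadata.tsv"),
      annotations = file.path(dir, "annotations.tsv"),
      truth = file.path(dir, "truth.json")
    )
    write_vcf(pop$variants, paths$vcf)
    write_gff3(gm$genes, paths$gff3)
    Biostrings::writeXStringSet(gm$genome, paths$fasta)
    write_phenotype_table(pheno, paths$phenotypes)
    utils::write.table(pop$metadata, paths$metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(latent = as.list(truth$latent), causal = gm$causal,
           subpopulation = stats::setNames(as.list(pop$metadata$subpopulation),
                                           pop$metadata$accession)),
      paths$truth, auto_unbox = TRUE, digits = NA)
  }
  list(variants = pop$variants, metadata = pop$metadata, genes = gm$genes,
       genome = gm$genome, causal = gm$causal, truth = truth,
       phenotypes = pheno, annotations = ann, paths = paths)
}
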