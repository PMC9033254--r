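## Stage orchestration: one configuration object drives simulate -> traits ->
## gwas -> loci -> haplotypes -> pyramid, every stage reading and writing
## diffable TSV artifacts under the output directory and recording a
## machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects input paths, output directory, thresholds and the master seed.
#' Defaults mirror the analysis conventions of the germination-stage
#' alkali-tolerance study design: missingness < 0.20, MAF > 0.05, alpha 0.05,
#' 150-kb locus merge window, haplotype minimum 10 accessions, combination
#' minimum 15, criterion-2 threshold "more than 3 traits".
#'
#' @param outdir output directory.
#' @param vcf,gff3,fasta,phenotypes,metadata,annotations input paths; when
#'   `NULL` they default to the files the `simulate` stage writes under
#'   `file.path(outdir, "dataset")`.
#' @param panels subset of `c("whole", "Xian", "Geng")` to scan.
#' @param traits trait columns to scan (e.g. `c("RGE", "RRL")`).
#' @param max_missing,min_maf,alpha,locus_window,hap_min,group_min,crit2_traits_gt,n_pc
#'   thresholds (see Details above).
#' @param sim named list of [sim_config()] overrides for the simulate stage.
#' @param seed master seed; each stage derives its own RNG stream so stages
#'   can be rerun independently.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            vcf = NULL, gff3 = NULL, fasta = NULL,
                            phenotypes = NULL, metadata = NULL,
                            annotations = NULL,
                            panels = c("whole", "Xian", "Geng"),
                            traits = "RGE",
                            max_missing = 0.20, min_maf = 0.05, alpha = 0.05,
                            locus_window = 150000, hap_min = 10,
                            group_min = 15, crit2_traits_gt = 3, n_pc = 3,
                            sim = list(), seed = 1) {
  ds <- file.path(outdir, "dataset")
  cfg <- list(
    outdir = outdir,
    vcf = vcf %||% file.path(ds, "genotypes.vcf"),
    gff3 = gff3 %||% file.path(ds, "genes.gff3"),
    fasta = fasta %||% file.path(ds, "reference.fasta"),
    phenotypes = phenotypes %||% file.path(ds, "phenotypes.tsv"),
    metadata = metadata %||% file.path(ds, "metadata.tsv"),
    annotations = annotations %||% file.path(ds, "annotations.tsv"),
    panels = match.arg(panels, c("whole", "Xian", "Geng"), several.ok = TRUE),
    traits = traits,
    max_missing = max_missing, min_maf = min_maf, alpha = alpha,
    locus_window = locus_window, hap_min = hap_min, group_min = group_min,
    crit2_traits_gt = crit2_traits_gt, n_pc = n_pc,
    sim = sim, seed = as.integer(seed)
  )
  stopifnot(max_missing > 0, max_missing <= 1, min_maf >= 0, min_maf < 0.5,
            alpha > 0, alpha < 1, locus_window > 0, hap_min >= 2,
            group_min >= 2)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @param ... overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  dots <- list(...)
  y[names(dots)] <- dots
  do.call(pipeline_config, y)
}

stage_order <- c("simulate", "traits", "gwas", "loci", "haplotypes", "pyramid")

require_artifact <- function(path, producing_stage) {
  if (!file.exists(path))
    ag_stop(sprintf("missing artifact '%s'; run stage '%s' first",
                    path, producing_stage),
            "alkagerm_dependency_error")
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (write the synthetic dataset), `traits` (21-trait
#' table, summaries, damage, correlations), `gwas` (per-panel filtering,
#' pruning, kinship, PCs, REML and scan for each configured trait), `loci`
#' (thresholding, clustering, cross-trait unification), `haplotypes`
#' (candidate genes, CDS-haplotypes, Duncan letters, LD blocks), `pyramid`
#' (favorable-haplotype combinations), or `all`. Each run writes
#' `run_manifest.json` (inputs, config hash, package version, seed, stages,
#' wall time); every TSV carries a commented header with the stage and config
#' hash, so reruns with identical configuration are byte-identical.
#'
#' @param stage one of `simulate`, `traits`, `gwas`, `loci`, `haplotypes`,
#'   `pyramid`, `all`.
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list of the stage's main in-memory results.
#' @export
run_stage <- function(stage = c("all", stage_order), cfg) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages_run <- if (stage == "all") c(stage_order, "all") else stage
  res <- list()
  for (st in setdiff(stages_run, "all")) {
    res[[st]] <- switch(st,
      simulate = stage_simulate(cfg),
      traits = stage_traits(cfg),
      gwas = stage_gwas(cfg),
      loci = stage_loci(cfg),
      haplotypes = stage_haplotypes(cfg),
      pyramid = stage_pyramid(cfg)
    )
  }
  manifest <- list(
    package = "alkagerm",
    version = as.character(utils::packageVersion("alkagerm")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    inputs = cfg[c("vcf", "gff3", "fasta", "phenotypes", "metadata",
                   "annotations")],
    stages = stages_run,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Run the full pipeline
#'
#' Convenience wrapper for `run_stage("all", cfg)`.
#' @param cfg a [pipeline_config()].
#' @return Invisibly, the per-stage results list.
#' @export
run_pipeline <- function(cfg) run_stage("all", cfg)

stage_header <- function(cfg, stage)
  c(sprintf("alkagerm stage=%s", stage),
    sprintf("config_hash=%s seed=%d", config_hash(cfg), cfg$seed))

stage_simulate <- function(cfg) {
  sim_args <- cfg$sim
  sim_args$seed <- derive_seed(cfg$seed, 11)
  scfg <- do.call(sim_config, sim_args)
  simulate_dataset(scfg, dir = file.path(cfg$outdir, "dataset"))
}

stage_traits <- function(cfg) {
  gc <- read_phenotype_table(require_artifact(cfg$phenotypes, "simulate"))
  traits <- compute_trait_table(gc)
  hd <- stage_header(cfg, "traits")
  write_result_tsv(traits, file.path(cfg$outdir, "traits.tsv"), hd)
  write_result_tsv(summarize_traits(traits),
                   file.path(cfg$outdir, "trait_summary.tsv"), hd)
  write_result_tsv(relative_damage(traits),
                   file.path(cfg$outdir, "relative_damage.tsv"), hd)
  cm <- correlate_traits(traits)
  write_result_tsv(data.frame(trait = rownames(cm), round(cm, 4)),
                   file.path(cfg$outdir, "trait_correlations.tsv"), hd)
  traits
}

stage_gwas <- function(cfg) {
  vt <- read_vcf(require_artifact(cfg$vcf, "simulate"))
  meta <- read_metadata(require_artifact(cfg$metadata, "simulate"))
  traits <- read_result_tsv(require_artifact(
    file.path(cfg$outdir, "traits.tsv"), "traits"))
  hd <- stage_header(cfg, "gwas")
  out <- list()
  for (panel in cfg$panels) {
    acc <- if (panel == "whole") meta$accession
           else meta$accession[meta$subpopulation == panel]
    acc <- intersect(acc, rownames(vt$geno))
    pvt <- subset_variants(vt, accessions = acc)
    pvt <- filter_variants(pvt, cfg$max_missing, cfg$min_maf)
    pruned <- subset_variants(pvt, snps = ld_prune(pvt))
    K <- ibs_kinship(pruned)
    pcs <- pca_covariates(K, cfg$n_pc)
    n_eff <- effective_marker_number(pvt)
    writeLines(
      c(sprintf("panel\t%s", panel), sprintf("n_snps\t%d", n_snps(pvt)),
        sprintf("n_eff\t%d", n_eff),
        sprintf("threshold\t%.6g", significance_threshold(n_eff))),
      file.path(cfg$outdir, sprintf("threshold_%s.tsv", panel)))
    for (tr in cfg$traits) {
      y <- traits[[tr]][match(acc, traits$accession)]
      ok <- !is.na(y)
      X <- cbind(1, pcs[ok, , drop = FALSE])
      fit <- reml_fit(y[ok], X, K[ok, ok])
      scan <- association_scan(y[ok], X, fit,
                               subset_variants(pvt, accessions = which(ok)),
                               trait = tr, panel = panel)
      write_result_tsv(scan,
        file.path(cfg$outdir, sprintf("assoc_%s_%s.tsv", tr, panel)), hd)
      out[[paste(tr, panel, sep = "|")]] <-
        list(fit = fit, scan = scan, n_eff = n_eff)
    }
  }
  out
}

read_thresholds <- function(cfg) {
  sapply(cfg$panels, function(panel) {
    f <- require_artifact(file.path(cfg$outdir,
                                    sprintf("threshold_%s.tsv", panel)), "gwas")
    kv <- utils::read.delim(f, header = FALSE)
    as.numeric(kv$V2[kv$V1 == "threshold"])
  })
}

stage_loci <- function(cfg) {
  thr <- read_thresholds(cfg)
  hd <- stage_header(cfg, "loci")
  per <- list()
  for (panel in cfg$panels) {
    for (tr in cfg$traits) {
      f <- require_artifact(file.path(cfg$outdir,
                                      sprintf("assoc_%s_%s.tsv", tr, panel)),
                            "gwas")
      scan <- read_result_tsv(f)
      sig <- scan[!is.na(scan$p) & scan$p < thr[[panel]], , drop = FALSE]
      per[[paste(tr, panel, sep = "|")]] <-
        cluster_loci(sig, window = cfg$locus_window)
    }
  }
  sig_all <- do.call(rbind, lapply(names(per), function(nm) {
    lab <- strsplit(nm, "|", fixed = TRUE)[[1]]
    lt <- per[[nm]]
    if (nrow(lt) == 0) return(NULL)
    cbind(lt, trait = lab[1], panel = lab[2])
  }))
  unified <- merge_across_traits(per, window = cfg$locus_window)
  if (!is.null(sig_all))
    write_result_tsv(sig_all, file.path(cfg$outdir, "loci.tsv"), hd)
  else
    write_result_tsv(data.frame(), file.path(cfg$outdir, "loci.tsv"), hd)
  write_result_tsv(unified, file.path(cfg$outdir, "loci_unified.tsv"), hd)
  list(per_trait = per, unified = unified)
}

## All significant associations across panels/traits, as one data.frame.
collect_significant <- function(cfg) {
  thr <- read_thresholds(cfg)
  rows <- list()
  for (panel in cfg$panels) {
    for (tr in cfg$traits) {
      f <- require_artifact(file.path(cfg$outdir,
                                      sprintf("assoc_%s_%s.tsv", tr, panel)),
                            "gwas")
      scan <- read_result_tsv(f)
      sig <- scan[!is.na(scan$p) & scan$p < thr[[panel]], , drop = FALSE]
      if (nrow(sig)) rows[[paste(tr, panel)]] <- sig
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

stage_haplotypes <- function(cfg) {
  genes <- read_gff3(require_artifact(cfg$gff3, "simulate"))
  genome <- Biostrings::readDNAStringSet(require_artifact(cfg$fasta, "simulate"))
  names(genome) <- sub(" .*", "", names(genome))
  vt <- read_vcf(require_artifact(cfg$vcf, "simulate"))
  meta <- read_metadata(cfg$metadata)
  ann <- if (file.exists(cfg$annotations)) read_annotations(cfg$annotations) else NULL
  traits <- read_result_tsv(require_artifact(
    file.path(cfg$outdir, "traits.tsv"), "traits"))
  sig <- collect_significant(cfg)
  ## n_eff of the first panel drives criterion 3 (per-panel thresholds are in
  ## the threshold files)
  kv <- utils::read.delim(file.path(cfg$outdir,
                                    sprintf("threshold_%s.tsv", cfg$panels[1])),
                          header = FALSE)
  n_eff <- as.numeric(kv$V2[kv$V1 == "n_eff"])
  cand <- select_candidate_genes(sig, genes, ann, n_eff,
                                 crit2_traits_gt = cfg$crit2_traits_gt)
  hd <- stage_header(cfg, "haplotypes")
  write_result_tsv(as.data.frame(cand),
                   file.path(cfg$outdir, "candidate_genes.tsv"), hd)
  hap_rows <- list(); duncan_rows <- list(); block_rows <- list()
  haps <- list()
  trait_main <- cfg$traits[1]
  tvals <- stats::setNames(traits[[trait_main]], traits$accession)
  for (gid in cand$gene_id) {
    gene <- genes[[gid]]
    if (is.null(gene)) next
    eff <- classify_cds_snps(gene, genome, vt)
    if (nrow(eff) == 0) next
    h <- build_haplotypes(gene, eff, vt, min_size = cfg$hap_min)
    if (!nrow(h$table)) next
    haps[[gid]] <- h
    hap_rows[[gid]] <- cbind(gene_id = gid, h$table)
    retained <- h$assignment[h$assignment != "rare"]
    if (length(unique(retained)) >= 2) {
      dt <- duncan_mrt(tvals[names(retained)], retained, alpha = cfg$alpha)
      duncan_rows[[gid]] <- cbind(gene_id = gid, trait = trait_main, dt$table,
                                  F = dt$F, p = dt$p)
    }
    i <- match(gid, cand$gene_id)
    anchor <- sig$pos[match(cand$best_snp[i], sig$snp_id)]
    win <- subset_variants(vt, snps = which(
      vt$info$chrom == gene$chrom & abs(vt$info$pos - anchor) <= 3e5))
    if (n_snps(win) >= 1) {
      blk <- detect_ld_block(anchor, win)
      block_rows[[gid]] <- data.frame(gene_id = gid, chrom = blk$chrom,
                                      start = blk$start, end = blk$end,
                                      n_snps = blk$n_snps)
    }
  }
  bindf <- function(x) if (length(x)) do.call(rbind, x) else data.frame()
  write_result_tsv(bindf(hap_rows), file.path(cfg$outdir, "haplotypes.tsv"), hd)
  write_result_tsv(bindf(duncan_rows),
                   file.path(cfg$outdir, "haplotype_duncan.tsv"), hd)
  write_result_tsv(bindf(block_rows), file.path(cfg$outdir, "ld_blocks.tsv"), hd)
  list(candidates = cand, haplotypes = haps)
}

stage_pyramid <- function(cfg) {
  require_artifact(file.path(cfg$outdir, "candidate_genes.tsv"), "haplotypes")
  ## rebuild haplotype objects (stages communicate through text artifacts)
  hres <- stage_haplotypes_rebuild(cfg)
  haps <- hres$haplotypes
  traits <- read_result_tsv(file.path(cfg$outdir, "traits.tsv"))
  tvals <- stats::setNames(traits[["RGE"]], traits$accession)
  hd <- stage_header(cfg, "pyramid")
  usable <- Filter(function(h) {
    length(unique(h$assignment[h$assignment != "rare"])) >= 2
  }, haps)
  if (length(usable) < 1) {
    write_result_tsv(data.frame(), file.path(cfg$outdir, "pyramid.tsv"), hd)
    return(list(combinations = NULL))
  }
  cand <- read_result_tsv(file.path(cfg$outdir, "candidate_genes.tsv"))
  ord <- cand$gene_id[order(cand$best_p)]
  top <- utils::head(intersect(ord, names(usable)), 3)
  usable <- usable[top]
  fav <- vapply(usable, function(h) favorable_haplotype(h, tvals), character(1))
  comb <- combine_haplotypes(usable, fav, tvals, min_group = cfg$group_min,
                             alpha = cfg$alpha)
  write_result_tsv(cbind(genes = paste(top, collapse = ","), comb$table),
                   file.path(cfg$outdir, "pyramid.tsv"), hd)
  list(combinations = comb, favorable = fav, genes = top)
}

## Rebuild cds_haplotypes objects for the pyramid stage from the written
## candidate table and raw inputs.
stage_haplotypes_rebuild <- function(cfg) {
  genes <- read_gff3(cfg$gff3)
  genome <- Biostrings::readDNAStringSet(cfg$fasta)
  names(genome) <- sub(" .*", "", names(genome))
  vt <- read_vcf(cfg$vcf)
  cand <- read_result_tsv(file.path(cfg$outdir, "candidate_genes.tsv"))
  haps <- list()
  for (gid in cand$gene_id) {
    gene <- genes[[gid]]
    if (is.null(gene)) next
    eff <- classify_cds_snps(gene, genome, vt)
    if (nrow(eff) == 0) next
    h <- build_haplotypes(gene, eff, vt, min_size = cfg$hap_min)
    if (nrow(h$table)) haps[[gid]] <- h
  }
  list(haplotypes = haps)
}
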