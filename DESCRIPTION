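Package: alkagerm
Title: Germination-Stage Alkali-Tolerance GWAS and Haplotype Analysis for Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting alkali tolerance of rice at the germination
    stage: computation of germination indices (germination rate, energy, index,
    mean germination time, vigor index) and their stress to control ratio traits;
    mixed-linear-model genome-wide association with an identity-by-state kinship,
    spectral REML variance components and an EMMAX-style generalized-least-squares
    scan; clustering of significant SNPs into loci and candidate-gene selection;
    gene-CDS-haplotype analysis with codon-aware synonymous collapsing and
    Duncan's multiple range comparisons; and favorable-haplotype pyramiding.
    Includes a synthetic-data generator with planted genetic effects (two
    differentiated subpopulations, LD-blocked inbred genotypes, gene models with
    coding SNPs, and a germination-day phenotype model) so the whole pipeline can
    be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
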