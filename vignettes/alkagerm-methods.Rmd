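---
title: "Methods: germination-stage alkali-tolerance GWAS and haplotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germination-stage alkali-tolerance GWAS and haplotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkagerm)
```

# The analysis this package implements

Soda-saline (alkali) stress is a major constraint on direct-seeded rice, and
tolerance at germination is the trait that decides whether a direct-seeded
crop establishes at all. `alkagerm` implements a complete quantitative-genetics
workflow for dissecting germination-stage alkali tolerance in a rice diversity
panel:

1. **Germination traits.** From daily germination counts over a 7-day assay
   (typically 3 replicate dishes of 20 seeds per accession under a control and
   an alkali-stress condition), the package computes, per replicate:
   germination rate $GR = C_7/N_0$ and germination energy $GE = C_3/N_0$
   (cumulative germinated fractions at days 7 and 3), mean germination time
   $MGT = \sum_t t\,N_t / \sum_t N_t$ over newly germinated counts $N_t$,
   germination index $GI = \frac{1}{N_0}\sum_{t=1}^{7} C_t/t$ with cumulative
   counts $C_t$, measured root and shoot lengths (cm), and vigor index
   $VI = \overline{SL}\times GI$. Replicates are averaged within condition,
   and seven stress:control ratio traits (RMGT, RGR, RGI, RVI, RRL, RSL, RGE)
   quantify relative alkali damage per accession.
2. **Mixed-linear-model GWAS.** SNPs are filtered (missingness strictly below
   20%, MAF strictly above 5%), LD-pruned (window 50, step 10, $r^2 > 0.1$),
   and an identity-by-state kinship $K$ is built from the pruned set. The
   phenotype model is $y = X\beta + g + e$ with $\mathrm{cov}(g) = \sigma_g^2
   K$; the first three kinship principal components are covariates. Variance
   components are estimated once per trait by spectral REML and reused for
   every SNP test (the EMMAX approximation), each SNP being tested by
   generalized least squares in the eigenbasis of $K$ with a Wald t-test on
   $n - \mathrm{rank}(X) - 1$ degrees of freedom. The suggestive significance
   threshold is $1/N$ with $N$ the effective number of independent markers.
3. **Loci and candidate genes.** Significant SNPs are clustered greedily: the
   lowest-p unassigned SNP leads a locus and absorbs significant SNPs within
   150 kb on either side (span at most 300 kb); loci are unified across
   traits and panels when lead SNPs are within 150 kb. Candidate genes meet
   at least one of three criteria: (1) a significant SNP plus a
   stress-related functional annotation, (2) significant SNPs for more than
   three distinct traits, (3) holding a trait's most significant SNP at
   $p < 0.05/N$. Intergenic SNPs are assigned to the downstream gene.
4. **Gene-CDS haplotypes.** Coding SNPs are mapped to codons (strand-aware)
   and translated; haplotypes are defined by the allele vector over
   *non-synonymous* sites only, so synonymous variation merges. Haplotypes
   with at least 10 accessions enter phenotype comparisons by Duncan's
   multiple range test. The favorable haplotype of a gene is the one with the
   highest mean RGE (the ratio trait most sensitive to alkali stress).
5. **Pyramiding.** Accessions are grouped by their favorable/inferior pattern
   over the top candidate genes; groups of at least 15 accessions are
   compared by one-way ANOVA with Fisher's LSD letters, and the rank
   correlation between a group's favorable-haplotype count and its mean RGE
   measures whether stacking favorable haplotypes increases tolerance.

# Key statistical choices

**GI normalization.** The classical germination index
$GI = \sum_t C_t/t$ is dimensionally inconsistent with the reported 0–1.1
scale of GI unless divided by the seed number, and the day-3-complete case
then equals the reported GI ceiling exactly
($\sum_{t=3}^{7} 1/t = 1.093$). We therefore adopt
$GI = \frac{1}{N_0}\sum_t C_t/t$. This is the single most consequential
interpretation in the package and is pinned by a test.

**MGT for zero germination** is undefined and reported missing, never clamped
to 7: a clamp would silently distort the trait for near-zero germinators,
which do occur under strong stress. Similarly **RGE is missing when the
control germination energy is zero**, and such accessions are excluded
pairwise from RGE analyses.

**EMMAX approximation.** Variance components are fitted once on the null
model per trait and reused for every SNP. This is the standard trade-off for
panel-scale scans; it is exact when the tested SNP explains little variance
and slightly conservative otherwise. The REML profile over
$\log\delta = \log(\sigma_e^2/\sigma_g^2)$ is evaluated on a 121-point grid
from $-10$ to $10$ and refined by bounded scalar optimization; hitting a grid
boundary raises a warning flag (it usually means $h^2 \approx 0$ or
$\approx 1$). With $K = I$ the scan reduces exactly to OLS, which the test
suite checks to $10^{-8}$.

**Heterozygous calls.** Rice diversity panels are essentially inbred.
Heterozygous dosages are retained (as 1) for the association scan, where they
carry information, but treated as missing during haplotype construction,
where a half-call cannot be assigned to a haplotype class; affected
accessions are excluded from that gene with a logged count.

**Duncan's test.** Means $p$ steps apart in the descending order are compared
against $q_{\alpha_p, p, \nu}\sqrt{MSE/n_h}$, with protection level
$\alpha_p = 1-(1-\alpha)^{p-1}$, exact studentized-range quantiles, and the
harmonic mean group size $n_h$ for unequal groups. A non-significant wide
range protects all ranges it contains (step-down), and the compact letter
display is assembled by insert-and-absorb over maximal non-significant
intervals. The implementation is validated against an independently coded
brute-force reference on randomized fixtures, including the all-equal case.
The pyramiding comparison uses Fisher's LSD on the pooled ANOVA mean square,
matching the convention for combination analyses.

**Effective marker number.** The simpleM-style estimator: within
non-overlapping 200-SNP windows per chromosome, count the top eigenvalues of
the SNP correlation matrix needed to capture 99.5% of the trace, and sum over
windows. Different LD-aware tools produce somewhat different $N$ on real
data; the threshold definition $1/N$ is what matters here.

**LD blocks.** Pairwise $|D'|$ confidence bounds are computed by normalizing
the multinomial likelihood over a 101-point $|D'|$ grid (allele frequencies
fixed at sample values) and taking the 5th/95th percentiles. A pair is in
strong LD when the bounds reach 0.70/0.98, shows strong recombination when
the upper bound is below 0.90, and a block is the widest anchor-containing
run whose outermost pair is strong and whose informative pairs are at least
95% strong. For tractability at most 80 SNPs nearest the anchor enter the
pairwise computation.

**Coordinates.** All positions are 1-based inclusive everywhere, matching
VCF/GFF3 and the R genomics ecosystem (IRanges, vcfR); no internal coordinate
system conversion exists to get wrong.

**"Downstream gene"** for intergenic SNPs is ambiguous between
coordinate-relative and strand-relative readings; the package uses the next
gene in ascending genomic coordinates, deterministically.
**"More than three traits"** in candidate criterion 2 is read strictly
(4 or more), with a configurable override, since the boundary cannot be
resolved from common usage, which varies.

# The synthetic-data generator

Real 3K-RG-scale genotypes are neither redistributable nor desk-scale, so
validation runs on a generator whose defaults emulate the study conditions: a
400-accession panel split 65:35 between the two rice subspecies (Xian/indica
and Geng/japonica, mirroring a 278:125-style panel), 20,000 biallelic SNPs on
12 chromosomes, and a 7-day germination assay of 3 × 20 seeds per condition.

* **Genotypes.** Ancestral allele frequencies are Uniform(0.05, 0.95);
  subpopulation frequencies follow the Balding–Nichols distribution at
  $F_{ST} = 0.3$, the order of Xian–Geng differentiation. Each subpopulation
  carries 24 founder haplotypes, and each fully inbred accession is a block
  mosaic of founders (12-kb copy blocks, switch probability 0.8 at block
  boundaries), which produces block-wise LD and realistic kinship structure.
  The founder pool adds a small drift excess of roughly $(1-F_{ST})/24$ to
  realized differentiation, which keeps the Hudson $F_{ST}$ estimate within
  the generator's calibration contract ($\pm 0.08$). Causal SNPs are placed
  at codon position 2 of a G_C codon context inside a gene's CDS, making the
  alternate allele provably missense, and are required to segregate within
  both major subpopulations so that a planted effect is identifiable by a
  structure-corrected scan rather than aliased with stratification.
* **Phenotypes.** A latent tolerance $L_i$ (subpopulation shift 0.8 SD,
  Xian the more tolerant + causal effects on the founder-allele indicator
  dosage/2 + Gaussian noise) drives a discretized log-normal germination-day
  model: control mean day 3.8 (dispersion 0.20 on the log scale), stress mean
  day $3.8 + 2.5 - 1.2\,L_i$ floored at one day (dispersion 0.35), seeds
  viable with probability 0.97, and draws past day 7 counted as
  non-germinated. The log-normal is a deliberate two-parameter choice that
  reproduces the long right tail typical of reported mean-germination-time
  ranges (3–7 days). Root/shoot lengths are constants plus noise under
  control and linear in $L_i$ under stress. With these defaults the simulated
  trait table lands on realistic scales (control germination ~0.96,
  stress germination mean ~0.7 with wide spread, mean RGE ~0.2–0.3).
* **What it does not emulate.** No coalescent realism, recombination maps,
  selection, outcrossing, genotyping error beyond uniform missingness, or
  shared environment between replicates. Passing tests therefore demonstrate
  that the *methods* recover planted truth under a faithful caricature of the
  design — not that any particular real-data result is reproduced.

Everything is deterministic given the configuration: each generator step and
each pipeline stage derives its own RNG stream from the master seed, so
stages can be rerun independently and reruns are byte-identical.

# Problem sizes used in the test suite

Module tests run on small panels (60–200 accessions, hundreds of SNPs). The
property-based validation uses the default desk scale where the property
demands it: planted-QTL recovery runs 20 replicates at 400 accessions ×
20,000 SNPs (a SNP explaining 10% of variance must top the scan, and the
trait→scan→locus→candidate→haplotype chain must recover the planted gene and
its tolerant haplotype in at least 90% of replicates); type-I error is
checked on 2,000 near-independent SNPs at nominal 0.05; codon-effect
classification is checked against whole-CDS translation on 1,000 random
mutations across both strands; and pyramiding monotonicity on a 3-gene
additive architecture over 20 replicates. These sizes were chosen so the
full suite completes comfortably on a laptop while leaving the statistical
bars (18/20, binomial bounds) meaningful.

# Known limitations

* The scan is the EMMAX approximation, not exact per-SNP REML; with very
  large single-SNP effects its p-values are conservative.
* The effective-marker estimator is one member of a family; real-data
  thresholds will differ from other tools' by a modest factor.
* The LD-block detector uses fixed default D' bounds (0.70/0.98/0.90); block
  edges on sparse windows are only resolved to about one SNP.
* Gene models take the first mRNA of a gene; alternative transcripts are out
  of scope, as are promoter/UTR haplotypes and phasing.
* Duncan's test controls its classical step-down error rate, not FDR across
  genes; gene-level multiplicity is the user's call, as in standard practice
  for this analysis type.
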