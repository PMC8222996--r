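---
title: "Methods: quantifying m6A inheritance in hybrids with meripherit"
author: "meripherit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying m6A inheritance in hybrids with meripherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripherit)
```

# Overview

`meripherit` implements a MeRIP-seq (m6A immunoprecipitation sequencing)
analysis pipeline for a two-parent / reciprocal-hybrid design: two inbred
parental genotypes (labelled Col0 and Ler) and their reciprocal F1 hybrids
(F1CL, F1LC). The package answers three questions about methylation
inheritance:

1. **Differential methylation** — which peaks differ in m6A enrichment
   between the parents?
2. **Additivity** — in a hybrid, does peak methylation (and gene
   expression) sit at the mid-parent value (MPV), as expected under purely
   additive inheritance, or deviate from it?
3. **Allelic balance** — within a hybrid, are the two parental alleles of
   a peak methylated equally (cis/trans dissection via allele-specific
   reads)?

A self-contained synthetic-data generator produces genomes, annotation,
alignments, and a complete ground-truth ledger, so every statistical
component can be validated against planted truth.

# Data model

Coordinates are 0-based, half-open throughout the package; GTF input and
output are converted at the boundary (`parse_gtf()`, `write_gtf()`).
Alignments are plain data frames (`chrom`, `start`, `end`, `strand`,
`read_id`, `allele`, optionally `seq`) loaded from SAM/BAM via
`Rsamtools`/`GenomicAlignments` or from a TSV dialect
(`load_alignments()`); multi-mappers (`NH > 1`) are dropped. A
`merip_experiment` object bundles a sample sheet (genotype, assay = IP or
input, replicate, total mapped reads), the per-sample alignments, the
transcript annotation, and the peak set.

# Peak quantification

For each genotype, `quantify_peaks()` computes per peak:

* **Normalized coverage** — for each library, reads overlapping the peak
  per million mapped reads (RPM); IP and input libraries are averaged
  separately.
* **Enrichment** — mean IP RPM divided by `max(mean input RPM, 0.5)`; the
  0.5 pseudocount guards low-coverage peaks, which are flagged.
* **Summit** — the leftmost position maximizing the IP-minus-input
  coverage residual within the peak (`call_summit()`); flagged degenerate
  when the residual is flat.
* **Feature** — tiered assignment of the summit position: 3'UTR beats
  5'UTR beats CDS when transcript isoforms overlap (`assign_feature()`),
  plus 200-nt windows centered on the start and stop codons
  (`assign_codon_segment()`).
* **Expression context** — gene FPKM from the input libraries and peak
  input FPKM, used by `filter_peaks()`: a peak is kept when its gene has
  input FPKM ≥ 1 and the peak itself has input FPKM ≥ 5 (both inclusive).

`metagene_profile()` bins each mRNA into 100 bins per feature (5'UTR,
CDS, 3'UTR; 300 bins total), normalizing each transcript profile by its
mean so highly expressed genes do not dominate.

# Differential methylation

`call_dmps()` matches peaks across genotypes by largest reciprocal
overlap (`common_peaks()`), then tests each common peak with a two-sided
Fisher exact test on the 2x2 table `[IP_a, input_a; IP_b, input_b]`.

**Depth equalization.** Raw counts are scaled to the smallest of the four
library-depth totals (`count * min(totals) / total`, rounded half-up)
before testing. Fisher's test treats its inputs as independent counts, so
the *effective* sample size must reflect true sequencing depth: scaling
everything to the shallowest library makes the test's operating
characteristics depth-honest. (Scaling RPM values *up* to a nominal
per-million unit inflates effective counts and wrecks null calibration —
a pitfall this design avoids; the synthetic null holds the raw p < 0.05
fraction at its nominal level.)

P-values are corrected per comparison family with the Bonferroni–Holm
step-down (`holm_adjust()`), and a peak is called a DMP when the adjusted
p is below 0.05 **and** the enrichment fold change strictly exceeds 1.5.

# Additivity

`classify_peak_additivity()` equalizes the six counts (hybrid IP/input
and both parents' IP/input) to the common minimum depth, forms the
expected hybrid counts as the rounded mid-parent value of the equalized
parental counts, and Fisher-tests observed hybrid counts against that
expectation, with Holm correction; a peak is non-additive when the
adjusted p falls below 0.05. `classify_expression_additivity()` applies
the same logic to gene-level input counts, and
`associate_nonadditive()` cross-tabulates non-additive methylation with
non-additive expression (chi-square association).

# Allele-specific methylation

The allelic module avoids reference-mapping bias with a symmetric
in-silico cross-mapping step written for this pipeline:

1. `fragment_genome()` tiles each parental genome into 100-nt fragments
   (1-nt step).
2. `cross_map_pileup()` places each fragment on the other genome with a
   seed-and-extend strategy: exact 16-mers at offsets 0, 16, 32, 48, 64,
   80 (six seeds, so up to 5 mismatches per 100 nt still leaves an exact
   seed, by pigeonhole); ambiguous (duplicated) seeds are masked;
   fragments with multiple equally-good placements are discarded.
3. `call_candidate_snps()` calls a site from the reciprocal pileups when
   coverage is at least 90 and the mutant-base ratio is at least 0.90 in
   **both** directions with consistent alleles. Because the inputs are
   error-free genome fragments, recall on planted substitutions is exact.
4. `bias_filter()` drops sites whose simulated hybrid reads map with more
   than 10% imbalance between the two references.
5. `homozygosity_filter()` drops sites where either parent's own reads
   support its own allele in fewer than 90% of informative reads
   (residual-heterozygosity guard).

`count_allelic_reads()` then assigns each hybrid IP/input read to an
allele via the surviving SNPs (reads voting for both alleles across SNPs
in one peak are discarded and counted), and `asm_test()` Fisher-tests
`[IP_A, input_A; IP_B, input_B]` per peak with Holm correction after
IP/input depth equalization. `allelic_ratio_distribution()` summarizes
the log2 allelic expression and methylation ratios; for balanced peaks
these center at 0 with the bulk inside (-1, 1).

# Synthetic-data generator

`sim_config()` fixes every parameter (all lengths in nucleotides):

* 300 transcripts on one chromosome pair: 5'UTR ~ N(150, 30) (min 60),
  CDS ~ N(660, 90) rounded to codon multiples (min 300), 3'UTR ~
  N(350, 60) (min 150); 200-nt intergenic spacers.
* SNP substitutions at rate 0.004 per interior site between the two
  parental genomes; optional heterozygous-like and mapping-biased
  nuisance sites planted at isolated positions.
* Expression: per-gene lognormal medians (median 900) times a
  gamma-distributed replicate factor (CV 0.1) that is **shared across
  genotypes**. This gamma-Poisson construction gives negative-binomial
  marginal counts while keeping parent-vs-parent null contrasts
  calibrated — biological dispersion that differed by genotype would be
  real signal, not noise.
* Peaks: width 180, one per selected transcript, with summits placed in
  5'UTR/CDS/3'UTR at 5/25/70%; IP read centers are drawn triangularly
  around the summit (half-width 60) so the coverage argmax is sharp at
  the summit (wider flat-topped shapes make the argmax unstable).
* IP background: within each genotype the non-peak IP rate `b` is solved
  so total IP read mass balances total input mass (clamped to
  [0.02, 1]), i.e. enrichment is a redistribution of reads into peaks,
  not free extra depth. Ler IP libraries are scaled to 80% depth to
  exercise normalization.
* Planted effects, exact in count: 16% DMPs at 2-fold (Col0-biased 97:3),
  5% non-additive peaks at 2.5-fold deviations from MPV, 2% ASM peaks at
  3:1 allelic skew (ASM peaks are guaranteed an informative SNP).
* All randomness flows from a single seed; `simulate_experiment()` is
  byte-reproducible, and `write_experiment()` / `write_truth()` emit
  FASTA, GTF, BED, TSV alignments and the truth ledger.

**Scope and limits.** The generator models exonic, single-isoform,
strand-forward transcripts without introns or splicing, uniform base
quality, error-free reads of fixed length 100, and exactly one peak per
methylated gene. It is designed to validate the statistics and the
cross-mapper, not to emulate sequencer error profiles, PCR duplication,
or isoform complexity.

# Problem sizes and runtime

Default scale — 300 transcripts, ~0.5 Mb genomes, 2 replicates, 8–16
libraries of ~10^5 reads — runs end to end (`run_pipeline()`) in seconds
to a few tens of seconds per genotype set on a single core. The
cross-mapper is vectorized with a colinear fast path and handles the two
default genomes in under ~10 s. The full acceptance suite (nine
criteria, multiple seeds each) completes in about two minutes.

# Reproducibility

`run_pipeline(sim_config(seed = ...))` is deterministic: repeated runs
write byte-identical outputs (`write_pipeline_outputs()`), which the test
suite asserts by file hashing.
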