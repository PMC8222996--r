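Package: meripherit
Title: Differential, Inheritance and Allele-Specific Analysis of m6A
    MeRIP-Seq Peaks in Parent-Hybrid Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Downstream analysis of MeRIP-seq (m6A-seq) experiments that
    compare two parental genotypes and their reciprocal F1 hybrids.
    Quantifies immunoprecipitation enrichment over externally called peaks,
    filters peaks by expression and input coverage, calls peak summits from
    IP-minus-input coverage residuals, assigns peaks to transcript features
    (3'UTR, 5'UTR, CDS, start/stop-codon segments) and builds metagene
    profiles.  Identifies differentially methylated peaks with Fisher's
    exact test on IP/input contingency tables under Bonferroni-Holm
    correction and a fold-change criterion, classifies hybrid peaks and
    gene expression as additive or non-additive relative to the mid-parent
    value, and tests allele-specific methylation after in-silico
    cross-mapping SNP discovery between the two parental genomes.  A
    seeded synthetic-data generator plants known truth (peaks, enrichment
    folds, SNPs, allelic skew) so every stage can be validated without
    the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
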