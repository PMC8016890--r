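Package: asescan
Title: Allele-Specific Expression QTL Mapping in Phased Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discovering candidate cis-regulatory variants
    (aseQTLs) from phased genotypes and allele-specific RNA-seq read
    counts. Implements per-animal binomial tests of allelic imbalance
    with Benjamini-Hochberg FDR control, a genotype-stratified Wilcoxon
    rank-sum scan of SNPs within 1 Mb of each allele-specific-expression
    marker, pairwise D-prime linkage disequilibrium and threshold-based
    block detection from phased haplotypes, a permutation test for the
    overlap between candidate variants and trait QTL intervals, gene-model
    annotation and RRBS methylation integration with phase-aware
    silencing checks, and allele-differential transcription-factor and
    miRNA binding-site screening. A synthetic-population generator with
    known cis effects provides ground truth for calibration and power
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
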