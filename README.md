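# asescan

Mapping candidate *cis*-regulatory variants (aseQTLs) from
allele-specific expression in phased populations.

## What it does

When RNA-seq reads over a transcribed SNP in a heterozygous animal
consistently favour one allele, the gene shows allele-specific
expression (ASE). A regulatory variant acting in *cis* explains this
pattern with a specific signature: animals **heterozygous** for the
regulatory variant show allelic imbalance at the transcribed marker,
animals homozygous for it do not. `asescan` implements that inference
for populations of phased, genotyped animals (it was built around a
bovine muscle design with ~190 animals), plus the companion analyses
that qualify the hits:

1. **ASE detection** — per animal and SNP, a two-sided exact binomial
   test of the read counts against 0.5,
   `p = min(1, 2·P[X ≤ min(ref, alt)])`, with global
   Benjamini–Hochberg FDR (`binomial_ase_test()`, `run_ase_tests()`,
   `call_ase_snps()`).
2. **The aseQTL scan** — for every SNP within 1 Mb of an ASE marker,
   the folded imbalance ratio `|ref/(ref+alt) − 0.5|` of
   marker-heterozygous animals is compared between candidate
   heterozygotes and the larger candidate homozygous class with a
   one-sided Wilcoxon rank-sum test; ≥ 10 heterozygotes required on
   both sides of the design, raw p ≤ 0.05, deliberately uncorrected
   (`scan_aseqtl()`).
3. **LD structure** — pairwise D′ from phased haplotypes in three
   pairing schemes and greedy D′ ≥ 0.8 blocks (`d_prime()`,
   `pairwise_ld()`, `find_blocks()`).
4. **QTL overlap** — permutation enrichment of aseQTL positions inside
   trait QTL intervals, uniform within-chromosome null, add-one
   estimator `(b+1)/(K+1)` (`permutation_test()`).
5. **Context** — gene-model feature classes, TSS distances, percent
   methylation `100·m/(m+u)`, and a phase-aware check of whether a
   methylated aseQTL allele silences the in-phase ASE allele
   (`classify_location()`, `methylation_ase_crosscheck()`).
6. **Regulatory screen** — 51-bp allelic flanks, allele-differential
   TF/miRNA binding hits (one allele only), strict MFE < −18.0 filter,
   muscle-expressed factor intersection (`extract_flanks()`,
   `differential_hits()`, `mfe_filter()`).

A synthetic-population generator (`simulate_population()`) with a
one-parameter cis effect — the haplotype in phase with the causal
alternative allele is expressed at relative rate `1 − β`, giving its
allele the expressed fraction `(1 − β)/(2 − β)` — provides ground
truth for every stage. See `vignettes/aseqtl-mapping.Rmd` for the
model, parameter rationale and limitations.

## Worked example

Simulate two genes with complete silencing of one haplotype (β = 1)
and scan for the planted causal variants:

```r
library(asescan)

cfg  <- sim_config(n_blocks = 2, beta = 1, rng_seed = 7)
sim  <- simulate_population(cfg)
scan <- scan_aseqtl(sim$geno, sim$counts, sim$truth$blocks$marker)
head(scan[order(scan$p_value),
          c("ase_variant", "candidate_variant", "n_het", "n_hom",
            "p_value", "distance_bp")], 5)
```

```
 ase_variant candidate_variant n_het n_hom      p_value distance_bp
   snp_01_13         snp_01_07    41    31 6.338754e-16       12000
   snp_02_13         snp_02_16    38    34 1.583809e-15        6000
   snp_01_13         snp_01_19    32    27 6.739194e-10       12000
   snp_02_13         snp_02_25    34    41 9.385345e-10       24000
   snp_02_13         snp_02_05    39    28 1.967788e-09       16000
```

The two smallest p-values are exactly the planted causal variants
(`sim$truth$blocks` records `snp_01_07` and `snp_02_16` as the causal
SNPs, 12 kb and 6 kb from their markers); the runners-up are block
neighbours in LD with them. Each row reads: among the `n_het`
marker-heterozygous animals that are also heterozygous at the
candidate, imbalance is higher than in the `n_hom` homozygotes, with
the one-sided Wilcoxon p shown. `summarize_scan(scan)` reports 48
valid tests, 18 significant, and a mean aseQTL reference-allele
frequency of 0.72.

## The analysis workflow

`analysis/` holds the numbered end-to-end drivers, each a thin script
over the package that prints what it found and writes tables under
`results/`:

```sh
Rscript analysis/01_simulate_population.R   # study files under results/data/
Rscript analysis/02_genotype_qc.R           # MAF / call-rate / HWE filters
Rscript analysis/03_ase_detection.R         # per-animal binomial tests, ASE calls
Rscript analysis/04_aseqtl_scan.R           # the 1 Mb Wilcoxon scan
Rscript analysis/05_ld_blocks.R             # D' pairings and blocks
Rscript analysis/06_qtl_overlap.R           # permutation enrichment
Rscript analysis/07_annotation_methylation.R
Rscript analysis/08_regulatory_screen.R
```

The bulky genome FASTA written by step 1 goes to `scratch/` (it is
regenerable from the seed); everything else lands in `results/`.

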