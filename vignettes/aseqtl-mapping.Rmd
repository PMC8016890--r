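---
title: "Mapping cis-regulatory variants from allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cis-regulatory variants from allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asescan)
```

## The problem

In a heterozygous animal the two alleles of a transcribed SNP should
contribute equally to the transcript pool. When RNA-seq reads covering
such a SNP consistently favour one allele, the gene shows
allele-specific expression (ASE), and the cause is often a
*cis*-regulatory variant nearby: a promoter or enhancer SNP, an
allele-specific methylation mark, or an allele that creates or destroys
a transcription-factor or miRNA binding site. `asescan` implements the
full chain of inference from phased genotypes and per-allele read
counts to candidate regulatory variants — called aseQTLs — together
with their linkage structure, QTL-overlap enrichment, methylation
context and allele-differential binding-site screen. It was designed
around cattle muscle transcriptomes (populations of around 190
genotyped, phased animals), but nothing in it is species-specific.

## The statistics

**ASE detection.** For each animal heterozygous at a transcribed SNP
with reference and alternative read counts $(a, b)$, $a + b \ge 10$,
the two-sided exact binomial p-value against $p = 0.5$ is
$\min\{1,\, 2 \Pr[X \le \min(a, b)]\}$ with
$X \sim \mathrm{Bin}(a + b, 1/2)$. Benjamini–Hochberg FDR is applied
globally across all (animal, SNP) tests — the per-animal tests of one
SNP are not a natural family on their own — and a SNP is declared an
ASE marker when at least one animal is significant at FDR < 0.05. Both
choices are configurable (`fdr_scope`, `min_significant_samples`); the
defaults are the most permissive readings and are stated here because
the aggregation rule is genuinely open.

**The aseQTL scan.** The response is the folded allelic imbalance
ratio $|a/(a+b) - 1/2| \in [0, 0.5]$ of each marker-heterozygous
animal: 0 means balanced, 0.5 monoallelic expression. (Internally the
ratio is computed as $|a - b| / (2(a+b))$, an algebraically identical
form whose floating-point value is bit-identical under allele
relabelling; the unfolded reference fraction is also emitted for
phase-aware downstream checks.) For every candidate SNP within 1 Mb of
the marker (closed bound, same chromosome, the marker itself excluded
but neighbouring markers allowed), marker-heterozygous animals are
split by candidate genotype into heterozygotes and the **larger**
homozygous class, and compared with a one-sided Wilcoxon rank-sum test
(heterozygote imbalance greater): a true cis-variant produces imbalance
only in its heterozygotes, while its homozygotes express both marker
alleles equally. Tests require at least 10 heterozygotes at both the
candidate and the marker and at least `min_hom = 3` homozygotes; the
two 10-heterozygote floors are the procedure's published design, the
homozygous floor is ours (the procedure states none, but an empty or
single-animal comparison group leaves the test undefined in practice).
Ties between the two homozygous classes resolve to hom-ref.
Significance is declared at raw $p \le 0.05$ **without**
multiple-testing correction — deliberate and inherited from the
procedure this package reimplements, where the heterozygote requirement
already prunes the test set severely; a BH column is emitted for users
who prefer it. The Wilcoxon p uses the exact distribution when
$n_1 n_2 \le 400$ and the data are tie-free, otherwise the normal
approximation with tie and continuity correction; with imbalance ratios
ties are common, so the approximate branch dominates at realistic group
sizes. A degenerate comparison (every value identical in both groups)
returns $p = 1$ with a flag.

**Linkage disequilibrium.** From phased haplotypes,
$D = p_{AB} - p_A p_B$ and $D' = |D| / D_{\max}$ with the usual
normalisation; $D'$ rather than $r^2$ because it is less sensitive to
allele-frequency differences (both are reported). Haplotypes with a
missing or unphased allele at either locus are dropped pairwise; no EM
reconstruction from unphased genotypes is attempted. Blocks are called
by a transparent greedy rule — extend a genomically ordered run while
every within-run pair has $D' \ge 0.8$, emit runs of two or more. This
is **not** the Gabriel confidence-interval method of Haploview; the
greedy rule is fully specified by its threshold, which we consider a
feature.

**QTL overlap.** A 1-based point overlaps an internal 0-based
half-open interval $[s, e)$ when $s < p \le e$. The permutation null
re-places every point uniformly within its own chromosome
(per-chromosome counts preserved), 1000 iterations by default, and the
empirical p-value is the add-one estimator $(b + 1)/(K + 1)$, bounded
below by $1/(K+1) \approx 0.001$ at $K = 1000$ — an honest floor that
estimators quoting smaller values at the same $K$ do not have. No
assembly-gap masking is applied by default and QTL confidence
intervals are not padded.

**Annotation and methylation.** Feature classes come from a minimal
gene-model classifier with priority splice region > UTRs > exonic >
intronic > non-coding transcript > intergenic; the splice region is the
3 terminal exonic bases and first 8 intronic bases of each internal
exon junction — a documented stand-in for consequence predictors, which
keeps the analysis self-contained and reproducible offline. Exonic
variants are not split into synonymous/missense (no codon model).
Percent methylation is $100\,m/(m+u)$ per cytosine and animal; a
methylation record is attributed to an aseQTL only at the exact
position (a window option exists, default 0). The phase-aware
cross-check assigns the methylated allele from base context when
exactly one allele is a cytosine (or guanine, for the opposite strand)
and asks whether the ASE-marker allele in phase with it is
under-expressed: animals are *consistent* when that allele's expressed
fraction falls below 0.5 by more than 0.1, *inconsistent* when
expression is balanced (within 0.1) or skewed the other way, and
*uninformative* when homozygous, unphased, uncovered, ambiguous-base,
or below 50% methylation. The 0.1 margin and 50% floor are our
choices: the margin is about one binomial standard deviation of the
read fraction at depth 25, and a site methylated on fewer than half the
reads of a diploid cannot be confidently assigned to one haplotype.

**Regulatory screen.** Allelic 51-base flanks (25 bp each side, both
allelic versions, reference base verified against the genome) feed the
binding predictions. The package deliberately does **not** reimplement
biophysical affinity models or hybridisation thermodynamics: production
predictions enter as external hit tables, and the built-in log-odds PWM
scanner ($\sum_i \log_2 p_{b_i,i}/q_{b_i}$, both strands) exists so the
allele-differential logic — a factor hitting exactly one allele — is
testable end to end. miRNA interactions are kept only with MFE strictly
below −18.0 kcal/mol, and TF over-representation tables are thresholded
at BH-corrected $p \le 0.05$; both thresholds exactly as printed in the
protocol this follows, boundary values excluded.

## The synthetic population

`simulate_population()` generates the statistical structure the
analysis assumes, with ground truth for every stage. Per gene (one per
chromosome) a pool of `pool_size = 8` ancestral haplotypes over
`snps_per_block = 25` SNPs is drawn; each of `n_samples = 190` animals
receives two independent pool haplotypes. The finite pool creates
strong D′ within blocks and independence between blocks — a clean,
checkable LD ground truth. The cis effect is one parameter: in a
causal-heterozygote the haplotype in phase with the causal alternative
allele is expressed at relative rate $1 - \beta$, so the allele it
carries has expressed fraction $(1-\beta)/(2-\beta)$ — 0.5 at
$\beta = 0$ (null), 1/3 at $\beta = 0.5$, 0 (monoallelic) at
$\beta = 1$. Read depth at the marker is negative binomial (mean 30,
size 5, floored at 1), overdispersed as RNA-seq coverage is; reference
counts are binomial at the phase-determined rate. Methylation records
are emitted at causal positions for a 12-animal subset (the size of a
typical RRBS companion experiment) with per-read methylation
probability 0.8 in carriers of the causal alternative allele and 0.05
otherwise; causal variants always carry a T>C substitution so the
methylatable cytosine belongs to one allele. Trait QTL intervals
(20–60 kb) are planted over causal variants with probability 0.6 plus
uniform decoys.

Two constraints on the marker/causal pool columns matter. First, the
realised pool frequency must fall within `1/pool_size` of the
configured MAF: with eight haplotypes an unconstrained Bernoulli draw
routinely lands far from its target, and the configured frequency is a
study condition, not a suggestion. Second, a causal column inducing the
same sample partition as its marker (identical or complementary pool
pattern) is redrawn: such a variant is in perfect LD with the marker,
every marker heterozygote is a causal heterozygote, no homozygous
comparison group exists, and the scan's premise — a *distinct*
regulatory variant — is violated by construction.

What the generator does **not** emulate: reference-mapping bias toward
the reference allele, extra-binomial (beta-binomial) overdispersion of
allelic counts, coalescent-realistic recombination gradients within
blocks, relatedness between animals, genotyping error, and
multi-transcript gene structure. Passing calibration and recovery tests
on this generator therefore demonstrates that the inference machinery
is correct under its own model, not that real-data confounders are
handled; on real data the binomial ASE test is anti-conservative in
the presence of mapping bias, which is why upstream pipelines align to
individualised diploid genomes.

## Test problem sizes

The suite calibrates the scan's type-I error on four null populations
(β = 0, 190 animals, 20 genes × 30 SNPs each, ≥ 2000 valid tests,
expecting an empirical rate in [0.03, 0.07]) and measures recovery on
200 single-gene populations (β = 1, causal MAF 0.3, depth 30),
expecting the causal variant significant in ≥ 95% of replicates and
among its window's five smallest p-values in ≥ 90%. Oracle tests
enumerate the binomial tail for all depths ≤ 30, the Wilcoxon null for
all tie-free group sizes ≤ 8, D′ on 500 random haplotype sets, and BH
on 1000 random vectors. These sizes keep the whole suite under a
couple of minutes on one core while leaving the Monte-Carlo margins
comfortable.

## Known limitations

* The scan tests one candidate at a time; haplotype-level or
  conditional analysis of multiple linked candidates is out of scope,
  which is why the LD module reports blocks — hits inside one block are
  one signal, not many.
* The greedy block rule can split a Haploview-style block at a single
  weak pair; counts of blocks are not comparable across methods.
* The permutation null ignores the genomic clustering of markers
  (points are re-placed independently) and matches regioneR's
  uniform re-placement rather than circular shifts; a circular-shift
  null would preserve inter-point spacing.
* The exact Wilcoxon branch is limited to $n_1 n_2 \le 400$ tie-free
  inputs; beyond that the normal approximation's accuracy (~1e-2
  absolute near $p = 0.05$) bounds the precision of borderline calls.
* `classify_location` uses one flattened transcript per gene; variants
  in genes with isoform-specific UTRs may be classed by the union
  annotation.
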