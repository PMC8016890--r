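#!/usr/bin/env Rscript

# Step 4 — the aseQTL scan.
#
# For every ASE marker, all QC-passing SNPs within 1 Mb are candidates.
# Imbalance ratios of marker-heterozygous animals are compared between
# candidate heterozygotes and the larger candidate homozygous class with
# a one-sided Wilcoxon rank-sum test; significance at raw p <= 0.05 (no
# multiple-testing correction — the 10-heterozygote requirement already
# restricts the tests), with a BH column for reference.

suppressMessages(library(asescan))

geno <- read_phased_vcf("results/data/genotypes.vcf")
qc <- read.delim("results/qc_variants.tsv")
geno <- subset_geno(geno, variants = qc$id[qc$pass])
counts <- read_counts_table("results/data/counts.tsv")
calls <- read.delim("results/ase_calls.tsv")
ase_ids <- calls$variant[calls$is_ase]
models <- read_gene_models("results/data/genes.gff3")

# an ASE marker's gene: the annotated gene whose span contains it
marker_pos <- geno$variants[match(ase_ids, geno$variants$id), ]
gene_map <- vapply(seq_along(ase_ids), function(i) {
  g <- models$genes
  hit <- g$chrom == marker_pos$chrom[i] & g$start <= marker_pos$pos[i] &
    marker_pos$pos[i] <= g$end
  if (any(hit)) g$gene_id[which(hit)[1]] else NA_character_
}, character(1))
names(gene_map) <- ase_ids

scan <- scan_aseqtl(geno, counts, ase_ids, window_bp = 1e6,
                    min_het = 10, min_hom = 3, min_depth = 10,
                    alpha = 0.05, gene_map = gene_map, gene_models = models)

write.table(scan, "results/aseqtl.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
skips <- attr(scan, "skips")
if (!is.null(skips))
  write.table(skips, "results/aseqtl_skips.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)

s <- summarize_scan(scan)
cat("Valid tests:", s$n_tests, "; skipped pairs:",
    if (is.null(skips)) 0 else nrow(skips), "\n")
cat("Significant aseQTLs (p <= 0.05):", s$n_significant, "associated with",
    s$n_ase_with_aseqtl, "ASE markers\n")
cat(sprintf("Mean aseQTLs per marker: %.1f\n", s$mean_aseqtls_per_marker))
cat(sprintf("Mean reference-allele frequency of aseQTLs: %.2f\n",
            s$mean_ref_allele_freq))
cat(sprintf("Mean distance to ASE marker: %.0f bp; to TSS: %.0f bp\n",
            s$mean_distance_bp, s$mean_distance_to_tss))
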