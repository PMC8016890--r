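#!/usr/bin/env Rscript

# Step 7 — genomic context and methylation of the aseQTLs.
#
# Feature-class annotation from the gene models, TSS distances, percent
# methylation at aseQTL positions, and the phase-aware cross-check of
# whether methylated aseQTL alleles silence the in-phase ASE allele.

suppressMessages(library(asescan))

geno <- read_phased_vcf("results/data/genotypes.vcf")
counts <- read_counts_table("results/data/counts.tsv")
scan <- read.delim("results/aseqtl.tsv")
models <- read_gene_models("results/data/genes.gff3")
meth <- read_methylation_table("results/data/methylation.tsv")

ann <- annotate_aseqtls(scan, geno, models, meth)
write.table(ann, "results/aseqtl_annotated.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- ann[ann$significant, ]
cat("Feature classes of the", nrow(sig), "significant aseQTLs:\n")
print(round(100 * sort(table(sig$feature_class), decreasing = TRUE) /
              nrow(sig), 1))
cat(sprintf("Mean distance to TSS: %.0f bp\n",
            mean(sig$distance_to_tss, na.rm = TRUE)))
cat("Methylated aseQTLs (>= 1 covered animal):",
    sum(sig$n_meth_samples > 0), "\n")

# phase-aware silencing cross-check for every methylated significant pair
checks <- list()
for (i in which(sig$n_meth_samples > 0)) {
  res <- methylation_ase_crosscheck(geno, counts, sig$candidate_variant[i],
                                    sig$ase_variant[i], meth)
  if (nrow(res)) {
    res$aseqtl <- sig$candidate_variant[i]
    res$ase_marker <- sig$ase_variant[i]
    checks[[length(checks) + 1]] <- res
  }
}
if (length(checks)) {
  cc <- do.call(rbind, checks)
  write.table(cc, "results/methylation_crosscheck.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("Methylation/ASE cross-check verdicts:\n")
  print(table(cc$status))
}
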