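#!/usr/bin/env Rscript

# Step 5 — linkage disequilibrium structure of the hits.
#
# D' from phased haplotypes in the three pairings the scan motivates:
# each aseQTL against its own ASE marker, all aseQTLs among themselves,
# and all ASE markers among themselves; then greedy D' >= 0.8 blocks
# over the aseQTLs.

suppressMessages(library(asescan))

geno <- read_phased_vcf("results/data/genotypes.vcf")
scan <- read.delim("results/aseqtl.tsv")
sig <- scan[scan$significant, ]
aseqtls <- unique(sig$candidate_variant)
markers <- unique(sig$ase_variant)

ld_pairs <- pairwise_ld(geno, "aseqtl_vs_ase", pairs = sig)
ld_among <- pairwise_ld(geno, "among_aseqtls", variants = aseqtls)
ld_markers <- pairwise_ld(geno, "among_ase", variants = markers)

for (x in list(list(ld_pairs, "ld_aseqtl_vs_ase"),
               list(ld_among, "ld_among_aseqtls"),
               list(ld_markers, "ld_among_ase"))) {
  write.table(x[[1]], file.path("results", paste0(x[[2]], ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- attr(x[[1]], "summary")
  cat(sprintf("%-18s %4d pairs; D' > 0.8: %4d; D' = 1: %4d\n",
              s$mode, s$n_pairs, s$n_high_ld, s$n_complete_ld))
}

blocks <- find_blocks(ld_among, geno$variants, threshold = 0.8)
block_df <- do.call(rbind, lapply(seq_along(blocks), function(i)
  data.frame(block = i, chrom = blocks[[i]]$chrom,
             n_variants = length(blocks[[i]]$variants),
             min_d_prime = blocks[[i]]$min_d_prime,
             variants = paste(blocks[[i]]$variants, collapse = ","))))
if (!is.null(block_df))
  write.table(block_df, "results/ld_blocks.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
cat("aseQTL LD blocks (all pairwise D' >= 0.8):", length(blocks), "\n")
if (length(blocks))
  cat("Block sizes:", paste(sapply(blocks, function(b)
    length(b$variants)), collapse = ", "), "\n")
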