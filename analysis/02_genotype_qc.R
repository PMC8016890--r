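#!/usr/bin/env Rscript

# Step 2 — marker and sample quality control.
#
# Array-era filters with strict thresholds: samples with call rate below
# 95% first, then variants with call rate below 95%, MAF below 5%, or
# HWE p <= 1e-4. Survivor lists drive every later step.

suppressMessages(library(asescan))

geno <- read_phased_vcf("results/data/genotypes.vcf", require_phased = TRUE)
qc <- apply_filters(geno, maf_min = 0.05, call_rate_min = 0.95,
                    hwe_alpha = 1e-4)

write.table(qc$report$variants, "results/qc_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(qc$report$samples, "results/qc_samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

v <- qc$report$variants
cat("Samples passing call-rate filter:", sum(qc$report$samples$pass),
    "of", nrow(qc$report$samples), "\n")
cat("Variants passing all filters:", sum(v$pass), "of", nrow(v), "\n")
if (any(!v$pass)) print(table(v$reason[!v$pass]))
cat("MAF range among survivors:",
    sprintf("%.3f - %.3f", min(v$maf[v$pass]), max(v$maf[v$pass])), "\n")
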