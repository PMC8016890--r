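#!/usr/bin/env Rscript

# Step 1 — generate the study population.
#
# A synthetic stand-in for the study data: 190 phased animals, 12 LD
# blocks (one gene each), an ASE marker per gene with allele-specific
# read counts, a causal cis-variant whose heterozygosity silences one
# haplotype, RRBS methylation for 12 animals, and trait QTL intervals
# partly planted over the causal variants. All downstream steps read the
# files written here, exactly as they would read real study data.

suppressMessages(library(asescan))

cfg <- sim_config(n_blocks = 12, beta = 0.8, rng_seed = 42)
sim <- simulate_population(cfg, with_genome = TRUE)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
paths <- write_simulation(sim, "results/data", genome_dir = "scratch")

# chromosome sizes, needed by the permutation overlap test in step 6
sizes <- data.frame(chrom = as.character(seq_len(cfg$n_blocks)),
                    size = as.integer(cfg$chrom_length))
write.table(sizes, "results/data/chrom_sizes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", cfg$n_samples, "animals x", nrow(sim$geno$variants),
    "SNPs in", cfg$n_blocks, "blocks (beta =", cfg$beta, ")\n")
cat("ASE markers:", paste(sim$truth$blocks$marker, collapse = ", "), "\n")
cat("Causal variants lie", min(sim$truth$blocks$distance), "-",
    max(sim$truth$blocks$distance), "bp from their markers\n")
cat("Files written:\n")
for (p in paths) cat("  ", p, "\n")
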