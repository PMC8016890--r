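toy_models <- function() {
  list(
    genes = data.frame(
      gene_id = c("gPlus", "gMinus", "gNc"),
      chrom = c("1", "1", "2"),
      start = c(1000L, 5000L, 100L),
      end = c(3000L, 5900L, 900L),
      strand = c("+", "-", "+"),
      coding = c(TRUE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    features = data.frame(
      gene_id = c("gPlus", "gPlus", "gPlus", "gPlus", "gMinus"),
      type = c("exon", "exon", "five_prime_UTR", "three_prime_UTR", "exon"),
      chrom = c("1", "1", "1", "1", "1"),
      start = c(1000L, 2500L, 1000L, 2900L, 5000L),
      end = c(1500L, 3000L, 1100L, 3000L, 5900L),
      stringsAsFactors = FALSE))
}

test_that("TSS distance is strand-aware and unsigned", {
  gm <- toy_models()
  expect_equal(distance_to_tss(1500000, "gX", gm), NA_real_)
  expect_equal(distance_to_tss(1000, "gPlus", gm), 0)
  expect_equal(distance_to_tss(1500, "gPlus", gm), 500)
  # minus-strand gene spanning 5000-5900: TSS at the end coordinate
  expect_equal(distance_to_tss(5950, "gMinus", gm), 50)
  expect_equal(distance_to_tss(5000, "gMinus", gm), 900)
})

test_that("feature classification follows the documented priority order", {
  gm <- toy_models()
  cls <- function(chrom, pos) classify_location(chrom, pos, gm)
  expect_equal(cls("1", 4000), "intergenic")
  expect_equal(cls("1", 2000), "intronic")
  expect_equal(cls("1", 1300), "exonic")
  expect_equal(cls("1", 1050), "five_prime_UTR")
  expect_equal(cls("1", 2950), "three_prime_UTR")
  expect_equal(cls("2", 500), "non_coding_transcript")
  # 2 bp into the intron from the junction at 1500/1501
  expect_equal(cls("1", 1502), "splice_region")
  # 9 bp into the intron: outside the 8 bp splice window
  expect_equal(cls("1", 1509), "intronic")
  # terminal exonic bases at an internal junction outrank UTR/exon classes
  expect_equal(cls("1", 1500), "splice_region")
  expect_equal(cls("1", 2500), "splice_region")
  # gene-terminal exon edges are not splice junctions
  expect_equal(cls("1", 1000), "five_prime_UTR")
  expect_equal(cls("1", 3000), "three_prime_UTR")
})

test_that("feature classes partition the variants of a simulated population", {
  cfg <- sim_config(n_blocks = 3, rng_seed = 41)
  sim <- simulate_population(cfg)
  v <- sim$geno$variants
  cls <- vapply(seq_len(nrow(v)), function(i)
    classify_location(v$chrom[i], v$pos[i], sim$gene_models), character(1))
  expect_equal(length(cls), nrow(v))
  expect_true(all(cls %in% c("intergenic", "intronic", "exonic",
                             "five_prime_UTR", "three_prime_UTR",
                             "splice_region", "non_coding_transcript")))
  expect_equal(sum(table(cls)), nrow(v))
})

test_that("percent methylation is 100 m / (m + u)", {
  expect_equal(methylation_percent(5, 15), 25)
  expect_equal(methylation_percent(7, 0), 100)
  expect_equal(methylation_percent(0, 9), 0)
  expect_error(methylation_percent(0, 0), "zero")
})

crosscheck_toy <- function(ref_count, alt_count, aseqtl_gt = c(0L, 1L),
                           ase_gt = c(0L, 1L), meth_pct = 100) {
  # aseQTL at pos 100 (T>C: methylation on the alternative allele),
  # ASE marker at pos 200
  pgm <- toy_geno(hap_a = cbind(aseqtl_gt[1], ase_gt[1]),
                  hap_b = cbind(aseqtl_gt[2], ase_gt[2]),
                  pos = c(100L, 200L), ids = c("q", "m"),
                  ref = c("T", "A"), alt = c("C", "G"))
  counts <- data.frame(sample = "s1", variant = "m",
                       ref_count = ref_count, alt_count = alt_count,
                       stringsAsFactors = FALSE)
  meth <- data.frame(sample = "s1", chrom = "1", pos = 100L,
                     methylated_count = as.integer(meth_pct / 10),
                     unmethylated_count = as.integer(10 - meth_pct / 10),
                     stringsAsFactors = FALSE)
  methylation_ase_crosscheck(pgm, counts, "q", "m", meth)
}

test_that("the phase-aware methylation cross-check labels the clear cases", {
  # methylated allele (C) on hap B, in phase with marker alt; the animal
  # expresses only the allele in trans (marker ref): consistent silencing
  res <- crosscheck_toy(ref_count = 30L, alt_count = 0L)
  expect_equal(res$status, "consistent")
  expect_equal(res$phase_allele, "alt")
  expect_equal(res$expressed_fraction, 0)
  # balanced expression despite 100% methylation: inconsistent
  expect_equal(crosscheck_toy(15L, 15L)$status, "inconsistent")
  # imbalance in the wrong direction: inconsistent
  expect_equal(crosscheck_toy(0L, 30L)$status, "inconsistent")
  # homozygous ASE marker: uninformative
  expect_equal(crosscheck_toy(30L, 0L, ase_gt = c(1L, 1L))$status,
               "uninformative")
  # homozygous aseQTL: no methylated/unmethylated haplotype contrast
  expect_equal(crosscheck_toy(30L, 0L, aseqtl_gt = c(1L, 1L))$status,
               "uninformative")
  # weak methylation is uninformative by default
  expect_equal(crosscheck_toy(30L, 0L, meth_pct = 20)$status,
               "uninformative")
})

test_that("unphased genotypes are uninformative", {
  pgm <- toy_geno(hap_a = cbind(0L, 0L), hap_b = cbind(1L, 1L),
                  pos = c(100L, 200L), ids = c("q", "m"),
                  ref = c("T", "A"), alt = c("C", "G"),
                  phased = matrix(FALSE, 1, 2))
  counts <- data.frame(sample = "s1", variant = "m",
                       ref_count = 30L, alt_count = 0L)
  meth <- data.frame(sample = "s1", chrom = "1", pos = 100L,
                     methylated_count = 10L, unmethylated_count = 0L)
  expect_equal(methylation_ase_crosscheck(pgm, counts, "q", "m", meth)$status,
               "uninformative")
})

test_that("planted silencing methylation reads as consistent in most animals", {
  cfg <- sim_config(n_blocks = 4, beta = 1, n_meth_samples = 190,
                    rng_seed = 43)
  sim <- simulate_population(cfg)
  statuses <- c()
  for (b in 1:4) {
    tb <- sim$truth$blocks[b, ]
    res <- methylation_ase_crosscheck(sim$geno, sim$counts, tb$causal,
                                      tb$marker, sim$methylation)
    statuses <- c(statuses, res$status)
  }
  informative <- statuses[statuses != "uninformative"]
  expect_gt(length(informative), 20)
  expect_gte(mean(informative == "consistent"), 0.9)
})

test_that("scan annotation attaches feature classes and methylation", {
  cfg <- sim_config(n_blocks = 2, beta = 1, rng_seed = 44)
  sim <- simulate_population(cfg)
  sc <- scan_aseqtl(sim$geno, sim$counts, sim$truth$blocks$marker)
  ann <- annotate_aseqtls(sc, sim$geno, sim$gene_models, sim$methylation)
  expect_equal(nrow(ann), nrow(sc))
  expect_true(all(nzchar(ann$feature_class)))
  covered <- ann[ann$candidate_variant %in% sim$truth$blocks$causal, ]
  expect_true(all(covered$n_meth_samples > 0))
  expect_true(all(covered$mean_meth_percent >= 0 &
                    covered$mean_meth_percent <= 100))
})
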