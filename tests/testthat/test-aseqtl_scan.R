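test_that("the imbalance ratio folds the reference fraction around 0.5", {
  expect_equal(imbalance_ratio(0, 30), 0.5)   # monoallelic alternative
  expect_equal(imbalance_ratio(30, 0), 0.5)
  expect_equal(imbalance_ratio(15, 15), 0)
  expect_equal(imbalance_ratio(9, 3), 0.25)
  expect_true(is.na(imbalance_ratio(0, 0)))
})

test_that("candidate windows use a closed 1 Mb bound on the same chromosome", {
  v <- data.frame(id = c("a1", "c_at", "c_over", "c_near", "other", "a2"),
                  chrom = c("1", "1", "1", "1", "2", "1"),
                  pos = c(2e6, 1e6, 999999, 2.5e6, 2e6, 2.2e6),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  w <- build_windows(c("a1", "a2"), v, half_width = 1e6)
  w1 <- w$candidate_variant[w$ase_variant == "a1"]
  expect_true("c_at" %in% w1)          # exactly 1,000,000 bp away: included
  expect_false("c_over" %in% w1)       # 1,000,001 bp: excluded
  expect_false("other" %in% w1)        # different chromosome
  expect_false("a1" %in% w1)           # never its own candidate
  expect_true("a2" %in% w1)            # a neighbouring ASE SNP can be one
  expect_true("a1" %in% w$candidate_variant[w$ase_variant == "a2"])
})

scan_toy <- function(n_het = 12, n_hom0 = 20, n_hom2 = 5, het_imb = 0.4,
                     hom_imb = 0.05, depth = 20L) {
  n <- n_het + n_hom0 + n_hom2
  cand <- c(rep(1L, n_het), rep(0L, n_hom0), rep(2L, n_hom2))
  pgm <- geno_from_codes(cbind(rep(1L, n), cand), ids = c("ase", "cand"),
                         pos = c(1000L, 2000L))
  imb <- c(rep(het_imb, n_het), rep(hom_imb, n_hom0 + n_hom2))
  counts <- data.frame(sample = pgm$samples, variant = "ase",
                       ref_count = as.integer(round(depth * (0.5 + imb))),
                       alt_count = as.integer(depth -
                                                round(depth * (0.5 + imb))),
                       stringsAsFactors = FALSE)
  list(pgm = pgm, counts = counts)
}

test_that("grouping keeps ASE-heterozygous samples and the larger hom class", {
  toy <- scan_toy()
  prof <- imbalance_profile(toy$counts, toy$pgm, "ase")
  grp <- group_samples("cand", "ase", toy$pgm, prof)
  expect_equal(grp$n_het, 12L)
  expect_equal(grp$hom_group, "0/0")
  expect_equal(grp$n_hom, 20L)
  # fewer than 10 candidate heterozygotes is a recorded skip
  toy9 <- scan_toy(n_het = 9)
  prof9 <- imbalance_profile(toy9$counts, toy9$pgm, "ase")
  expect_equal(group_samples("cand", "ase", toy9$pgm, prof9)$skip,
               "min_het_candidate")
  # tied homozygous groups use hom-ref by convention
  tied <- scan_toy(n_hom0 = 15, n_hom2 = 15)
  ptied <- imbalance_profile(tied$counts, tied$pgm, "ase")
  expect_equal(group_samples("cand", "ase", tied$pgm, ptied)$hom_group, "0/0")
  # hom group below the floor is a skip
  small <- scan_toy(n_hom0 = 2, n_hom2 = 1)
  psmall <- imbalance_profile(small$counts, small$pgm, "ase")
  expect_equal(group_samples("cand", "ase", small$pgm, psmall)$skip,
               "min_hom")
})

test_that("the one-sided Wilcoxon p matches exact enumeration", {
  res <- wilcoxon_rank_sum(c(0.40, 0.45, 0.50), c(0.05, 0.10, 0.15))
  expect_equal(res$p_value, 1 / 20)  # het fully above hom: 1 of C(6,3)
  expect_true(res$exact)
  # identical multisets carry no evidence in the "greater" direction
  res2 <- wilcoxon_rank_sum(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1))
  expect_gte(res2$p_value, 0.5)
  # fully reversed ordering
  res3 <- wilcoxon_rank_sum(c(0.05, 0.10, 0.15), c(0.40, 0.45, 0.50))
  expect_equal(res3$p_value, 1)
  # degenerate all-identical values
  res4 <- wilcoxon_rank_sum(rep(0.2, 5), rep(0.2, 4))
  expect_equal(res4$p_value, 1)
  expect_true(res4$degenerate)
  # random tie-free cases against the enumeration oracle
  set.seed(13)
  for (i in 1:20) {
    x <- runif(sample(3:8, 1)); y <- runif(sample(3:8, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcox_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact and approximate branches agree to first order", {
  set.seed(14)
  for (i in 1:20) {
    x <- runif(8); y <- runif(8)
    p_exact <- wilcoxon_rank_sum(x, y)$p_value
    p_approx <- suppressWarnings(stats::wilcox.test(
      x, y, alternative = "greater", exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("the scan flags the planted causal variant and logs skips", {
  cfg <- sim_config(n_blocks = 2, beta = 1, rng_seed = 71)
  sim <- simulate_population(cfg)
  sc <- scan_aseqtl(sim$geno, sim$counts, sim$truth$blocks$marker,
                    gene_map = stats::setNames(sim$truth$blocks$gene_id,
                                               sim$truth$blocks$marker),
                    gene_models = sim$gene_models)
  for (b in 1:2) {
    row <- sc[sc$ase_variant == sim$truth$blocks$marker[b] &
                sc$candidate_variant == sim$truth$blocks$causal[b], ]
    expect_equal(nrow(row), 1L)
    expect_true(row$significant)
  }
  expect_true(all(sc$p_value > 0 & sc$p_value <= 1))
  expect_true(all(sc$distance_bp <= cfg$window_bp))
  expect_true(all(!is.na(sc$distance_to_tss)))
  # skips (if any) carry named reasons
  skips <- attr(sc, "skips")
  if (!is.null(skips))
    expect_true(all(skips$reason %in%
                      c("min_het_candidate", "min_het_ase", "min_hom")))
  sm <- summarize_scan(sc)
  expect_equal(sm$n_tests, nrow(sc))
  expect_gte(sm$mean_ref_allele_freq, 0)
})

test_that("relabelling ref/alt at the ASE marker leaves p-values unchanged", {
  cfg <- sim_config(n_blocks = 1, beta = 0.8, rng_seed = 72)
  sim <- simulate_population(cfg)
  marker <- sim$truth$blocks$marker
  sc1 <- scan_aseqtl(sim$geno, sim$counts, marker)
  # swap alleles: flip haplotype codes at the marker and swap the counts
  pgm2 <- sim$geno
  mi <- match(marker, pgm2$variants$id)
  pgm2$hap_a[, mi] <- 1L - pgm2$hap_a[, mi]
  pgm2$hap_b[, mi] <- 1L - pgm2$hap_b[, mi]
  pgm2$variants$ref[mi] <- sim$geno$variants$alt[mi]
  pgm2$variants$alt[mi] <- sim$geno$variants$ref[mi]
  counts2 <- sim$counts
  counts2$ref_count <- sim$counts$alt_count
  counts2$alt_count <- sim$counts$ref_count
  sc2 <- scan_aseqtl(pgm2, counts2, marker)
  expect_equal(sc1$p_value, sc2$p_value)
  expect_equal(sc1$candidate_variant, sc2$candidate_variant)
})

test_that("a scan with no valid test returns an empty result with skip log", {
  toy <- scan_toy(n_het = 9, n_hom0 = 30, n_hom2 = 0)
  sc <- scan_aseqtl(toy$pgm, toy$counts, "ase")
  expect_equal(nrow(sc), 0L)
  expect_gt(nrow(attr(sc, "skips")), 0L)
})
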