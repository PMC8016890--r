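test_that("D' from haplotype counts reproduces the frequency arithmetic", {
  expect_equal(d_prime_counts(c(50, 0, 0, 50))$d_prime, 1)
  expect_equal(d_prime_counts(c(25, 25, 25, 25))$d_prime, 0)
  res <- d_prime_counts(c(40, 10, 10, 40))
  expect_equal(res$D, 0.15)
  expect_equal(res$d_prime, 0.6)  # D_max = 0.25
  expect_equal(res$r2, 0.36)
  # monomorphic locus: undefined
  expect_true(is.na(d_prime_counts(c(50, 50, 0, 0))$d_prime))
  # any empty haplotype class forces D' = 1
  set.seed(3)
  for (i in 1:30) {
    cnt <- sample(1:50, 4)
    cnt[sample(4, 1)] <- 0
    res <- d_prime_counts(cnt)
    if (!is.na(res$d_prime)) expect_equal(res$d_prime, 1)
  }
})

test_that("matrix-based D' is symmetric, relabel-invariant and bounded", {
  set.seed(4)
  for (i in 1:40) {
    hp <- random_hap_pair(60)
    n <- 30
    pgm <- toy_geno(cbind(hp$a[1:n], hp$b[1:n]),
                    cbind(hp$a[(n + 1):(2 * n)], hp$b[(n + 1):(2 * n)]))
    d_ab <- d_prime(pgm, "v1", "v2")$d_prime
    d_ba <- d_prime(pgm, "v2", "v1")$d_prime
    if (is.na(d_ab)) next
    expect_equal(d_ab, d_ba)
    expect_gte(d_ab, 0); expect_lte(d_ab, 1)
    # relabel alleles at the first locus
    pgm2 <- pgm
    pgm2$hap_a[, 1] <- 1L - pgm2$hap_a[, 1]
    pgm2$hap_b[, 1] <- 1L - pgm2$hap_b[, 1]
    expect_equal(d_prime(pgm2, "v1", "v2")$d_prime, d_ab)
  }
})

test_that("D' agrees with brute-force haplotype tabulation", {
  set.seed(6)
  for (i in 1:100) {
    hp <- random_hap_pair(50)
    n <- 25
    pgm <- toy_geno(cbind(hp$a[1:n], hp$b[1:n]),
                    cbind(hp$a[(n + 1):(2 * n)], hp$b[(n + 1):(2 * n)]))
    got <- d_prime(pgm, "v1", "v2")$d_prime
    want <- dprime_oracle(hp$a, hp$b)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("missing haplotypes are dropped pairwise", {
  a <- c(0L, 0L, 1L, 1L, NA, 0L)
  b <- c(0L, 0L, 1L, 1L, 1L, NA)
  pgm <- toy_geno(cbind(a[1:3], b[1:3]), cbind(a[4:6], b[4:6]))
  res <- d_prime(pgm, "v1", "v2")
  expect_equal(sum(res$n_AB, res$n_Ab, res$n_aB, res$n_ab), 4)
  expect_equal(res$d_prime, 1)
})

test_that("pairing schemes restrict to within-chromosome pairs and summarise", {
  set.seed(9)
  ha <- matrix(sample(0:1, 40 * 4, TRUE), 40)
  hb <- matrix(sample(0:1, 40 * 4, TRUE), 40)
  pgm <- toy_geno(ha, hb, chrom = c("1", "1", "2", "2"))
  ld <- pairwise_ld(pgm, "among_aseqtls", variants = paste0("v", 1:4))
  expect_equal(nrow(ld), 2L)  # (v1,v2) and (v3,v4) only
  expect_setequal(paste(ld$variant_a, ld$variant_b), c("v1 v2", "v3 v4"))
  s <- attr(ld, "summary")
  expect_equal(s$n_pairs, 2L)
  expect_equal(s$n_high_ld, sum(!is.na(ld$d_prime) & ld$d_prime > 0.8))
  # explicit pair mode drops cross-chromosome requests
  pairs <- data.frame(ase_variant = c("v1", "v1"),
                      candidate_variant = c("v2", "v3"))
  ld2 <- pairwise_ld(pgm, "aseqtl_vs_ase", pairs = pairs)
  expect_equal(nrow(ld2), 1L)
  expect_equal(ld2$variant_a, "v2")
})

test_that("greedy block detection follows the documented threshold rule", {
  v <- data.frame(id = paste0("v", 1:4), chrom = "1",
                  pos = 1:4 * 1000L, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  full <- expand.grid(a = 1:4, b = 1:4)
  full <- full[full$a < full$b, ]
  mk_pairs <- function(dp_fun) data.frame(
    variant_a = paste0("v", full$a), variant_b = paste0("v", full$b),
    d_prime = mapply(dp_fun, full$a, full$b), stringsAsFactors = FALSE)

  # chain of four in complete LD: a single block of four
  all1 <- mk_pairs(function(a, b) 1)
  blocks <- find_blocks(all1, v)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$variants, paste0("v", 1:4))
  expect_equal(blocks[[1]]$min_d_prime, 1)

  # first three tight, the fourth unlinked: block of three, singleton dropped
  mixed <- mk_pairs(function(a, b) if (b <= 3) 1 else 0.2)
  blocks <- find_blocks(mixed, v)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$variants, paste0("v", 1:3))

  # nothing above threshold: no blocks
  low <- mk_pairs(function(a, b) 0.3)
  expect_length(find_blocks(low, v), 0L)
})

test_that("simulated blocks are recovered as high-D' runs", {
  cfg <- sim_config(n_samples = 150, n_blocks = 2, snps_per_block = 6,
                    pool_size = 4, rng_seed = 17)
  sim <- simulate_population(cfg)
  ids <- sim$geno$variants$id
  ld <- pairwise_ld(sim$geno, "among_aseqtls", variants = ids)
  blocks <- find_blocks(ld, sim$geno$variants, threshold = 0.8)
  expect_gte(length(blocks), 1L)
  for (bl in blocks) {
    expect_gte(length(bl$variants), 2L)
    expect_gte(bl$min_d_prime, 0.8)
    expect_equal(length(unique(
      sim$geno$variants$chrom[match(bl$variants, sim$geno$variants$id)])), 1L)
  }
})
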