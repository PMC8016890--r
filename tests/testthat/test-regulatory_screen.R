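toy_genome <- function() {
  set.seed(19)
  seqs <- Biostrings::DNAStringSet(c(
    paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")))
  names(seqs) <- "1"
  seqs
}

test_that("allelic flanks are centred, substituted and edge-truncated", {
  genome <- toy_genome()
  base100 <- as.character(Biostrings::subseq(genome[[1]], 100, 100))
  alt <- setdiff(c("A", "C", "G", "T"), base100)[1]
  v <- data.frame(id = "rsX", chrom = "1", pos = 100L,
                  ref = base100, alt = alt, stringsAsFactors = FALSE)
  fl <- extract_flanks(v, genome)
  expect_equal(nchar(fl$ref_seq), 51L)
  expect_equal(fl$center, 26L)
  expect_false(fl$truncated)
  expect_equal(substr(fl$ref_seq, 26, 26), base100)
  expect_equal(substr(fl$alt_seq, 26, 26), alt)
  # sequences differ at exactly the centre
  diffs <- which(strsplit(fl$ref_seq, "")[[1]] != strsplit(fl$alt_seq, "")[[1]])
  expect_equal(diffs, 26L)
  # substituting the centre maps ref_seq onto alt_seq and back
  back <- fl$alt_seq
  substr(back, fl$center, fl$center) <- v$ref
  expect_equal(back, fl$ref_seq)

  # truncation near the contig edge
  base10 <- as.character(Biostrings::subseq(genome[[1]], 10, 10))
  v10 <- data.frame(id = "rsEdge", chrom = "1", pos = 10L, ref = base10,
                    alt = setdiff(c("A", "C", "G", "T"), base10)[1])
  fl10 <- extract_flanks(v10, genome)
  expect_true(fl10$truncated)
  expect_equal(nchar(fl10$ref_seq), 35L)  # 9 left + 1 + 25 right
  expect_equal(fl10$center, 10L)

  # genome/ref mismatch is a hard error naming the variant
  vbad <- v; vbad$ref <- alt; vbad$alt <- base100
  expect_error(extract_flanks(vbad, genome), "rsX")
})

test_that("the MFE filter keeps strictly-below-threshold interactions", {
  tab <- data.frame(variant = paste0("v", 1:4), factor = "miR-1",
                    mfe = c(-20, -17, -18, NA), stringsAsFactors = FALSE)
  expect_warning(out <- mfe_filter(tab), "without MFE")
  expect_equal(out$variant, "v1")  # -18.0 exactly is dropped
  expect_equal(nrow(mfe_filter(tab[1:3, ])), 1L)
})

test_that("differential hits are allele-exclusive and antisymmetric", {
  hr <- data.frame(variant = c("v1", "v2", "v3"),
                   factor = c("TF_A", "TF_B", "TF_C"),
                   score = c(5, 6, 7), stringsAsFactors = FALSE)
  ha <- data.frame(variant = c("v2", "v4"), factor = c("TF_B", "TF_D"),
                   score = c(6.5, 8), stringsAsFactors = FALSE)
  d <- differential_hits(hr, ha)
  expect_setequal(paste(d$variant, d$factor, d$allele),
                  c("v1 TF_A ref", "v3 TF_C ref", "v4 TF_D alt"))
  # shared (v2, TF_B) is excluded entirely
  expect_false("v2" %in% d$variant)
  # swapping the tables swaps the allele labels exactly
  d2 <- differential_hits(ha, hr)
  m <- merge(d, d2, by = c("variant", "factor"))
  expect_true(all((m$allele.x == "ref") == (m$allele.y == "alt")))
  # empty alternative table: every reference hit is differential
  d3 <- differential_hits(hr, ha[0, ])
  expect_equal(sort(d3$variant), c("v1", "v2", "v3"))
  expect_true(all(d3$allele == "ref"))
})

test_that("expressed-factor intersection filters, counts and warns", {
  tab <- data.frame(variant = c("v1", "v2", "v3"),
                    factor = c("SMAD4", "AHR", "NOT_EXPR"),
                    stringsAsFactors = FALSE)
  out <- intersect_expressed(tab, c("SMAD4", "AHR", "AHR"))
  expect_equal(nrow(out), 2L)
  expect_false("NOT_EXPR" %in% out$factor)
  expect_equal(unname(attr(out, "factor_counts")[["SMAD4"]]), 1L)
  expect_warning(empty <- intersect_expressed(tab, character(0)), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("the PWM scanner is allele-aware and strand-symmetric", {
  genome <- toy_genome()
  base <- as.character(Biostrings::subseq(genome[[1]], 500, 500))
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  v <- data.frame(id = "rsP", chrom = "1", pos = 500L, ref = base, alt = alt,
                  stringsAsFactors = FALSE)
  fl <- extract_flanks(v, genome)
  # a probability-1 motif equal to the reference centre 7-mer
  kmer <- strsplit(substr(fl$ref_seq, 23, 29), "")[[1]]
  pwm <- matrix(0, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(match(kmer, rownames(pwm)), 1:7)] <- 1
  hits <- pwm_scan(fl, pwm, score_min = 7)
  expect_true("ref" %in% hits$allele)
  expect_false("alt" %in% hits$allele)  # centre mismatch kills the motif
  # a uniform PWM scores zero everywhere
  unif <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(nrow(pwm_scan(fl, unif, score_min = 0.5)), 0L)
  expect_gt(nrow(pwm_scan(fl, unif, score_min = 0)), 0L)
  expect_true(all(pwm_scan(fl, unif, score_min = 0)$score == 0))
  # scanning with the reverse-complement motif finds the same alleles
  rc <- pwm[c("T", "G", "C", "A"), 7:1]
  rownames(rc) <- c("A", "C", "G", "T")
  hits_rc <- pwm_scan(fl, rc, score_min = 7)
  expect_setequal(unique(hits_rc$allele), unique(hits$allele))
  expect_setequal(hits_rc$strand, setdiff(c("+", "-"), hits$strand))
  # malformed PWM columns are rejected
  bad <- pwm; bad[1, 1] <- 0.5
  expect_error(pwm_scan(fl, bad), "sum to 1")
})

test_that("flank pairs feed an end-to-end differential screen", {
  cfg <- sim_config(n_blocks = 2, rng_seed = 37)
  sim <- simulate_population(cfg, with_genome = TRUE)
  causal <- sim$geno$variants[
    sim$geno$variants$id %in% sim$truth$blocks$causal, ]
  fl <- extract_flanks(causal, sim$genome)
  # motif built on the first causal variant's alternative-allele centre
  seqs <- strsplit(fl$alt_seq[1], "")[[1]]
  kmer <- seqs[(fl$center[1] - 3):(fl$center[1] + 3)]
  pwm <- matrix(0, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(match(kmer, rownames(pwm)), 1:7)] <- 1
  hits <- pwm_scan(fl, pwm, score_min = 7, factor_id = "TF_SYN")
  d <- differential_hits(hits[hits$allele == "ref", ],
                         hits[hits$allele == "alt", ])
  expect_true(any(d$variant == fl$variant[1] & d$allele == "alt"))
})
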