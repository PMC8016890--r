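# Small builders and independent brute-force oracles shared by the tests.

toy_geno <- function(hap_a, hap_b, chrom = NULL, pos = NULL, ids = NULL,
                     ref = NULL, alt = NULL, phased = NULL) {
  hap_a <- as.matrix(hap_a); hap_b <- as.matrix(hap_b)
  n <- nrow(hap_a); m <- ncol(hap_a)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  phased_genotype_matrix(
    paste0("s", seq_len(n)),
    data.frame(id = ids, chrom = chrom, pos = as.integer(pos),
               ref = ref, alt = alt, stringsAsFactors = FALSE),
    hap_a, hap_b, phased = phased)
}

# Genotype-code shorthand: build haplotypes from 0/1/2 codes (hets as 0|1).
geno_from_codes <- function(codes, ...) {
  codes <- as.matrix(codes)
  ha <- ifelse(is.na(codes), NA_integer_, as.integer(codes >= 2))
  hb <- ifelse(is.na(codes), NA_integer_, as.integer(codes >= 1))
  toy_geno(ha, hb, ...)
}

# Two-sided exact binomial p under 0.5 by explicit enumeration of both tails.
binom_two_sided_oracle <- function(a, b) {
  n <- a + b
  m <- min(a, b)
  if (2 * m >= n) return(1)
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[seq_len(m + 1)]) + sum(probs[seq(n - m + 1, n + 1)])
}

# BH step-up by sort / step-up / cumulative-minimum.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# One-sided (x greater) Mann-Whitney p by full enumeration of group
# assignments; tie-free inputs only.
wilcox_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(u_all >= u_obs)
}

# D' by direct haplotype tabulation and first-principles frequencies.
dprime_oracle <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (length(unique(a)) < 2 || length(unique(b)) < 2) return(NA_real_)
  pAB <- 0
  for (i in seq_len(n)) if (a[i] == 0 && b[i] == 0) pAB <- pAB + 1 / n
  pA <- mean(a == 0); pB <- mean(b == 0)
  D <- pAB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
    else min(pA * pB, (1 - pA) * (1 - pB))
  if (D == 0) 0 else min(abs(D) / dmax, 1)
}

random_hap_pair <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    a <- sample(0:1, n, replace = TRUE)
    b <- if (runif(1) < 0.5) ifelse(runif(n) < 0.7, a, sample(0:1, n, TRUE))
      else sample(0:1, n, replace = TRUE)
    if (length(unique(a)) == 2 && length(unique(b)) == 2)
      return(list(a = a, b = b))
  }
}
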