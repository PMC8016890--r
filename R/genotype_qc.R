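#' Minor allele frequency
#'
#' MAF per variant from non-missing allele copies: `min(p, 1 - p)` where
#' `p` is the alternative-allele frequency. Variants with no non-missing
#' genotype get `NA`.
#'
#' @param pgm A [phased_genotype_matrix()].
#' @param variant Optional single variant id; default computes all.
#' @return Named numeric vector of MAFs in `[0, 0.5]` (or one value).
#' @export
compute_maf <- function(pgm, variant = NULL) {
  stopifnot(inherits(pgm, "phased_geno"))
  g <- genotype_codes(pgm)
  if (!is.null(variant)) g <- g[, variant_index(pgm, variant), drop = FALSE]
  alt <- colSums(g, na.rm = TRUE)
  copies <- 2L * colSums(!is.na(g))
  p <- ifelse(copies > 0, alt / copies, NA_real_)
  maf <- pmin(p, 1 - p)
  names(maf) <- colnames(g)
  if (!is.null(variant) && length(variant) == 1L) unname(maf) else maf
}

#' Genotype call rates
#'
#' @param pgm A [phased_genotype_matrix()].
#' @return List with numeric vectors `variant` and `sample` of call rates
#'   in `[0, 1]`.
#' @export
call_rates <- function(pgm) {
  stopifnot(inherits(pgm, "phased_geno"))
  g <- !is.na(genotype_codes(pgm))
  list(variant = colMeans(g), sample = rowMeans(g))
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness of fit of observed genotype
#' counts against the expected `p^2 : 2pq : q^2` proportions (no continuity
#' correction), the usual array-QC default. An exact test (full enumeration
#' of heterozygote counts conditional on the allele counts) is available
#' via `method = "exact"`. Monomorphic variants return `p = 1` by
#' convention.
#'
#' @param n_aa,n_ab,n_bb Counts of hom-ref, het and hom-alt genotypes.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return The HWE p-value.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("need at least one genotype")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  if (method == "chisq") {
    p <- n_a / (2 * n)
    exp_counts <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((c(n_aa, n_ab, n_bb) - exp_counts)^2 / exp_counts)
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    hwe_exact_p(n_aa, n_ab, n_bb)
  }
}

# Exact HWE p: sum of probabilities of heterozygote counts (with the
# observed allele counts fixed) no more likely than the observed one.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  nr <- min(n_a, 2 * n - n_a); nc <- max(n_a, 2 * n - n_a)
  logp <- vapply(hets, function(h) {
    hom_r <- (nr - h) / 2; hom_c <- (nc - h) / 2
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(nr + 1) + lgamma(nc + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Apply marker and sample quality-control filters
#'
#' Replicates array-era QC with strict thresholds exactly as printed:
#' samples with call rate lower than `call_rate_min` are removed first;
#' then variants with call rate lower than `call_rate_min`, MAF lower than
#' `maf_min`, or HWE p-value less than or equal to `hwe_alpha` (computed on
#' the surviving samples) are removed. Variants with no non-missing
#' genotype fail with reason `all_missing`.
#'
#' @param pgm A [phased_genotype_matrix()].
#' @param maf_min,call_rate_min,hwe_alpha Thresholds (defaults 0.05, 0.95,
#'   1e-4).
#' @param hwe_method Passed to [hwe_test()].
#' @return List with `matrix` (the filtered `phased_geno`) and `report`, a
#'   list of data frames `samples` (id, call_rate, pass) and `variants`
#'   (id, maf, call_rate, hwe_p, pass, reason).
#' @export
apply_filters <- function(pgm, maf_min = 0.05, call_rate_min = 0.95,
                          hwe_alpha = 1e-4, hwe_method = "chisq") {
  stopifnot(inherits(pgm, "phased_geno"))
  cr <- call_rates(pgm)
  sample_pass <- !(cr$sample < call_rate_min)
  samples_report <- data.frame(id = pgm$samples, call_rate = cr$sample,
                               pass = sample_pass, stringsAsFactors = FALSE)
  if (!any(sample_pass)) stop("no samples survive the call-rate filter")
  kept <- subset_geno(pgm, samples = pgm$samples[sample_pass])

  g <- genotype_codes(kept)
  maf <- compute_maf(kept)
  vcr <- call_rates(kept)$variant
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    gj <- gj[!is.na(gj)]
    if (length(gj) == 0) return(NA_real_)
    hwe_test(sum(gj == 0L), sum(gj == 1L), sum(gj == 2L),
             method = hwe_method)
  }, numeric(1))

  reason <- character(ncol(g))
  add_reason <- function(reason, fail, code)
    ifelse(fail, ifelse(nzchar(reason), paste(reason, code, sep = ","), code),
           reason)
  all_missing <- is.na(maf)
  reason <- add_reason(reason, all_missing, "all_missing")
  reason <- add_reason(reason, !all_missing & vcr < call_rate_min, "call_rate")
  reason <- add_reason(reason, !all_missing & maf < maf_min, "maf")
  reason <- add_reason(reason, !all_missing & !is.na(hwe_p) &
                         hwe_p <= hwe_alpha, "hwe")
  pass <- !nzchar(reason)
  variants_report <- data.frame(id = kept$variants$id, maf = maf,
                                call_rate = vcr, hwe_p = hwe_p,
                                pass = pass, reason = reason,
                                stringsAsFactors = FALSE, row.names = NULL)
  if (!any(pass)) stop("no variants survive the filters")
  list(matrix = subset_geno(kept, variants = kept$variants$id[pass]),
       report = list(samples = samples_report, variants = variants_report))
}
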