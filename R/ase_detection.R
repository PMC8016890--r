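#' Two-sided exact binomial test of allelic imbalance
#'
#' Tests whether the reference/alternative read counts of one heterozygous
#' animal at one transcribed SNP deviate from the balanced expectation
#' (success probability 0.5). The p-value is the two-sided exact tail sum
#' `min(1, 2 * P(X <= min(ref, alt)))` with `X ~ Binomial(ref + alt, 0.5)`;
#' under the symmetric null this equals the usual minimum-likelihood
#' two-sided p.
#'
#' @param ref_count,alt_count Non-negative read counts (vectorised).
#' @return P-values in `(0, 1]`.
#' @export
binomial_ase_test <- function(ref_count, alt_count) {
  stopifnot(all(ref_count >= 0), all(alt_count >= 0),
            all(ref_count + alt_count >= 1))
  n <- ref_count + alt_count
  pmin(1, 2 * stats::pbinom(pmin(ref_count, alt_count), n, 0.5))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with enforced monotonicity,
#' order-preserving with respect to the input. Also used to threshold
#' externally produced transcription-factor over-representation tables.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run per-animal binomial ASE tests over a count table
#'
#' Each (sample, variant) record is tested when the sample is heterozygous
#' at the variant and the read depth reaches `min_depth`; other records are
#' recorded untested with a reason. FDR adjustment is applied globally
#' across all performed tests (the default), or within each variant with
#' `fdr_scope = "per_variant"`.
#'
#' @param counts Data frame from [read_counts_table()].
#' @param pgm A [phased_genotype_matrix()] covering the count variants.
#' @param min_depth Minimum reads per test (default 10).
#' @param alpha FDR level used for the `significant` flag (default 0.05).
#' @param fdr_scope `"global"` or `"per_variant"`.
#' @return Data frame with columns `sample`, `variant`, `ref_count`,
#'   `alt_count`, `tested`, `reason`, `p_value`, `q_value`, `significant`.
#' @export
run_ase_tests <- function(counts, pgm, min_depth = 10, alpha = 0.05,
                          fdr_scope = c("global", "per_variant")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(pgm, "phased_geno"))
  g <- genotype_codes(pgm)
  si <- match(counts$sample, pgm$samples)
  vi <- match(counts$variant, pgm$variants$id)
  if (anyNA(si)) stop("counts refer to unknown sample(s)")
  if (anyNA(vi)) stop("counts refer to unknown variant(s)")
  geno <- g[cbind(si, vi)]
  depth <- counts$ref_count + counts$alt_count
  out <- counts[, c("sample", "variant", "ref_count", "alt_count")]
  out$tested <- !is.na(geno) & geno == 1L & depth >= min_depth
  out$reason <- ifelse(out$tested, "",
                       ifelse(is.na(geno) | geno != 1L, "not_het",
                              "low_depth"))
  out$p_value <- NA_real_
  out$p_value[out$tested] <- binomial_ase_test(out$ref_count[out$tested],
                                               out$alt_count[out$tested])
  out$q_value <- NA_real_
  if (any(out$tested)) {
    if (fdr_scope == "global") {
      out$q_value[out$tested] <- bh_fdr(out$p_value[out$tested])
    } else {
      for (v in unique(out$variant[out$tested])) {
        idx <- out$tested & out$variant == v
        out$q_value[idx] <- bh_fdr(out$p_value[idx])
      }
    }
  }
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  out
}

#' Aggregate per-animal ASE tests into SNP-level ASE calls
#'
#' A variant is declared an ASE SNP when at least
#' `min_significant_samples` of its tested heterozygous animals are
#' FDR-significant. Variants never tested (all animals homozygous or
#' under-covered) are absent from the calls and listed in the
#' `untestable` attribute.
#'
#' @param results Output of [run_ase_tests()].
#' @param alpha FDR level (default 0.05; applied to the stored q-values).
#' @param min_significant_samples Aggregation threshold (default 1).
#' @return Data frame with `variant`, `n_tested`, `n_significant`,
#'   `is_ase`; attribute `untestable` holds the untested variant ids.
#' @export
call_ase_snps <- function(results, alpha = 0.05, min_significant_samples = 1) {
  tested <- results[results$tested, , drop = FALSE]
  untestable <- setdiff(unique(results$variant), unique(tested$variant))
  if (nrow(tested) == 0) {
    out <- data.frame(variant = character(), n_tested = integer(),
                      n_significant = integer(), is_ase = logical())
    attr(out, "untestable") <- untestable
    return(out)
  }
  sig <- !is.na(tested$q_value) & tested$q_value < alpha
  agg <- stats::aggregate(
    cbind(n_tested = rep(1L, nrow(tested)), n_significant = as.integer(sig)),
    by = list(variant = tested$variant), FUN = sum)
  agg$is_ase <- agg$n_significant >= min_significant_samples
  attr(agg, "untestable") <- untestable
  agg
}
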