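#' Allelic imbalance ratio
#'
#' Folded deviation of the reference-allele read fraction from one half:
#' `|ref / (ref + alt) - 0.5|`. 0 means balanced expression of the two
#' alleles; 0.5 means monoallelic expression (e.g. an animal expressing
#' only the alternative allele has ratio 0.5).
#'
#' @param ref_count,alt_count Non-negative read counts (vectorised).
#' @return Values in `[0, 0.5]`; `NA` where the depth is zero.
#' @export
imbalance_ratio <- function(ref_count, alt_count) {
  depth <- ref_count + alt_count
  # |ref/depth - 0.5| written with an integer numerator so the value is
  # bit-identical under ref/alt exchange
  ifelse(depth > 0, abs(ref_count - alt_count) / (2 * depth), NA_real_)
}

#' Per-sample imbalance profile of ASE markers
#'
#' Computes, for each ASE marker SNP, the imbalance ratio of every
#' heterozygous sample with sufficient read depth. Samples homozygous at
#' the marker or below `min_depth` are excluded (their imbalance is not
#' measurable / not reliable).
#'
#' @param counts Allele count data frame.
#' @param pgm A [phased_genotype_matrix()].
#' @param ase_ids Variant ids of the ASE markers.
#' @param min_depth Minimum reads (default 10).
#' @return Data frame `variant`, `sample`, `ref_count`, `alt_count`,
#'   `ref_fraction`, `imbalance`.
#' @export
imbalance_profile <- function(counts, pgm, ase_ids, min_depth = 10) {
  stopifnot(inherits(pgm, "phased_geno"))
  keep <- counts$variant %in% ase_ids
  df <- counts[keep, , drop = FALSE]
  g <- genotype_codes(pgm)
  geno <- g[cbind(match(df$sample, pgm$samples),
                  match(df$variant, pgm$variants$id))]
  depth <- df$ref_count + df$alt_count
  df <- df[!is.na(geno) & geno == 1L & depth >= min_depth, , drop = FALSE]
  data.frame(variant = df$variant, sample = df$sample,
             ref_count = df$ref_count, alt_count = df$alt_count,
             ref_fraction = df$ref_count / (df$ref_count + df$alt_count),
             imbalance = imbalance_ratio(df$ref_count, df$alt_count),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Candidate windows around ASE markers
#'
#' For each ASE marker, all other variants on the same chromosome within
#' `half_width` bp (closed bound: a candidate at exactly `half_width` is
#' included). The marker itself is excluded from its own window, but an
#' ASE marker may appear as a candidate in a neighbouring marker's window,
#' and one variant may be a candidate for several markers.
#'
#' @param ase_ids Variant ids of the ASE markers.
#' @param variants Variant data frame (`id`, `chrom`, `pos`).
#' @param half_width Window half-width in bp (default 1 Mb).
#' @return Data frame `ase_variant`, `candidate_variant`, `distance_bp`.
#' @export
build_windows <- function(ase_ids, variants, half_width = 1e6) {
  out <- lapply(ase_ids, function(a) {
    i <- match(a, variants$id)
    if (is.na(i)) stop("unknown ASE variant id: ", a)
    same <- variants$chrom == variants$chrom[i]
    d <- abs(variants$pos - variants$pos[i])
    keep <- same & d <= half_width & variants$id != a
    if (!any(keep)) return(NULL)
    data.frame(ase_variant = a, candidate_variant = variants$id[keep],
               distance_bp = d[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(ase_variant = character(),
                      candidate_variant = character(),
                      distance_bp = integer())
  out
}

#' Split imbalance values by candidate genotype class
#'
#' Only samples heterozygous at the ASE marker (with measurable imbalance)
#' enter either group; they are split by their genotype at the candidate
#' into heterozygotes and the larger homozygous class (ties broken in
#' favour of hom-ref). The test is skipped — a recorded outcome, not an
#' error — when fewer than `min_het` heterozygotes are available at the
#' candidate or at the ASE marker, or when the larger homozygous group is
#' smaller than `min_hom`.
#'
#' @param candidate,ase_snp Variant ids.
#' @param pgm A [phased_genotype_matrix()].
#' @param profile Output of [imbalance_profile()].
#' @param min_het Minimum heterozygotes for both the candidate and the ASE
#'   marker (default 10).
#' @param min_hom Minimum size of the homozygous comparison group
#'   (default 3).
#' @return List with `het_values`, `hom_values`, `hom_group` ("0/0" or
#'   "1/1"), `n_het`, `n_hom`; or, when skipped, a list with `skip` set to
#'   the reason (`"min_het_candidate"`, `"min_het_ase"`, `"min_hom"`).
#' @export
group_samples <- function(candidate, ase_snp, pgm, profile,
                          min_het = 10, min_hom = 3) {
  prof <- profile[profile$variant == ase_snp, , drop = FALSE]
  if (nrow(prof) < min_het) return(list(skip = "min_het_ase"))
  g <- genotype_codes(pgm)
  cg <- g[match(prof$sample, pgm$samples), variant_index(pgm, candidate)]
  het <- !is.na(cg) & cg == 1L
  hom0 <- !is.na(cg) & cg == 0L
  hom2 <- !is.na(cg) & cg == 2L
  if (sum(het) < min_het) return(list(skip = "min_het_candidate"))
  hom_group <- if (sum(hom0) >= sum(hom2)) "0/0" else "1/1"
  hom <- if (hom_group == "0/0") hom0 else hom2
  if (sum(hom) < min_hom) return(list(skip = "min_hom"))
  list(het_values = prof$imbalance[het], hom_values = prof$imbalance[hom],
       hom_group = hom_group, n_het = sum(het), n_hom = sum(hom))
}

#' One-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney test of whether `het_values` are stochastically greater
#' than `hom_values`. The exact null distribution is used when
#' `n1 * n2 <= 400` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. When every
#' value in both groups is identical the test is degenerate and returns
#' `p = 1` with a flag.
#'
#' @param het_values,hom_values Non-empty numeric vectors.
#' @param alternative Passed to [stats::wilcox.test()] (default
#'   `"greater"`).
#' @return List with `statistic` (the Mann-Whitney U of the first group),
#'   `p_value`, `exact` (logical), `degenerate` (logical).
#' @export
wilcoxon_rank_sum <- function(het_values, hom_values,
                              alternative = "greater") {
  stopifnot(length(het_values) > 0, length(hom_values) > 0)
  all_values <- c(het_values, hom_values)
  if (length(unique(all_values)) == 1L) {
    u <- length(het_values) * length(hom_values) / 2
    return(list(statistic = u, p_value = 1, exact = FALSE,
                degenerate = TRUE))
  }
  ties <- anyDuplicated(all_values) > 0
  use_exact <- !ties &&
    length(het_values) * length(hom_values) <= 400
  wt <- suppressWarnings(stats::wilcox.test(
    het_values, hom_values, alternative = alternative,
    exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact, degenerate = FALSE)
}

#' Scan candidate windows for aseQTLs
#'
#' The core procedure: for every ASE marker with measurable imbalance and
#' every candidate SNP within the window, the imbalance ratios of samples
#' heterozygous at the marker are compared between candidate heterozygotes
#' and the larger candidate homozygous class with a one-sided Wilcoxon
#' rank-sum test (het imbalance greater). Significance is declared at raw
#' `p <= alpha` — deliberately without multiple-testing correction, the
#' restrictive heterozygote requirement standing in for it — but a BH
#' column is emitted for users who want one.
#'
#' @param pgm A [phased_genotype_matrix()].
#' @param counts Allele count data frame.
#' @param ase_ids ASE marker variant ids.
#' @param window_bp Window half-width (default 1 Mb).
#' @param min_het,min_hom,min_depth See [group_samples()] /
#'   [imbalance_profile()].
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param gene_map Optional named vector mapping ASE marker id to gene id
#'   for TSS distances.
#' @param gene_models Optional gene models (see [read_gene_models()]).
#' @return Data frame with one row per performed test: `ase_variant`,
#'   `candidate_variant`, `chrom`, `n_het`, `hom_group`, `n_hom`,
#'   `statistic`, `p_value`, `q_value`, `cand_ref_freq`, `distance_bp`,
#'   `distance_to_tss`, `significant`. Attribute `skips` records the
#'   skipped pairs and reasons.
#' @export
scan_aseqtl <- function(pgm, counts, ase_ids, window_bp = 1e6,
                        min_het = 10, min_hom = 3, min_depth = 10,
                        alpha = 0.05, gene_map = NULL, gene_models = NULL) {
  stopifnot(inherits(pgm, "phased_geno"))
  profile <- imbalance_profile(counts, pgm, ase_ids, min_depth = min_depth)
  windows <- build_windows(intersect(ase_ids, unique(profile$variant)),
                           pgm$variants, half_width = window_bp)
  ref_freq <- 1 - colSums(genotype_codes(pgm), na.rm = TRUE) /
    (2 * colSums(!is.na(genotype_codes(pgm))))
  rows <- vector("list", nrow(windows))
  skips <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    a <- windows$ase_variant[i]; cand <- windows$candidate_variant[i]
    grp <- group_samples(cand, a, pgm, profile,
                         min_het = min_het, min_hom = min_hom)
    if (!is.null(grp$skip)) {
      skips[[i]] <- data.frame(ase_variant = a, candidate_variant = cand,
                               reason = grp$skip, stringsAsFactors = FALSE)
      next
    }
    wt <- wilcoxon_rank_sum(grp$het_values, grp$hom_values)
    rows[[i]] <- data.frame(
      ase_variant = a, candidate_variant = cand,
      chrom = pgm$variants$chrom[variant_index(pgm, cand)],
      n_het = grp$n_het, hom_group = grp$hom_group, n_hom = grp$n_hom,
      statistic = wt$statistic, p_value = wt$p_value,
      cand_ref_freq = unname(ref_freq[cand]),
      distance_bp = windows$distance_bp[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ase_variant = character(), candidate_variant = character(),
                      chrom = character(), n_het = integer(),
                      hom_group = character(), n_hom = integer(),
                      statistic = numeric(), p_value = numeric(),
                      cand_ref_freq = numeric(), distance_bp = integer())
  }
  out$q_value <- if (nrow(out)) bh_fdr(out$p_value) else numeric(0)
  out$distance_to_tss <- rep(NA_real_, nrow(out))
  if (!is.null(gene_map) && !is.null(gene_models) && nrow(out)) {
    gid <- gene_map[out$ase_variant]
    pos <- pgm$variants$pos[variant_index(pgm, out$candidate_variant)]
    out$distance_to_tss <- vapply(seq_len(nrow(out)), function(i) {
      if (is.na(gid[i])) return(NA_real_)
      distance_to_tss(pos[i], gid[i], gene_models)
    }, numeric(1))
  }
  out$significant <- out$p_value <= alpha
  attr(out, "skips") <- do.call(rbind, skips)
  out
}

#' Summarise an aseQTL scan
#'
#' Headline numbers of a scan: tested and significant pair counts, the
#' number of distinct markers with at least one aseQTL, aseQTLs per marker,
#' the mean reference-allele frequency of significant candidates, and mean
#' distances to the marker and (when annotated) to the TSS.
#'
#' @param scan Output of [scan_aseqtl()].
#' @return List of summary statistics.
#' @export
summarize_scan <- function(scan) {
  sig <- scan[scan$significant, , drop = FALSE]
  per_marker <- if (nrow(sig)) table(sig$ase_variant) else integer(0)
  list(n_tests = nrow(scan),
       n_significant = nrow(sig),
       n_ase_with_aseqtl = length(per_marker),
       mean_aseqtls_per_marker = if (length(per_marker))
         mean(per_marker) else NA_real_,
       mean_ref_allele_freq = if (nrow(sig))
         mean(sig$cand_ref_freq) else NA_real_,
       mean_distance_bp = if (nrow(sig))
         mean(sig$distance_bp) else NA_real_,
       mean_distance_to_tss = if (nrow(sig) && !all(is.na(sig$distance_to_tss)))
         mean(sig$distance_to_tss, na.rm = TRUE) else NA_real_)
}
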