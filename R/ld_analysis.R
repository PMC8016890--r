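#' D' from haplotype class counts
#'
#' Computes the linkage-disequilibrium coefficient `D = p_AB - p_A * p_B`
#' and its normalisation `D' = |D| / D_max`, where `D_max` is
#' `min(p_A * p_b, p_a * p_B)` when `D > 0` and
#' `min(p_A * p_B, p_a * p_b)` otherwise. `D' = 1` whenever at most three
#' of the four haplotype classes are observed; it is undefined (`NA`) when
#' either locus is monomorphic.
#'
#' @param counts Numeric vector of the four haplotype counts
#'   `(n_AB, n_Ab, n_aB, n_ab)`, where `A`/`a` are the reference /
#'   alternative alleles at the first locus and `B`/`b` at the second.
#' @return List with `n` (the counts), `D`, `d_prime`, `r2`.
#' @export
d_prime_counts <- function(counts) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) return(list(n = counts, D = NA_real_, d_prime = NA_real_,
                          r2 = NA_real_))
  f <- counts / n
  p_a1 <- f[1] + f[2]   # allele A at locus 1
  p_b1 <- f[1] + f[3]   # allele B at locus 2
  if (p_a1 %in% c(0, 1) || p_b1 %in% c(0, 1))
    return(list(n = counts, D = NA_real_, d_prime = NA_real_, r2 = NA_real_))
  D <- f[1] - p_a1 * p_b1
  d_max <- if (D > 0) min(p_a1 * (1 - p_b1), (1 - p_a1) * p_b1)
    else min(p_a1 * p_b1, (1 - p_a1) * (1 - p_b1))
  dp <- if (D == 0) 0 else abs(D) / d_max
  r2 <- D^2 / (p_a1 * (1 - p_a1) * p_b1 * (1 - p_b1))
  list(n = counts, D = unname(D), d_prime = unname(min(dp, 1)),
       r2 = unname(r2))
}

#' Pairwise D' between two variants of a phased matrix
#'
#' Tabulates the 2n haplotypes over the two loci (haplotypes with a
#' missing or unphased allele at either locus are dropped pairwise) and
#' applies [d_prime_counts()].
#'
#' @param pgm A [phased_genotype_matrix()].
#' @param id_a,id_b Variant ids.
#' @return One-row data frame: `variant_a`, `variant_b`, `n_AB`, `n_Ab`,
#'   `n_aB`, `n_ab`, `D`, `d_prime`, `r2`.
#' @export
d_prime <- function(pgm, id_a, id_b) {
  stopifnot(inherits(pgm, "phased_geno"))
  ia <- variant_index(pgm, id_a); ib <- variant_index(pgm, id_b)
  ok <- pgm$phased[, ia] & pgm$phased[, ib]
  a <- c(pgm$hap_a[ok, ia], pgm$hap_b[ok, ia])
  b <- c(pgm$hap_a[ok, ib], pgm$hap_b[ok, ib])
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  counts <- c(sum(a == 0 & b == 0), sum(a == 0 & b == 1),
              sum(a == 1 & b == 0), sum(a == 1 & b == 1))
  res <- d_prime_counts(counts)
  data.frame(variant_a = id_a, variant_b = id_b,
             n_AB = counts[1], n_Ab = counts[2],
             n_aB = counts[3], n_ab = counts[4],
             D = res$D, d_prime = res$d_prime, r2 = res$r2,
             stringsAsFactors = FALSE)
}

#' Pairwise LD over one of the study's three pairing schemes
#'
#' Mirrors the three comparisons the aseQTL analysis makes: (1) each
#' aseQTL against its own ASE marker (`mode = "aseqtl_vs_ase"`, driven by
#' a `pairs` data frame), (2) all aseQTLs against each other
#' (`"among_aseqtls"`), and (3) all ASE markers against each other
#' (`"among_ase"`); the last two take a variant id vector and form all
#' within-chromosome pairs. Counts of pairs with `D' > 0.8` and `D' = 1`
#' are attached as a `summary` attribute.
#'
#' @param pgm A [phased_genotype_matrix()].
#' @param mode One of `"aseqtl_vs_ase"`, `"among_aseqtls"`, `"among_ase"`.
#' @param variants Variant ids (modes 2 and 3).
#' @param pairs Data frame with columns `ase_variant` and
#'   `candidate_variant` (mode 1).
#' @return Data frame of [d_prime()] rows, with attribute `summary`.
#' @export
pairwise_ld <- function(pgm, mode = c("among_aseqtls", "among_ase",
                                      "aseqtl_vs_ase"),
                        variants = NULL, pairs = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pgm, "phased_geno"))
  chrom_of <- function(id) pgm$variants$chrom[variant_index(pgm, id)]
  if (mode == "aseqtl_vs_ase") {
    if (is.null(pairs)) stop("mode 'aseqtl_vs_ase' needs a pairs data frame")
    pr <- data.frame(a = pairs$candidate_variant, b = pairs$ase_variant,
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(variants)) stop("this mode needs a variant id vector")
    ids <- unique(variants)
    pr <- NULL
    for (ch in unique(chrom_of(ids))) {
      v <- ids[chrom_of(ids) == ch]
      if (length(v) < 2) next
      cmb <- utils::combn(v, 2)
      pr <- rbind(pr, data.frame(a = cmb[1, ], b = cmb[2, ],
                                 stringsAsFactors = FALSE))
    }
    if (is.null(pr)) pr <- data.frame(a = character(), b = character())
  }
  same <- nrow(pr) > 0 & chrom_of(pr$a) == chrom_of(pr$b)
  pr <- pr[same & pr$a != pr$b, , drop = FALSE]
  pr <- unique(pr)
  out <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i)
    d_prime(pgm, pr$a[i], pr$b[i])))
  if (is.null(out))
    out <- data.frame(variant_a = character(), variant_b = character(),
                      n_AB = integer(), n_Ab = integer(), n_aB = integer(),
                      n_ab = integer(), D = numeric(), d_prime = numeric(),
                      r2 = numeric())
  dp <- out$d_prime
  attr(out, "summary") <- list(
    mode = mode, n_pairs = nrow(out),
    n_high_ld = sum(!is.na(dp) & dp > 0.8),
    n_complete_ld = sum(!is.na(dp) & dp >= 1 - 1e-9))
  out
}

#' Greedy D'-threshold LD blocks
#'
#' Transparent stand-in for confidence-interval block callers: walk the
#' variants in genomic order and grow a block while every pairwise D'
#' within it is at least `threshold`; maximal runs of two or more variants
#' are emitted. Pairs absent from `ld_pairs` (or with undefined D') are
#' treated as below threshold. This is deliberately not the Gabriel
#' confidence-interval method used by Haploview.
#'
#' @param ld_pairs Data frame with `variant_a`, `variant_b`, `d_prime`
#'   (e.g. from [pairwise_ld()]).
#' @param variants Variant data frame (`id`, `chrom`, `pos`) fixing
#'   genomic order; only ids appearing in `ld_pairs` are considered.
#' @param threshold Minimum pairwise D' (default 0.8).
#' @return List of blocks; each a list with `variants` (ordered member
#'   ids), `chrom` and `min_d_prime`.
#' @export
find_blocks <- function(ld_pairs, variants, threshold = 0.8) {
  ids <- unique(c(ld_pairs$variant_a, ld_pairs$variant_b))
  v <- variants[variants$id %in% ids, , drop = FALSE]
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  dp <- stats::setNames(ld_pairs$d_prime,
                        key(ld_pairs$variant_a, ld_pairs$variant_b))
  lookup <- function(a, b) {
    x <- dp[key(a, b)]
    if (is.na(x)) -Inf else x
  }
  blocks <- list()
  cur <- character(0); cur_chrom <- NA_character_
  flush <- function() {
    if (length(cur) >= 2) {
      mins <- min(vapply(utils::combn(cur, 2, simplify = FALSE),
                         function(p) lookup(p[1], p[2]), numeric(1)))
      blocks[[length(blocks) + 1L]] <<- list(variants = cur,
                                             chrom = cur_chrom,
                                             min_d_prime = mins)
    }
  }
  for (i in seq_len(nrow(v))) {
    id <- v$id[i]; ch <- v$chrom[i]
    ok <- length(cur) > 0 && identical(ch, cur_chrom) &&
      all(vapply(cur, function(m) lookup(m, id) >= threshold, logical(1)))
    if (ok) {
      cur <- c(cur, id)
    } else {
      flush()
      cur <- id; cur_chrom <- ch
    }
  }
  flush()
  blocks
}
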