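#' Phased genotype matrix
#'
#' Container for a samples-by-variants matrix of phased diploid genotypes.
#' Each cell holds an ordered pair of haplotype alleles (0 = reference,
#' 1 = alternative, `NA` = missing) plus a flag saying whether the pair is
#' phased. Genotype-level operations (QC, grouping by genotype class) use
#' the unordered pair; phase-aware operations (D', methylation silencing
#' checks) require the phased flag.
#'
#' @param samples Character vector of sample ids.
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based,
#'   VCF convention), `ref`, `alt`. Biallelic SNVs only.
#' @param hap_a,hap_b Integer matrices (samples x variants) of first/second
#'   haplotype alleles in 0/1/`NA`.
#' @param phased Logical matrix (samples x variants); `TRUE` where the
#'   allele pair order is meaningful.
#' @return An object of class `phased_geno`.
#' @export
phased_genotype_matrix <- function(samples, variants, hap_a, hap_b,
                                   phased = NULL) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (any(variants$pos < 1L)) stop("variant pos must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  dims <- c(length(samples), nrow(variants))
  for (m in list(hap_a, hap_b)) {
    if (!all(dim(m) == dims)) stop("haplotype matrix dimensions do not match")
    if (!all(m %in% c(0L, 1L, NA_integer_))) stop("haplotype alleles must be 0, 1 or NA")
  }
  if (is.null(phased)) phased <- matrix(TRUE, dims[1], dims[2])
  if (!all(dim(phased) == dims)) stop("phased flag dimensions do not match")
  hap_a <- matrix(as.integer(hap_a), dims[1], dims[2])
  hap_b <- matrix(as.integer(hap_b), dims[1], dims[2])
  dimnames(hap_a) <- dimnames(hap_b) <- dimnames(phased) <-
    list(samples, variants$id)
  structure(list(samples = samples, variants = variants,
                 hap_a = hap_a, hap_b = hap_b, phased = phased),
            class = "phased_geno")
}

#' @export
print.phased_geno <- function(x, ...) {
  cat(sprintf("phased_geno: %d samples x %d variants on %d chromosome(s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  cat(sprintf("  phased cells: %.1f%%; missing cells: %.1f%%\n",
              100 * mean(x$phased), 100 * mean(is.na(x$hap_a))))
  invisible(x)
}

#' @export
dim.phased_geno <- function(x) c(length(x$samples), nrow(x$variants))

#' Diploid genotype codes
#'
#' Returns the samples-by-variants matrix of unordered genotype codes:
#' 0 (hom ref), 1 (het), 2 (hom alt), `NA` missing (either allele missing).
#'
#' @param pgm A [phased_genotype_matrix()].
#' @return Integer matrix.
#' @export
genotype_codes <- function(pgm) {
  stopifnot(inherits(pgm, "phased_geno"))
  pgm$hap_a + pgm$hap_b
}

variant_index <- function(pgm, id) {
  i <- match(id, pgm$variants$id)
  if (anyNA(i)) stop("unknown variant id(s): ",
                     paste(id[is.na(i)], collapse = ", "))
  i
}

#' Subset a phased genotype matrix
#'
#' @param pgm A [phased_genotype_matrix()].
#' @param samples,variants Character vectors of ids to keep (default: all).
#' @return A `phased_geno` restricted to the requested ids, order preserved
#'   as given.
#' @export
subset_geno <- function(pgm, samples = NULL, variants = NULL) {
  stopifnot(inherits(pgm, "phased_geno"))
  si <- if (is.null(samples)) seq_along(pgm$samples) else {
    i <- match(samples, pgm$samples)
    if (anyNA(i)) stop("unknown sample id(s)")
    i
  }
  vi <- if (is.null(variants)) seq_len(nrow(pgm$variants)) else
    variant_index(pgm, variants)
  phased_genotype_matrix(pgm$samples[si], pgm$variants[vi, , drop = FALSE],
                         pgm$hap_a[si, vi, drop = FALSE],
                         pgm$hap_b[si, vi, drop = FALSE],
                         pgm$phased[si, vi, drop = FALSE])
}
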