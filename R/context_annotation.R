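#' Distance from a variant to a gene's transcription start site
#'
#' The TSS is the gene start for plus-strand genes and the gene end for
#' minus-strand genes (1-based inclusive gene coordinates); the distance
#' is unsigned.
#'
#' @param pos Variant position (1-based).
#' @param gene_id Gene identifier.
#' @param gene_models Gene models (see [read_gene_models()]).
#' @return Distance in bp, or `NA` when the gene is not annotated.
#' @export
distance_to_tss <- function(pos, gene_id, gene_models) {
  g <- gene_models$genes
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) return(NA_real_)
  tss <- if (g$strand[i] == "-") g$end[i] else g$start[i]
  abs(pos - tss)
}

#' Classify a variant's genomic feature context
#'
#' Minimal transparent re-implementation of consequence classing from gene
#' models, with the priority order `splice_region` > UTRs > `exonic` >
#' `intronic` > `non_coding_transcript` > `intergenic`. A position is
#' `splice_region` when it falls in the `splice_exonic` terminal exonic
#' bases or the first `splice_intronic` intronic bases flanking an
#' internal exon junction (defaults 3 and 8 bp). Exonic variants are not
#' further split into synonymous/missense (no codon model). When several
#' genes overlap the position, the highest-priority class wins.
#'
#' @param chrom,pos Variant coordinates (1-based).
#' @param gene_models Gene models (see [read_gene_models()]).
#' @param splice_exonic,splice_intronic Splice-region window widths in bp.
#' @return One of `"splice_region"`, `"five_prime_UTR"`,
#'   `"three_prime_UTR"`, `"exonic"`, `"intronic"`,
#'   `"non_coding_transcript"`, `"intergenic"`.
#' @export
classify_location <- function(chrom, pos, gene_models,
                              splice_exonic = 3, splice_intronic = 8) {
  g <- gene_models$genes
  f <- gene_models$features
  in_gene <- g$chrom == chrom & g$start <= pos & pos <= g$end
  if (!any(in_gene)) return("intergenic")
  priority <- c(splice_region = 1, five_prime_UTR = 2, three_prime_UTR = 3,
                exonic = 4, intronic = 5, non_coding_transcript = 6)
  best <- "intronic"; best_rank <- Inf
  consider <- function(cls) {
    if (priority[[cls]] < best_rank) {
      best <<- cls; best_rank <<- priority[[cls]]
    }
  }
  for (i in which(in_gene)) {
    gid <- g$gene_id[i]
    if (!g$coding[i]) { consider("non_coding_transcript"); next }
    ex <- f[f$gene_id == gid & f$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) == 0) { consider("intronic"); next }
    # internal junctions: exon edges other than the gene's outermost two
    ends_int <- ex$end[ex$end != max(ex$end)]        # intron starts at e + 1
    starts_int <- ex$start[ex$start != min(ex$start)] # intron ends at s - 1
    in_exon <- any(ex$start <= pos & pos <= ex$end)
    splice <-
      any(pos >= ends_int - (splice_exonic - 1) & pos <= ends_int) ||
      any(pos >= ends_int + 1 & pos <= ends_int + splice_intronic) ||
      any(pos >= starts_int & pos <= starts_int + (splice_exonic - 1)) ||
      any(pos >= starts_int - splice_intronic & pos <= starts_int - 1)
    if (in_exon) {
      if (splice) { consider("splice_region"); next }
      utr <- f[f$gene_id == gid & f$type %in%
                 c("five_prime_UTR", "three_prime_UTR") &
                 f$start <= pos & pos <= f$end, , drop = FALSE]
      if (nrow(utr) > 0) { consider(utr$type[1]); next }
      consider("exonic")
    } else {
      if (splice) { consider("splice_region"); next }
      consider("intronic")
    }
  }
  best
}

#' Percent methylation of one record
#'
#' `100 * methylated / (methylated + unmethylated)`.
#'
#' @param methylated_count,unmethylated_count Read counts (vectorised).
#' @return Percentages in `[0, 100]`.
#' @export
methylation_percent <- function(methylated_count, unmethylated_count) {
  total <- methylated_count + unmethylated_count
  if (any(total < 1)) stop("methylation record with zero covering reads")
  100 * methylated_count / total
}

#' Phase-aware methylation / ASE consistency check
#'
#' For each animal with a methylation record at the aseQTL position, the
#' check asks whether the observed expressed-allele fractions at the ASE
#' marker are consistent with silencing of the haplotype that carries the
#' putatively methylated aseQTL allele. The methylated allele is assigned
#' from base context: when exactly one of the aseQTL's two alleles is a
#' cytosine (C, or G for the opposite strand), the methylation is
#' attributed to that allele; otherwise the animal is reported
#' per-haplotype-ambiguous (uninformative). The report is descriptive —
#' `consistent`, `inconsistent` or `uninformative` per animal — with no
#' p-value.
#'
#' Animals are uninformative when homozygous or unphased at either SNP,
#' uncovered by read counts, or below the `meth_min` percent-methylation
#' floor. An animal is `consistent` when the ASE-marker allele in phase
#' with the methylated aseQTL allele has an expressed fraction below 0.5
#' by more than `balance_margin`; `inconsistent` when expression is
#' balanced (within the margin) or imbalanced the other way.
#'
#' @param pgm A [phased_genotype_matrix()] (phased).
#' @param counts Allele count data frame for the ASE marker.
#' @param aseqtl_id,ase_id Variant ids of the candidate aseQTL and its
#'   ASE marker.
#' @param methylation Methylation data frame (see
#'   [read_methylation_table()]).
#' @param meth_min Percent methylation below which an animal is
#'   uninformative (default 50).
#' @param balance_margin Folded-imbalance margin separating "balanced"
#'   from directional expression (default 0.1).
#' @return Data frame with one row per animal with methylation at the
#'   aseQTL position: `sample`, `meth_percent`, `meth_allele`,
#'   `phase_allele` (ASE-marker allele in phase with the methylated
#'   allele), `expressed_fraction` (of that allele), `status`.
#' @export
methylation_ase_crosscheck <- function(pgm, counts, aseqtl_id, ase_id,
                                       methylation, meth_min = 50,
                                       balance_margin = 0.1) {
  stopifnot(inherits(pgm, "phased_geno"))
  iq <- variant_index(pgm, aseqtl_id)
  im <- variant_index(pgm, ase_id)
  vq <- pgm$variants[iq, ]
  meth <- methylation[methylation$chrom == vq$chrom &
                        methylation$pos == vq$pos, , drop = FALSE]
  cbase <- c(vq$ref, vq$alt) %in% c("C", "G")
  meth_allele <- if (sum(cbase) == 1) c("ref", "alt")[cbase] else NA_character_
  rows <- lapply(seq_len(nrow(meth)), function(k) {
    smp <- meth$sample[k]
    pct <- methylation_percent(meth$methylated_count[k],
                               meth$unmethylated_count[k])
    si <- match(smp, pgm$samples)
    base <- data.frame(sample = smp, meth_percent = pct,
                       meth_allele = meth_allele,
                       phase_allele = NA_character_,
                       expressed_fraction = NA_real_,
                       status = "uninformative", stringsAsFactors = FALSE)
    if (is.na(si) || is.na(meth_allele) || pct < meth_min) return(base)
    qa <- pgm$hap_a[si, iq]; qb <- pgm$hap_b[si, iq]
    ma <- pgm$hap_a[si, im]; mb <- pgm$hap_b[si, im]
    if (anyNA(c(qa, qb, ma, mb)) ||
        !pgm$phased[si, iq] || !pgm$phased[si, im]) return(base)
    if (qa == qb || ma == mb) return(base)  # homozygous: no contrast
    cnt <- counts[counts$sample == smp & counts$variant == ase_id, ,
                  drop = FALSE]
    if (nrow(cnt) != 1 || cnt$ref_count + cnt$alt_count < 1) return(base)
    meth_code <- if (meth_allele == "ref") 0L else 1L
    meth_hap <- if (qa == meth_code) "a" else "b"
    marker_allele <- if (meth_hap == "a") ma else mb
    depth <- cnt$ref_count + cnt$alt_count
    f <- if (marker_allele == 0L) cnt$ref_count / depth
      else cnt$alt_count / depth
    base$phase_allele <- if (marker_allele == 0L) "ref" else "alt"
    base$expressed_fraction <- f
    base$status <- if (abs(f - 0.5) <= balance_margin) "inconsistent"
      else if (f < 0.5) "consistent" else "inconsistent"
    base
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = character(), meth_percent = numeric(),
                      meth_allele = character(), phase_allele = character(),
                      expressed_fraction = numeric(), status = character())
  out
}

#' Annotate aseQTL scan results with genomic context
#'
#' Adds the feature class and, when a gene map is supplied, the distance
#' to the associated ASE gene's TSS, plus per-sample percent methylation
#' at the candidate position when methylation data cover it.
#'
#' @param scan Output of [scan_aseqtl()].
#' @param pgm A [phased_genotype_matrix()].
#' @param gene_models Gene models (see [read_gene_models()]).
#' @param methylation Optional methylation data frame.
#' @return `scan` with extra columns `feature_class`, `n_meth_samples`,
#'   `mean_meth_percent`.
#' @export
annotate_aseqtls <- function(scan, pgm, gene_models, methylation = NULL) {
  idx <- variant_index(pgm, scan$candidate_variant)
  pos <- pgm$variants$pos[idx]
  chrom <- pgm$variants$chrom[idx]
  scan$feature_class <- vapply(seq_len(nrow(scan)), function(i)
    classify_location(chrom[i], pos[i], gene_models), character(1))
  scan$n_meth_samples <- 0L
  scan$mean_meth_percent <- NA_real_
  if (!is.null(methylation) && nrow(scan)) {
    for (i in seq_len(nrow(scan))) {
      m <- methylation[methylation$chrom == chrom[i] &
                         methylation$pos == pos[i], , drop = FALSE]
      if (nrow(m) > 0) {
        scan$n_meth_samples[i] <- nrow(m)
        scan$mean_meth_percent[i] <- mean(
          methylation_percent(m$methylated_count, m$unmethylated_count))
      }
    }
  }
  scan
}
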