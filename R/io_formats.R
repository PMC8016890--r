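#' Read phased genotypes from a VCF file
#'
#' Parses a VCF 4.x file (GT field only) into a [phased_genotype_matrix()].
#' Only biallelic SNVs are retained; multi-allelic or indel records are
#' skipped and counted in a message. `"0|1"` / `"1|0"` are preserved as
#' ordered pairs with `phased = TRUE`; `"0/1"` style genotypes keep the
#' written order but are flagged unphased; `"./."` is recorded missing.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param require_phased If `TRUE`, any non-missing unphased genotype is a
#'   hard error naming the offending record.
#' @return A `phased_geno` object.
#' @export
read_phased_vcf <- function(path, require_phased = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message(n_skip, " non-biallelic-SNV record(s) skipped")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  ids <- fix$ID
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  samples <- colnames(gt)
  # gt is variants x samples; split "a|b" / "a/b"
  gt_chr <- sub(":.*$", "", as.vector(gt))
  gt_chr[is.na(gt_chr) | gt_chr %in% c(".", "./.", ".|.")] <- NA
  phased <- grepl("|", gt_chr, fixed = TRUE)
  parts <- strsplit(gt_chr, "[/|]")
  a1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_,
               character(1))
  a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
               character(1))
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  to_int <- function(x) {
    bad <- !is.na(x) & !x %in% c("0", "1")
    if (any(bad)) stop("unexpected allele code in GT: ", x[bad][1])
    as.integer(x)
  }
  nv <- nrow(variants)
  hap_a <- matrix(to_int(a1), nrow = nv)
  hap_b <- matrix(to_int(a2), nrow = nv)
  ph <- matrix(phased, nrow = nv)
  miss <- is.na(hap_a) & is.na(hap_b)
  if (require_phased) {
    bad <- which(!ph & !miss, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("unphased genotype at variant ", variants$id[bad[1, 1]],
           ", sample ", samples[bad[1, 2]])
  }
  phased_genotype_matrix(samples, variants,
                         t(hap_a), t(hap_b), t(ph & !miss))
}

#' Read a per-sample allele count table
#'
#' Reads a TSV with header `sample`, `variant`, `ref_count`, `alt_count`
#' holding allele-specific RNA-seq read counts. Counts are only meaningful
#' for samples heterozygous at the variant; that constraint is enforced at
#' use time, not here.
#'
#' @param path TSV path.
#' @param known_variants Optional character vector; variant ids outside it
#'   are an error listing the offenders.
#' @return Data frame of typed records.
#' @export
read_counts_table <- function(path, known_variants = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "integer"))
  need <- c("sample", "variant", "ref_count", "alt_count")
  if (!identical(names(df)[seq_len(4)], need))
    stop("counts table must have header: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) return(df)
  if (any(df$ref_count < 0 | df$alt_count < 0, na.rm = TRUE))
    stop("negative read counts")
  if (anyNA(df$ref_count) || anyNA(df$alt_count))
    stop("missing read counts")
  key <- paste(df$sample, df$variant)
  if (anyDuplicated(key))
    stop("duplicate (sample, variant) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!is.null(known_variants)) {
    bad <- setdiff(unique(df$variant), known_variants)
    if (length(bad) > 0)
      stop("unknown variant id(s) in counts table: ",
           paste(bad, collapse = ", "))
  }
  df
}

#' Write an allele count table
#' @param counts Data frame as returned by [read_counts_table()].
#' @param path Output TSV path.
#' @export
write_counts_table <- function(counts, path) {
  utils::write.table(counts[, c("sample", "variant", "ref_count", "alt_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read trait-labelled genomic intervals
#'
#' Accepts BED (0-based half-open) or a 1-based fully-closed TSV, selected
#' by `one_based`. Intervals are normalised to the package-internal 0-based
#' half-open convention.
#'
#' @param path Path to a 3- or 4-column tab-separated file
#'   (chrom, start, end, optional label). Header lines starting with
#'   `#`, `track` or `browser` are skipped.
#' @param one_based If `TRUE` input coordinates are 1-based inclusive and
#'   converted; if `FALSE` (BED) they are taken as-is.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `label`.
#' @export
read_intervals <- function(path, one_based = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  fields <- strsplit(lines, "\t")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3)) stop("interval lines need >= 3 tab-separated fields")
  df <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    label = ifelse(nf >= 4, vapply(fields, function(f)
      if (length(f) >= 4) f[4] else NA_character_, character(1)),
      NA_character_),
    stringsAsFactors = FALSE)
  if (one_based) df$start <- df$start - 1L
  if (any(df$start < 0)) stop("negative interval start after normalization")
  if (any(df$start >= df$end))
    stop("interval with start >= end after normalization")
  df
}

#' Write intervals to BED
#' @param intervals Data frame in the internal 0-based half-open convention.
#' @param path Output BED path.
#' @export
write_intervals <- function(intervals, path) {
  out <- intervals[, c("chrom", "start", "end")]
  if (!is.null(intervals$label)) out$label <- intervals$label
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read per-cytosine methylation calls
#'
#' TSV with header `sample`, `chrom`, `pos` (1-based), `methylated_count`,
#' `unmethylated_count`, as produced by RRBS callers after alignment.
#'
#' @param path TSV path.
#' @return Data frame of records; each must have at least one covering read.
#' @export
read_methylation_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer",
                                         "integer", "integer"))
  need <- c("sample", "chrom", "pos", "methylated_count", "unmethylated_count")
  if (!identical(names(df)[seq_len(5)], need))
    stop("methylation table must have header: ", paste(need, collapse = ", "))
  if (any(df$methylated_count < 0 | df$unmethylated_count < 0))
    stop("negative methylation counts")
  if (any(df$methylated_count + df$unmethylated_count < 1))
    stop("methylation record with zero covering reads")
  df
}

#' Write a methylation table
#' @param meth Data frame as returned by [read_methylation_table()].
#' @param path Output TSV path.
#' @export
write_methylation_table <- function(meth, path) {
  utils::write.table(meth[, c("sample", "chrom", "pos", "methylated_count",
                              "unmethylated_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene models from GFF3
#'
#' Imports `gene`, `mRNA`, `exon`, `five_prime_UTR` and `three_prime_UTR`
#' features and reshapes them into the flat representation used by the
#' annotation functions. A gene is called coding if it has an mRNA child.
#'
#' @param path GFF3 path.
#' @return List with data frames `genes` (gene_id, chrom, start, end,
#'   strand, coding; 1-based inclusive) and `features` (gene_id, type,
#'   chrom, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gene_rows) == 0) stop("no gene features in ", path)
  gene_id_of <- function(rows) {
    if (!is.null(rows$gene_id) && !all(is.na(rows$gene_id))) return(rows$gene_id)
    rows$ID
  }
  parent_gene <- function(rows) {
    p <- vapply(rows$Parent, function(x)
      if (length(x) > 0) as.character(x[1]) else NA_character_, character(1))
    # exon/UTR parents are transcripts; map transcript -> gene
    tx <- df[df$type %in% c("mRNA", "transcript", "ncRNA"), , drop = FALSE]
    txp <- vapply(tx$Parent, function(x)
      if (length(x) > 0) as.character(x[1]) else NA_character_, character(1))
    map <- stats::setNames(txp, tx$ID)
    out <- ifelse(p %in% names(map), map[p], p)
    unname(out)
  }
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  coding_genes <- unique(parent_gene(tx)[tx$type == "mRNA"])
  genes <- data.frame(gene_id = gene_id_of(gene_rows),
                      chrom = gene_rows$seqnames,
                      start = gene_rows$start, end = gene_rows$end,
                      strand = gene_rows$strand,
                      stringsAsFactors = FALSE)
  genes$coding <- genes$gene_id %in% coding_genes
  feat_rows <- df[df$type %in% c("exon", "five_prime_UTR", "three_prime_UTR"),
                  , drop = FALSE]
  features <- data.frame(gene_id = parent_gene(feat_rows),
                         type = as.character(feat_rows$type),
                         chrom = feat_rows$seqnames,
                         start = feat_rows$start, end = feat_rows$end,
                         stringsAsFactors = FALSE)
  list(genes = genes, features = features)
}

#' Write gene models to GFF3
#' @param gene_models List as returned by [read_gene_models()].
#' @param path Output GFF3 path.
#' @export
write_gene_models <- function(gene_models, path) {
  g <- gene_models$genes
  f <- gene_models$features
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  tx_id <- paste0(g$gene_id, ".t1")
  tx_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = ifelse(g$coding, "mRNA", "ncRNA"),
    ID = tx_id, Parent = g$gene_id)
  strand_of <- g$strand[match(f$gene_id, g$gene_id)]
  feat_gr <- GenomicRanges::GRanges(
    f$chrom, IRanges::IRanges(f$start, f$end), strand = strand_of,
    type = f$type, ID = NA_character_,
    Parent = paste0(f$gene_id, ".t1"))
  gr <- c(gene_gr, tx_gr, feat_gr)
  rtracklayer::export(gr, path, format = "gff3")
}
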