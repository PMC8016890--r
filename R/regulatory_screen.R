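#' Allele-specific flanking sequences around variants
#'
#' Builds, for each variant, the two 2w+1-base sequences obtained by
#' placing the reference or the alternative allele at the variant position
#' with `w` bp of genomic context on either side (default 25, i.e. 51-base
#' sequences). The genome base at the position must equal the reference
#' allele; a mismatch is a hard error naming the variant. Near contig
#' edges the flank is truncated and flagged.
#'
#' @param variants Variant data frame (`id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param genome A `Biostrings::DNAStringSet` (or path to a FASTA read
#'   with `readDNAStringSet`; names must match the variant chromosomes).
#' @param w Flank width in bp (default 25).
#' @return Data frame `variant`, `ref_seq`, `alt_seq`, `center` (1-based
#'   offset of the variant base within the sequences), `truncated`.
#' @export
extract_flanks <- function(variants, genome, w = 25) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome))
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    ci <- match(v$chrom, nm)
    if (is.na(ci)) stop("chromosome ", v$chrom, " absent from genome")
    seq <- genome[[ci]]
    if (v$pos < 1 || v$pos > length(seq))
      stop("variant ", v$id, " outside contig ", v$chrom)
    base <- as.character(Biostrings::subseq(seq, v$pos, v$pos))
    if (base != v$ref)
      stop("genome base ", base, " at ", v$chrom, ":", v$pos,
           " does not match ref allele ", v$ref, " of variant ", v$id)
    left <- max(1L, v$pos - w)
    right <- min(length(seq), v$pos + w)
    ctx <- as.character(Biostrings::subseq(seq, left, right))
    center <- v$pos - left + 1L
    alt_seq <- ctx
    substr(alt_seq, center, center) <- v$alt
    data.frame(variant = v$id, ref_seq = ctx, alt_seq = alt_seq,
               center = center,
               truncated = (v$pos - left < w) || (right - v$pos < w),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter miRNA interactions by hybridisation energy
#'
#' Keeps interactions with a minimum free energy strictly below the
#' threshold (an MFE of exactly the threshold is dropped). Rows with a
#' missing MFE are dropped with a warning.
#'
#' @param interactions Data frame with an `mfe` column (kcal/mol).
#' @param threshold MFE cut-off (default -18.0).
#' @return The filtered data frame.
#' @export
mfe_filter <- function(interactions, threshold = -18.0) {
  if (is.null(interactions$mfe)) stop("interactions need an 'mfe' column")
  missing_mfe <- is.na(interactions$mfe)
  if (any(missing_mfe))
    warning(sum(missing_mfe), " interaction(s) without MFE dropped")
  interactions[!missing_mfe & interactions$mfe < threshold, , drop = FALSE]
}

#' Allele-differential binding hits
#'
#' Given hit tables for the reference-allele and alternative-allele
#' sequences over the same (variant, factor) key space, reports the
#' factors whose predicted binding exists for one allele only. Factors
#' hitting both alleles are excluded from the differential report.
#'
#' @param hits_ref,hits_alt Data frames with columns `variant`, `factor`
#'   (and optionally `score`).
#' @return Data frame `variant`, `factor`, `allele` (`"ref"` or `"alt"`),
#'   `score` (from the allele that hit).
#' @export
differential_hits <- function(hits_ref, hits_alt) {
  key <- function(df) paste(df$variant, df$factor)
  kr <- unique(key(hits_ref)); ka <- unique(key(hits_alt))
  pick <- function(df, keys, allele) {
    d <- df[key(df) %in% keys, , drop = FALSE]
    d <- d[!duplicated(key(d)), , drop = FALSE]
    if (nrow(d) == 0)
      return(data.frame(variant = character(), factor = character(),
                        allele = character(), score = numeric()))
    data.frame(variant = d$variant, factor = d$factor, allele = allele,
               score = if (!is.null(d$score)) d$score else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick(hits_ref, setdiff(kr, ka), "ref"),
               pick(hits_alt, setdiff(ka, kr), "alt"))
  row.names(out) <- NULL
  out
}

#' Restrict interactions to expressed factors
#'
#' Keeps interactions whose factor is on the supplied expressed-factor
#' list (deduplicated). An empty list yields an empty result with a
#' warning — there is no pass-through. A per-factor summary count is
#' attached.
#'
#' @param interactions Data frame with a `factor` column.
#' @param expressed_ids Character vector of expressed TF / miRNA ids.
#' @return Filtered data frame with attribute `factor_counts`.
#' @export
intersect_expressed <- function(interactions, expressed_ids) {
  expressed_ids <- unique(expressed_ids)
  if (length(expressed_ids) == 0) {
    warning("empty expressed-factor list: returning no interactions")
    out <- interactions[0, , drop = FALSE]
    attr(out, "factor_counts") <- integer(0)
    return(out)
  }
  out <- interactions[interactions$factor %in% expressed_ids, , drop = FALSE]
  attr(out, "factor_counts") <-
    sort(table(out$factor), decreasing = TRUE)
  out
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

pwm_scores <- function(seq, pwm, background) {
  bases <- strsplit(seq, "")[[1]]
  w <- ncol(pwm)
  n <- length(bases) - w + 1
  if (n < 1) return(numeric(0))
  logodds <- log2(pwm / background)
  vapply(seq_len(n), function(s) {
    idx <- match(bases[s:(s + w - 1)], rownames(pwm))
    if (anyNA(idx)) return(-Inf)
    sum(logodds[cbind(idx, seq_len(w))])
  }, numeric(1))
}

#' Scan allelic flanks with a position weight matrix
#'
#' Simple log-odds PWM scanner used as a transparent test engine for the
#' allele-differential pipeline (production affinity predictions are
#' consumed as external hit tables). Every window of each allelic
#' sequence, on both strands, is scored as `sum(log2(p[b, i] / q[b]))`;
#' windows scoring at least `score_min` are reported per allele.
#'
#' @param flanks One row of [extract_flanks()] output (or a data frame
#'   with `variant`, `ref_seq`, `alt_seq`).
#' @param pwm Numeric matrix, rows named `A`, `C`, `G`, `T`, columns
#'   positions; each column must sum to 1 (within 1e-6).
#' @param background Base composition (default uniform).
#' @param score_min Minimum reported score.
#' @param factor_id Factor name attached to the hits (default `"pwm"`).
#' @return Data frame `variant`, `factor`, `allele`, `strand`, `position`,
#'   `score` with one row per hit.
#' @export
pwm_scan <- function(flanks, pwm, background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                     score_min = 0, factor_id = "pwm") {
  stopifnot(is.matrix(pwm), setequal(rownames(pwm), c("A", "C", "G", "T")))
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  background <- background[c("A", "C", "G", "T")]
  if (any(abs(colSums(pwm) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  rows <- list()
  for (i in seq_len(nrow(flanks))) {
    for (allele in c("ref", "alt")) {
      seq <- flanks[[paste0(allele, "_seq")]][i]
      for (strand in c("+", "-")) {
        s <- if (strand == "+") seq else revcomp(seq)
        sc <- pwm_scores(s, pwm, background)
        hit <- which(sc >= score_min)
        if (length(hit))
          rows[[length(rows) + 1L]] <- data.frame(
            variant = flanks$variant[i], factor = factor_id,
            allele = allele, strand = strand, position = hit,
            score = sc[hit], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant = character(), factor = character(),
                      allele = character(), strand = character(),
                      position = integer(), score = numeric())
  out
}
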