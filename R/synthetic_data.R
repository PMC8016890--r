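#' Simulation configuration
#'
#' Parameters of the synthetic population generator. Defaults emulate the
#' study design the pipeline targets: 190 diploid animals genotyped at
#' biallelic SNVs organised in LD blocks, one transcribed allele-specific
#' expression (ASE) marker SNP per gene with binomially sampled per-allele
#' read counts, a causal cis-variant within 1 Mb of its marker whose
#' heterozygosity shifts the expressed-allele fraction, RRBS-style
#' methylation tables for a 12-animal subset, and trait QTL intervals a
#' configurable fraction of which cover causal variants.
#'
#' The cis effect is parameterised by `beta`, the fraction by which the
#' haplotype in phase with the causal alternative allele is silenced: in a
#' causal heterozygote that haplotype is expressed at relative rate
#' `1 - beta`, so the allele it carries has expressed fraction
#' `r = (1 - beta) / (2 - beta)` (0.5 at `beta = 0`, 0 at `beta = 1`).
#' Homozygotes at the causal site are balanced — exactly the contrast the
#' genotype-stratified scan exploits.
#'
#' @param n_samples Number of diploid individuals.
#' @param n_blocks Number of independent LD blocks (one gene each, one per
#'   chromosome).
#' @param snps_per_block SNPs per block, evenly spaced `snp_spacing` apart.
#' @param pool_size Ancestral haplotype pool size per block; haplotypes are
#'   drawn from this finite pool, which creates D' structure within blocks
#'   and independence between blocks.
#' @param beta Cis-effect size in `[0, 1]` (see above).
#' @param causal_maf,marker_maf Target minor allele frequencies of the
#'   causal variant and the ASE marker.
#' @param background_maf_range Range of the uniform MAF draw for the other
#'   block SNPs.
#' @param depth_mean,depth_dispersion Mean and size parameter of the
#'   negative-binomial RNA-seq depth model at the marker (floored at 1).
#' @param window_bp Scan window half-width; the causal variant always lies
#'   within this distance of its marker.
#' @param chrom_length,snp_spacing Chromosome length and inter-SNP spacing
#'   in bp.
#' @param meth_background,meth_silenced Per-read methylation probability at
#'   a causal position for non-carriers / carriers of the causal
#'   alternative allele.
#' @param meth_depth_mean Mean Poisson read depth of methylation records.
#' @param n_meth_samples Number of animals with methylation data.
#' @param qtl_cover_frac Probability that a block's causal variant is
#'   covered by a planted trait QTL interval.
#' @param n_qtl_decoys Number of additional QTL intervals placed uniformly
#'   at random.
#' @param rng_seed Integer seed; identical seeds give identical populations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 190, n_blocks = 10, snps_per_block = 25,
                       pool_size = 8, beta = 0.8,
                       causal_maf = 0.3, marker_maf = 0.3,
                       background_maf_range = c(0.1, 0.5),
                       depth_mean = 30, depth_dispersion = 5,
                       window_bp = 1e6, chrom_length = 5e5,
                       snp_spacing = 2000,
                       meth_background = 0.05, meth_silenced = 0.8,
                       meth_depth_mean = 20, n_meth_samples = 12,
                       qtl_cover_frac = 0.6, n_qtl_decoys = 10,
                       rng_seed = 1) {
  cfg <- as.list(environment())
  if (cfg$beta < 0 || cfg$beta > 1) stop("beta must lie in [0, 1]")
  for (f in c("causal_maf", "marker_maf"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop(f, " must lie in (0, 1)")
  if (any(cfg$background_maf_range <= 0) || any(cfg$background_maf_range >= 1))
    stop("background_maf_range must lie in (0, 1)")
  if (cfg$depth_mean < 1) stop("depth_mean must be >= 1")
  if (cfg$pool_size < 2) stop("pool_size must be >= 2")
  if (cfg$snps_per_block < 2) stop("snps_per_block must be >= 2")
  span <- (cfg$snps_per_block - 1) * cfg$snp_spacing
  if (span + 20000 > cfg$chrom_length)
    stop("chrom_length too small for the block span")
  if (span > cfg$window_bp)
    stop("block span exceeds window_bp; causal variant must stay in window")
  structure(cfg, class = "sim_config")
}

#' Expressed-allele fraction of the silenced haplotype
#'
#' In a causal heterozygote the haplotype in phase with the causal
#' alternative allele is expressed at relative rate `1 - beta`, so the
#' allele it carries has expressed fraction `(1 - beta) / (2 - beta)`.
#'
#' @param beta Cis-effect size in `[0, 1]`.
#' @return Expressed fraction in `[0, 0.5]`.
#' @export
silenced_fraction <- function(beta) {
  stopifnot(all(beta >= 0 & beta <= 1))
  (1 - beta) / (2 - beta)
}

# Draw one SNP's allele column for the ancestral haplotype pool.
# Monomorphic draws are resampled. With `tight`, the realised pool
# frequency must fall within 1/pool_size of the target (the configured
# MAF is a study condition, and small pools drift far from it otherwise).
# With `avoid`, columns inducing the same sample partition as `avoid`
# (identical or complementary) are resampled: a causal variant in perfect
# LD with its marker would leave no homozygous contrast group.
draw_pool_column <- function(pool_size, maf, tight = FALSE, avoid = NULL,
                             max_tries = 1000L) {
  tries <- 0L
  repeat {
    tries <- tries + 1L
    col <- stats::rbinom(pool_size, 1L, maf)
    ok <- length(unique(col)) > 1L
    if (ok && tight)
      ok <- abs(mean(col) - maf) <= 1 / pool_size + 1e-9
    if (ok && !is.null(avoid))
      ok <- !identical(col, avoid) && !identical(col, 1L - avoid)
    if (ok) return(list(col = col, tries = tries))
    if (tries >= max_tries)
      stop("could not draw a suitable pool column at maf = ", maf)
  }
}

sim_traits <- c("meat_tenderness", "ribeye_area", "intramuscular_fat",
                "body_weight", "shear_force", "backfat_thickness")

#' Simulate a phased population with a known cis-regulatory architecture
#'
#' Generates phased genotypes, allele-specific read counts at each gene's
#' ASE marker, methylation records at causal positions (elevated rate in
#' carriers of the causal alternative allele, whose haplotype is the
#' silenced one), trait QTL intervals partly planted over causal variants,
#' gene models, and a ground-truth record. Deterministic under
#' `config$rng_seed`. Causal variants always carry a T>C substitution so
#' the methylatable cytosine belongs to the alternative allele only.
#'
#' @param config A [sim_config()].
#' @param with_genome If `TRUE`, also generate a random genome sequence per
#'   chromosome (with the reference allele at every variant position) for
#'   flank-extraction work. Off by default: the sequence is bulky and only
#'   the regulatory screen needs it.
#' @return List of class `ase_sim` with elements `geno`
#'   ([phased_genotype_matrix()]), `counts`, `methylation`, `qtl`
#'   (internal 0-based half-open intervals), `gene_models`, `truth`,
#'   `genome` (a `DNAStringSet` or `NULL`) and `config`.
#' @export
simulate_population <- function(config = sim_config(), with_genome = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_samples
  ns <- config$snps_per_block
  samples <- sprintf("animal_%03d", seq_len(n))
  meth_samples <- samples[seq_len(min(config$n_meth_samples, n))]
  r_sil <- silenced_fraction(config$beta)

  ha_blocks <- hb_blocks <- vector("list", config$n_blocks)
  var_blocks <- genes <- feats <- truth_blocks <- vector("list", config$n_blocks)
  counts <- list(); meth <- list(); qtl <- list(); truth_expr <- list()
  retries <- 0L

  for (b in seq_len(config$n_blocks)) {
    chrom <- as.character(b)
    span <- (ns - 1L) * config$snp_spacing
    offset <- sample(seq(10000L, config$chrom_length - span - 10000L), 1L)
    pos <- as.integer(offset + (seq_len(ns) - 1L) * config$snp_spacing)
    marker_idx <- as.integer(ceiling(ns / 2))
    causal_idx <- sample(setdiff(seq_len(ns), marker_idx), 1L)

    pool <- matrix(0L, config$pool_size, ns)
    marker_draw <- draw_pool_column(config$pool_size, config$marker_maf,
                                    tight = TRUE)
    pool[, marker_idx] <- marker_draw$col
    causal_draw <- draw_pool_column(config$pool_size, config$causal_maf,
                                    tight = TRUE, avoid = marker_draw$col)
    pool[, causal_idx] <- causal_draw$col
    retries <- retries + causal_draw$tries - 1L
    for (j in setdiff(seq_len(ns), c(marker_idx, causal_idx))) {
      maf <- stats::runif(1, config$background_maf_range[1],
                          config$background_maf_range[2])
      pool[, j] <- draw_pool_column(config$pool_size, maf)$col
    }

    ha <- pool[sample.int(config$pool_size, n, replace = TRUE), , drop = FALSE]
    hb <- pool[sample.int(config$pool_size, n, replace = TRUE), , drop = FALSE]

    ids <- sprintf("snp_%02d_%02d", b, seq_len(ns))
    alleles <- t(vapply(seq_len(ns), function(j) {
      if (j == causal_idx) c("T", "C") else sample(c("A", "C", "G", "T"), 2L)
    }, character(2)))
    var_blocks[[b]] <- data.frame(id = ids, chrom = chrom, pos = pos,
                                  ref = alleles[, 1], alt = alleles[, 2],
                                  stringsAsFactors = FALSE)

    marker_id <- ids[marker_idx]; causal_id <- ids[causal_idx]
    het_marker <- ha[, marker_idx] != hb[, marker_idx]
    het_causal <- ha[, causal_idx] != hb[, causal_idx]
    for (s in which(het_marker)) {
      if (het_causal[s]) {
        # the haplotype carrying the causal ALT is silenced
        m_sil <- if (ha[s, causal_idx] == 1L) ha[s, marker_idx]
          else hb[s, marker_idx]
        p_ref <- if (m_sil == 0L) r_sil else 1 - r_sil
      } else p_ref <- 0.5
      depth <- max(1L, stats::rnbinom(1L, size = config$depth_dispersion,
                                      mu = config$depth_mean))
      rc <- stats::rbinom(1L, depth, p_ref)
      counts[[length(counts) + 1L]] <- data.frame(
        sample = samples[s], variant = marker_id,
        ref_count = rc, alt_count = depth - rc, stringsAsFactors = FALSE)
      truth_expr[[length(truth_expr) + 1L]] <- data.frame(
        sample = samples[s], marker = marker_id, p_ref = p_ref,
        causal_het = het_causal[s], stringsAsFactors = FALSE)
    }

    geno_causal <- ha[, causal_idx] + hb[, causal_idx]
    for (s in seq_along(meth_samples)) {
      rate <- if (geno_causal[s] >= 1L) config$meth_silenced
        else config$meth_background
      total <- max(1L, stats::rpois(1L, config$meth_depth_mean))
      m <- stats::rbinom(1L, total, rate)
      meth[[length(meth) + 1L]] <- data.frame(
        sample = meth_samples[s], chrom = chrom, pos = pos[causal_idx],
        methylated_count = m, unmethylated_count = total - m,
        stringsAsFactors = FALSE)
    }

    covered <- stats::runif(1) < config$qtl_cover_frac
    if (covered) {
      w <- sample(20000:60000, 1L)
      start0 <- max(0L, pos[causal_idx] - sample.int(w, 1L))
      end0 <- min(config$chrom_length, start0 + w)
      qtl[[length(qtl) + 1L]] <- data.frame(
        chrom = chrom, start = start0, end = end0,
        label = sample(sim_traits, 1L), stringsAsFactors = FALSE)
    }

    # one gene per block spanning the central half of the SNPs, with three
    # exons and terminal UTRs, alternating strand; the marker sits inside
    q1 <- pos[max(1L, floor(ns * 0.25))]
    q3 <- pos[min(ns, ceiling(ns * 0.75))]
    strand <- if (b %% 2L == 1L) "+" else "-"
    gid <- sprintf("gene_%02d", b)
    glen <- q3 - q1
    e1 <- c(q1, q1 + floor(glen * 0.2))
    e2 <- c(q1 + floor(glen * 0.4), q1 + floor(glen * 0.6))
    e3 <- c(q1 + floor(glen * 0.8), q3)
    genes[[b]] <- data.frame(gene_id = gid, chrom = chrom, start = q1,
                             end = q3, strand = strand, coding = TRUE,
                             stringsAsFactors = FALSE)
    utr5 <- if (strand == "+") c(e1[1], e1[1] + 200L) else c(e3[2] - 200L, e3[2])
    utr3 <- if (strand == "+") c(e3[2] - 200L, e3[2]) else c(e1[1], e1[1] + 200L)
    feats[[b]] <- data.frame(
      gene_id = gid,
      type = c("exon", "exon", "exon", "five_prime_UTR", "three_prime_UTR"),
      chrom = chrom,
      start = c(e1[1], e2[1], e3[1], utr5[1], utr3[1]),
      end = c(e1[2], e2[2], e3[2], utr5[2], utr3[2]),
      stringsAsFactors = FALSE)

    truth_blocks[[b]] <- data.frame(
      block = b, chrom = chrom, gene_id = gid,
      marker = marker_id, causal = causal_id,
      marker_pos = pos[marker_idx], causal_pos = pos[causal_idx],
      distance = abs(pos[causal_idx] - pos[marker_idx]),
      qtl_covered = covered, stringsAsFactors = FALSE)

    ha_blocks[[b]] <- ha
    hb_blocks[[b]] <- hb
  }

  variants <- do.call(rbind, var_blocks)
  geno <- phased_genotype_matrix(samples, variants,
                                 do.call(cbind, ha_blocks),
                                 do.call(cbind, hb_blocks))
  for (i in seq_len(config$n_qtl_decoys)) {
    chrom <- as.character(sample.int(config$n_blocks, 1L))
    w <- sample(20000:60000, 1L)
    start0 <- sample.int(config$chrom_length - w, 1L)
    qtl[[length(qtl) + 1L]] <- data.frame(
      chrom = chrom, start = start0, end = start0 + w,
      label = sample(sim_traits, 1L), stringsAsFactors = FALSE)
  }

  truth <- list(blocks = do.call(rbind, truth_blocks),
                expressed = do.call(rbind, truth_expr),
                causal_retries = retries)
  genome <- if (with_genome) sim_genome(variants, config) else NULL

  structure(list(geno = geno,
                 counts = do.call(rbind, counts),
                 methylation = do.call(rbind, meth),
                 qtl = do.call(rbind, qtl),
                 gene_models = list(genes = do.call(rbind, genes),
                                    features = do.call(rbind, feats)),
                 truth = truth, genome = genome, config = config),
            class = "ase_sim")
}

sim_genome <- function(variants, config) {
  chroms <- unique(variants$chrom)
  seqs <- lapply(chroms, function(ch) {
    bases <- sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE)
    v <- variants[variants$chrom == ch, ]
    bases[v$pos] <- v$ref
    paste(bases, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- chroms
  out
}

#' Write a simulated population to disk
#'
#' Emits the study files a real analysis would start from: a phased VCF,
#' the allele count TSV, the methylation TSV, a trait QTL BED, gene models
#' as GFF3, the ground truth as JSON, and (when the simulation carries a
#' genome) a genome FASTA plus a FASTA of 51-bp allelic flanks around each
#' causal variant.
#'
#' @param sim An `ase_sim` from [simulate_population()].
#' @param dir Output directory (created if needed).
#' @param genome_dir Directory for the bulky genome FASTA (defaults to
#'   `dir`).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir, genome_dir = dir) {
  stopifnot(inherits(sim, "ase_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             counts = file.path(dir, "counts.tsv"),
             methylation = file.path(dir, "methylation.tsv"),
             qtl = file.path(dir, "qtl.bed"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.json"))
  write_phased_vcf(sim$geno, paths[["vcf"]],
                   contig_lengths = stats::setNames(
                     rep(sim$config$chrom_length,
                         length(unique(sim$geno$variants$chrom))),
                     unique(sim$geno$variants$chrom)))
  write_counts_table(sim$counts, paths[["counts"]])
  write_methylation_table(sim$methylation, paths[["methylation"]])
  write_intervals(sim$qtl, paths[["qtl"]])
  write_gene_models(sim$gene_models, paths[["gff"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$genome)) {
    dir.create(genome_dir, recursive = TRUE, showWarnings = FALSE)
    paths[["genome"]] <- file.path(genome_dir, "genome.fasta")
    Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
    causal <- sim$geno$variants[
      sim$geno$variants$id %in% sim$truth$blocks$causal, , drop = FALSE]
    fl <- extract_flanks(causal, sim$genome)
    seqs <- Biostrings::DNAStringSet(c(fl$ref_seq, fl$alt_seq))
    names(seqs) <- c(paste0(fl$variant, "_ref"), paste0(fl$variant, "_alt"))
    paths[["flanks"]] <- file.path(dir, "flanks.fasta")
    Biostrings::writeXStringSet(seqs, paths[["flanks"]])
  }
  invisible(paths)
}

# Minimal phased-VCF emitter for generator output (GT field only).
write_phased_vcf <- function(pgm, path, contig_lengths = NULL) {
  stopifnot(inherits(pgm, "phased_geno"))
  v <- pgm$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=asescan-simulated",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", pgm$samples),
                      collapse = "\t"))
  sep <- ifelse(t(pgm$phased), "|", "/")
  a <- t(pgm$hap_a); b <- t(pgm$hap_b)
  gt <- matrix(paste0(ifelse(is.na(a), ".", a), sep,
                      ifelse(is.na(b), ".", b)),
               nrow = nrow(v))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}
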