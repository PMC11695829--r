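#' Oriented genomic window
#'
#' Builds the genomic interval corresponding to offsets `[from, to]`
#' (inclusive, in transcription orientation, 0 = the anchor base) around an
#' anchor position. On the minus strand the interval is mirrored.
#'
#' @return c(start, end) in genomic coordinates, or NULL if empty after
#'   truncation to `[1, chrom_len]` (truncation warns when `warn`).
#' @noRd
oriented_window <- function(anchor, strand, from, to, chrom_len,
                            warn = TRUE) {
  if (strand == "+") {
    s <- anchor + from; e <- anchor + to
  } else {
    s <- anchor - to; e <- anchor - from
  }
  if (s < 1L || e > chrom_len) {
    if (warn)
      warning("window truncated to chromosome bounds", call. = FALSE)
    s <- max(1L, s); e <- min(chrom_len, e)
  }
  if (e < s) return(NULL)
  c(s, e)
}

.unit_meta <- function(unit) {
  list(chrom = as.character(GenomeInfoDb::seqnames(unit)),
       strand = as.character(BiocGenerics::strand(unit)),
       tss = tss_position(unit), pas = pas_position(unit),
       len = BiocGenerics::width(unit))
}

.win_density <- function(cov, chrom, strand, win) {
  if (is.null(win)) return(NA_real_)
  window_density(cov, chrom, win[1L], win[2L], strand)
}

#' Promoter-proximal attenuation index
#'
#' Ratio of read density in the first `cfg$tss_window` bp downstream of the
#' TSS to the density over the remaining gene body. A high index means
#' signal is concentrated near the promoter, the signature of premature
#' termination / attenuation.
#'
#' @param cov a [stranded_coverage()].
#' @param unit a single transcription unit.
#' @param cfg an [analysis_config()].
#' @return The index, or `NA` (with a `"reason"` attribute) for genes not
#'   longer than the TSS window or with zero body density.
#' @export
attenuation_index <- function(cov, unit, cfg = analysis_config()) {
  m <- .unit_meta(unit)
  if (m$len <= cfg$tss_window) {
    out <- NA_real_; attr(out, "reason") <- "unit shorter than TSS window"
    return(out)
  }
  clen <- cov$seqlengths[[m$chrom]]
  w5 <- oriented_window(m$tss, m$strand, 0L, cfg$tss_window - 1L, clen)
  wb <- oriented_window(m$tss, m$strand, cfg$tss_window, m$len - 1L, clen)
  d5 <- .win_density(cov, m$chrom, m$strand, w5)
  db <- .win_density(cov, m$chrom, m$strand, wb)
  if (is.na(db) || db == 0) {
    out <- NA_real_; attr(out, "reason") <- "zero body density"
    return(out)
  }
  d5 / db
}

#' Readthrough index
#'
#' Density in the `cfg$readthrough_window` bp downstream of the PAS divided
#' by the gene-body density (from `cfg$metagene_trim` bp after the TSS to
#' the PAS). Quantifies transcription persisting past the cleavage site;
#' body normalisation makes it robust to global transcription changes.
#'
#' @inheritParams attenuation_index
#' @return The index, or `NA` with a `"reason"` attribute when the body is
#'   empty or has zero density. Downstream windows running off the
#'   chromosome end are truncated with a warning.
#' @export
readthrough_index <- function(cov, unit, cfg = analysis_config()) {
  m <- .unit_meta(unit)
  clen <- cov$seqlengths[[m$chrom]]
  if (m$len <= cfg$metagene_trim) {
    out <- NA_real_; attr(out, "reason") <- "unit shorter than body trim"
    return(out)
  }
  wd <- oriented_window(m$pas, m$strand, 1L, cfg$readthrough_window, clen)
  wb <- oriented_window(m$tss, m$strand, cfg$metagene_trim, m$len - 1L, clen)
  dd <- .win_density(cov, m$chrom, m$strand, wd)
  db <- .win_density(cov, m$chrom, m$strand, wb)
  if (is.na(db) || db == 0) {
    out <- NA_real_; attr(out, "reason") <- "zero body density"
    return(out)
  }
  if (is.na(dd)) dd <- 0
  dd / db
}

#' PAS cleavage index
#'
#' Density in the 2 x `cfg$pas_half_window` nt window centred on the
#' cleavage site divided by the density of a `cfg$body_window` bp gene-body
#' window ending `cfg$body_offset` bp upstream of the site (all windows in
#' transcription orientation). Efficient cleavage depletes signal at the
#' PAS, giving a low index; cleavage defects shift the index up.
#'
#' @param cov a [stranded_coverage()].
#' @param pas one-row data.frame with `chrom`, `position`, `strand` (see
#'   [select_pas_site()]).
#' @param cfg an [analysis_config()].
#' @return The index, or `NA` with a `"reason"` attribute if the body
#'   window has zero density.
#' @export
cleavage_index <- function(cov, pas, cfg = analysis_config()) {
  stopifnot(nrow(pas) == 1L)
  chrom <- pas$chrom; strand <- pas$strand; pos <- pas$position
  clen <- cov$seqlengths[[chrom]]
  h <- cfg$pas_half_window
  wn <- oriented_window(pos, strand, -h, h - 1L, clen)
  wb <- oriented_window(pos, strand, -(cfg$body_offset + cfg$body_window),
                        -(cfg$body_offset + 1L), clen)
  dn <- .win_density(cov, chrom, strand, wn)
  db <- .win_density(cov, chrom, strand, wb)
  if (is.na(db) || db == 0) {
    out <- NA_real_; attr(out, "reason") <- "zero body density"
    return(out)
  }
  if (is.na(dn)) dn <- 0
  dn / db
}

#' Intron retention index
#'
#' Per intron, the ratio of intronic read density to the mean density of
#' the two flanking exons; the gene aggregate is the mean of the defined
#' per-intron ratios. Uniform coverage gives 1, full splicing gives 0.
#'
#' @inheritParams attenuation_index
#' @return list with `per_intron` (numeric, genomic order) and `aggregate`;
#'   for intronless genes both are empty/`NA` with a `"reason"` attribute.
#' @export
intron_retention_index <- function(cov, unit) {
  m <- .unit_meta(unit)
  intr <- unit_introns(unit)
  if (length(intr) == 0L) {
    out <- list(per_intron = numeric(0), aggregate = NA_real_)
    attr(out, "reason") <- "intronless gene"
    return(out)
  }
  ex <- S4Vectors::mcols(unit)$exons[[1L]]
  dex <- window_means(cov, m$chrom, BiocGenerics::start(ex),
                      BiocGenerics::end(ex), m$strand)
  din <- window_means(cov, m$chrom, BiocGenerics::start(intr),
                      BiocGenerics::end(intr), m$strand)
  per <- vapply(seq_along(intr), function(i) {
    flank <- mean(c(dex[i], dex[i + 1L]))
    if (flank == 0) NA_real_ else din[i] / flank
  }, numeric(1))
  agg <- if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  list(per_intron = per, aggregate = agg)
}

#' Mean occupancy over a unit
#' @inheritParams attenuation_index
#' @return Mean per-base signal across the unit, strand-oriented.
#' @export
unit_mean_density <- function(cov, unit) {
  m <- .unit_meta(unit)
  window_density(cov, m$chrom, BiocGenerics::start(unit),
                 BiocGenerics::end(unit), m$strand)
}

#' Per-gene metric table
#'
#' Computes every per-gene index for each sample and returns a long table
#' (one row per unit x sample), the central exchange format of the
#' pipeline.
#'
#' @param covs named list of [stranded_coverage()] objects (TT-seq signal),
#'   one per sample.
#' @param units transcription units.
#' @param cfg an [analysis_config()].
#' @param pas optional data.frame of selected PAS sites (`unit_id`,
#'   `chrom`, `position`, `strand`); cleavage indices are `NA` for units
#'   without a site.
#' @param chip_covs optional named list of occupancy tracks parallel to
#'   `covs`; fills the `chip_mean` column.
#' @return data.frame with columns `tu_id`, `sample`, `biotype`, `length`,
#'   `n_introns`, `attenuation_index`, `readthrough_index`,
#'   `cleavage_index`, `intron_retention`, `chip_mean`.
#' @export
gene_metrics <- function(covs, units, cfg = analysis_config(), pas = NULL,
                         chip_covs = NULL) {
  stopifnot(is.list(covs), !is.null(names(covs)))
  ids <- S4Vectors::mcols(units)$tu_id
  res <- lapply(names(covs), function(s) {
    cov <- covs[[s]]
    chip <- if (is.null(chip_covs)) NULL else chip_covs[[s]]
    rows <- lapply(seq_along(units), function(i) {
      u <- units[i]
      att <- suppressWarnings(attenuation_index(cov, u, cfg))
      rt <- suppressWarnings(readthrough_index(cov, u, cfg))
      ci <- NA_real_
      if (!is.null(pas)) {
        p <- pas[pas$unit_id == ids[i], , drop = FALSE]
        if (nrow(p) == 1L)
          ci <- suppressWarnings(cleavage_index(cov, p, cfg))
      }
      ir <- intron_retention_index(cov, u)
      data.frame(
        tu_id = ids[i], sample = s,
        biotype = S4Vectors::mcols(u)$biotype,
        length = BiocGenerics::width(u),
        n_introns = max(0L, length(S4Vectors::mcols(u)$exons[[1L]]) - 1L),
        attenuation_index = as.numeric(att),
        readthrough_index = as.numeric(rt),
        cleavage_index = as.numeric(ci),
        intron_retention = ir$aggregate,
        chip_mean = if (is.null(chip)) NA_real_ else
          unit_mean_density(chip, u),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, res)
}

#' Select attenuated genes
#'
#' A gene is called attenuated when its attenuation index in the treated
#' (depleted) sample is at least `cfg$attenuation_fold` times the index in
#' the control sample (boundary inclusive), both indices being defined and
#' the gene longer than `cfg$min_len_attenuation`.
#'
#' @param metrics a [gene_metrics()] table.
#' @param cfg an [analysis_config()].
#' @param treated,control sample names present in `metrics`.
#' @return Character vector of selected `tu_id`s.
#' @export
select_attenuated <- function(metrics, cfg = analysis_config(),
                              treated, control) {
  mt <- metrics[metrics$sample == treated, ]
  mc <- metrics[metrics$sample == control, ]
  if (nrow(mt) == 0L || nrow(mc) == 0L)
    stop("treated/control samples not found in metrics", call. = FALSE)
  mc <- mc[match(mt$tu_id, mc$tu_id), ]
  ok <- mt$length > cfg$min_len_attenuation &
    !is.na(mt$attenuation_index) & !is.na(mc$attenuation_index) &
    mc$attenuation_index > 0
  ratio <- mt$attenuation_index / mc$attenuation_index
  sort(mt$tu_id[ok & ratio >= cfg$attenuation_fold])
}

#' Select occupancy target genes
#'
#' Restricts to coding genes longer than `cfg$chip_min_len` and keeps those
#' whose mean occupancy is at least `cfg$chip_enrichment` times the average
#' over that universe (boundary inclusive).
#'
#' @param metrics a [gene_metrics()] table for one sample (or a subset with
#'   a single sample).
#' @param cfg an [analysis_config()].
#' @return Character vector of target `tu_id`s.
#' @export
chip_target_set <- function(metrics, cfg = analysis_config()) {
  if (length(unique(metrics$sample)) > 1L)
    stop("metrics must be restricted to a single sample", call. = FALSE)
  uni <- metrics[metrics$biotype == "coding" &
                   metrics$length > cfg$chip_min_len &
                   !is.na(metrics$chip_mean), ]
  if (nrow(uni) == 0L) return(character(0))
  thr <- cfg$chip_enrichment * mean(uni$chip_mean)
  sort(uni$tu_id[uni$chip_mean >= thr])
}

#' Write / read a gene metric table
#' @param metrics a [gene_metrics()] table.
#' @param path TSV file.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Base-composition profile around an anchor
#'
#' Per-position A/C/G/T frequencies on the sense strand of each unit,
#' anchored at the TSS or PAS (position 0 = the anchor base). Positions
#' falling outside a chromosome are dropped from the counts of that gene
#' only, so edge genes still contribute where they can.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param units transcription units (non-empty).
#' @param anchor `"TSS"` or `"PAS"`.
#' @param upstream,downstream bp before/after the anchor (window length
#'   `upstream + downstream + 1`).
#' @return Numeric matrix, rows A/C/G/T summing to 1 per counted column,
#'   columns named by signed offset.
#' @export
base_composition_profile <- function(genome, units, anchor = c("TSS", "PAS"),
                                     upstream = 100L, downstream = 100L) {
  anchor <- match.arg(anchor)
  if (length(units) == 0L) stop("empty gene set", call. = FALSE)
  seqs <- anchored_sequences(genome, units, anchor, upstream, downstream)
  cm <- Biostrings::consensusMatrix(seqs)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, upstream + downstream + 1L,
                   dimnames = list(bases, seq(-upstream, downstream)))
  for (b in bases) if (b %in% rownames(cm)) counts[b, ] <- cm[b, ]
  tot <- colSums(counts)
  tot[tot == 0] <- NA_real_
  sweep(counts, 2, tot, "/")
}

#' Sense-strand sequences around unit anchors (N-padded at chromosome
#' edges so all windows align)
#' @noRd
anchored_sequences <- function(genome, units, anchor, upstream, downstream) {
  w <- upstream + downstream + 1L
  strs <- vapply(seq_along(units), function(i) {
    u <- units[i]; m <- .unit_meta(u)
    pos <- if (anchor == "TSS") m$tss else m$pas
    clen <- Biostrings::width(genome[names(genome) == m$chrom])[1L]
    if (m$strand == "+") { s <- pos - upstream; e <- pos + downstream }
    else { s <- pos - downstream; e <- pos + upstream }
    cs <- max(1L, s); ce <- min(clen, e)
    if (ce < cs) return(strrep("N", w))
    core <- Biostrings::subseq(genome[[m$chrom]], cs, ce)
    pad_l <- cs - s; pad_r <- e - ce
    seq <- paste0(strrep("N", pad_l), as.character(core), strrep("N", pad_r))
    if (m$strand == "-")
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    seq
  }, character(1))
  Biostrings::DNAStringSet(strs)
}

#' Poly-T run enrichment between two gene sets
#'
#' Fraction of genes in each set whose anchored sense-strand window
#' contains at least one run of `min_run` or more consecutive T, plus the
#' a/b ratio. Long T runs downstream of the cleavage site are a sequence
#' signature of attenuation-prone genes.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param set_a,set_b transcription-unit `GRanges` (overlapping sets are
#'   allowed but warned about).
#' @param anchor `"TSS"` or `"PAS"`.
#' @param upstream,downstream window around the anchor, as in
#'   [base_composition_profile()].
#' @param min_run minimum run length (>= 2).
#' @return list with `fraction_a`, `fraction_b`, `ratio` and the per-set
#'   logical vectors `has_run_a`, `has_run_b`.
#' @export
polyt_run_enrichment <- function(genome, set_a, set_b, anchor = "PAS",
                                 upstream = 0L, downstream = 100L,
                                 min_run = 5L) {
  stopifnot(min_run >= 2L)
  ia <- S4Vectors::mcols(set_a)$tu_id; ib <- S4Vectors::mcols(set_b)$tu_id
  if (length(intersect(ia, ib)))
    warning("gene sets overlap", call. = FALSE)
  pat <- sprintf("T{%d,}", min_run)
  run_frac <- function(set) {
    s <- as.character(anchored_sequences(genome, set, anchor,
                                         as.integer(upstream),
                                         as.integer(downstream)))
    grepl(pat, s)
  }
  ha <- run_frac(set_a); hb <- run_frac(set_b)
  fa <- mean(ha); fb <- mean(hb)
  list(fraction_a = fa, fraction_b = fb,
       ratio = if (fb == 0) NA_real_ else fa / fb,
       has_run_a = ha, has_run_b = hb)
}
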