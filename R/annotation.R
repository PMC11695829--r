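#' Construct a set of transcription units
#'
#' A transcription unit (TU) is a stranded genomic interval with a TSS, a
#' PAS, a biotype and an exon structure. Units are held as a
#' [GenomicRanges::GRanges] (1-based, closed intervals) with metadata
#' columns `tu_id`, `biotype` and `exons` (an [IRanges::IRangesList] of
#' genomic exon intervals, sorted and non-overlapping within each unit).
#'
#' @param tu_id character vector of unique unit identifiers.
#' @param chrom chromosome names.
#' @param start,end 1-based closed genomic interval of each unit.
#' @param strand `"+"` or `"-"`.
#' @param biotype `"coding"` or `"noncoding"`.
#' @param exons optional list of two-column matrices / data.frames
#'   (start, end) or an `IRangesList`; defaults to single-exon units.
#' @param seqlengths optional named integer vector of chromosome lengths.
#'
#' @return A `GRanges` of transcription units.
#' @export
transcription_units <- function(tu_id, chrom, start, end, strand, biotype,
                                exons = NULL, seqlengths = NULL) {
  n <- length(tu_id)
  stopifnot(!anyDuplicated(tu_id), all(strand %in% c("+", "-")),
            all(biotype %in% c("coding", "noncoding")))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start),
                              end = as.integer(end)),
    strand = strand
  )
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  if (is.null(exons)) {
    ex <- IRanges::IRangesList(lapply(seq_len(n), function(i)
      IRanges::IRanges(BiocGenerics::start(gr)[i],
                       BiocGenerics::end(gr)[i])))
  } else if (methods::is(exons, "IRangesList")) {
    ex <- exons
  } else {
    ex <- IRanges::IRangesList(lapply(exons, function(e) {
      e <- as.matrix(as.data.frame(e)[, 1:2])
      IRanges::IRanges(start = as.integer(e[, 1]), end = as.integer(e[, 2]))
    }))
  }
  S4Vectors::mcols(gr)$tu_id <- as.character(tu_id)
  S4Vectors::mcols(gr)$biotype <- as.character(biotype)
  S4Vectors::mcols(gr)$exons <- ex
  validate_units(gr)
  gr
}

#' Validate transcription-unit invariants
#'
#' Checks widths >= 1, exon containment, sortedness and non-overlap.
#' @param units a `GRanges` built by [transcription_units()] or
#'   [load_annotation()].
#' @return The input, invisibly; stops on violation.
#' @export
validate_units <- function(units) {
  stopifnot(methods::is(units, "GRanges"))
  mc <- S4Vectors::mcols(units)
  need <- c("tu_id", "biotype", "exons")
  if (!all(need %in% names(mc)))
    stop("units must carry tu_id, biotype and exons metadata", call. = FALSE)
  if (any(BiocGenerics::width(units) < 1L))
    stop("transcription units must have length >= 1", call. = FALSE)
  if (!all(mc$biotype %in% c("coding", "noncoding")))
    stop("biotype must be coding or noncoding", call. = FALSE)
  if (!all(as.character(BiocGenerics::strand(units)) %in% c("+", "-")))
    stop("strand must be + or -", call. = FALSE)
  ex <- mc$exons
  us <- BiocGenerics::start(units); ue <- BiocGenerics::end(units)
  for (i in seq_along(units)) {
    e <- ex[[i]]
    if (length(e) == 0L)
      stop("unit ", mc$tu_id[i], " has no exons", call. = FALSE)
    if (min(BiocGenerics::start(e)) < us[i] || max(BiocGenerics::end(e)) > ue[i])
      stop("exon outside unit bounds for ", mc$tu_id[i], call. = FALSE)
    if (is.unsorted(BiocGenerics::start(e), strictly = TRUE) && length(e) > 1L)
      stop("exons not sorted for ", mc$tu_id[i], call. = FALSE)
    if (length(e) > 1L &&
        any(BiocGenerics::start(e)[-1L] <= BiocGenerics::end(e)[-length(e)]))
      stop("overlapping exons for ", mc$tu_id[i], call. = FALSE)
  }
  invisible(units)
}

#' TSS and PAS anchor positions
#'
#' The TSS is the 5' end of the unit in transcription orientation (genomic
#' start on `+`, end on `-`); the PAS is the 3' end.
#'
#' @param units transcription units (`GRanges`).
#' @return Integer vector of 1-based genomic positions.
#' @export
tss_position <- function(units) {
  plus <- as.character(BiocGenerics::strand(units)) == "+"
  ifelse(plus, BiocGenerics::start(units), BiocGenerics::end(units))
}

#' @rdname tss_position
#' @export
pas_position <- function(units) {
  plus <- as.character(BiocGenerics::strand(units)) == "+"
  ifelse(plus, BiocGenerics::end(units), BiocGenerics::start(units))
}

#' Intron intervals of a transcription unit
#'
#' @param unit a single transcription unit (length-1 `GRanges`).
#' @return An `IRanges` of genomic intron intervals (possibly empty),
#'   ordered by genomic position.
#' @export
unit_introns <- function(unit) {
  stopifnot(length(unit) == 1L)
  e <- S4Vectors::mcols(unit)$exons[[1L]]
  if (length(e) < 2L) return(IRanges::IRanges())
  IRanges::IRanges(start = BiocGenerics::end(e)[-length(e)] + 1L,
                   end = BiocGenerics::start(e)[-1L] - 1L)
}

#' Load a transcription-unit annotation
#'
#' Reads GFF3 (1-based closed, converted directly) or BED12 (0-based
#' half-open, shifted on import by rtracklayer) into the internal `GRanges`
#' representation. For GFF3, features of type `gene` define units and
#' `exon` features are attached through their `Parent` attribute (an
#' intermediate mRNA/transcript level is resolved when present); a
#' `biotype` or `gene_biotype` attribute of `"noncoding"` marks noncoding
#' units. For BED12, blocks become exons and records whose thick (CDS)
#' interval is empty are noncoding.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed12"`.
#' @return A validated transcription-unit `GRanges`.
#' @export
load_annotation <- function(path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gff <- tryCatch(rtracklayer::import(path, format = "gff3"),
                    error = function(e)
                      stop("GFF3 parse error in '", path, "': ",
                           conditionMessage(e), call. = FALSE))
    type <- as.character(gff$type)
    genes <- gff[type == "gene"]
    if (length(genes) == 0L)
      genes <- gff[type %in% c("mRNA", "transcript")]
    if (length(genes) == 0L)
      stop("no gene/mRNA/transcript features in '", path, "'", call. = FALSE)
    ids <- genes$ID
    if (is.null(ids) || anyNA(ids))
      stop("gene features must carry unique ID attributes", call. = FALSE)
    bio <- genes$biotype
    if (is.null(bio)) bio <- genes$gene_biotype
    if (is.null(bio)) bio <- rep("coding", length(genes))
    bio <- ifelse(is.na(bio) | bio != "noncoding", "coding", "noncoding")
    # map exon Parent -> gene, through one transcript level if needed
    tx <- gff[type %in% c("mRNA", "transcript")]
    tx2gene <- if (length(tx)) {
      stats::setNames(as.character(unlist(tx$Parent)), tx$ID)
    } else character()
    exons <- gff[type == "exon"]
    exmap <- vector("list", length(genes))
    names(exmap) <- ids
    if (length(exons)) {
      par <- as.character(unlist(exons$Parent))
      par <- ifelse(par %in% names(tx2gene), tx2gene[par], par)
      keep <- par %in% ids
      exons <- exons[keep]; par <- par[keep]
      sp <- split(IRanges::ranges(exons), factor(par, levels = ids))
      exmap <- lapply(sp, IRanges::reduce)  # reduce output is sorted
    }
    exlist <- IRanges::IRangesList(lapply(seq_along(genes), function(i) {
      e <- exmap[[ids[i]]]
      if (is.null(e) || length(e) == 0L)
        IRanges::IRanges(BiocGenerics::start(genes)[i],
                         BiocGenerics::end(genes)[i])
      else e
    }))
    transcription_units(
      tu_id = ids,
      chrom = as.character(GenomeInfoDb::seqnames(genes)),
      start = BiocGenerics::start(genes),
      end = BiocGenerics::end(genes),
      strand = as.character(BiocGenerics::strand(genes)),
      biotype = bio,
      exons = exlist
    )
  } else {
    bed <- tryCatch(rtracklayer::import(path, format = "bed"),
                    error = function(e)
                      stop("BED parse error in '", path, "': ",
                           conditionMessage(e), call. = FALSE))
    n <- length(bed)
    if (is.null(bed$blocks)) {
      exlist <- IRanges::IRangesList(lapply(seq_len(n), function(i)
        IRanges::IRanges(BiocGenerics::start(bed)[i],
                         BiocGenerics::end(bed)[i])))
    } else {
      # rtracklayer blocks are relative to the feature start
      exlist <- IRanges::shift(bed$blocks, BiocGenerics::start(bed) - 1L)
    }
    bio <- if (is.null(bed$thick)) rep("coding", n) else
      ifelse(BiocGenerics::width(bed$thick) >= 1L, "coding", "noncoding")
    ids <- if (is.null(bed$name)) sprintf("tu%04d", seq_len(n)) else bed$name
    transcription_units(
      tu_id = ids,
      chrom = as.character(GenomeInfoDb::seqnames(bed)),
      start = BiocGenerics::start(bed),
      end = BiocGenerics::end(bed),
      strand = as.character(BiocGenerics::strand(bed)),
      biotype = bio,
      exons = exlist
    )
  }
}

#' Select isolated coding genes
#'
#' Keeps coding units that have no other transcription unit (of any
#' biotype) on the same strand within `flank` bp upstream of the TSS or
#' downstream of the PAS. Because the flank is applied on both sides, the
#' test is equivalent to requiring that no other same-strand unit overlaps
#' the unit extended by `flank` bp at each end; containment counts as
#' overlap, and opposite-strand neighbours never disqualify.
#'
#' @param units transcription units (`GRanges`).
#' @param flank flank size in bp (>= 0); default per [analysis_config()].
#' @return The subset of `units` that are isolated coding genes.
#' @export
filter_isolated_coding <- function(units, flank = 250L) {
  stopifnot(flank >= 0L)
  coding <- units[S4Vectors::mcols(units)$biotype == "coding"]
  if (length(coding) == 0L) return(coding)
  flanked <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(coding),
    ranges = IRanges::IRanges(
      start = BiocGenerics::start(coding) - as.integer(flank),
      end = BiocGenerics::end(coding) + as.integer(flank)),
    strand = BiocGenerics::strand(coding)
  )
  hits <- GenomicRanges::findOverlaps(flanked, units, ignore.strand = FALSE)
  self <- S4Vectors::mcols(coding)$tu_id[S4Vectors::queryHits(hits)] ==
    S4Vectors::mcols(units)$tu_id[S4Vectors::subjectHits(hits)]
  bad <- unique(S4Vectors::queryHits(hits)[!self])
  coding[setdiff(seq_along(coding), bad)]
}

#' Scan a sequence for exact motif matches
#'
#' Reports every exact occurrence of each motif, including overlapping
#' occurrences; `N` in the sequence never matches.
#'
#' @param sequence a character string or [Biostrings::DNAString] over
#'   ACGTN.
#' @param motifs non-empty character vector of motifs (ACGT).
#' @return data.frame with columns `start` (1-based offset) and `motif`,
#'   ordered by position then motif.
#' @export
scan_motifs <- function(sequence, motifs) {
  if (length(motifs) == 0L) stop("motif set must be non-empty", call. = FALSE)
  s <- if (methods::is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(as.character(sequence))
  out <- lapply(unique(toupper(motifs)), function(m) {
    hits <- Biostrings::matchPattern(m, s, fixed = TRUE)
    if (length(hits) == 0L) return(NULL)
    data.frame(start = BiocGenerics::start(hits), motif = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(start = integer(), motif = character(),
                      stringsAsFactors = FALSE))
  out[order(out$start, out$motif), , drop = FALSE]
}

#' Read / write candidate PAS sites (BED6)
#'
#' Candidate cleavage sites are exchanged as BED6: the score column holds
#' the site's prominence (read support in the source atlas) and the name
#' column the identifier of the transcription unit the site belongs to.
#' Positions are converted between 0-based half-open BED and the 1-based
#' internal convention.
#'
#' @param path BED6 file.
#' @return data.frame with columns `chrom`, `position` (1-based),
#'   `strand`, `prominence`, `unit_id`.
#' @export
read_pas_bed <- function(path) {
  bed <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(bed)),
    position = BiocGenerics::start(bed),
    strand = as.character(BiocGenerics::strand(bed)),
    prominence = if (is.null(bed$score)) rep(0, length(bed)) else
      as.numeric(bed$score),
    unit_id = if (is.null(bed$name)) rep(NA_character_, length(bed)) else
      as.character(bed$name),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_pas_bed
#' @param sites data.frame of PAS sites as returned by [read_pas_bed()].
#' @export
write_pas_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$position, width = 1L),
    strand = sites$strand,
    name = sites$unit_id,
    score = sites$prominence
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Select the representative PAS site for a gene
#'
#' From candidate cleavage sites belonging to one transcription unit, keeps
#' those with a PAS motif (any member of `cfg$pas_motifs`) in the
#' `cfg$motif_upstream` bp immediately upstream of the site in
#' transcription orientation (the site base itself is excluded), then
#' returns the most prominent site; exact prominence ties are broken by
#' distance to the annotated transcript end, then by genomic coordinate.
#'
#' @param candidates data.frame of PAS sites (see [read_pas_bed()]); all
#'   rows must match the unit's chromosome and strand.
#' @param unit a single transcription unit.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param cfg an [analysis_config()].
#' @return A one-row data.frame, or `NULL` if no candidate passes.
#' @export
select_pas_site <- function(candidates, unit, genome, cfg = analysis_config()) {
  stopifnot(length(unit) == 1L, methods::is(genome, "DNAStringSet"))
  if (nrow(candidates) == 0L) return(NULL)
  chrom <- as.character(GenomeInfoDb::seqnames(unit))
  strand <- as.character(BiocGenerics::strand(unit))
  if (!all(candidates$chrom == chrom) || !all(candidates$strand == strand))
    stop("candidates must match the unit's chromosome and strand",
         call. = FALSE)
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not in genome", call. = FALSE)
  clen <- Biostrings::width(genome[names(genome) == chrom])[1L]
  if (any(candidates$position < 1L | candidates$position > clen))
    stop("PAS site outside genome bounds", call. = FALSE)
  w <- cfg$motif_upstream
  ok <- vapply(seq_len(nrow(candidates)), function(i) {
    p <- candidates$position[i]
    if (strand == "+") {
      from <- max(1L, p - w); to <- p - 1L
    } else {
      from <- p + 1L; to <- min(clen, p + w)
    }
    if (to < from) return(FALSE)
    s <- Biostrings::subseq(genome[[chrom]], start = from, end = to)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    nrow(scan_motifs(s, cfg$pas_motifs)) > 0L
  }, logical(1))
  passing <- candidates[ok, , drop = FALSE]
  if (nrow(passing) == 0L) return(NULL)
  dist_end <- abs(passing$position - pas_position(unit))
  ord <- order(-passing$prominence, dist_end, passing$position)
  passing[ord[1L], , drop = FALSE]
}
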