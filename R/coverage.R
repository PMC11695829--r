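#' Stranded base-resolution coverage
#'
#' Holds per-chromosome, per-strand nonnegative signal at base resolution.
#' Signal is stored run-length encoded ([S4Vectors::Rle] per chromosome);
#' dense vectors are extracted on demand, so long chromosomes with sparse
#' signal stay cheap.
#'
#' @param plus,minus named list of numeric vectors or `Rle` objects, one
#'   per chromosome, or `NULL` for all-zero signal on that strand.
#' @param seqlengths named integer vector of chromosome lengths.
#' @return An object of class `stranded_coverage`.
#' @export
stranded_coverage <- function(plus = NULL, minus = NULL, seqlengths) {
  stopifnot(!is.null(names(seqlengths)), all(seqlengths >= 1))
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  obj <- structure(
    list(plus = .as_rlelist(plus, seqlengths),
         minus = .as_rlelist(minus, seqlengths),
         seqlengths = seqlengths),
    class = "stranded_coverage")
  obj
}

.as_rlelist <- function(x, seqlengths) {
  out <- lapply(names(seqlengths), function(ch) {
    v <- if (is.null(x)) NULL else x[[ch]]
    if (is.null(v)) return(S4Vectors::Rle(0, seqlengths[[ch]]))
    r <- if (methods::is(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
    if (length(r) != seqlengths[[ch]])
      stop("coverage length for '", ch, "' (", length(r),
           ") != chromosome length (", seqlengths[[ch]], ")", call. = FALSE)
    r
  })
  names(out) <- names(seqlengths)
  out
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat("stranded_coverage:", length(x$seqlengths), "chromosome(s)\n")
  for (ch in names(x$seqlengths))
    cat(sprintf("  %s (%d bp)  mean+ %.4g  mean- %.4g\n", ch,
                x$seqlengths[[ch]], mean(x$plus[[ch]]), mean(x$minus[[ch]])))
  invisible(x)
}

.strand_slot <- function(strand) {
  if (!strand %in% c("+", "-")) stop("strand must be + or -", call. = FALSE)
  if (strand == "+") "plus" else "minus"
}

cov_rle <- function(cov, chrom, strand) {
  sl <- .strand_slot(strand)
  r <- cov[[sl]][[chrom]]
  if (is.null(r)) stop("unknown chromosome '", chrom, "'", call. = FALSE)
  r
}

#' Apply a function to every chromosome/strand of one or two coverages
#' @noRd
.cov_map <- function(a, f, b = NULL) {
  if (!is.null(b) && !identical(a$seqlengths, b$seqlengths))
    stop("coverage objects have mismatched chromosome sets", call. = FALSE)
  out <- a
  for (sl in c("plus", "minus"))
    for (ch in names(a$seqlengths))
      out[[sl]][[ch]] <- if (is.null(b)) f(a[[sl]][[ch]]) else
        f(a[[sl]][[ch]], b[[sl]][[ch]])
  out
}

#' Read a coverage track
#'
#' Imports a bedGraph (0-based half-open, converted on import) or bigWig
#' track as the signal of one strand. Intervals must be non-overlapping;
#' bases not covered by any interval are zero.
#'
#' @param path track file.
#' @param format `"bedgraph"` or `"bigwig"`.
#' @param strand which strand the track describes.
#' @param seqlengths chromosome lengths; if `NULL`, taken from the file
#'   header when available, otherwise from the largest covered position.
#' @return A `stranded_coverage` with the other strand all zero; combine
#'   strands with [merge_strands()].
#' @export
read_track <- function(path, format = c("bedgraph", "bigwig"),
                       strand = "+", seqlengths = NULL) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path,
                            format = ifelse(format == "bedgraph",
                                            "bedGraph", "BigWig"))
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  if (length(gr) > 1L) {
    same <- as.character(GenomeInfoDb::seqnames(gr))[-1L] ==
      as.character(GenomeInfoDb::seqnames(gr))[-length(gr)]
    if (any(same & (BiocGenerics::start(gr)[-1L] <=
                    BiocGenerics::end(gr)[-length(gr)])))
      stop("overlapping intervals in '", path, "'", call. = FALSE)
  }
  if (is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (anyNA(sl)) {
      mx <- vapply(split(BiocGenerics::end(gr),
                         as.character(GenomeInfoDb::seqnames(gr))),
                   max, numeric(1))
      sl[is.na(sl)] <- mx[names(sl)[is.na(sl)]]
    }
    seqlengths <- sl
  }
  covs <- GenomicRanges::coverage(
    GenomeInfoDb::keepSeqlevels(gr, names(seqlengths),
                                pruning.mode = "coarse"),
    weight = gr$score, width = as.list(seqlengths))
  lst <- stats::setNames(lapply(names(seqlengths),
                                function(ch) covs[[ch]]),
                         names(seqlengths))
  if (strand == "+") stranded_coverage(plus = lst, seqlengths = seqlengths)
  else stranded_coverage(minus = lst, seqlengths = seqlengths)
}

#' @rdname read_track
#' @param cov a `stranded_coverage`.
#' @export
write_track <- function(cov, path, format = c("bedgraph", "bigwig"),
                        strand = "+") {
  format <- match.arg(format)
  sl <- .strand_slot(strand)
  grl <- lapply(names(cov$seqlengths), function(ch) {
    r <- cov[[sl]][[ch]]
    gr <- methods::as(stats::setNames(IRanges::RleList(r), ch), "GRanges")
    gr[gr$score != 0]
  })
  gr <- suppressWarnings(do.call(c, grl))
  GenomeInfoDb::seqlengths(gr) <- cov$seqlengths[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path,
                      format = ifelse(format == "bedgraph",
                                      "bedGraph", "BigWig"))
  invisible(path)
}

#' Pad a coverage to a common chromosome layout
#'
#' Extends chromosomes with zeros and adds missing all-zero chromosomes so
#' tracks read from files without declared lengths can be combined.
#' @param cov a `stranded_coverage`.
#' @param seqlengths target layout; every existing chromosome must fit.
#' @return The padded `stranded_coverage`.
#' @export
expand_seqlengths <- function(cov, seqlengths) {
  out <- list()
  for (sl in c("plus", "minus")) {
    out[[sl]] <- lapply(stats::setNames(names(seqlengths),
                                        names(seqlengths)), function(ch) {
      L <- seqlengths[[ch]]
      r <- cov[[sl]][[ch]]
      if (is.null(r)) return(S4Vectors::Rle(0, L))
      if (length(r) > L)
        stop("chromosome '", ch, "' longer than target layout",
             call. = FALSE)
      if (length(r) < L) r <- c(r, S4Vectors::Rle(0, L - length(r)))
      r
    })
  }
  stranded_coverage(plus = out$plus, minus = out$minus,
                    seqlengths = seqlengths)
}

#' Combine the strands of two single-strand coverages
#' @param plus_cov,minus_cov `stranded_coverage` objects carrying the plus
#'   and minus strand signal respectively.
#' @return A `stranded_coverage` with both strands populated.
#' @export
merge_strands <- function(plus_cov, minus_cov) {
  if (!identical(plus_cov$seqlengths, minus_cov$seqlengths))
    stop("mismatched chromosome sets", call. = FALSE)
  stranded_coverage(plus = plus_cov$plus, minus = minus_cov$minus,
                    seqlengths = plus_cov$seqlengths)
}

#' Mean per-base signal in a window
#'
#' @param cov a `stranded_coverage`.
#' @param chrom chromosome.
#' @param start,end 1-based closed window, `1 <= start <= end <= length`.
#' @param strand strand to read.
#' @return Mean signal per base over the window.
#' @export
window_density <- function(cov, chrom, start, end, strand = "+") {
  r <- cov_rle(cov, chrom, strand)
  if (start < 1L || end < start || end > length(r))
    stop("invalid window [", start, ", ", end, "] on '", chrom, "' (length ",
         length(r), ")", call. = FALSE)
  sum(S4Vectors::window(r, start, end)) / (end - start + 1L)
}

#' Vectorised window means (internal fast path)
#' @noRd
window_means <- function(cov, chrom, starts, ends, strand) {
  r <- cov_rle(cov, chrom, strand)
  IRanges::viewMeans(IRanges::Views(r, IRanges::IRanges(starts, ends)))
}

#' Spike-in normalization factors
#'
#' For each library, the factor is the reference library's spike-in read
#' count divided by that library's spike-in count, so the reference maps to
#' exactly 1 and multiplying each sample's signal by its factor equalises
#' spike-in representation across samples. Invariant to uniform rescaling
#' of all spike counts.
#'
#' @param counts data.frame with columns `sample_id`, `experimental_reads`,
#'   `spikein_reads`.
#' @param reference `sample_id` of the reference library.
#' @return Named numeric vector of positive factors.
#' @export
spikein_factors <- function(counts, reference) {
  stopifnot(all(c("sample_id", "experimental_reads", "spikein_reads") %in%
                  names(counts)))
  if (!reference %in% counts$sample_id)
    stop("reference sample '", reference, "' not present", call. = FALSE)
  if (any(counts$spikein_reads <= 0))
    stop("library with zero spike-in reads cannot be normalised",
         call. = FALSE)
  if (any(counts$experimental_reads < 0))
    stop("negative read counts", call. = FALSE)
  ref <- counts$spikein_reads[match(reference, counts$sample_id)]
  stats::setNames(ref / counts$spikein_reads, counts$sample_id)
}

#' Apply normalization factors to a track
#'
#' Every base is multiplied by `spike_factor`. The sequencing-depth
#' normalise-then-reverse sequence used upstream of spike-in scaling is
#' algebraically the identity, so `depth_factor` is accepted and logged but
#' the net multiplier is `spike_factor` alone.
#'
#' @param cov a `stranded_coverage`.
#' @param depth_factor sequencing-depth factor (> 0), logged only.
#' @param spike_factor spike-in factor (> 0), the applied multiplier.
#' @param verbose log the factors to the console.
#' @return The scaled `stranded_coverage`.
#' @export
apply_normalization <- function(cov, depth_factor = 1, spike_factor = 1,
                                verbose = FALSE) {
  if (depth_factor <= 0 || spike_factor <= 0)
    stop("normalization factors must be positive", call. = FALSE)
  if (verbose)
    message(sprintf(
      "depth factor %.6g applied and reversed (net 1); spike factor %.6g applied",
      depth_factor, spike_factor))
  .cov_map(cov, function(r) r * spike_factor)
}

#' Background subtraction for occupancy tracks
#'
#' Per base `max(ip - input, 0)`: only positive values are retained, so the
#' result satisfies the nonnegativity invariant. Both tracks must be on the
#' same (spike-normalised) scale and genome.
#'
#' @param ip,input `stranded_coverage` objects.
#' @return The clamped difference track.
#' @export
chip_input_subtract <- function(ip, input) {
  .cov_map(ip, function(a, b) {
    d <- a - b
    d[d < 0] <- 0
    d
  }, input)
}

#' Average replicate tracks
#'
#' @param tracks non-empty list of `stranded_coverage` objects on a common
#'   genome.
#' @return Per-base arithmetic mean track.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) == 0L) stop("need at least one track", call. = FALSE)
  acc <- tracks[[1L]]
  if (length(tracks) > 1L)
    for (i in 2L:length(tracks))
      acc <- .cov_map(acc, `+`, tracks[[i]])
  .cov_map(acc, function(r) r / length(tracks))
}

#' Adjust occupancy for global polymerase change
#'
#' Scales a factor's occupancy track by the ratio of RNA polymerase II
#' signal between control and treated samples, so a factor's apparent
#' occupancy change is read relative to the polymerase it travels with.
#'
#' @param target `stranded_coverage` to adjust.
#' @param polII_treated_mean,polII_control_mean mean Pol II densities over
#'   the analysis gene set in the treated and control samples (> 0).
#' @return The adjusted track (every base multiplied by
#'   `polII_control_mean / polII_treated_mean`).
#' @export
occupancy_adjust <- function(target, polII_treated_mean, polII_control_mean) {
  if (polII_treated_mean <= 0 || polII_control_mean <= 0)
    stop("Pol II means must be positive", call. = FALSE)
  .cov_map(target, function(r) r * (polII_control_mean / polII_treated_mean))
}

#' Multiply a track by a positive scalar
#' @param cov a `stranded_coverage`.
#' @param factor positive scalar.
#' @return Scaled track.
#' @export
scale_coverage <- function(cov, factor) {
  stopifnot(factor > 0)
  .cov_map(cov, function(r) r * factor)
}

#' Read a sample sheet
#'
#' Tab-separated table with columns `sample_id`, `condition`, `plus_track`,
#' `minus_track`, `experimental_reads`, `spikein_reads`. Track paths are
#' resolved relative to the sheet's directory.
#'
#' @param path TSV file.
#' @return data.frame with absolute track paths.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "plus_track", "minus_track",
            "experimental_reads", "spikein_reads")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  base <- dirname(normalizePath(path))
  for (col in c("plus_track", "minus_track")) {
    rel <- !grepl("^(/|[A-Za-z]:)", sheet[[col]])
    sheet[[col]][rel] <- file.path(base, sheet[[col]][rel])
  }
  sheet
}
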