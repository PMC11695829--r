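#' Signal matrices for metagene analysis
#'
#' A `signal_matrix` is a numeric matrix (rows = genes/anchors, columns =
#' positional bins) carrying a `bins` attribute that records each column's
#' segment (`upstream`, `body`, `downstream`) and oriented offset, so two
#' matrices can be checked for scheme compatibility before being combined.
#'
#' @name signal_matrix
NULL

new_signal_matrix <- function(values, bins, skipped = character(0)) {
  stopifnot(ncol(values) == nrow(bins))
  structure(values, bins = bins, skipped = skipped,
            class = c("signal_matrix", class(values)))
}

#' @export
print.signal_matrix <- function(x, ...) {
  b <- attr(x, "bins")
  cat(sprintf("signal_matrix: %d rows x %d bins (%s)\n", nrow(x), ncol(x),
              paste(sprintf("%s:%d", unique(b$segment),
                            tabulate(factor(b$segment,
                                            unique(b$segment)))),
                    collapse = ", ")))
  sk <- attr(x, "skipped")
  if (length(sk)) cat("  skipped units:", length(sk), "\n")
  invisible(x)
}

#' Column scheme of a signal matrix
#' @param m a `signal_matrix`.
#' @return data.frame with columns `segment` and `offset`.
#' @export
matrix_bins <- function(m) attr(m, "bins")

#' Dense oriented signal with NA padding outside the chromosome
#' @noRd
.dense_oriented <- function(cov, chrom, strand, gstart, gend) {
  r <- cov_rle(cov, chrom, strand)
  clen <- length(r)
  cs <- max(1L, gstart); ce <- min(clen, gend)
  core <- if (ce >= cs) as.numeric(S4Vectors::window(r, cs, ce)) else numeric(0)
  v <- c(rep(NA_real_, cs - gstart), core, rep(NA_real_, gend - ce))
  if (strand == "-") rev(v) else v
}

.bin_means <- function(v, boundaries) {
  vapply(seq_len(length(boundaries) - 1L), function(i) {
    seg <- v[(boundaries[i] + 1L):boundaries[i + 1L]]
    if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
  }, numeric(1))
}

#' Gene-body-scaled signal matrix
#'
#' For each unit, extracts a fixed-size upstream flank (before the TSS), the
#' gene body between `trim` bp after the TSS and `trim` bp before the PAS
#' rescaled into `n_body_bins` equal-length bins, and a fixed-size
#' downstream flank (after the PAS), all in transcription orientation. Each
#' cell is the mean per-base density over its span, so two genes with the
#' same signal shape at different lengths produce identical body rows.
#'
#' @param cov a [stranded_coverage()].
#' @param units transcription units; units not longer than
#'   `2 * trim + n_body_bins` are skipped (ids recorded in the `skipped`
#'   attribute).
#' @param n_body_bins number of scaled gene-body bins.
#' @param upstream,downstream flank sizes in bp (multiples of the
#'   respective bin sizes).
#' @param trim bp discarded after the TSS and before the PAS.
#' @param up_binsize,down_binsize flank bin widths in bp.
#' @return A [signal_matrix] with one row per retained unit.
#' @export
scaled_matrix <- function(cov, units, n_body_bins = 100L, upstream = 500L,
                          downstream = 500L, trim = 250L,
                          up_binsize = 10L, down_binsize = 10L) {
  stopifnot(upstream %% up_binsize == 0L, downstream %% down_binsize == 0L,
            n_body_bins >= 1L)
  n_up <- upstream %/% up_binsize
  n_dn <- downstream %/% down_binsize
  ids <- S4Vectors::mcols(units)$tu_id
  keep <- BiocGenerics::width(units) > 2L * trim + n_body_bins
  skipped <- ids[!keep]
  units <- units[keep]; ids <- ids[keep]
  rows <- lapply(seq_along(units), function(i) {
    m <- .unit_meta(units[i])
    clen <- cov$seqlengths[[m$chrom]]
    # upstream flank: offsets [-upstream, -1] relative to TSS
    up_w <- if (m$strand == "+")
      c(m$tss - upstream, m$tss - 1L) else c(m$tss + 1L, m$tss + upstream)
    up_v <- .dense_oriented(cov, m$chrom, m$strand, up_w[1L], up_w[2L])
    up <- .bin_means(up_v, seq(0L, upstream, by = up_binsize))
    # body: offsets [trim, len-1-trim] relative to TSS
    bs <- BiocGenerics::start(units[i]) + trim
    be <- BiocGenerics::end(units[i]) - trim
    body_v <- .dense_oriented(cov, m$chrom, m$strand, bs, be)
    lb <- length(body_v)
    bounds <- round(seq(0, lb, length.out = n_body_bins + 1L))
    body <- .bin_means(body_v, bounds)
    # downstream flank: offsets [1, downstream] relative to PAS
    dn_w <- if (m$strand == "+")
      c(m$pas + 1L, m$pas + downstream) else c(m$pas - downstream, m$pas - 1L)
    dn_v <- .dense_oriented(cov, m$chrom, m$strand, dn_w[1L], dn_w[2L])
    dn <- .bin_means(dn_v, seq(0L, downstream, by = down_binsize))
    c(up, body, dn)
  })
  vals <- do.call(rbind, rows)
  if (is.null(vals)) vals <- matrix(numeric(0), 0L, n_up + n_body_bins + n_dn)
  rownames(vals) <- ids
  bins <- data.frame(
    segment = rep(c("upstream", "body", "downstream"),
                  c(n_up, n_body_bins, n_dn)),
    offset = c(seq(-upstream, -up_binsize, by = up_binsize),
               seq_len(n_body_bins), seq(down_binsize, downstream,
                                         by = down_binsize)),
    stringsAsFactors = FALSE)
  new_signal_matrix(vals, bins, skipped)
}

#' Anchor-centred signal matrix
#'
#' Unscaled matrix of binned density around a set of anchor positions
#' (e.g. PAS sites), in transcription orientation, with offset 0 at the
#' anchor base. Windows truncated by a chromosome end contribute `NA`
#' cells.
#'
#' @param cov a [stranded_coverage()].
#' @param anchors data.frame with columns `unit_id`, `chrom`, `position`,
#'   `strand`.
#' @param upstream,downstream bp before/after the anchor (multiples of
#'   `binsize`); the window covers offsets `[-upstream, downstream - 1]`.
#' @param binsize bin width in bp.
#' @return A [signal_matrix].
#' @export
anchored_matrix <- function(cov, anchors, upstream = 500L,
                            downstream = 500L, binsize = 10L) {
  stopifnot(upstream %% binsize == 0L, downstream %% binsize == 0L)
  w <- upstream + downstream
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    ch <- anchors$chrom[i]; st <- anchors$strand[i]; p <- anchors$position[i]
    win <- if (st == "+") c(p - upstream, p + downstream - 1L) else
      c(p - downstream + 1L, p + upstream)
    v <- .dense_oriented(cov, ch, st, win[1L], win[2L])
    .bin_means(v, seq(0L, w, by = binsize))
  })
  vals <- do.call(rbind, rows)
  rownames(vals) <- anchors$unit_id
  bins <- data.frame(segment = "anchored",
                     offset = seq(-upstream, downstream - binsize,
                                  by = binsize),
                     stringsAsFactors = FALSE)
  new_signal_matrix(vals, bins)
}

#' Elementwise log2 ratio of two signal matrices
#'
#' `log2((a + p) / (b + p))` with pseudocount `p` in units of per-base
#' density; both matrices must share rows and binning scheme.
#'
#' @param a,b [signal_matrix] objects on the same scheme.
#' @param pseudocount positive pseudocount.
#' @return A [signal_matrix] of log2 ratios.
#' @export
log2_ratio <- function(a, b, pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  if (!identical(dim(a), dim(b)) ||
      !identical(matrix_bins(a), matrix_bins(b)) ||
      !identical(rownames(a), rownames(b)))
    stop("signal matrices have different schemes", call. = FALSE)
  vals <- log2((unclass(a) + pseudocount) / (unclass(b) + pseudocount))
  new_signal_matrix(vals, matrix_bins(a))
}

#' Metagene profile with bootstrap confidence band
#'
#' Columnwise mean over genes plus a seeded percentile-bootstrap band
#' (resampling genes with replacement).
#'
#' @param m a [signal_matrix] with at least one row.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for resampling.
#' @return data.frame with `segment`, `offset`, `mean`, `lower`, `upper`
#'   (`lower`/`upper` are `NA` for a single-row matrix).
#' @export
profile_with_ci <- function(m, level = 0.95, n_boot = 1000L, seed = 1L) {
  stopifnot(nrow(m) >= 1L, level > 0, level < 1)
  vals <- unclass(m)
  mu <- colMeans(vals, na.rm = TRUE)
  bins <- matrix_bins(m)
  if (nrow(vals) < 2L) {
    return(data.frame(bins, mean = mu, lower = NA_real_, upper = NA_real_))
  }
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, ncol(vals))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(vals), replace = TRUE)
    boots[b, ] <- colMeans(vals[idx, , drop = FALSE], na.rm = TRUE)
  }
  alpha <- (1 - level) / 2
  qs <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  data.frame(bins, mean = mu, lower = qs[1L, ], upper = qs[2L, ])
}

#' Write a signal matrix as TSV
#'
#' The header line (prefixed `#`) records the binning scheme so the matrix
#' can be interpreted without the generating call.
#' @param m a [signal_matrix].
#' @param path output TSV.
#' @export
write_signal_matrix <- function(m, path) {
  b <- matrix_bins(m)
  hdr <- paste0("# bins\t",
                paste(sprintf("%s:%d", b$segment, b$offset), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(tu_id = rownames(m), unclass(m),
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a metagene profile with its confidence band
#'
#' Convenience base-graphics plot; the analysis output is the data.frame
#' from [profile_with_ci()], not the figure.
#' @param profile output of [profile_with_ci()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_metagene <- function(profile, ...) {
  x <- seq_len(nrow(profile))
  graphics::plot(x, profile$mean, type = "n",
                 xlab = "bin", ylab = "mean density", ...)
  if (!all(is.na(profile$lower)))
    graphics::polygon(c(x, rev(x)), c(profile$lower, rev(profile$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  graphics::lines(x, profile$mean, col = "steelblue4", lwd = 2)
  invisible(profile)
}

#' Heatmap of a signal matrix
#'
#' Rows ordered by descending mean of `order_by` (default: the matrix
#' itself), mirroring the usual presentation of per-gene log2-ratio
#' matrices.
#' @param m a [signal_matrix].
#' @param order_by optional matrix supplying the row ordering statistic.
#' @param ... passed to [graphics::image()].
#' @export
plot_signal_heatmap <- function(m, order_by = NULL, ...) {
  ob <- if (is.null(order_by)) m else order_by
  ord <- order(rowMeans(unclass(ob), na.rm = TRUE), decreasing = TRUE)
  vals <- unclass(m)[ord, , drop = FALSE]
  graphics::image(t(vals[rev(seq_len(nrow(vals))), , drop = FALSE]),
                  xlab = "bin", ylab = "gene", axes = FALSE, ...)
  invisible(ord)
}
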