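# Independent brute-force oracles and small builders used across tests.
# Oracles deliberately avoid the package's fast paths: plain loops over
# dense vectors, all-pairs scans, naive string matching.

# a stranded_coverage from plain per-strand vectors on one chromosome
cov1 <- function(plus = NULL, minus = NULL, len = NULL, chrom = "chrI") {
  if (is.null(len)) len <- max(length(plus), length(minus))
  if (!is.null(plus) && length(plus) < len) plus <- c(plus, rep(0, len - length(plus)))
  if (!is.null(minus) && length(minus) < len) minus <- c(minus, rep(0, len - length(minus)))
  stranded_coverage(
    plus = if (is.null(plus)) NULL else stats::setNames(list(plus), chrom),
    minus = if (is.null(minus)) NULL else stats::setNames(list(minus), chrom),
    seqlengths = stats::setNames(len, chrom))
}

dense_cov <- function(cov, chrom, strand) {
  as.numeric(cov[[if (strand == "+") "plus" else "minus"]][[chrom]])
}

# single-gene unit set builder
tu <- function(id = "g1", start, end, strand = "+", biotype = "coding",
               exons = NULL, chrom = "chrI", len = NULL) {
  transcription_units(id, chrom, start, end, strand, biotype,
                      exons = if (is.null(exons)) NULL else list(exons),
                      seqlengths = if (is.null(len)) NULL else
                        stats::setNames(len, chrom))
}

# per-base loop density oracle
naive_density <- function(v, start, end) mean(v[start:end])

# naive sliding-window motif scan
naive_scan <- function(seq, motifs) {
  chars <- strsplit(seq, "")[[1]]
  out <- list()
  for (m in unique(motifs)) {
    k <- nchar(m)
    mm <- strsplit(m, "")[[1]]
    if (length(chars) < k) next
    for (i in seq_len(length(chars) - k + 1)) {
      if (all(chars[i:(i + k - 1)] == mm))
        out[[length(out) + 1]] <- data.frame(start = i, motif = m,
                                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(start = integer(), motif = character(),
                                      stringsAsFactors = FALSE))
  res <- res[order(res$start, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# O(n^2) all-pairs isolation oracle: coding unit kept iff no other unit on
# the same strand overlaps [start - flank, end + flank]
naive_isolated <- function(df, flank) {
  keep <- character(0)
  for (i in seq_len(nrow(df))) {
    if (df$biotype[i] != "coding") next
    lo <- df$start[i] - flank; hi <- df$end[i] + flank
    clash <- FALSE
    for (j in seq_len(nrow(df))) {
      if (j == i) next
      if (df$chrom[j] != df$chrom[i] || df$strand[j] != df$strand[i]) next
      if (df$start[j] <= hi && df$end[j] >= lo) { clash <- TRUE; break }
    }
    if (!clash) keep <- c(keep, df$tu_id[i])
  }
  sort(keep)
}

# random annotation as a data.frame (may overlap freely)
random_annotation <- function(n, chrom_len = 50000L, n_chrom = 2L) {
  chroms <- paste0("chr", seq_len(n_chrom))
  start <- 200L + sample.int(chrom_len - 2500L, n, replace = TRUE)
  len <- sample(200:1500, n, replace = TRUE)
  data.frame(tu_id = sprintf("r%04d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             biotype = sample(c("coding", "noncoding"), n, replace = TRUE,
                              prob = c(0.8, 0.2)),
             stringsAsFactors = FALSE)
}

units_from_df <- function(df, chrom_lengths = NULL) {
  transcription_units(df$tu_id, df$chrom, df$start, df$end, df$strand,
                      df$biotype, seqlengths = chrom_lengths)
}

# mirror transform: reverse-complement the genome, flip all coordinates
# and strands. Position p on a chromosome of length L maps to L + 1 - p.
mirror_units_df <- function(df, chrom_lengths) {
  L <- chrom_lengths[df$chrom]
  out <- df
  out$start <- as.integer(L + 1L - df$end)
  out$end <- as.integer(L + 1L - df$start)
  out$strand <- ifelse(df$strand == "+", "-", "+")
  out
}

mirror_cov <- function(cov) {
  sl <- cov$seqlengths
  stranded_coverage(
    plus = lapply(stats::setNames(names(sl), names(sl)),
                  function(ch) rev(as.numeric(cov$minus[[ch]]))),
    minus = lapply(stats::setNames(names(sl), names(sl)),
                   function(ch) rev(as.numeric(cov$plus[[ch]]))),
    seqlengths = sl)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
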