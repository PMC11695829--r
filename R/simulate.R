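#' Simulation parameters and ground truth
#'
#' [make_genome_annotation()] builds a random genome with non-overlapping
#' transcription units and a `SimulationTruth` list recording, per gene,
#' its expression level, planted attenuation (5'/body ratio), readthrough
#' tail length-scales, per-intron retention fractions and sequence
#' plantings, so every downstream index is analytically predictable.
#'
#' Defaults emulate the design of the fission-yeast degron experiments:
#' two 500 kb chromosomes, 200 genes, 10% of genes attenuated (planted
#' ratio 3) in the depleted condition, 20% of genes with 1-3 introns,
#' readthrough tails beyond the PAS, a global transcription loss in the
#' depleted condition, and a 100:1 experimental:spike-in library mixture.
#'
#' @param n_genes number of transcription units.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param gene_length_range min/max gene length (bp), drawn log-uniformly.
#' @param spacing_range min/max gap between consecutive genes (bp).
#' @param intron_fraction fraction of genes carrying 1-3 introns.
#' @param intron_length_range min/max intron length (bp).
#' @param attenuation_fraction fraction of genes attenuated when depleted.
#' @param attenuation_ratio planted 5'/body density ratio for attenuated
#'   genes in the depleted condition.
#' @param attenuation_window bp of elevated 5' signal (matches the
#'   TSS window of the attenuation index).
#' @param readthrough_fraction fraction of genes with a long readthrough
#'   tail in the depleted condition.
#' @param tail_scale_control,tail_scale_depleted exponential tail
#'   length-scales (bp) beyond the PAS; the depleted value applies only to
#'   planted readthrough genes.
#' @param retention_control,retention_depleted per-intron retention
#'   fractions by condition.
#' @param expression_meanlog,expression_sdlog log-normal parameters of the
#'   per-gene expected body coverage (defaults give mean body coverage
#'   near 20).
#' @param global_scale_depleted multiplier on all expression in the
#'   depleted condition (global elongation/synthesis loss).
#' @param spike_fraction spike-in:experimental RNA mixing fraction
#'   (default 1/101, i.e. a 100:1 mixture).
#' @param pas_motif_fraction fraction of genes with a PAS motif planted
#'   26-31 bp upstream of the annotated end (sense strand).
#' @param t_tract_fraction fraction of genes with a poly-T tract planted
#'   downstream of the PAS on the sense strand.
#' @param t_tract_offset,t_tract_length position (bp after PAS) and length
#'   of the planted tract.
#' @param noncoding_fraction fraction of units annotated noncoding.
#' @param seed RNG seed; all outputs are reproducible given the seed.
#'
#' @return list with `genome` ([Biostrings::DNAStringSet]), `units`
#'   (transcription-unit `GRanges`) and `truth` (the ground-truth list).
#' @export
make_genome_annotation <- function(n_genes = 200L,
                                   chrom_lengths = c(chrI = 500000L,
                                                     chrII = 500000L),
                                   gene_length_range = c(700L, 4000L),
                                   spacing_range = c(1000L, 3000L),
                                   intron_fraction = 0.2,
                                   intron_length_range = c(60L, 200L),
                                   attenuation_fraction = 0.1,
                                   attenuation_ratio = 3,
                                   attenuation_window = 300L,
                                   readthrough_fraction = 0.3,
                                   tail_scale_control = 40,
                                   tail_scale_depleted = 800,
                                   retention_control = 0.05,
                                   retention_depleted = 0.3,
                                   expression_meanlog = log(20),
                                   expression_sdlog = 0.5,
                                   global_scale_depleted = 0.6,
                                   spike_fraction = 1 / 101,
                                   pas_motif_fraction = 1.0,
                                   t_tract_fraction = 0,
                                   t_tract_offset = 20L,
                                   t_tract_length = 8L,
                                   noncoding_fraction = 0,
                                   seed = 1L) {
  set.seed(seed)
  chroms <- names(chrom_lengths)
  stopifnot(!is.null(chroms), n_genes >= 1L)
  # place genes chromosome by chromosome with random gaps
  lens <- round(exp(stats::runif(n_genes, log(gene_length_range[1L]),
                                 log(gene_length_range[2L]))))
  per_chrom <- split(seq_len(n_genes),
                     rep_len(seq_along(chroms), n_genes))
  rows <- list()
  for (ci in seq_along(chroms)) {
    idx <- per_chrom[[ci]]
    pos <- 1L
    for (i in idx) {
      gap <- sample(spacing_range[1L]:spacing_range[2L], 1L)
      start <- pos + gap
      end <- start + lens[i] - 1L
      if (end + spacing_range[1L] > chrom_lengths[[ci]])
        stop("infeasible packing: genes exceed chromosome '", chroms[ci],
             "'", call. = FALSE)
      rows[[i]] <- data.frame(tu_id = sprintf("gene%03d", i),
                              chrom = chroms[ci], start = start, end = end,
                              strand = sample(c("+", "-"), 1L),
                              stringsAsFactors = FALSE)
      pos <- end
    }
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chrom, genes$start), ]
  n <- nrow(genes)
  genes$biotype <- ifelse(stats::runif(n) < noncoding_fraction,
                          "noncoding", "coding")
  genes$expression <- stats::rlnorm(n, expression_meanlog, expression_sdlog)
  genes$attenuated <- stats::runif(n) < attenuation_fraction &
    (genes$end - genes$start + 1L) > 2L * attenuation_window
  genes$attenuation_ratio <- ifelse(genes$attenuated, attenuation_ratio, 1)
  genes$readthrough <- stats::runif(n) < readthrough_fraction
  genes$tail_scale_control <- tail_scale_control
  genes$tail_scale_depleted <- ifelse(genes$readthrough,
                                      tail_scale_depleted,
                                      tail_scale_control)
  genes$has_pas_motif <- stats::runif(n) < pas_motif_fraction
  genes$has_t_tract <- stats::runif(n) < t_tract_fraction

  # exon/intron structure
  exlist <- vector("list", n)
  introns <- vector("list", n)
  names(introns) <- genes$tu_id
  for (i in seq_len(n)) {
    glen <- genes$end[i] - genes$start[i] + 1L
    n_int <- if (stats::runif(1) < intron_fraction &&
                 glen > 4L * (intron_length_range[2L] + 150L))
      sample(1:3, 1L) else 0L
    if (n_int == 0L) {
      exlist[[i]] <- IRanges::IRanges(genes$start[i], genes$end[i])
      introns[[i]] <- data.frame(start = integer(), end = integer(),
                                 retention_control = numeric(),
                                 retention_depleted = numeric())
      next
    }
    ilens <- sample(intron_length_range[1L]:intron_length_range[2L], n_int,
                    replace = TRUE)
    # split the gene into n_int + 1 exon segments of >= 100 bp
    avail <- glen - sum(ilens)
    cuts <- sort(sample(100:(avail - 100L), n_int))
    cuts <- cuts[!duplicated(cuts)]
    while (length(cuts) < n_int || any(diff(c(0L, cuts, avail)) < 100L)) {
      cuts <- sort(sample(100:(avail - 100L), n_int))
      cuts <- cuts[!duplicated(cuts)]
    }
    exlens <- diff(c(0L, cuts, avail))
    starts <- genes$start[i] +
      cumsum(c(0L, exlens[-length(exlens)] + ilens)) # exon starts
    exlist[[i]] <- IRanges::IRanges(starts, starts + exlens - 1L)
    istart <- starts[-length(starts)] + exlens[-length(exlens)]
    introns[[i]] <- data.frame(start = istart, end = istart + ilens - 1L,
                               retention_control = retention_control,
                               retention_depleted = retention_depleted)
  }
  units <- transcription_units(genes$tu_id, genes$chrom, genes$start,
                               genes$end, genes$strand, genes$biotype,
                               exons = IRanges::IRangesList(exlist),
                               seqlengths = chrom_lengths)
  # genome with planted PAS motifs and optional T tracts
  seqs <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), chrom_lengths[[ch]], replace = TRUE))
  names(seqs) <- chroms
  pas <- ifelse(genes$strand == "+", genes$end, genes$start)
  for (i in seq_len(n)) {
    ch <- genes$chrom[i]
    if (genes$has_pas_motif[i]) {
      if (genes$strand[i] == "+")
        seqs[[ch]][(pas[i] - 31L):(pas[i] - 26L)] <-
          strsplit("AATAAA", "")[[1L]]
      else
        seqs[[ch]][(pas[i] + 26L):(pas[i] + 31L)] <-
          strsplit("TTTATT", "")[[1L]]
    }
    if (genes$has_t_tract[i]) {
      off <- t_tract_offset; len <- t_tract_length
      if (genes$strand[i] == "+")
        seqs[[ch]][(pas[i] + off):(pas[i] + off + len - 1L)] <- "T"
      else
        seqs[[ch]][(pas[i] - off - len + 1L):(pas[i] - off)] <- "A"
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms
  truth <- list(genes = genes, introns = introns,
                attenuation_window = as.integer(attenuation_window),
                global_scale_depleted = global_scale_depleted,
                spike_fraction = spike_fraction,
                chrom_lengths = as.list(chrom_lengths),
                seed = seed)
  list(genome = genome, units = units, truth = truth)
}

#' Expected per-base signal of one gene
#'
#' Deterministic expectation used by the simulator and by tests that
#' predict index values analytically: a gene-body plateau at the expression
#' level, introns reduced to the retention fraction, the 5' window elevated
#' relative to the body for attenuated genes in the depleted condition, and
#' beyond the PAS a readthrough component
#' `(1 - cleavage_efficiency) + cleavage_efficiency * exp(-d / tail_scale)`
#' times the body-end level.
#'
#' @param truth ground-truth list from [make_genome_annotation()].
#' @param tu_id gene identifier.
#' @param condition `"control"` or `"depleted"`.
#' @param cleavage_efficiency fraction of transcripts cleaved at the PAS
#'   (1 = clean termination apart from the tail, 0 = full readthrough).
#' @return list with `positions` (genomic, covering gene plus tail) and
#'   `lambda` (expected signal), both in genomic order on the gene strand.
#' @export
expected_gene_signal <- function(truth, tu_id, condition = "control",
                                 cleavage_efficiency = 1) {
  g <- truth$genes[truth$genes$tu_id == tu_id, ]
  stopifnot(nrow(g) == 1L)
  depleted <- condition == "depleted"
  e <- g$expression * if (depleted) truth$global_scale_depleted else 1
  glen <- g$end - g$start + 1L
  lam <- rep(e, glen)
  # attenuation: body beyond the 5' window reduced in the depleted condition
  aw <- truth$attenuation_window
  if (depleted && g$attenuated && glen > aw) {
    body_idx <- if (g$strand == "+") (aw + 1L):glen else 1L:(glen - aw)
    lam[body_idx] <- e / g$attenuation_ratio
  }
  # intron retention
  intr <- truth$introns[[tu_id]]
  ret_col <- if (depleted) "retention_depleted" else "retention_control"
  if (nrow(intr)) {
    for (j in seq_len(nrow(intr))) {
      idx <- (intr$start[j] - g$start + 1L):(intr$end[j] - g$start + 1L)
      lam[idx] <- lam[idx] * intr[[ret_col]][j]
    }
  }
  # readthrough tail beyond the PAS
  scale <- if (depleted) g$tail_scale_depleted else g$tail_scale_control
  body_end <- if (depleted && g$attenuated) e / g$attenuation_ratio else e
  tail_len <- as.integer(min(ceiling(6 * scale), 5000))
  d <- seq_len(tail_len)
  tail_lam <- body_end * ((1 - cleavage_efficiency) +
                            cleavage_efficiency * exp(-d / scale))
  clen <- truth$chrom_lengths[[g$chrom]]
  if (g$strand == "+") {
    pos <- g$start:min(clen, g$end + tail_len)
    lam <- c(lam, tail_lam)[seq_along(pos)]
  } else {
    tail_pos_n <- min(tail_len, g$start - 1L)
    pos <- max(1L, g$start - tail_len):g$end
    lam <- c(rev(tail_lam[seq_len(tail_pos_n)]), lam)
  }
  list(positions = pos, lambda = lam)
}

#' Simulate stranded coverage and library counts
#'
#' Per-base counts are Poisson with mean `lambda * noise`, divided by
#' `noise`, so `noise = 1` is plain Poisson counting noise and
#' `noise = Inf` returns the expectation exactly (expectation mode).
#' Spike-in read counts are drawn to match the mixing fraction recorded in
#' the truth, relative to the control condition's expected experimental
#' yield (the spike amount is fixed at mixing time, so a global
#' transcription loss lowers experimental but not spike-in reads).
#'
#' @param units transcription units from [make_genome_annotation()].
#' @param truth matching ground-truth list.
#' @param condition `"control"` or `"depleted"`.
#' @param noise Poisson mean scale (see above).
#' @param seed RNG seed.
#' @param cleavage_efficiency passed to [expected_gene_signal()].
#' @param sample_id label for the library-count record.
#' @return list with `coverage` (a [stranded_coverage()]) and `counts`
#'   (one-row data.frame: `sample_id`, `experimental_reads`,
#'   `spikein_reads`).
#' @export
simulate_coverage <- function(units, truth,
                              condition = c("control", "depleted"),
                              noise = 1, seed = 1L,
                              cleavage_efficiency = 1,
                              sample_id = condition[1L]) {
  condition <- match.arg(condition)
  set.seed(seed)
  chroms <- names(truth$chrom_lengths)
  acc <- list(plus = lapply(truth$chrom_lengths, function(L) numeric(L)),
              minus = lapply(truth$chrom_lengths, function(L) numeric(L)))
  g <- truth$genes
  for (i in seq_len(nrow(g))) {
    sig <- expected_gene_signal(truth, g$tu_id[i], condition,
                                cleavage_efficiency)
    sl <- if (g$strand[i] == "+") "plus" else "minus"
    ch <- g$chrom[i]
    acc[[sl]][[ch]][sig$positions] <- acc[[sl]][[ch]][sig$positions] +
      sig$lambda
  }
  expectation <- is.infinite(noise)
  total <- 0
  for (sl in c("plus", "minus")) for (ch in chroms) {
    lam <- acc[[sl]][[ch]]
    if (!expectation) {
      nz <- which(lam > 0)
      v <- numeric(length(lam))
      v[nz] <- stats::rpois(length(nz), lam[nz] * noise) / noise
      acc[[sl]][[ch]] <- v
    }
    total <- total + sum(acc[[sl]][[ch]])
  }
  cov <- stranded_coverage(plus = acc$plus, minus = acc$minus,
                           seqlengths = unlist(truth$chrom_lengths))
  # expected control-condition yield fixes the spike amount (100:1 mixing)
  exp_control <- sum(vapply(seq_len(nrow(g)), function(i) {
    s <- expected_gene_signal(truth, g$tu_id[i], "control")
    sum(s$lambda)
  }, numeric(1)))
  spike_lambda <- exp_control * truth$spike_fraction /
    (1 - truth$spike_fraction)
  spike <- if (expectation) spike_lambda else stats::rpois(1L, spike_lambda)
  counts <- data.frame(sample_id = sample_id,
                       experimental_reads = round(total),
                       spikein_reads = round(spike),
                       stringsAsFactors = FALSE)
  list(coverage = cov, counts = counts)
}

#' Simulate candidate PAS sites for a gene set
#'
#' One true site at each gene's annotated end (high prominence) plus decoy
#' sites at random offsets inside the gene with lower prominence; decoys
#' inherit whatever sequence happens to lie upstream of them, so most fail
#' the motif filter.
#'
#' @param units transcription units.
#' @param n_decoys decoys per gene.
#' @param seed RNG seed.
#' @return data.frame of candidate sites (see [read_pas_bed()]).
#' @export
simulate_pas_candidates <- function(units, n_decoys = 2L, seed = 1L) {
  set.seed(seed)
  ids <- S4Vectors::mcols(units)$tu_id
  rows <- lapply(seq_along(units), function(i) {
    m <- .unit_meta(units[i])
    offs <- sample(100:max(200L, m$len - 100L), n_decoys, replace = TRUE)
    decoy_pos <- if (m$strand == "+") m$pas - offs else m$pas + offs
    data.frame(chrom = m$chrom,
               position = c(m$pas, decoy_pos),
               strand = m$strand,
               prominence = c(stats::rpois(1L, 80) + 40,
                              stats::rpois(n_decoys, 10)),
               unit_id = ids[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate kinetics measurements
#'
#' Model values plus seeded Gaussian noise.
#'
#' @param k decay rate (/s), `k > 0`.
#' @param plateau plateau level in `[0, 1)`.
#' @param times sampling times (s).
#' @param sigma Gaussian noise SD (>= 0).
#' @param seed RNG seed.
#' @return A [decay_trace()].
#' @export
simulate_decay <- function(k, plateau = 0, times = seq(0, 600, by = 10),
                           sigma = 0, seed = 1L) {
  stopifnot(k > 0, sigma >= 0)
  set.seed(seed)
  y <- (1 - plateau) * exp(-k * times) + plateau +
    stats::rnorm(length(times), 0, sigma)
  decay_trace(times, y)
}

#' @rdname simulate_decay
#' @param Kd dissociation constant (molar).
#' @param probe probe concentration (molar).
#' @param conc protein concentration grid (molar).
#' @param a_free,a_bound anisotropy of free and bound probe.
#' @return A [titration()].
#' @export
simulate_titration <- function(Kd, probe = 50e-9,
                               conc = 10^seq(-9, -5, length.out = 12),
                               sigma = 0, seed = 1L,
                               a_free = 0.05, a_bound = 0.25) {
  stopifnot(Kd > 0, sigma >= 0)
  set.seed(seed)
  y <- a_free + (a_bound - a_free) * binding_fraction(conc, probe, Kd) +
    stats::rnorm(length(conc), 0, sigma)
  titration(conc, y, probe_conc = probe)
}

#' Write a complete synthetic fixture to disk
#'
#' Simulates both conditions and writes FASTA, GFF3, per-strand bedGraph
#' tracks, a sample sheet, candidate PAS sites (BED6) and the ground truth
#' (JSON), i.e. everything the pipeline stages consume.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed governing the whole fixture.
#' @param noise Poisson mean scale for [simulate_coverage()].
#' @param ... passed to [make_genome_annotation()].
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
write_fixture <- function(dir, seed = 1L, noise = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_genome_annotation(seed = seed, ...)
  conds <- c("control", "depleted")
  covs <- list()
  counts <- list()
  for (j in seq_along(conds)) {
    out <- simulate_coverage(sim$units, sim$truth, conds[j], noise = noise,
                             seed = seed + j, sample_id = conds[j])
    covs[[conds[j]]] <- out$coverage
    counts[[j]] <- out$counts
  }
  counts <- do.call(rbind, counts)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  gff <- file.path(dir, "annotation.gff3")
  export_annotation_gff3(sim$units, gff)
  tracks <- list()
  for (cond in conds) {
    for (st in c("+", "-")) {
      nm <- paste0(cond, ifelse(st == "+", "_plus", "_minus"), ".bedGraph")
      write_track(covs[[cond]], file.path(dir, nm), "bedgraph", strand = st)
      tracks[[paste0(cond, st)]] <- nm
    }
  }
  sheet <- data.frame(
    sample_id = conds, condition = conds,
    plus_track = c(tracks[["control+"]], tracks[["depleted+"]]),
    minus_track = c(tracks[["control-"]], tracks[["depleted-"]]),
    experimental_reads = counts$experimental_reads,
    spikein_reads = counts$spikein_reads, stringsAsFactors = FALSE)
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pas <- simulate_pas_candidates(sim$units, seed = seed)
  pas_path <- file.path(dir, "pas_candidates.bed")
  write_pas_bed(pas, pas_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(list(sim = sim, coverage = covs, counts = counts,
                 paths = list(genome = fa, annotation = gff,
                              sample_sheet = sheet_path, pas = pas_path,
                              truth = truth_path)))
}

#' Export transcription units as GFF3
#' @param units transcription-unit `GRanges`.
#' @param path output file.
#' @export
export_annotation_gff3 <- function(units, path) {
  ids <- S4Vectors::mcols(units)$tu_id
  genes <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(units),
    ranges = IRanges::ranges(units),
    strand = BiocGenerics::strand(units),
    type = "gene", ID = ids,
    biotype = S4Vectors::mcols(units)$biotype)
  exl <- S4Vectors::mcols(units)$exons
  nex <- lengths(exl)
  flat <- unlist(IRanges::IRangesList(exl))
  exons <- GenomicRanges::GRanges(
    seqnames = rep(as.character(GenomeInfoDb::seqnames(units)), nex),
    ranges = flat,
    strand = rep(as.character(BiocGenerics::strand(units)), nex),
    type = "exon",
    ID = paste0(rep(ids, nex), ":exon",
                unlist(lapply(nex, seq_len))),
    Parent = rep(ids, nex))
  gr <- suppressWarnings(c(genes, exons))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
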