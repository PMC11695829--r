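#' Polyadenylation-signal hexamer set
#'
#' The curated PAS motif list used when filtering candidate cleavage sites.
#' The published list contains eight tokens with one hexamer repeated three
#' times; the deduplicated set of six distinct hexamers is stored.
#'
#' @return Character vector of six distinct hexamers over the ACGT alphabet.
#' @examples
#' pas_motif_set()
#' @export
pas_motif_set <- function() {
  unique(c("AATAAA", "AATGAA", "AATAAT", "TAATAA",
           "AAATAA", "AATAAT", "ATAATA", "AATAAT"))
}

#' Analysis configuration
#'
#' Collects every numeric threshold and window used by the quantification
#' pipeline, with defaults matching the published analysis of fission-yeast
#' TT-seq and ChIP-seq data.
#'
#' @param flank_isolation bp on the same strand that must be free of another
#'   transcription unit upstream of the TSS and downstream of the PAS for a
#'   gene to count as isolated (default 250).
#' @param tss_window bp downstream of the TSS forming the numerator of the
#'   promoter-proximal attenuation index (default 300).
#' @param attenuation_fold minimum fold change of the attenuation index
#'   (depleted over control) for a gene to be called attenuated (default 1.5).
#' @param min_len_attenuation minimum gene length in bp for the attenuation
#'   analysis universe (default 600).
#' @param pas_half_window half-width in nt of the cleavage-index window
#'   centred on the PAS (default 5, i.e. a 10 nt window).
#' @param body_window width in bp of the gene-body window normalising the
#'   cleavage index (default 400).
#' @param body_offset gap in bp between the PAS and the start of the
#'   cleavage-index body window (default 100).
#' @param motif_upstream bp of sequence immediately upstream of a candidate
#'   PAS scanned for a PAS motif (default 50; the PAS base itself is
#'   excluded).
#' @param pas_motifs character vector of hexamers accepted as PAS motifs.
#' @param chip_min_len minimum coding-gene length in bp for the ChIP target
#'   universe (default 500).
#' @param chip_enrichment fold over the universe average ChIP signal required
#'   to call a gene a ChIP target (default 2).
#' @param metagene_trim bp trimmed after the TSS and before the PAS when
#'   scaling gene bodies, and start offset of the readthrough-index body
#'   window (default 250).
#' @param readthrough_window bp downstream of the PAS used by the
#'   readthrough index (default 500).
#' @param normalization `"spike"` to apply spike-in factors, `"depth_only"`
#'   to normalise to sequencing depth alone (used when a perturbation is
#'   known to affect the spike-in species).
#' @param pseudocount density pseudocount for log2-ratio matrices.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$tss_window
#' @export
analysis_config <- function(flank_isolation = 250L,
                            tss_window = 300L,
                            attenuation_fold = 1.5,
                            min_len_attenuation = 600L,
                            pas_half_window = 5L,
                            body_window = 400L,
                            body_offset = 100L,
                            motif_upstream = 50L,
                            pas_motifs = pas_motif_set(),
                            chip_min_len = 500L,
                            chip_enrichment = 2.0,
                            metagene_trim = 250L,
                            readthrough_window = 500L,
                            normalization = c("spike", "depth_only"),
                            pseudocount = 0.01) {
  cfg <- list(
    flank_isolation = as.integer(flank_isolation),
    tss_window = as.integer(tss_window),
    attenuation_fold = as.numeric(attenuation_fold),
    min_len_attenuation = as.integer(min_len_attenuation),
    pas_half_window = as.integer(pas_half_window),
    body_window = as.integer(body_window),
    body_offset = as.integer(body_offset),
    motif_upstream = as.integer(motif_upstream),
    pas_motifs = toupper(as.character(pas_motifs)),
    chip_min_len = as.integer(chip_min_len),
    chip_enrichment = as.numeric(chip_enrichment),
    metagene_trim = as.integer(metagene_trim),
    readthrough_window = as.integer(readthrough_window),
    normalization = match.arg(normalization),
    pseudocount = as.numeric(pseudocount)
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  windows <- c("flank_isolation", "tss_window", "min_len_attenuation",
               "pas_half_window", "body_window", "body_offset",
               "motif_upstream", "chip_min_len", "metagene_trim",
               "readthrough_window")
  for (w in windows) {
    v <- cfg[[w]]
    if (length(v) != 1L || is.na(v) || v <= 0L)
      stop("config field '", w, "' must be a single positive integer",
           call. = FALSE)
  }
  if (cfg$attenuation_fold <= 0 || cfg$chip_enrichment <= 0)
    stop("fold thresholds must be positive", call. = FALSE)
  if (cfg$pseudocount <= 0)
    stop("pseudocount must be positive", call. = FALSE)
  m <- cfg$pas_motifs
  if (length(m) == 0L)
    stop("pas_motifs must be non-empty", call. = FALSE)
  if (any(nchar(m) != 6L) || any(grepl("[^ACGT]", m)))
    stop("pas_motifs must be hexamers over ACGT", call. = FALSE)
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm, paste(v, collapse = " ")))
  }
  invisible(x)
}
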