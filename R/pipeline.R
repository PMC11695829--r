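#' Default run configuration
#'
#' Flat key/value configuration for [run_pipeline()]. Analysis thresholds
#' default to the values of [analysis_config()]; paths default to the
#' synthetic fixture layout written by the `simulate` stage.
#'
#' @param out_dir output directory.
#' @param seed global RNG seed.
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(out_dir = "ttkit_out", seed = 1L) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    # inputs (the simulate stage fills these in)
    genome = NULL, annotation = NULL, sample_sheet = NULL, pas = NULL,
    decay_tsv = NULL, titration_tsv = NULL,
    reference_sample = "control",
    treated_sample = "depleted",
    control_sample = "control",
    normalization = "spike",
    # simulate-stage knobs
    n_genes = 200L, noise = 1,
    # metagene knobs
    n_body_bins = 50L, flank = 500L, binsize = 10L, n_boot = 200L
  )
  ac <- analysis_config()
  for (nm in setdiff(names(ac), c("pas_motifs", "normalization")))
    cfg[[nm]] <- ac[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos fail before compute; relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file of flat key/value pairs.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  base <- dirname(normalizePath(path))
  for (nm in c("genome", "annotation", "sample_sheet", "pas",
               "decay_tsv", "titration_tsv", "out_dir")) {
    p <- cfg[[nm]]
    if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p))
      cfg[[nm]] <- file.path(base, p)
  }
  cfg
}

.cfg_analysis <- function(cfg) {
  analysis_config(
    flank_isolation = cfg$flank_isolation, tss_window = cfg$tss_window,
    attenuation_fold = cfg$attenuation_fold,
    min_len_attenuation = cfg$min_len_attenuation,
    pas_half_window = cfg$pas_half_window, body_window = cfg$body_window,
    body_offset = cfg$body_offset, motif_upstream = cfg$motif_upstream,
    chip_min_len = cfg$chip_min_len, chip_enrichment = cfg$chip_enrichment,
    metagene_trim = cfg$metagene_trim,
    readthrough_window = cfg$readthrough_window,
    normalization = cfg$normalization)
}

.need <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("missing ", what, " input: ",
         if (is.null(path)) "(not set)" else path, call. = FALSE)
  path
}

.load_samples <- function(cfg) {
  sheet <- read_sample_sheet(.need(cfg$sample_sheet, "sample sheet"))
  raw <- lapply(seq_len(nrow(sheet)), function(i) list(
    p = read_track(.need(sheet$plus_track[i], "plus track"),
                   "bedgraph", "+"),
    m = read_track(.need(sheet$minus_track[i], "minus track"),
                   "bedgraph", "-")))
  # bedGraph carries no chromosome lengths; harmonize across all tracks
  common <- integer(0)
  for (r in raw) for (cv in r) for (ch in names(cv$seqlengths))
    common[ch] <- max(common[ch], cv$seqlengths[[ch]], 0L, na.rm = TRUE)
  covs <- lapply(raw, function(r)
    merge_strands(expand_seqlengths(r$p, common),
                  expand_seqlengths(r$m, common)))
  names(covs) <- sheet$sample_id
  list(sheet = sheet, covs = covs)
}

.write_manifest <- function(stage_dir, cfg, stage, inputs, outputs) {
  cfg_json <- file.path(stage_dir, "config.json")
  plain <- cfg; attributes(plain) <- list(names = names(cfg))
  jsonlite::write_json(plain, cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(stage = stage,
                   package_version = as.character(
                     utils::packageVersion("ttkit")),
                   config_md5 = unname(tools::md5sum(cfg_json)),
                   inputs = inputs, outputs = outputs)
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run pipeline stages
#'
#' Orchestrates the analysis stages over one configuration; each stage
#' writes its artifacts plus a manifest (inputs, config hash, package
#' version) into `out_dir/<stage>/`. Deterministic stages are byte-stable
#' under a fixed config. On failure the stage directory is removed so no
#' partial outputs survive.
#'
#' @param stage one of `"simulate"`, `"normalize"`, `"indices"`,
#'   `"metagene"`, `"kinetics"`, `"all"`.
#' @param config a `run_config` list ([default_run_config()],
#'   [read_run_config()]).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(stage = c("simulate", "normalize", "indices",
                                   "metagene", "kinetics", "all"),
                         config = default_run_config()) {
  stage <- match.arg(stage)
  acfg <- .cfg_analysis(config)   # validates thresholds up front
  if (stage == "all") {
    arts <- run_pipeline("simulate", config)
    config$genome <- arts$genome
    config$annotation <- arts$annotation
    config$sample_sheet <- arts$sample_sheet
    config$pas <- arts$pas
    for (st in c("normalize", "indices", "metagene"))
      arts <- c(arts, run_pipeline(st, config))
    return(invisible(arts))
  }
  stage_dir <- file.path(config$out_dir, stage)
  dir.create(stage_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage_dir, recursive = TRUE), add = TRUE)
  arts <- switch(
    stage,
    simulate = {
      fx <- write_fixture(stage_dir, seed = config$seed,
                          noise = config$noise,
                          n_genes = config$n_genes)
      out <- fx$paths
      .write_manifest(stage_dir, config, stage, list(),
                      lapply(out, as.character))
      out
    },
    normalize = {
      ss <- .load_samples(config)
      fac <- if (config$normalization == "spike")
        spikein_factors(ss$sheet, config$reference_sample)
      else {
        ref <- ss$sheet$experimental_reads[
          match(config$reference_sample, ss$sheet$sample_id)]
        stats::setNames(ref / ss$sheet$experimental_reads,
                        ss$sheet$sample_id)
      }
      out <- list()
      for (s in names(ss$covs)) {
        nc <- apply_normalization(ss$covs[[s]], spike_factor = fac[[s]])
        for (st in c("+", "-")) {
          p <- file.path(stage_dir,
                         paste0(s, ifelse(st == "+", "_plus", "_minus"),
                                ".norm.bedGraph"))
          write_track(nc, p, "bedgraph", strand = st)
          out[[paste0(s, st)]] <- p
        }
      }
      utils::write.table(
        data.frame(sample_id = names(fac), factor = unname(fac)),
        file.path(stage_dir, "factors.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      out$factors <- file.path(stage_dir, "factors.tsv")
      .write_manifest(stage_dir, config, stage,
                      list(sample_sheet = config$sample_sheet),
                      lapply(out, as.character))
      out
    },
    indices = {
      units <- load_annotation(.need(config$annotation, "annotation"),
                               "gff3")
      genome <- Biostrings::readDNAStringSet(.need(config$genome,
                                                   "genome"))
      names(genome) <- sub("\\s.*$", "", names(genome))
      ss <- .load_samples(config)
      iso <- filter_isolated_coding(units, acfg$flank_isolation)
      pas_sel <- NULL
      if (!is.null(config$pas)) {
        cands <- read_pas_bed(.need(config$pas, "PAS candidates"))
        pas_sel <- do.call(rbind, lapply(seq_along(iso), function(i) {
          id <- S4Vectors::mcols(iso)$tu_id[i]
          cc <- cands[cands$unit_id == id, , drop = FALSE]
          if (nrow(cc) == 0L) return(NULL)
          select_pas_site(cc, iso[i], genome, acfg)
        }))
      }
      metrics <- gene_metrics(ss$covs, iso, acfg, pas = pas_sel,
                              chip_covs = ss$covs)
      write_metrics(metrics, file.path(stage_dir, "gene_metrics.tsv"))
      att <- select_attenuated(metrics, acfg, config$treated_sample,
                               config$control_sample)
      writeLines(att, file.path(stage_dir, "attenuated_genes.txt"))
      writeLines(S4Vectors::mcols(iso)$tu_id,
                 file.path(stage_dir, "isolated_genes.txt"))
      out <- list(metrics = file.path(stage_dir, "gene_metrics.tsv"),
                  attenuated = file.path(stage_dir, "attenuated_genes.txt"),
                  isolated = file.path(stage_dir, "isolated_genes.txt"))
      if (!is.null(pas_sel)) {
        write_pas_bed(pas_sel, file.path(stage_dir, "selected_pas.bed"))
        out$selected_pas <- file.path(stage_dir, "selected_pas.bed")
      }
      .write_manifest(stage_dir, config, stage,
                      list(annotation = config$annotation,
                           genome = config$genome,
                           sample_sheet = config$sample_sheet),
                      lapply(out, as.character))
      out
    },
    metagene = {
      units <- load_annotation(.need(config$annotation, "annotation"),
                               "gff3")
      ss <- .load_samples(config)
      iso <- filter_isolated_coding(units, acfg$flank_isolation)
      mats <- lapply(ss$covs, scaled_matrix, units = iso,
                     n_body_bins = config$n_body_bins,
                     upstream = config$flank, downstream = config$flank,
                     trim = acfg$metagene_trim,
                     up_binsize = config$binsize,
                     down_binsize = config$binsize)
      out <- list()
      for (s in names(mats)) {
        p <- file.path(stage_dir, paste0(s, ".scaled_matrix.tsv"))
        write_signal_matrix(mats[[s]], p)
        out[[s]] <- p
      }
      tr <- config$treated_sample; ctl <- config$control_sample
      if (all(c(tr, ctl) %in% names(mats))) {
        lr <- log2_ratio(mats[[tr]], mats[[ctl]], acfg$pseudocount)
        p <- file.path(stage_dir, "log2_ratio.tsv")
        write_signal_matrix(lr, p)
        out$log2_ratio <- p
        prof <- profile_with_ci(lr, n_boot = config$n_boot,
                                seed = config$seed)
        pp <- file.path(stage_dir, "log2_ratio_profile.tsv")
        utils::write.table(prof, pp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        out$profile <- pp
      }
      .write_manifest(stage_dir, config, stage,
                      list(annotation = config$annotation,
                           sample_sheet = config$sample_sheet),
                      lapply(out, as.character))
      out
    },
    kinetics = {
      out <- list()
      if (!is.null(config$decay_tsv)) {
        tr <- read_decay_tsv(.need(config$decay_tsv, "decay trace"))
        fit <- fit_exponential(rescale_unit_interval(tr))
        p <- file.path(stage_dir, "decay_fit.json")
        write_fit_report(fit, p)
        out$decay_fit <- p
      }
      if (!is.null(config$titration_tsv)) {
        ti <- read_titration_tsv(.need(config$titration_tsv, "titration"))
        fit <- fit_binding(ti)
        p <- file.path(stage_dir, "binding_fit.json")
        write_fit_report(fit, p)
        out$binding_fit <- p
      }
      if (length(out) == 0L)
        stop("kinetics stage needs decay_tsv and/or titration_tsv",
             call. = FALSE)
      .write_manifest(stage_dir, config, stage,
                      list(decay_tsv = config$decay_tsv,
                           titration_tsv = config$titration_tsv),
                      lapply(out, as.character))
      out
    })
  ok <- TRUE
  invisible(arts)
}
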