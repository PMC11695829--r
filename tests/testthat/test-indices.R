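# piecewise track builder: value `vals[i]` over genomic [from[i], to[i]]
piecewise <- function(len, from, to, vals, strand = "+") {
  v <- numeric(len)
  for (i in seq_along(from)) v[from[i]:to[i]] <- vals[i]
  if (strand == "+") cov1(plus = v, len = len) else
    cov1(minus = v, len = len)
}

test_that("uniform coverage yields index 1 for every ratio index", {
  cfg <- analysis_config()
  cov <- cov1(plus = rep(3, 6000), minus = rep(3, 6000))
  exons <- cbind(c(1001, 1901, 2801), c(1800, 2700, 3600))
  for (st in c("+", "-")) {
    unit <- tu("g1", 1001, 3600, st, exons = exons, len = 6000L)
    expect_equal(attenuation_index(cov, unit, cfg), 1.0)
    expect_equal(readthrough_index(cov, unit, cfg), 1.0)
    ir <- intron_retention_index(cov, unit)
    expect_equal(ir$per_intron, c(1, 1))
    expect_equal(ir$aggregate, 1.0)
    pas <- data.frame(chrom = "chrI", position = pas_position(unit),
                      strand = st)
    expect_equal(cleavage_index(cov, pas, cfg), 1.0)
  }
})

test_that("attenuation index is the 5' to body density ratio", {
  cfg <- analysis_config()
  # gene 1001..3000 on +: 5' window 1001..1300 at 3, body 1301..3000 at 1
  cov <- piecewise(4000, c(1001, 1301), c(1300, 3000), c(3, 1))
  unit <- tu("g1", 1001, 3000, "+", len = 4000L)
  expect_equal(attenuation_index(cov, unit, cfg), 3.0)
  # unit not longer than the TSS window is skipped with a reason
  short <- tu("s1", 1001, 1300, "+", len = 4000L)
  res <- attenuation_index(cov, short, cfg)
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "shorter")
  # zero body density is undefined, not infinite
  cov0 <- piecewise(4000, 1001, 1300, 3)
  res0 <- attenuation_index(cov0, unit, cfg)
  expect_true(is.na(res0))
})

test_that("attenuation selection applies length and inclusive fold rules", {
  cfg <- analysis_config()
  mk <- function(id, len, t, c)
    data.frame(tu_id = id, sample = rep(c("trt", "ctl"), each = 1),
               biotype = "coding", length = len, n_introns = 0L,
               attenuation_index = c(t, c), readthrough_index = NA,
               cleavage_index = NA, intron_retention = NA, chip_mean = NA,
               stringsAsFactors = FALSE)
  metrics <- rbind(mk("boundary", 1000, 3.0, 2.0),   # ratio exactly 1.5
                   mk("weak", 1000, 1.4, 1.0),       # below threshold
                   mk("short", 600, 9.0, 1.0),       # not longer than 600
                   mk("undef", 1000, 2.0, NA))       # undefined control
  sel <- select_attenuated(metrics, cfg, "trt", "ctl")
  expect_identical(sel, "boundary")
  # identical conditions select nothing
  same <- rbind(mk("a", 1000, 2.0, 2.0), mk("b", 2000, 0.7, 0.7))
  expect_length(select_attenuated(same, cfg, "trt", "ctl"), 0L)
})

test_that("readthrough index normalises downstream signal to the body", {
  cfg <- analysis_config()
  # body (TSS+250 onwards) at 2, 500 bp downstream of PAS at 1
  cov <- piecewise(5000, c(1001, 3001), c(3000, 3500), c(2, 1))
  unit <- tu("g1", 1001, 3000, "+", len = 5000L)
  expect_equal(readthrough_index(cov, unit, cfg), 0.5)
  # clean termination: zero signal after the PAS
  cov2 <- piecewise(5000, 1001, 3000, 2)
  expect_equal(readthrough_index(cov2, unit, cfg), 0.0)
  # window past the chromosome end is truncated with a warning
  edge <- tu("g2", 1001, 4800, "+", len = 5000L)
  cove <- piecewise(5000, 1001, 5000, 2)
  expect_warning(ri <- readthrough_index(cove, edge, cfg), "truncated")
  expect_equal(ri, 1.0)
})

test_that("cleavage index uses the 10 nt PAS window over the offset body window", {
  cfg <- analysis_config()
  # + strand PAS at 2000: numerator [1995, 2004], body [1500, 1899]
  cov <- piecewise(4000, c(1500, 1995), c(1899, 2004), c(2, 0.2))
  pas <- data.frame(chrom = "chrI", position = 2000L, strand = "+")
  expect_equal(cleavage_index(cov, pas, cfg), 0.1)
  # minus strand mirror: numerator [1996, 2005], body [2101, 2500]
  covm <- piecewise(4000, c(2101, 1996), c(2500, 2005), c(2, 0.2),
                    strand = "-")
  pasm <- data.frame(chrom = "chrI", position = 2000L, strand = "-")
  expect_equal(cleavage_index(covm, pasm, cfg), 0.1)
})

test_that("intron retention relates intronic to flanking exonic density", {
  # exon1 1001..2000 at 2, intron 2001..2500 at 1, exon2 2501..3500 at 4
  cov <- piecewise(5000, c(1001, 2001, 2501), c(2000, 2500, 3500),
                   c(2, 1, 4))
  unit <- tu("g1", 1001, 3500, "+",
             exons = cbind(c(1001, 2501), c(2000, 3500)), len = 5000L)
  ir <- intron_retention_index(cov, unit)
  expect_equal(ir$per_intron, 1 / 3)
  expect_equal(ir$aggregate, 1 / 3)
  # fully spliced
  cov2 <- piecewise(5000, c(1001, 2501), c(2000, 3500), c(2, 4))
  expect_equal(intron_retention_index(cov2, unit)$aggregate, 0)
  # intronless gene -> skip with reason
  single <- tu("g2", 1001, 3500, "+", len = 5000L)
  res <- intron_retention_index(cov, single)
  expect_length(res$per_intron, 0L)
  expect_match(attr(res, "reason"), "intronless")
})

test_that("all indices are invariant to track scaling and strand mirroring", {
  set.seed(31)
  len <- 20000L
  v_plus <- rpois(len, 4) * runif(len, 0.5, 1.5)
  v_minus <- rpois(len, 2) * runif(len, 0.5, 1.5)
  cov <- cov1(plus = v_plus, minus = v_minus, len = len)
  cfg <- analysis_config()
  units <- list(
    tu("p1", 2001, 5000, "+", exons = cbind(c(2001, 3501), c(3300, 5000)),
       len = len),
    tu("m1", 8001, 11000, "-", exons = cbind(c(8001, 9601), c(9400, 11000)),
       len = len))
  for (unit in units) {
    st <- as.character(BiocGenerics::strand(unit))
    pas <- data.frame(chrom = "chrI", position = pas_position(unit),
                      strand = st)
    a0 <- attenuation_index(cov, unit, cfg)
    r0 <- readthrough_index(cov, unit, cfg)
    c0 <- cleavage_index(cov, pas, cfg)
    i0 <- intron_retention_index(cov, unit)$aggregate
    # scaling invariance
    sc <- scale_coverage(cov, 17.3)
    expect_equal(attenuation_index(sc, unit, cfg), a0, tolerance = 1e-12)
    expect_equal(readthrough_index(sc, unit, cfg), r0, tolerance = 1e-12)
    expect_equal(cleavage_index(sc, pas, cfg), c0, tolerance = 1e-12)
    expect_equal(intron_retention_index(sc, unit)$aggregate, i0,
                 tolerance = 1e-12)
    # strand mirror invariance
    mcov <- mirror_cov(cov)
    ex <- S4Vectors::mcols(unit)$exons[[1]]
    mex <- cbind(len + 1L - rev(BiocGenerics::end(ex)),
                 len + 1L - rev(BiocGenerics::start(ex)))
    munit <- tu("m", len + 1L - BiocGenerics::end(unit),
                len + 1L - BiocGenerics::start(unit),
                ifelse(st == "+", "-", "+"), exons = mex, len = len)
    mpas <- data.frame(chrom = "chrI", position = len + 1L - pas$position,
                       strand = ifelse(st == "+", "-", "+"))
    expect_equal(attenuation_index(mcov, munit, cfg), a0, tolerance = 1e-12)
    expect_equal(readthrough_index(mcov, munit, cfg), r0, tolerance = 1e-12)
    expect_equal(cleavage_index(mcov, mpas, cfg), c0, tolerance = 1e-12)
    expect_equal(intron_retention_index(mcov, munit)$aggregate, i0,
                 tolerance = 1e-12)
  }
})

test_that("ChIP target selection matches brute-force recomputation", {
  cfg <- analysis_config()
  mk <- function(id, len, chip, biotype = "coding")
    data.frame(tu_id = id, sample = "s", biotype = biotype, length = len,
               n_introns = 0L, attenuation_index = NA,
               readthrough_index = NA, cleavage_index = NA,
               intron_retention = NA, chip_mean = chip,
               stringsAsFactors = FALSE)
  # all equal -> nobody reaches 2x the mean
  eq <- do.call(rbind, lapply(1:10, function(i) mk(paste0("g", i), 1000, 5)))
  expect_length(chip_target_set(eq, cfg), 0L)
  # one gene at 10 among ninety-nine at 1
  mix <- do.call(rbind, c(list(mk("hot", 1000, 10)),
                          lapply(1:99, function(i)
                            mk(paste0("g", i), 1000, 1))))
  expect_identical(chip_target_set(mix, cfg), "hot")
  # short gene with huge signal is excluded from the universe
  mix2 <- rbind(mix, mk("short", 400, 100))
  expect_identical(chip_target_set(mix2, cfg), "hot")
  # brute force on random tables
  set.seed(77)
  for (rep in 1:5) {
    tab <- do.call(rbind, lapply(1:80, function(i)
      mk(paste0("r", i), sample(300:3000, 1), rexp(1, 0.2),
         sample(c("coding", "noncoding"), 1, prob = c(0.8, 0.2)))))
    uni <- tab[tab$biotype == "coding" & tab$length > 500, ]
    want <- sort(uni$tu_id[uni$chip_mean >= 2 * mean(uni$chip_mean)])
    expect_identical(chip_target_set(tab, cfg), want)
  }
})

test_that("base composition profiles recover planted sequence structure", {
  # all-T genome
  genome <- Biostrings::DNAStringSet(strrep("T", 5000))
  names(genome) <- "chrI"
  u <- tu("g1", 2001, 3000, "+", len = 5000L)
  p <- base_composition_profile(genome, u, "TSS", 50, 50)
  expect_true(all(p["T", ] == 1))
  expect_true(all(colSums(p) == 1))
  # planted T tract at +20 after the PAS in half the genes
  sim <- make_genome_annotation(n_genes = 300,
                                chrom_lengths = c(chrI = 2000000L),
                                t_tract_fraction = 0.5, t_tract_offset = 20,
                                t_tract_length = 8, seed = 5)
  prof <- base_composition_profile(sim$genome, sim$units, "PAS", 10, 40)
  frac_planted <- mean(sim$truth$genes$has_t_tract)
  expected_peak <- frac_planted * 1 + (1 - frac_planted) * 0.25
  peak <- prof["T", as.character(24)]
  expect_lt(abs(peak - expected_peak), 0.06)
  # random background is near 0.25 everywhere far from plantings
  expect_lt(abs(mean(prof["A", as.character(-10:-1)]) - 0.25), 0.05)
})

test_that("poly-T run detection matches a naive run-scan", {
  genome <- Biostrings::DNAStringSet(c(chrI = random_dna(100000)))
  set.seed(19)
  df <- random_annotation(60, chrom_len = 90000L, n_chrom = 1L)
  df$chrom <- "chrI"
  units <- units_from_df(df, c(chrI = 100000L))
  half <- units[1:30]; rest <- units[31:60]
  res <- polyt_run_enrichment(genome, half, rest, anchor = "PAS",
                              upstream = 0, downstream = 80, min_run = 4)
  # oracle: explicit run scan over the sense-strand windows
  scan_set <- function(set) {
    vapply(seq_along(set), function(i) {
      m <- list(chrom = as.character(GenomeInfoDb::seqnames(set[i])),
                strand = as.character(BiocGenerics::strand(set[i])))
      pos <- pas_position(set[i])
      if (m$strand == "+") s <- Biostrings::subseq(genome[[m$chrom]],
                                                   pos, pos + 80)
      else s <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[m$chrom]], pos - 80, pos))
      chars <- strsplit(as.character(s), "")[[1]]
      run <- 0; best <- 0
      for (ch in chars) {
        run <- if (ch == "T") run + 1 else 0
        best <- max(best, run)
      }
      best >= 4
    }, logical(1))
  }
  expect_equal(res$has_run_a, scan_set(half))
  expect_equal(res$has_run_b, scan_set(rest))
  expect_equal(res$fraction_a, mean(scan_set(half)))
  # identical sets give ratio 1 (and warn about overlap)
  expect_warning(same <- polyt_run_enrichment(genome, half, half,
                                              upstream = 0, downstream = 80,
                                              min_run = 4), "overlap")
  if (same$fraction_b > 0) expect_equal(same$ratio, 1.0)
})
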