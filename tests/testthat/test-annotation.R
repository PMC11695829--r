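test_that("GFF3 and BED12 records map onto the internal representation", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\ttest\tgene\t1\t100\t.\t+\t.\tID=g1;biotype=coding",
    "chrI\ttest\texon\t1\t100\t.\t+\t.\tID=g1:e1;Parent=g1"), gff)
  u <- load_annotation(gff, "gff3")
  expect_equal(BiocGenerics::start(u), 1L)
  expect_equal(BiocGenerics::end(u), 100L)
  expect_equal(length(S4Vectors::mcols(u)$exons[[1]]), 1L)
  expect_equal(S4Vectors::mcols(u)$biotype, "coding")

  bed <- tempfile(fileext = ".bed")
  writeLines(paste(c("chrI", 99, 200, "g2", 0, "+", 99, 200, "0", 2,
                     "20,30", "0,71"), collapse = "\t"), bed)
  b <- load_annotation(bed, "bed12")
  expect_equal(BiocGenerics::start(b), 100L)
  expect_equal(BiocGenerics::end(b), 200L)
  ex <- S4Vectors::mcols(b)$exons[[1]]
  expect_equal(BiocGenerics::start(ex), c(100L, 171L))
  expect_equal(BiocGenerics::end(ex), c(119L, 200L))
  intr <- unit_introns(b[1])
  expect_equal(length(intr), 1L)
  expect_equal(c(BiocGenerics::start(intr), BiocGenerics::end(intr)),
               c(120L, 170L))
})

test_that("a generated annotation round-trips through GFF3 unchanged", {
  sim <- make_genome_annotation(n_genes = 50, chrom_lengths = c(chrI = 300000L),
                                intron_fraction = 0.5, seed = 11)
  path <- tempfile(fileext = ".gff3")
  export_annotation_gff3(sim$units, path)
  back <- load_annotation(path, "gff3")
  ord <- match(S4Vectors::mcols(sim$units)$tu_id,
               S4Vectors::mcols(back)$tu_id)
  back <- back[ord]
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(sim$units))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(sim$units))
  expect_equal(as.character(BiocGenerics::strand(back)),
               as.character(BiocGenerics::strand(sim$units)))
  expect_equal(S4Vectors::mcols(back)$biotype,
               S4Vectors::mcols(sim$units)$biotype)
  for (i in seq_along(back))
    expect_equal(as.data.frame(S4Vectors::mcols(back)$exons[[i]]),
                 as.data.frame(S4Vectors::mcols(sim$units)$exons[[i]]))
})

test_that("malformed annotation records are rejected with clear errors", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrI\ttest\tgene\t50\t40\t.\t+\t.\tID=g1"), bad)
  expect_error(load_annotation(bad, "gff3"))
  expect_error(
    transcription_units("g1", "chrI", 10, 100, "+", "coding",
                        exons = list(cbind(5, 50))),
    "exon outside unit bounds")
  expect_error(
    transcription_units("g1", "chrI", 10, 100, "+", "coding",
                        exons = list(cbind(c(10, 30), c(40, 90)))),
    "overlapping exons")
})

test_that("isolation filter honours gap size and strand", {
  # two + strand genes, 300 bp gap, flank 250 -> both kept
  two <- function(gap) data.frame(
    tu_id = c("a", "b"), chrom = "chrI",
    start = c(1000L, 2999L + gap), end = c(2998L, 4000L + gap),
    strand = "+", biotype = "coding", stringsAsFactors = FALSE)
  kept <- filter_isolated_coding(units_from_df(two(301L)), 250)
  expect_setequal(S4Vectors::mcols(kept)$tu_id, c("a", "b"))
  # 200 bp gap -> both removed
  kept <- filter_isolated_coding(units_from_df(two(200L)), 250)
  expect_length(kept, 0L)
  # adjacent opposite-strand gene never disqualifies
  df <- two(301L); df$strand <- c("+", "-"); df$start[2] <- 2999L
  kept <- filter_isolated_coding(units_from_df(df), 250)
  expect_setequal(S4Vectors::mcols(kept)$tu_id, c("a", "b"))
})

test_that("isolation filter matches the all-pairs oracle on random annotations", {
  set.seed(42)
  for (rep in 1:8) {
    df <- random_annotation(sample(50:300, 1))
    got <- sort(S4Vectors::mcols(
      filter_isolated_coding(units_from_df(df), 250))$tu_id)
    expect_identical(got, naive_isolated(df, 250))
  }
})

test_that("motif scanning is exact, overlap-aware and N-safe", {
  expect_equal(scan_motifs("AATAAA", "AATAAA"),
               data.frame(start = 1L, motif = "AATAAA",
                          stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  hits <- scan_motifs("AATAATAAT", "AATAAT")
  expect_equal(hits$start, c(1L, 4L))
  expect_equal(nrow(scan_motifs("AANAAA", "AATAAA")), 0L)
  expect_error(scan_motifs("ACGT", character(0)), "non-empty")
  set.seed(7)
  motifs <- pas_motif_set()
  for (i in 1:200) {
    s <- random_dna(200)
    got <- scan_motifs(s, motifs)
    rownames(got) <- NULL
    expect_identical(got, naive_scan(s, motifs))
  }
})

test_that("the default PAS motif set has six distinct hexamers", {
  m <- pas_motif_set()
  expect_length(m, 6L)
  expect_false(anyDuplicated(m) > 0)
  expect_true(all(nchar(m) == 6L))
})

test_that("PAS site selection applies the motif filter and tie-breaks", {
  # genome: gene on + at 101..700, planted AATAAA 30 bp upstream of pos 700
  g <- rep("C", 1000)
  g[670:675] <- strsplit("AATAAA", "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(g, collapse = ""))
  names(genome) <- "chrI"
  unit <- tu("g1", 101, 700, "+", len = 1000)
  cfg <- analysis_config()
  # candidate at 700 has the motif in its 50 bp upstream window
  cands <- data.frame(chrom = "chrI", position = c(700L, 400L),
                      strand = "+", prominence = c(5, 50),
                      unit_id = "g1", stringsAsFactors = FALSE)
  sel <- select_pas_site(cands, unit, genome, cfg)
  expect_equal(sel$position, 700L)  # high-prominence decoy fails the motif
  # no motif anywhere -> NULL
  clean <- Biostrings::DNAStringSet(paste(rep("C", 1000), collapse = ""))
  names(clean) <- "chrI"
  expect_null(select_pas_site(cands, unit, clean, cfg))
  # prominence tie broken by distance to the annotated end
  g2 <- rep("C", 1000)
  g2[620:625] <- strsplit("AATAAA", "")[[1]]
  g2[660:665] <- strsplit("AATAAA", "")[[1]]
  genome2 <- Biostrings::DNAStringSet(paste(g2, collapse = ""))
  names(genome2) <- "chrI"
  cands2 <- data.frame(chrom = "chrI", position = c(695L, 650L),
                       strand = "+", prominence = c(10, 10),
                       unit_id = "g1", stringsAsFactors = FALSE)
  sel2 <- select_pas_site(cands2, unit, genome2, cfg)
  expect_equal(sel2$position, 695L)  # 5 bp from end beats 50 bp
  # out-of-bounds candidate is a coordinate error
  bad <- data.frame(chrom = "chrI", position = 5000L, strand = "+",
                    prominence = 1, unit_id = "g1", stringsAsFactors = FALSE)
  expect_error(select_pas_site(bad, unit, genome, cfg), "bounds")
})

test_that("mirror transform leaves isolation and PAS selection invariant", {
  set.seed(13)
  chrom_lengths <- c(chr1 = 50000L, chr2 = 50000L)
  df <- random_annotation(120)
  iso <- sort(S4Vectors::mcols(filter_isolated_coding(
    units_from_df(df, chrom_lengths), 250))$tu_id)
  mdf <- mirror_units_df(df, chrom_lengths)
  miso <- sort(S4Vectors::mcols(filter_isolated_coding(
    units_from_df(mdf, chrom_lengths), 250))$tu_id)
  expect_identical(iso, miso)

  # PAS selection on a minus-strand gene mirrors the plus-strand case
  g <- rep("C", 1000)
  g[670:675] <- strsplit("AATAAA", "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(g, collapse = ""))
  names(genome) <- "chrI"
  unit <- tu("g1", 101, 700, "+", len = 1000)
  cands <- data.frame(chrom = "chrI", position = c(700L, 690L),
                      strand = "+", prominence = c(7, 3),
                      unit_id = "g1", stringsAsFactors = FALSE)
  sel <- select_pas_site(cands, unit, genome, analysis_config())
  mgenome <- Biostrings::DNAStringSet(Biostrings::reverseComplement(genome[[1]]))
  names(mgenome) <- "chrI"
  munit <- tu("g1", 1000 - 700 + 1, 1000 - 101 + 1, "-", len = 1000)
  mcands <- cands
  mcands$position <- 1000L - cands$position + 1L
  mcands$strand <- "-"
  msel <- select_pas_site(mcands, munit, mgenome, analysis_config())
  expect_equal(1000L - msel$position + 1L, sel$position)
})
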