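test_that("scaled matrices average exactly per bin and scale with gene length", {
  # constant track -> constant row
  cov <- cov1(plus = rep(2, 20000), len = 20000L)
  unit <- tu("g1", 5001, 6500, "+", len = 20000L)
  m <- scaled_matrix(cov, unit, n_body_bins = 10, upstream = 100,
                     downstream = 100, trim = 250, up_binsize = 10,
                     down_binsize = 10)
  expect_equal(dim(m), c(1L, 30L))
  expect_true(all(unclass(m) == 2))
  # linear ramp across a 1000 bp body, 10 bins -> means 0.05 .. 0.95
  len <- 20000L
  v <- numeric(len)
  body <- (5001 + 250):(6500 - 250)  # 1000 bases
  v[body] <- (seq_along(body) - 0.5) / length(body)
  covr <- cov1(plus = v, len = len)
  mr <- scaled_matrix(covr, unit, n_body_bins = 10, upstream = 100,
                      downstream = 100, trim = 250)
  bodycols <- matrix_bins(mr)$segment == "body"
  expect_equal(unname(unclass(mr)[1, bodycols]),
               seq(0.05, 0.95, by = 0.1), tolerance = 1e-12)
  # same shape at 10x the length gives the identical body row
  unit10 <- tu("g2", 5001, 15500, "+", len = 20000L)  # body 10000 bases
  v10 <- numeric(len)
  body10 <- (5001 + 250):(15500 - 250)
  v10[body10] <- (seq_along(body10) - 0.5) / length(body10)
  m10 <- scaled_matrix(cov1(plus = v10, len = len), unit10,
                       n_body_bins = 10, upstream = 100, downstream = 100,
                       trim = 250)
  expect_equal(unname(unclass(m10)[1, bodycols]),
               unname(unclass(mr)[1, bodycols]), tolerance = 1e-12)
  # too-short units are skipped and recorded
  tiny <- tu("t1", 100, 650, "+", len = 20000L)
  both <- suppressWarnings(c(unit, tiny))
  ms <- scaled_matrix(cov, both, n_body_bins = 100, upstream = 100,
                      downstream = 100, trim = 250)
  expect_equal(rownames(ms), "g1")
  expect_equal(attr(ms, "skipped"), "t1")
})

test_that("anchored matrices are strand-aware and match per-base means", {
  set.seed(23)
  len <- 10000L
  vp <- rexp(len)
  cov <- cov1(plus = vp, minus = rev(vp), len = len)
  anchors <- data.frame(unit_id = "a1", chrom = "chrI", position = 4000L,
                        strand = "+", stringsAsFactors = FALSE)
  m <- anchored_matrix(cov, anchors, upstream = 200, downstream = 200,
                       binsize = 20)
  expect_equal(dim(m), c(1L, 20L))
  # oracle: per-base loop
  win <- 3800:4199
  want <- vapply(seq_len(20), function(b)
    mean(vp[win[((b - 1) * 20 + 1):(b * 20)]]), numeric(1))
  expect_equal(unname(unclass(m)[1, ]), want, tolerance = 1e-12)
  # the mirrored minus-strand anchor reproduces the same row
  manchors <- data.frame(unit_id = "a1", chrom = "chrI",
                         position = len + 1L - 4000L, strand = "-",
                         stringsAsFactors = FALSE)
  mm <- anchored_matrix(cov, manchors, upstream = 200, downstream = 200,
                        binsize = 20)
  expect_equal(unclass(mm), unclass(m), tolerance = 1e-12)
})

test_that("log2 ratio is zero on identity, ~1 on doubling, antisymmetric", {
  set.seed(29)
  cov_a <- cov1(plus = rexp(20000) + 1, len = 20000L)
  cov_b <- scale_coverage(cov_a, 0.5)
  units <- suppressWarnings(c(tu("g1", 3001, 6000, "+", len = 20000L),
                              tu("g2", 9001, 13000, "+", len = 20000L)))
  ma <- scaled_matrix(cov_a, units, n_body_bins = 20, upstream = 100,
                      downstream = 100)
  mb <- scaled_matrix(cov_b, units, n_body_bins = 20, upstream = 100,
                      downstream = 100)
  expect_true(all(unclass(log2_ratio(ma, ma)) == 0))
  near1 <- log2_ratio(ma, mb, pseudocount = 1e-6)
  expect_equal(unname(as.vector(unclass(near1))),
               rep(1, length(near1)), tolerance = 1e-3)
  expect_equal(unclass(log2_ratio(mb, ma, 0.01)),
               -unclass(log2_ratio(ma, mb, 0.01)), tolerance = 1e-12)
  short <- scaled_matrix(cov_a, units, n_body_bins = 10, upstream = 100,
                         downstream = 100)
  expect_error(log2_ratio(ma, short), "scheme")
})

test_that("bootstrap confidence bands behave like the CLT on Gaussian rows", {
  set.seed(101)
  n <- 400L; p <- 12L
  rows <- matrix(rnorm(n * p, mean = 5, sd = 1), n, p)
  m <- ttkit:::new_signal_matrix(rows, data.frame(segment = "anchored",
                                                  offset = seq_len(p)))
  prof <- profile_with_ci(m, level = 0.95, n_boot = 500, seed = 4)
  halfwidth <- (prof$upper - prof$lower) / 2
  clt <- 1.96 * 1 / sqrt(n)
  expect_true(all(abs(halfwidth - clt) / clt < 0.2))
  expect_equal(prof$mean, colMeans(rows), tolerance = 1e-12,
               ignore_attr = TRUE)
  # determinism and degenerate cases
  prof2 <- profile_with_ci(m, level = 0.95, n_boot = 500, seed = 4)
  expect_identical(prof, prof2)
  same <- ttkit:::new_signal_matrix(matrix(3, 5, p),
                                    data.frame(segment = "anchored",
                                               offset = seq_len(p)))
  ps <- profile_with_ci(same, n_boot = 50, seed = 1)
  expect_true(all(ps$upper == ps$lower))
  one <- ttkit:::new_signal_matrix(matrix(1, 1, p),
                                   data.frame(segment = "anchored",
                                              offset = seq_len(p)))
  po <- profile_with_ci(one, n_boot = 10, seed = 1)
  expect_true(all(is.na(po$lower)))
})

test_that("signal matrices serialise with their binning scheme", {
  cov <- cov1(plus = rep(1.5, 9000), len = 9000L)
  u <- tu("g1", 2001, 4000, "+", len = 9000L)
  m <- scaled_matrix(cov, u, n_body_bins = 5, upstream = 50,
                     downstream = 50)
  path <- tempfile(fileext = ".tsv")
  write_signal_matrix(m, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# bins")
  tab <- utils::read.delim(path, skip = 1, check.names = FALSE)
  expect_equal(tab$tu_id, "g1")
  expect_equal(as.numeric(tab[1, -1]), unname(unclass(m)[1, ]))
})
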