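test_that("rrpm_scale follows the spike-in fraction convention", {
  # reference given as a bare count: reference fraction shares the
  # sample's total, reducing to (1e6/total) * (ref/spikein)
  expect_equal(rrpm_scale(10e6, 100e3, reference_spikein = 50e3), 0.05)
  # spike-in equal to reference: plain RPM scale
  expect_equal(rrpm_scale(10e6, 100e3, reference_spikein = 100e3),
               1e6 / 10e6)
  expect_error(rrpm_scale(10e6, 0, 50e3), "RPM")
})

test_that("RRPM is invariant to joint library scaling", {
  withr::local_seed(21)
  raw <- abs(stats::rnorm(200, 5))
  totals <- c(1e6, 2e6)
  spikes <- c(8e4, 3e5)
  ref <- cohort_reference(totals, spikes)
  expect_equal(ref, 1)  # sample 1 has the smaller spike fraction
  base <- normalize_track(tiny_track(raw, units = "raw"), totals[2],
                          spikes[2], "RRPM",
                          reference_spikein = spikes[ref],
                          reference_total = totals[ref])
  for (c in c(2, 10)) {
    scaled <- normalize_track(tiny_track(raw * c, units = "raw"),
                              totals[2] * c, spikes[2] * c, "RRPM",
                              reference_spikein = spikes[ref],
                              reference_total = totals[ref])
    expect_lt(max(abs(scaled$values$chr1 - base$values$chr1)), 1e-9)
  }
})

test_that("region_counts sums covered bins with scaling", {
  tr <- tiny_track(rep(1, 50))
  expect_equal(region_counts(genomic_intervals("chr1", 0, 70), tr), 7)
  expect_equal(region_counts(genomic_intervals("chr1", 0, 70), tr,
                             scale = 2), 14)
  expect_length(region_counts(genomic_intervals(character(), numeric(),
                                                numeric()), tr), 0)
  # overlapping regions sum independently
  both <- genomic_intervals("chr1", c(0, 30), c(70, 100))
  expect_equal(region_counts(both, tr), c(7, 7))
  expect_warning(region_counts(genomic_intervals("chr1", 900, 1000), tr),
                 "off the covered grid")
})

test_that("composite profile is exact on constant and symmetric tracks", {
  const <- tiny_track(rep(3, 1000))
  centers <- data.frame(chrom = "chr1", pos = c(3000, 7000))
  prof <- composite_profile(const, centers, flank = 500, bin = 10)
  expect_true(all(prof$mean_signal == 3))
  expect_equal(nrow(prof), 100)
  # symmetric bump around its center gives a mirror-symmetric profile
  v <- numeric(1000)
  v[481:520] <- c(1:20, 20:1)
  bump <- tiny_track(v)
  prof <- composite_profile(bump, data.frame(chrom = "chr1", pos = 5000),
                            flank = 300, bin = 10)
  expect_equal(prof$mean_signal, rev(prof$mean_signal))
  # two centers: elementwise mean of the single-center profiles
  v2 <- numeric(1000)
  v2[101:110] <- 4
  v2[301:310] <- 8
  tr <- tiny_track(v2)
  p1 <- composite_profile(tr, data.frame(chrom = "chr1", pos = 1050),
                          flank = 100, bin = 10)
  p2 <- composite_profile(tr, data.frame(chrom = "chr1", pos = 3050),
                          flank = 100, bin = 10)
  p12 <- composite_profile(tr, data.frame(chrom = "chr1",
                                          pos = c(1050, 3050)),
                           flank = 100, bin = 10)
  expect_equal(p12$mean_signal, (p1$mean_signal + p2$mean_signal) / 2)
  expect_error(composite_profile(tr, data.frame(chrom = character(),
                                                pos = numeric())),
               "no centers")
  # edge-adjacent centers are zero-padded and flagged
  pe <- composite_profile(tr, data.frame(chrom = "chr1", pos = 50),
                          flank = 100, bin = 10)
  expect_equal(attr(pe, "n_padded"), 1)
})

test_that("profile_matrix sorts by the sort track and matches profiles", {
  v <- numeric(3000)
  v[101:110] <- 5; v[1101:1110] <- 1; v[2101:2110] <- 9
  tr <- tiny_track(v)
  centers <- data.frame(chrom = "chr1",
                        pos = c(1050, 11050, 21050))
  m <- profile_matrix(tr, centers, flank = 100, bin = 10,
                      sort_track = tr)
  # totals 50, 10, 90 -> order 3rd, 1st, 2nd
  expect_equal(rownames(m), c("chr1:20950-21150", "chr1:950-1150",
                              "chr1:10950-11150"))
  # stable order for identical rows
  m2 <- profile_matrix(tiny_track(rep(1, 3000)), centers, 100, 10,
                       sort_track = tiny_track(rep(1, 3000)))
  expect_equal(rownames(m2), c("chr1:950-1150", "chr1:10950-11150",
                               "chr1:20950-21150"))
  # column means of the unsorted matrix equal the composite profile
  m3 <- profile_matrix(tr, centers, flank = 100, bin = 10)
  prof <- composite_profile(tr, centers, flank = 100, bin = 10)
  expect_equal(unname(colMeans(m3)), prof$mean_signal)
})

test_that("delta_track is antisymmetric and enforces its contract", {
  a <- tiny_track(rep(3, 50))
  b <- tiny_track(rep(1, 50))
  d <- delta_track(a, b)
  expect_true(all(d$values$chr1 == 2))
  d0 <- delta_track(a, a)
  expect_true(all(d0$values$chr1 == 0))
  dr <- delta_track(b, a)
  expect_equal(d$values$chr1, -dr$values$chr1)
  raw <- tiny_track(rep(1, 50), units = "raw")
  expect_error(delta_track(raw, raw), "normalized")
  rrpm <- tiny_track(rep(1, 50), units = "RRPM")
  expect_error(delta_track(a, rrpm), "unit mismatch")
  short <- signal_track(list(chr1 = rep(1, 10)), 10, "RPM")
  expect_error(delta_track(a, short), "grid mismatch")
})

test_that("bedGraph round-trips tracks and delta tracks", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  v <- c(0, 0, 3, 3, 1, 0, 2, 2, 2, 0)
  tr <- tiny_track(v, bin = 25, units = "raw")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, bin_size = 25, units = "raw")
  expect_equal(back$values$chr1, v[1:9])  # trailing zeros are implicit
  d <- delta_track(tiny_track(v + 1), tiny_track(rep(1, 10)))
  write_bedgraph(d, f)
  lines <- readLines(f)
  expect_equal(length(lines), 6)  # zero runs kept for deltas
})

test_that("signal_track refuses negative bins", {
  expect_error(signal_track(list(chr1 = c(1, -1)), 10, "RPM"),
               "nonnegative")
})
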