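test_that("read_bed parses BED dialect and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=demo", "chr1\t100\t200",
               "chr2\t0\t50\tpk1\t7.5"), f)
  df <- read_bed(f)
  expect_equal(nrow(df), 2)
  expect_equal(df$start, c(100, 0))
  expect_equal(df$end, c(200, 50))
  expect_equal(df$score, c(NA, 7.5))

  writeLines(c("chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t100\t200", "chr1\tx\t300"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\t100", f)
  expect_error(read_bed(f), "3 tab-separated")
})

test_that("merge_intervals handles overlap, gaps and the empty case", {
  m <- merge_intervals(genomic_intervals("chr1", c(100, 150), c(200, 250)))
  expect_equal(m[, c("start", "end")],
               data.frame(start = 100, end = 250))
  # gap 100 > min_gap 50: unchanged
  m <- merge_intervals(genomic_intervals("chr1", c(100, 300), c(200, 400)),
                       min_gap = 50)
  expect_equal(nrow(m), 2)
  # gap exactly min_gap merges; touching intervals merge at min_gap 0
  m <- merge_intervals(genomic_intervals("chr1", c(100, 300), c(200, 400)),
                       min_gap = 100)
  expect_equal(m$end, 400)
  m <- merge_intervals(genomic_intervals("chr1", c(100, 200), c(200, 300)))
  expect_equal(nrow(m), 1)
  expect_equal(nrow(merge_intervals(genomic_intervals(character(),
                                                      numeric(),
                                                      numeric()))), 0)
  expect_error(merge_intervals(genomic_intervals("chr1", 0, 10), -1),
               "min_gap")
})

test_that("consensus_peaks matches the worked depth example", {
  a <- peak_set(genomic_intervals("chr1", 100, 200), "TF", "A")
  b <- peak_set(genomic_intervals("chr1", 150, 250), "TF", "B")
  cc <- peak_set(genomic_intervals("chr1", 400, 500), "TF", "C")
  cons <- consensus_peaks(list(a, b, cc), k = 2)
  expect_equal(cons$peaks$start, 150)
  expect_equal(cons$peaks$end, 200)
  expect_equal(cons$peaks$support, "A,B")
  # single set, k = 1: merged copy
  one <- peak_set(genomic_intervals("chr1", c(0, 50), c(60, 100)), "TF")
  expect_equal(consensus_peaks(list(one), 1)$peaks$end, 100)
  # pairwise-disjoint sets, k = 2: empty
  d <- lapply(c(0, 1000, 2000), function(s)
    peak_set(genomic_intervals("chr1", s, s + 100), "TF"))
  expect_equal(length(consensus_peaks(d, 2)), 0)
  expect_error(consensus_peaks(d, 4), "exceeds")
  expect_error(consensus_peaks(d, 0), "positive")
})

test_that("consensus union mode widens to contributing intervals", {
  a <- peak_set(genomic_intervals("chr1", 100, 200), "TF", "A")
  b <- peak_set(genomic_intervals("chr1", 150, 250), "TF", "B")
  u <- consensus_peaks(list(a, b), 2, mode = "union")
  expect_equal(u$peaks$start, 100)
  expect_equal(u$peaks$end, 250)
})

test_that("consensus is monotone in k and idempotent on identical sets", {
  withr::local_seed(7)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i)
      peak_set(random_intervals(15), "TF", paste0("L", i)))
    cons <- lapply(1:3, function(k) consensus_peaks(sets, k)$peaks)
    # coverage at k+1 is a subset of coverage at k
    for (k in 1:2) {
      mk <- membership(cons[[k]])
      mk1 <- membership(cons[[k + 1]])
      expect_true(all(mk[mk1]))
    }
    same <- replicate(3, sets[[1]], simplify = FALSE)
    merged <- merge_intervals(sets[[1]]$peaks)
    for (k in 1:3)
      expect_equal(consensus_peaks(same, k)$peaks[, c("start", "end")],
                   merged[, c("start", "end")])
  }
})

test_that("classify_cooccupancy matches worked examples and partitions", {
  a <- peak_set(genomic_intervals("chr1", 100, 200), "SNAI2")
  b <- peak_set(genomic_intervals("chr1", 150, 250), "MYOD")
  cl <- classify_cooccupancy(a, b)
  expect_equal(unname(cl$counts), c(0, 0, 1))
  d <- peak_set(genomic_intervals("chr1", 500, 600), "MYOD")
  expect_equal(unname(classify_cooccupancy(a, d)$counts), c(1, 1, 0))
  self <- classify_cooccupancy(a, a)
  expect_equal(unname(self$counts), c(0, 0, 1))
  # min_overlap: 50 bp overlap fails a 51 bp requirement
  expect_equal(unname(classify_cooccupancy(a, b, min_overlap = 51)$counts),
               c(1, 1, 0))
  expect_equal(unname(classify_cooccupancy(a, b, min_overlap = 50)$counts),
               c(0, 0, 1))
  # partition: every A peak in exactly one class
  withr::local_seed(11)
  for (rep in 1:20) {
    pa <- peak_set(random_intervals(30), "A")
    pb <- peak_set(random_intervals(30), "B")
    cl <- classify_cooccupancy(pa, pb)
    expect_equal(length(cl$a_only) + length(cl$shared), length(pa))
    expect_equal(unname(cl$counts["n_a_only"] + cl$counts["n_shared"]),
                 length(pa))
  }
})

test_that("interval operations equal the per-base oracle on random data", {
  withr::local_seed(42)
  for (rep in 1:60) {
    df <- random_intervals()
    gap <- sample(c(0, 1, 10, 500), 1)
    got <- merge_intervals(df, gap)
    expect_equal(got[, c("start", "end")],
                 oracle_merge(df, gap)[, c("start", "end")],
                 ignore_attr = TRUE)
    sets <- lapply(1:3, function(i) random_intervals(20))
    k <- sample(1:3, 1)
    got <- consensus_peaks(lapply(sets, peak_set, factor = "TF"), k)
    expect_equal(got$peaks[, c("start", "end")],
                 oracle_consensus(sets, k)[, c("start", "end")],
                 ignore_attr = TRUE)
    a <- random_intervals(25)
    b <- random_intervals(25)
    mo <- sample(c(1, 25, 200), 1)
    cl <- classify_cooccupancy(peak_set(a, "A"), peak_set(b, "B"), mo)
    expect_equal(unname(cl$counts["n_shared"]),
                 sum(oracle_overlap_hits(a, b, mo)))
    expect_equal(unname(cl$counts["n_b_only"]),
                 sum(!oracle_overlap_hits(b, a, mo)))
  }
})

test_that("peak_set validates summits, scores and factor", {
  expect_error(peak_set(genomic_intervals("chr1", 0, 10), ""), "factor")
  pk <- genomic_intervals("chr1", 100, 200)
  pk$summit <- 250
  expect_error(peak_set(pk, "TF"), "summit")
  pk$summit <- 150
  pk$score <- -1
  expect_error(peak_set(pk, "TF"), "nonnegative")
})

test_that("BED round-trip preserves intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  df <- genomic_intervals("chr2", c(5, 1000), c(600, 22000))
  df$name <- c("a", "b")
  write_bed(df, f)
  back <- read_bed(f)
  expect_equal(back[, c("chrom", "start", "end", "name")],
               df[, c("chrom", "start", "end", "name")])
})
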