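# small config keeps the generator fast in unit tests
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chrom = 2, chrom_length = 5e5,
             n_tads_per_chrom = 5, genes_per_tad = 6,
             n_direct = 8, n_indirect = 12,
             n_repressor = 60, n_activator = 120, ...)
}

test_that("simulated genome is deterministic and respects its config", {
  g1 <- simulate_genome(small_config())
  g2 <- simulate_genome(small_config())
  expect_identical(g1, g2)
  expect_false(identical(g1$tads,
                         simulate_genome(small_config(seed = 2))$tads))
  expect_equal(nrow(g1$tads), 10)
  expect_equal(nrow(g1$genes), 60)
  # every gene's TSS inside its TAD
  tad_of <- assign_to_tads(g1$genes, g1$tads)
  expect_false(any(is.na(tad_of)))
  # boundary gaps: TAD footprint ~ (1 - gap_fraction) of the genome
  footprint <- sum(g1$tads$end - g1$tads$start)
  expect_equal(footprint / 1e6, 0.9, tolerance = 0.02)
  expect_error(simulate_genome(sim_config(n_tads_per_chrom = 1,
                                          genes_per_tad = 1e7)),
               "infeasible")
})

test_that("planted ground-truth invariants hold on generated bundles", {
  cfg <- small_config()
  g <- simulate_genome(cfg)
  sp <- simulate_peaksets(cfg, g)
  truth <- sp$truth
  expect_equal(sum(truth$gene_class == "direct"), 8)
  expect_equal(sum(truth$gene_class == "indirect"), 12)
  # indirect genes' TADs contain no repressor master peak
  tad_of <- assign_to_tads(g$genes, g$tads)
  ind_tads <- unique(tad_of[truth$gene_class == "indirect"])
  rep_tads <- assign_to_tads(sp$master$repressor, g$tads,
                             anchor = "midpoint")
  expect_length(intersect(ind_tads, rep_tads), 0)
  # every direct gene's TAD holds >= 1 repressor peak seen in >= 2 lines
  dir_tads <- unique(tad_of[truth$gene_class == "direct"])
  strong <- rep_tads[sp$master$repressor$n_lines >= 2]
  expect_true(all(dir_tads %in% strong))
})

test_that("peak reproducibility drives consensus recovery", {
  cfg <- small_config(reproducibility = 1.0)
  g <- simulate_genome(cfg)
  sp <- simulate_peaksets(cfg, g)
  sets <- lapply(sp$peaksets, `[[`, "repressor")
  cons <- consensus_peaks(sets, k = length(sets))
  master <- merge_intervals(sp$master$repressor)
  expect_equal(cons$peaks[, c("chrom", "start", "end")],
               master[, c("chrom", "start", "end")], ignore_attr = TRUE)
  cfg0 <- small_config(reproducibility = 0)
  sp0 <- simulate_peaksets(cfg0, simulate_genome(cfg0))
  sets0 <- lapply(sp0$peaksets, `[[`, "repressor")
  expect_true(all(vapply(sets0, length, 0L) == 0))
})

test_that("shared-fraction accounting is respected", {
  cfg <- sim_config(seed = 1, shared_fraction = 0.6, n_repressor = 500)
  g <- simulate_genome(cfg)
  sp <- simulate_peaksets(cfg, g)
  # forced direct-TAD peaks may add a few repressor_only rows
  frac <- mean(sp$master$repressor$class == "shared")
  expect_equal(frac, 0.6, tolerance = 0.05)
})

test_that("noise-free tracks equal the bump expectation exactly", {
  cfg <- small_config(noise = "none", background_rate = 0)
  g <- simulate_genome(cfg)
  sp <- simulate_peaksets(cfg, g)
  tr <- simulate_tracks(cfg, g, sp, conditions = "control")
  v <- tr[["repressor.control"]]$track$values
  m <- sp$master$repressor
  # peak bins positive at a known summit, zero far away
  i <- which.max(m$height)
  bin <- floor(m$center[i] / cfg$bin_size) + 1
  expect_gt(v[[m$chrom[i]]][bin], 0)
  total_bumps <- sum(unlist(v))
  # triangular kernel area ~ height * halfwidth per peak
  expect_equal(total_bumps,
               sum(m$height * (m$end - m$start) / 2) / cfg$bin_size,
               tolerance = 0.05)
  # knockdown factor 1: conditions agree after spike-in normalization
  # (raw tracks differ only by the planted depth/efficiency factors)
  cfg1 <- small_config(noise = "none", background_rate = 0,
                       knockdown_factor = 1, activator_boost = 1)
  trk <- simulate_tracks(cfg1, g, sp, c("control", "knockdown"))
  totals <- vapply(trk, `[[`, 0, "total_mapped_reads")
  spikes <- vapply(trk, `[[`, 0, "spikein_reads")
  ref <- cohort_reference(totals, spikes)
  nrm <- lapply(trk, function(s)
    normalize_track(s$track, s$total_mapped_reads, s$spikein_reads,
                    "RRPM", reference_spikein = spikes[ref],
                    reference_total = totals[ref]))
  expect_equal(nrm[["repressor.control"]]$values,
               nrm[["repressor.knockdown"]]$values, tolerance = 1e-9)
})

test_that("planted knockdown effect appears in normalized deltas", {
  cfg <- small_config()
  g <- simulate_genome(cfg)
  sp <- simulate_peaksets(cfg, g)
  tr <- simulate_tracks(cfg, g, sp, c("control", "knockdown"))
  totals <- vapply(tr, `[[`, 0, "total_mapped_reads")
  spikes <- vapply(tr, `[[`, 0, "spikein_reads")
  ref <- cohort_reference(totals, spikes)
  norm <- lapply(tr, function(s)
    normalize_track(s$track, s$total_mapped_reads, s$spikein_reads,
                    "RRPM", reference_spikein = spikes[ref],
                    reference_total = totals[ref]))
  d <- delta_track(norm[["activator.knockdown"]],
                   norm[["activator.control"]])
  m <- sp$master$activator
  shared <- m[m$class == "shared", ]
  only <- m[m$class == "activator_only", ]
  expect_gt(mean_delta(d, shared), mean_delta(d, only))
  # repressor signal drops at its own sites under knockdown
  dr <- delta_track(norm[["repressor.knockdown"]],
                    norm[["repressor.control"]])
  expect_lt(mean_delta(dr, sp$master$repressor), 0)
})

test_that("simulated expression separates planted classes", {
  cfg <- small_config()
  g <- simulate_genome(cfg)
  sp <- simulate_peaksets(cfg, g)
  ex <- simulate_expression(cfg, sp$truth)
  expect_named(ex, c("knockdown", "treatment"))
  tb <- ex$knockdown$CL1
  up <- sp$truth$gene_class != "null"
  expect_gt(mean(tb$log2FC[up]), mean(tb$log2FC[!up]) + 1)
  expect_true(all(tb$fdr >= tb$pvalue - 1e-12))
  # fixed seed reproduces tables exactly
  ex2 <- simulate_expression(cfg, sp$truth)
  expect_identical(ex, ex2)
})

test_that("knockdown and treatment contrasts agree on the planted program", {
  cfg <- small_config()
  g <- simulate_genome(cfg)
  truth <- simulate_peaksets(cfg, g)$truth
  ex <- simulate_expression(cfg, truth)
  direct <- names(truth$gene_class)[truth$gene_class == "direct"]
  for (con in c("knockdown", "treatment"))
    for (cl in names(ex[[con]])) {
      tb <- ex[[con]][[cl]]
      l2fc <- stats::setNames(tb$log2FC, tb$gene_id)
      expect_gt(stats::median(l2fc[direct]), 0)
    }
  # per-gene fold changes of the two contrasts correlate positively
  kd <- ex$knockdown$CL1
  tr <- ex$treatment$CL1
  r <- stats::cor(kd$log2FC, tr$log2FC)
  expect_gt(r, 0)
})

test_that("fixture bundles round-trip and regenerate byte-identically", {
  cfg <- small_config()
  bundle <- simulate_bundle(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(bundle, d1)
  write_fixture_bundle(simulate_bundle(cfg), d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  back <- read_fixture_bundle(d1)
  expect_equal(back$genome$tads$tad_id, bundle$genome$tads$tad_id)
  expect_equal(back$genome$genes$tss, bundle$genome$genes$tss)
  expect_identical(sort(names(back$truth$gene_class)),
                   sort(names(bundle$truth$gene_class)))
  expect_equal(back$truth$gene_class[names(bundle$truth$gene_class)],
               bundle$truth$gene_class)
  # truth classes partition the gene list
  expect_setequal(names(back$truth$gene_class),
                  bundle$genome$genes$gene_id)
  # DE tables and tracks survive exactly
  expect_equal(back$expression$knockdown$CL1$log2FC,
               bundle$expression$knockdown$CL1$log2FC)
  expect_equal(back$tracks[["activator.control"]]$track$values$chr1,
               bundle$tracks[["activator.control"]]$track$values$chr1)
  expect_equal(back$peaksets$CL1$repressor$peaks$start,
               bundle$peaksets$CL1$repressor$peaks$start)
})
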