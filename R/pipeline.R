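#' Pipeline configuration
#'
#' One configuration object driving [run_pipeline()]: either a fixture
#' directory written by [write_fixture_bundle()] (`input_dir`) or a
#' simulation seed (`simulate = TRUE`), plus every tunable of the
#' downstream modules with defaults matching the package's documented
#' conventions. The config is echoed verbatim into the report.
#'
#' @param input_dir fixture bundle directory, or `NULL` with
#'   `simulate = TRUE`.
#' @param simulate when `TRUE`, generate the bundle from `sim` first.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param outdir output directory.
#' @param consensus_k minimum supporting cell lines for a consensus peak.
#' @param min_overlap co-occupancy overlap in bp.
#' @param stitch_gap,tss_exclusion ROSE stitching parameters (bp).
#' @param flank,profile_bin composite-profile window half-width and bin.
#' @param l2fc_min,fdr_max consistent-upregulation thresholds
#'   (exclusive).
#' @param normalization `"RRPM"` or `"RPM"` for tracks and deltas.
#' @param gsea_n_perm,gsea_weight_p preranked enrichment parameters.
#' @param seed RNG seed for permutation stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = is.null(input_dir),
                            sim = sim_config(seed = seed),
                            outdir = tempfile("tadtarget_run"),
                            consensus_k = 2, min_overlap = 1,
                            stitch_gap = 12500, tss_exclusion = 2500,
                            flank = 2000, profile_bin = NULL,
                            l2fc_min = 0, fdr_max = 0.05,
                            normalization = "RRPM",
                            gsea_n_perm = 1000, gsea_weight_p = 1,
                            seed = 1) {
  cfg <- as.list(environment())
  cfg$sim <- if (simulate) unclass(sim) else NULL
  stopifnot(cfg$normalization %in% c("RPM", "RRPM"))
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the end-to-end target-classification pipeline
#'
#' Executes, in order: consensus peak calling across cell lines;
#' repressor/activator co-occupancy; chromatin-state density (when a
#' segmentation is present); super-enhancer calling on the activator
#' track; spike-in-normalized condition deltas at peak classes;
#' TAD-constrained direct/indirect target classification of the
#' consistently upregulated candidate genes; and preranked enrichment of
#' the candidate gene set. Writes all intermediate tables under
#' `config$outdir` and returns (and writes) a machine-readable report
#' whose stage counts satisfy the partition identity
#' `n_direct + n_indirect + n_excluded = n_candidates`.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report` list (also written as `report.json` and
#'   `summary.tsv` in `outdir`); the runtime lives in a separate
#'   `runtime_sec` field so reports are otherwise deterministic.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- pipeline_stage("input", {
    if (config$simulate) {
      sim <- do.call(sim_config, config$sim)
      b <- simulate_bundle(sim)
      write_fixture_bundle(b, file.path(outdir, "bundle"))
      b$chrom_lengths <- b$genome$chrom_lengths
      b
    } else read_fixture_bundle(config$input_dir)
  })
  cell_lines <- names(bundle$peaksets)
  rep_sets <- lapply(bundle$peaksets, `[[`, "repressor")
  act_sets <- lapply(bundle$peaksets, `[[`, "activator")

  hc <- pipeline_stage("consensus", {
    if (config$consensus_k > length(rep_sets))
      stop("consensus_k exceeds the number of cell lines")
    consensus_peaks(rep_sets, k = config$consensus_k)
  })
  hc_all <- pipeline_stage("consensus", consensus_peaks(
    rep_sets, k = length(rep_sets)))
  act_hc <- pipeline_stage("consensus",
                           consensus_peaks(act_sets,
                                           k = min(config$consensus_k,
                                                   length(act_sets))))
  write_bed(cbind(hc$peaks[c("chrom", "start", "end")],
                  name = hc$peaks$support),
            file.path(outdir, "consensus_repressor.bed"))

  venn <- pipeline_stage("cooccupancy",
                         classify_cooccupancy(hc, act_hc,
                                              config$min_overlap))

  density <- NULL
  if (!is.null(bundle$segmentation))
    density <- pipeline_stage("states",
                              peaks_per_gb(hc, bundle$segmentation))

  # tracks: normalize, rank enhancers on the activator control track
  norm <- pipeline_stage("normalize", {
    tr <- bundle$tracks
    totals <- vapply(tr, `[[`, 0, "total_mapped_reads")
    spikes <- vapply(tr, `[[`, 0, "spikein_reads")
    if (config$normalization == "RRPM") {
      ref <- cohort_reference(totals, spikes)
      lapply(tr, function(s)
        normalize_track(s$track, s$total_mapped_reads, s$spikein_reads,
                        units = "RRPM",
                        reference_spikein = spikes[ref],
                        reference_total = totals[ref]))
    } else lapply(tr, function(s)
      normalize_track(s$track, s$total_mapped_reads, units = "RPM"))
  })

  rose <- pipeline_stage("rose", {
    tss <- bundle$genome$genes
    call_super_enhancers(act_hc, norm[["activator.control"]],
                         tss_list = tss, max_gap = config$stitch_gap,
                         tss_exclusion = config$tss_exclusion)
  })
  write_enhancer_ranking(rose, file.path(outdir, "enhancers.tsv"),
                         file.path(outdir, "super_enhancers.bed"))

  deltas <- pipeline_stage("profiles", {
    da <- delta_track(norm[["activator.knockdown"]],
                      norm[["activator.control"]],
                      label = "activator knockdown minus control")
    write_bedgraph(da, file.path(outdir, "delta_activator.bedGraph"))
    shared_act <- classify_cooccupancy(act_hc, hc, config$min_overlap)
    list(delta = da,
         mean_shared = mean_delta(da, shared_act$shared$peaks),
         mean_activator_only = mean_delta(da, shared_act$a_only$peaks))
  })

  candidates <- pipeline_stage("classify", {
    kd <- bundle$expression$knockdown
    consistent_upregulated(kd, l2fc_min = config$l2fc_min,
                           fdr_max = config$fdr_max,
                           universe = bundle$gene_sets[["myogenic"]])
  })
  evidence <- lapply(bundle$expression$knockdown, function(tb)
    stats::setNames(tb$log2FC, tb$gene_id))
  calls <- pipeline_stage("classify",
                          classify_targets(candidates, hc,
                                           bundle$genome$tads,
                                           bundle$genome$genes,
                                           evidence = evidence))
  write_target_calls(calls, file.path(outdir, "target_calls.tsv"),
                     file.path(outdir, "target_calls.json"))

  enrich <- pipeline_stage("enrich", {
    tb <- bundle$expression$knockdown[[1]]
    ranked <- stats::setNames(tb$log2FC, tb$gene_id)
    preranked_enrichment(ranked, bundle$gene_sets[["myogenic"]],
                         weight_p = config$gsea_weight_p,
                         n_perm = config$gsea_n_perm,
                         seed = config$seed)
  })

  counts <- attr(calls, "counts")
  report <- list(
    tool = "tadtarget",
    version = as.character(utils::packageVersion("tadtarget")),
    parameters = unclass(config)[setdiff(names(config), "outdir")],
    cell_lines = cell_lines,
    n_consensus_peaks = length(hc),
    n_consensus_all_lines = length(hc_all),
    cooccupancy = as.list(venn$counts),
    state_density = if (!is.null(density)) density else NULL,
    n_enhancers = nrow(rose$enhancers),
    n_super = rose$n_super,
    n_typical = rose$n_typical,
    delta_mean_shared = deltas$mean_shared,
    delta_mean_activator_only = deltas$mean_activator_only,
    n_candidates = length(candidates),
    n_direct = unname(counts["n_direct"]),
    n_indirect = unname(counts["n_indirect"]),
    n_excluded = unname(counts["n_excluded"]),
    enrichment = list(es = enrich$es, nes = enrich$nes,
                      nominal_p = enrich$nominal_p))
  stopifnot(report$n_direct + report$n_indirect + report$n_excluded ==
              report$n_candidates)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  summary_df <- data.frame(
    stat = c("n_consensus_peaks", "n_consensus_all_lines", "n_shared",
             "n_enhancers", "n_super", "n_candidates", "n_direct",
             "n_indirect", "n_excluded"),
    value = c(report$n_consensus_peaks, report$n_consensus_all_lines,
              report$cooccupancy$n_shared, report$n_enhancers,
              report$n_super, report$n_candidates, report$n_direct,
              report$n_indirect, report$n_excluded))
  utils::write.table(summary_df, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$runtime_sec <- runtime
  report$outdir <- outdir
  report$calls <- calls
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n",
      sprintf("  consensus peaks (>=k lines): %d (all lines: %d)\n",
              x$n_consensus_peaks, x$n_consensus_all_lines),
      sprintf("  co-occupancy a/b/shared: %d/%d/%d\n",
              x$cooccupancy$n_a_only, x$cooccupancy$n_b_only,
              x$cooccupancy$n_shared),
      sprintf("  enhancers: %d (%d super, %d typical)\n", x$n_enhancers,
              x$n_super, x$n_typical),
      sprintf("  delta (kd - ctrl): shared %.3f vs activator-only %.3f\n",
              x$delta_mean_shared, x$delta_mean_activator_only),
      sprintf("  candidates %d = direct %d + indirect %d + excluded %d\n",
              x$n_candidates, x$n_direct, x$n_indirect, x$n_excluded),
      sprintf("  enrichment: ES %.3f, NES %.3f, p %.4g\n",
              x$enrichment$es, x$enrichment$nes,
              x$enrichment$nominal_p),
      sprintf("  runtime: %.1f s -> %s\n", x$runtime_sec, x$outdir),
      sep = "")
  invisible(x)
}
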