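#' Simulation configuration
#'
#' Defaults describe the toy study the test suite exercises end to end:
#' three cell lines of a fusion-negative sarcoma-like system, a
#' repressor (SNAI2-like) and an activator (MYOD-like) profiled by
#' ChIP-seq with exogenous spike-in, TAD maps, and knockdown plus
#' treatment-mimic RNA-seq contrasts with planted direct/indirect/null
#' target genes. Scale (3 chromosomes x 2 Mb, 30 TADs, 300 genes, 600
#' activator + 300 repressor master peaks) keeps every stage in seconds
#' while preserving the statistical structure being tested.
#'
#' @param seed integer RNG seed; the single source of randomness.
#' @param n_chrom,chrom_length toy genome shape.
#' @param n_tads_per_chrom,tad_gap_fraction TADs per chromosome and the
#'   fraction of each chromosome left as boundary gaps.
#' @param genes_per_tad genes planted per TAD (TSS inside the TAD).
#' @param n_direct,n_indirect planted direct / indirect target genes
#'   (remaining genes are null).
#' @param cell_lines cell line names (>= 2).
#' @param n_repressor,n_activator master peak counts.
#' @param peak_width_min,peak_width_max peak widths (uniform draw).
#' @param reproducibility probability a master peak is called in a given
#'   cell line.
#' @param shared_fraction fraction of repressor master peaks placed at
#'   an activator peak (co-occupied class).
#' @param shared_offset_sd bp jitter between co-occupied repressor and
#'   activator peak centers.
#' @param bin_size track bin width (bp).
#' @param bump_height mean bump height (reads/bin at peak center).
#' @param background_rate Poisson background rate per bin.
#' @param knockdown_factor multiplier on repressor bump height under
#'   knockdown (< 1: depletion).
#' @param activator_boost multiplier on activator bump height at
#'   co-occupied peaks under knockdown/treatment (> 1: invasion of the
#'   vacated sites).
#' @param noise `"poisson"` or `"none"` (tracks equal their expected
#'   bump profile exactly).
#' @param l2fc_mean,l2fc_sd planted log2 fold change for direct and
#'   indirect genes (both upregulated on knockdown in every cell line).
#' @param de_sigma null log2FC standard deviation (p-values are
#'   two-sided normal tails at this sigma).
#' @param spikein_base,total_base baseline spike-in / total mapped reads
#'   per sample (conditions vary around these).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 3, chrom_length = 2e6,
                       n_tads_per_chrom = 10, tad_gap_fraction = 0.1,
                       genes_per_tad = 10,
                       n_direct = 30, n_indirect = 100,
                       cell_lines = c("CL1", "CL2", "CL3"),
                       n_repressor = 300, n_activator = 600,
                       peak_width_min = 200, peak_width_max = 600,
                       reproducibility = 0.85,
                       shared_fraction = 0.6, shared_offset_sd = 50,
                       bin_size = 50, bump_height = 30,
                       background_rate = 0.2,
                       knockdown_factor = 0.2, activator_boost = 1.8,
                       noise = "poisson",
                       l2fc_mean = 2, l2fc_sd = 0.5, de_sigma = 0.5,
                       spikein_base = 1e5, total_base = 1e6) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chrom >= 1, cfg$chrom_length > 0,
            cfg$n_tads_per_chrom >= 1,
            cfg$tad_gap_fraction >= 0, cfg$tad_gap_fraction < 1,
            cfg$reproducibility >= 0, cfg$reproducibility <= 1,
            cfg$shared_fraction >= 0, cfg$shared_fraction <= 1,
            cfg$noise %in% c("poisson", "none"),
            length(cfg$cell_lines) >= 2)
  n_genes <- cfg$n_chrom * cfg$n_tads_per_chrom * cfg$genes_per_tad
  if (cfg$n_direct + cfg$n_indirect > n_genes)
    stop("infeasible config: more planted targets than genes",
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a toy genome: chromosomes, TADs and genes
#'
#' TADs come from sorted random breakpoints per chromosome, shrunk
#' toward their centers so `tad_gap_fraction` of each chromosome is
#' boundary gap; each gene's TSS lies inside its TAD. Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()].
#' @return List with `chrom_lengths` (named), `tads` ([tad_map()]) and
#'   `genes` ([gene_table()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_chrom))
  chrom_lengths <- stats::setNames(rep(L, config$n_chrom), chroms)
  nt <- config$n_tads_per_chrom
  tads <- do.call(rbind, lapply(chroms, function(ch) {
    w <- stats::runif(nt, 0.5, 1.5)       # TAD size heterogeneity
    bp <- c(0, cumsum(w / sum(w)) * L)
    shrink <- config$tad_gap_fraction / 2
    start <- floor(bp[-length(bp)] + shrink * diff(bp))
    end <- ceiling(bp[-1] - shrink * diff(bp))
    data.frame(chrom = ch, start = start, end = end,
               tad_id = sprintf("%s_tad%02d", ch, seq_len(nt)),
               stringsAsFactors = FALSE)
  }))
  tads <- tad_map(tads)
  gpt <- config$genes_per_tad
  # every gene needs its own TSS base inside the TAD
  if (any(gpt > (tads$end - tads$start - 1)))
    stop("infeasible config: genes_per_tad exceeds TAD capacity",
         call. = FALSE)
  genes <- do.call(rbind, lapply(seq_len(nrow(tads)), function(i) {
    tss <- floor(stats::runif(gpt, tads$start[i], tads$end[i] - 1))
    len <- floor(stats::runif(gpt, 2000, 20000))
    strand <- sample(c("+", "-"), gpt, replace = TRUE)
    start <- ifelse(strand == "+", tss, pmax(0, tss + 1 - len))
    end <- ifelse(strand == "+",
                  pmin(config$chrom_length, tss + len), tss + 1)
    data.frame(gene_id = sprintf("%s_g%02d", tads$tad_id[i],
                                 seq_len(gpt)),
               symbol = sprintf("G%s.%d", i, seq_len(gpt)),
               chrom = tads$chrom[i], start = start, end = end,
               strand = strand, stringsAsFactors = FALSE)
  }))
  list(chrom_lengths = chrom_lengths, tads = tads,
       genes = gene_table(genes))
}

#' Simulate multi-cell-line peak sets with planted ground truth
#'
#' Builds a master list of activator peaks and repressor peaks; a
#' configured fraction of repressor peaks is planted at an activator
#' peak (the co-occupied "shared" class, centers jittered by
#' `shared_offset_sd`). Each cell line includes each master peak
#' independently with probability `reproducibility`. Gene classes are
#' planted TAD-wise: direct genes live in TADs that receive at least one
#' repressor master peak present in >= 2 cell lines; indirect genes live
#' in TADs kept entirely repressor-free.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return List with `peaksets` (per cell line: `repressor`,
#'   `activator` [peak_set()]s), `master` (data frames with planted
#'   class columns) and `truth` (gene classes, peak classes, TAD roles).
#' @export
simulate_peaksets <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  force(genome)  # evaluate before seeding: the genome draw has its own seed
  set.seed(config$seed + 1L)
  tads <- genome$tads
  genes <- genome$genes
  n_tads <- nrow(tads)
  gpt <- config$genes_per_tad
  n_direct_tads <- ceiling(config$n_direct / gpt)
  n_indirect_tads <- ceiling(config$n_indirect / gpt)
  if (n_direct_tads + n_indirect_tads > n_tads)
    stop("infeasible config: not enough TADs for planted classes",
         call. = FALSE)
  role <- rep("free", n_tads)
  ord <- sample.int(n_tads)
  role[ord[seq_len(n_direct_tads)]] <- "direct"
  role[ord[n_direct_tads + seq_len(n_indirect_tads)]] <- "indirect"
  tad_of_gene <- rep(seq_len(n_tads), each = gpt)
  gene_class <- rep("null", nrow(genes))
  direct_pool <- which(role[tad_of_gene] == "direct")
  indirect_pool <- which(role[tad_of_gene] == "indirect")
  gene_class[sample(direct_pool, config$n_direct)] <- "direct"
  gene_class[sample(indirect_pool, config$n_indirect)] <- "indirect"
  # repressor-free zone: indirect TADs (no repressor peak may land
  # there); expanded by the peak width plus co-localization jitter so no
  # repressor *interval* can reach into an indirect TAD
  indirect_tads <- tads[role == "indirect", , drop = FALSE]
  margin <- config$peak_width_max + 4 * config$shared_offset_sd
  indirect_expanded <- indirect_tads
  if (nrow(indirect_expanded)) {
    indirect_expanded$start <- pmax(0, indirect_expanded$start - margin)
    indirect_expanded$end <- indirect_expanded$end + margin
  }
  draw_centers <- function(n, avoid) {
    out <- data.frame(chrom = character(), center = numeric())
    while (nrow(out) < n) {
      need <- n - nrow(out)
      ch <- sample(names(genome$chrom_lengths), need * 2, replace = TRUE)
      ce <- floor(stats::runif(need * 2, 2000,
                               genome$chrom_lengths[ch] - 2000))
      cand <- data.frame(chrom = ch, center = ce,
                         stringsAsFactors = FALSE)
      if (nrow(avoid)) {
        bad <- overlaps_any0(data.frame(chrom = cand$chrom,
                                        start = cand$center,
                                        end = cand$center + 1),
                             avoid)
        cand <- cand[!bad, , drop = FALSE]
      }
      out <- rbind(out, utils::head(cand, need))
    }
    out
  }
  # activator master peaks: anywhere
  act <- draw_centers(config$n_activator,
                      avoid = indirect_tads[0, , drop = FALSE])
  act$width <- floor(stats::runif(config$n_activator,
                                  config$peak_width_min,
                                  config$peak_width_max))
  # repressor master peaks: outside indirect TADs; a shared fraction sits
  # on an activator peak
  n_rep <- config$n_repressor
  n_shared <- round(config$shared_fraction * n_rep)
  rep_rows <- draw_centers(n_rep, avoid = indirect_expanded)
  rep_rows$width <- floor(stats::runif(n_rep, config$peak_width_min,
                                       config$peak_width_max))
  rep_rows$class <- "repressor_only"
  if (n_shared > 0) {
    # anchor shared repressor peaks to activator peaks outside indirect TADs
    act_anchor_ok <- !overlaps_any0(
      data.frame(chrom = act$chrom, start = act$center,
                 end = act$center + 1), indirect_expanded)
    anchors <- sample(which(act_anchor_ok), n_shared,
                      replace = n_shared > sum(act_anchor_ok))
    idx <- seq_len(n_shared)
    jitter <- round(stats::rnorm(n_shared, 0, config$shared_offset_sd))
    jitter <- pmin(pmax(jitter, -3 * config$shared_offset_sd),
                   3 * config$shared_offset_sd)
    rep_rows$chrom[idx] <- act$chrom[anchors]
    rep_rows$center[idx] <- pmax(2000, act$center[anchors] + jitter)
    rep_rows$class[idx] <- "shared"
    act$class <- "activator_only"
    act$class[anchors] <- "shared"
  } else act$class <- "activator_only"
  # guarantee every direct TAD carries >= 1 repressor master peak
  direct_tads <- tads[role == "direct", , drop = FALSE]
  has_peak <- vapply(seq_len(nrow(direct_tads)), function(i)
    any(overlaps_any0(data.frame(chrom = rep_rows$chrom,
                                 start = rep_rows$center,
                                 end = rep_rows$center + 1),
                      direct_tads[i, , drop = FALSE])), TRUE)
  if (any(!has_peak)) {
    extra <- direct_tads[!has_peak, , drop = FALSE]
    add <- data.frame(chrom = extra$chrom,
                      center = floor((extra$start + extra$end) / 2),
                      width = floor(stats::runif(nrow(extra),
                                                 config$peak_width_min,
                                                 config$peak_width_max)),
                      class = "repressor_only",
                      stringsAsFactors = FALSE)
    rep_rows <- rbind(rep_rows, add)
  }
  rep_rows$height <- stats::rlnorm(nrow(rep_rows), log(config$bump_height),
                                   0.4)
  act$height <- stats::rlnorm(nrow(act), log(config$bump_height), 0.4)
  rep_rows$forced <- FALSE
  # cell-line inclusion: Bernoulli(reproducibility); repressor peaks inside
  # direct TADs are forced into >= 2 cell lines so consensus recovers them
  in_direct_tad <- overlaps_any0(data.frame(chrom = rep_rows$chrom,
                                            start = rep_rows$center,
                                            end = rep_rows$center + 1),
                                 direct_tads)
  rep_rows$forced <- in_direct_tad
  mk_peaks <- function(master, present) {
    m <- master[present, , drop = FALSE]
    df <- data.frame(chrom = m$chrom,
                     start = pmax(0, m$center - floor(m$width / 2)),
                     end = m$center + ceiling(m$width / 2),
                     strand = rep(".", nrow(m)), summit = m$center,
                     score = m$height, stringsAsFactors = FALSE)
    df[order(df$chrom, df$start), , drop = FALSE]
  }
  peaksets <- lapply(config$cell_lines, function(cl) NULL)
  names(peaksets) <- config$cell_lines
  ncl <- length(config$cell_lines)
  inc_rep <- matrix(stats::runif(nrow(rep_rows) * ncl) <
                      config$reproducibility, ncol = ncl)
  inc_act <- matrix(stats::runif(nrow(act) * ncl) <
                      config$reproducibility, ncol = ncl)
  if (config$reproducibility > 0) {
    for (i in which(rep_rows$forced)) {
      if (sum(inc_rep[i, ]) < 2) {
        on <- sample.int(ncl, 2)
        inc_rep[i, on] <- TRUE
      }
    }
  }
  for (j in seq_len(ncl)) {
    cl <- config$cell_lines[j]
    peaksets[[cl]] <- list(
      repressor = peak_set(mk_peaks(rep_rows, inc_rep[, j]),
                           factor = "repressor", cell_line = cl),
      activator = peak_set(mk_peaks(act, inc_act[, j]),
                           factor = "activator", cell_line = cl))
  }
  master_rep <- data.frame(chrom = rep_rows$chrom,
                           start = pmax(0, rep_rows$center -
                                          floor(rep_rows$width / 2)),
                           end = rep_rows$center +
                             ceiling(rep_rows$width / 2),
                           center = rep_rows$center,
                           class = rep_rows$class,
                           height = rep_rows$height,
                           n_lines = rowSums(inc_rep),
                           stringsAsFactors = FALSE)
  master_act <- data.frame(chrom = act$chrom,
                           start = pmax(0, act$center -
                                          floor(act$width / 2)),
                           end = act$center + ceiling(act$width / 2),
                           center = act$center, class = act$class,
                           height = act$height,
                           n_lines = rowSums(inc_act),
                           stringsAsFactors = FALSE)
  truth <- list(gene_class = stats::setNames(gene_class, genes$gene_id),
                tad_role = stats::setNames(role, tads$tad_id),
                repressor_class = master_rep$class,
                activator_class = master_act$class)
  # planted invariants, asserted at generation time
  stopifnot(sum(truth$gene_class == "direct") == config$n_direct,
            sum(truth$gene_class == "indirect") == config$n_indirect,
            !any(overlaps_any0(master_rep, indirect_tads)))
  list(peaksets = peaksets,
       master = list(repressor = master_rep, activator = master_act),
       truth = truth)
}

# expected (noise-free) binned profile: triangular bumps over background
bump_expectation <- function(chrom_lengths, bin_size, centers, heights,
                             widths, background = 0) {
  vals <- lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_size)
    v <- rep(as.numeric(background), nb)
    sel <- which(centers$chrom == ch)
    for (i in sel) {
      half <- widths[i] / 2
      lo <- max(1, floor((centers$center[i] - half) / bin_size) + 1)
      hi <- min(nb, ceiling((centers$center[i] + half) / bin_size))
      if (lo > hi) next
      mid <- (seq(lo, hi) - 0.5) * bin_size
      v[lo:hi] <- v[lo:hi] +
        heights[i] * pmax(0, 1 - abs(mid - centers$center[i]) / half)
    }
    v
  })
  stats::setNames(vals, names(chrom_lengths))
}

#' Simulate ChIP signal tracks with spike-in counts
#'
#' Raw tracks are Poisson draws around triangular bumps at the master
#' peaks plus a flat background (or the exact expectation when `noise =
#' "none"`). Under knockdown the repressor bump height is multiplied by
#' `knockdown_factor` everywhere, and the activator bump height by
#' `activator_boost` at co-occupied ("shared") peaks only — the planted
#' analogue of the activator invading sites vacated by the repressor. A
#' treatment condition uses the same generative model as knockdown with
#' independent noise.
#'
#' Each sample carries a sequencing-depth factor and a ChIP-efficiency
#' factor: raw genomic counts scale with both, total mapped reads with
#' depth, and spike-in reads with both (exogenous chromatin recovery
#' tracks antibody efficiency) — so spike-in (RRPM) normalization, which
#' divides out the spike-in *fraction*, recovers comparable occupancy
#' across conditions while plain RPM would not.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param sim_peaks output of [simulate_peaksets()].
#' @param conditions subset of `c("control", "knockdown", "treatment")`.
#' @return List per sample name (`factor.condition`) of
#'   `list(track, total_mapped_reads, spikein_reads)`; tracks are raw
#'   units.
#' @export
simulate_tracks <- function(config, genome, sim_peaks,
                            conditions = c("control", "knockdown")) {
  stopifnot(inherits(config, "sim_config"),
            all(conditions %in% c("control", "knockdown", "treatment")))
  force(genome); force(sim_peaks)  # evaluate upstream draws first
  set.seed(config$seed + 2L)
  master <- sim_peaks$master
  depth <- c(control = 1, knockdown = 0.75, treatment = 0.9)
  efficiency <- c(control = 1, knockdown = 1.3, treatment = 1.1)
  out <- list()
  for (cond in conditions) {
    for (fac in c("repressor", "activator")) {
      m <- master[[fac]]
      heights <- m$height
      if (cond != "control") {
        if (fac == "repressor")
          heights <- heights * config$knockdown_factor
        else
          heights <- ifelse(m$class == "shared",
                            heights * config$activator_boost, heights)
      }
      capture <- depth[cond] * efficiency[cond]
      mu <- bump_expectation(genome$chrom_lengths, config$bin_size,
                             m[, c("chrom", "center")],
                             heights * capture,
                             m$end - m$start,
                             config$background_rate * capture)
      vals <- if (config$noise == "poisson")
        lapply(mu, function(v) as.numeric(stats::rpois(length(v), v)))
      else mu
      nm <- paste(fac, cond, sep = ".")
      out[[nm]] <- list(
        track = signal_track(vals, config$bin_size, "raw"),
        total_mapped_reads = round(config$total_base * depth[cond]),
        spikein_reads = round(config$spikein_base * capture))
    }
  }
  out
}

#' Simulate knockdown / treatment differential-expression tables
#'
#' Direct and indirect genes draw `log2FC ~ N(l2fc_mean, l2fc_sd)` in
#' every cell line and contrast (both classes are upregulated when the
#' repressor is lost; the treatment contrast mimics pathway inhibition
#' converging on the same program); null genes draw `N(0, l2fc_sd)`.
#' P-values are two-sided normal tails of `log2FC / de_sigma`; FDR via
#' [benjamini_hochberg()].
#'
#' @param config a [sim_config()].
#' @param truth `truth` element of [simulate_peaksets()] output.
#' @param contrasts contrast names (default knockdown + treatment).
#' @return Nested list `tables[[contrast]][[cell_line]]` of
#'   [de_table()]s.
#' @export
simulate_expression <- function(config, truth,
                                contrasts = c("knockdown", "treatment")) {
  stopifnot(inherits(config, "sim_config"))
  force(truth)
  set.seed(config$seed + 3L)
  gene_ids <- names(truth$gene_class)
  up <- truth$gene_class %in% c("direct", "indirect")
  out <- list()
  for (con in contrasts) {
    out[[con]] <- lapply(stats::setNames(nm = config$cell_lines),
                         function(cl) {
      mu <- ifelse(up, config$l2fc_mean, 0)
      l2fc <- stats::rnorm(length(gene_ids), mu, config$l2fc_sd)
      p <- 2 * stats::pnorm(-abs(l2fc) / config$de_sigma)
      de_table(data.frame(gene_id = gene_ids, log2FC = l2fc,
                          pvalue = p, stringsAsFactors = FALSE),
               contrast = sprintf("%s vs control (%s)", con, cl))
    })
  }
  out
}

#' Simulate a myogenic gene-set universe
#'
#' A stand-in for the myogenic gene list the candidate filter intersects
#' with: all planted direct and indirect genes plus a random sample of
#' null genes (so the universe, like a curated list, contains
#' non-responding members).
#'
#' @param config a [sim_config()].
#' @param truth `truth` element of [simulate_peaksets()] output.
#' @param n_null_members null genes to include (default 40, capped at
#'   half the nulls so the universe never swallows the whole gene list).
#' @return Named list with one gene set, `myogenic`.
#' @export
simulate_gene_universe <- function(config, truth, n_null_members = 40) {
  force(truth)
  set.seed(config$seed + 4L)
  gc <- truth$gene_class
  nulls <- names(gc)[gc == "null"]
  members <- c(names(gc)[gc != "null"],
               sample(nulls, min(n_null_members,
                                 floor(length(nulls) / 2))))
  list(myogenic = sort(members))
}

#' Generate the full synthetic bundle in memory
#'
#' Runs [simulate_genome()], [simulate_peaksets()],
#' [simulate_tracks()] and [simulate_expression()] under one config and
#' returns everything, ground truth included.
#'
#' @param config a [sim_config()].
#' @param conditions track conditions to simulate.
#' @return List: `config`, `genome`, `peaksets`, `master`, `truth`,
#'   `tracks`, `expression`, `gene_sets`.
#' @export
simulate_bundle <- function(config = sim_config(),
                            conditions = c("control", "knockdown")) {
  genome <- simulate_genome(config)
  sp <- simulate_peaksets(config, genome)
  tracks <- simulate_tracks(config, genome, sp, conditions)
  expr <- simulate_expression(config, sp$truth)
  sets <- simulate_gene_universe(config, sp$truth)
  list(config = config, genome = genome, peaksets = sp$peaksets,
       master = sp$master, truth = sp$truth, tracks = tracks,
       expression = expr, gene_sets = sets)
}

#' Write a synthetic bundle to disk
#'
#' Plain-text fixture layout: per-cell-line peak BEDs
#' (`peaks_<factor>_<line>.bed`), raw bedGraph per sample
#' (`track_<factor>.<condition>.bedGraph`), `tads.bed` (BED4),
#' `genes.tsv`, DE tables `de_<contrast>_<line>.tsv`,
#' `gene_sets.gmt`, `samples.tsv` (library/spike-in counts),
#' `truth.json` and `config.yaml`. [read_fixture_bundle()] round-trips
#' it.
#'
#' @param bundle output of [simulate_bundle()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0)
    stop("cannot write to ", outdir, call. = FALSE)
  p <- function(...) file.path(outdir, ...)
  for (cl in names(bundle$peaksets))
    for (fac in names(bundle$peaksets[[cl]])) {
      ps <- bundle$peaksets[[cl]][[fac]]$peaks
      df <- data.frame(chrom = ps$chrom, start = ps$start, end = ps$end,
                       name = sprintf("%s_%s_%d", fac, cl,
                                      seq_len(nrow(ps))),
                       score = sprintf("%.17g", ps$score))
      write_bed(df, p(sprintf("peaks_%s_%s.bed", fac, cl)))
    }
  samples <- data.frame(sample = names(bundle$tracks),
                        total_mapped_reads = vapply(bundle$tracks,
                          `[[`, 0, "total_mapped_reads"),
                        spikein_reads = vapply(bundle$tracks,
                          `[[`, 0, "spikein_reads"))
  utils::write.table(samples, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$tracks))
    write_bedgraph(bundle$tracks[[nm]]$track,
                   p(sprintf("track_%s.bedGraph", nm)))
  write_bed(data.frame(chrom = bundle$genome$tads$chrom,
                       start = bundle$genome$tads$start,
                       end = bundle$genome$tads$end,
                       name = bundle$genome$tads$tad_id),
            p("tads.bed"))
  utils::write.table(bundle$genome$genes[, c("gene_id", "symbol",
                                             "chrom", "start", "end",
                                             "strand")],
                     p("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (con in names(bundle$expression))
    for (cl in names(bundle$expression[[con]])) {
      tb <- bundle$expression[[con]][[cl]]
      utils::write.table(
        data.frame(gene_id = tb$gene_id,
                   log2FC = sprintf("%.17g", tb$log2FC),
                   pvalue = sprintf("%.17g", tb$pvalue),
                   fdr = sprintf("%.17g", tb$fdr)),
        p(sprintf("de_%s_%s.tsv", con, cl)), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
  write_gmt(bundle$gene_sets, p("gene_sets.gmt"))
  jsonlite::write_json(lapply(bundle$truth, as.list), p("truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(bundle$config)
  yaml::write_yaml(c(list(schema = "tadtarget-sim/1"), cfg),
                   p("config.yaml"))
  jsonlite::write_json(as.list(bundle$genome$chrom_lengths),
                       p("chrom_lengths.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}

#' Read a synthetic bundle back from disk
#'
#' @param dir directory written by [write_fixture_bundle()].
#' @return List mirroring [simulate_bundle()] output (tracks carry their
#'   library counts; `config` is re-validated through [sim_config()]).
#' @export
read_fixture_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  cfg_raw <- yaml::read_yaml(p("config.yaml"))
  cfg_raw$schema <- NULL
  config <- do.call(sim_config, cfg_raw)
  chrom_lengths <- unlist(jsonlite::read_json(p("chrom_lengths.json")))
  tads <- read_tads(p("tads.bed"))
  genes <- read_genes(p("genes.tsv"))
  samples <- utils::read.delim(p("samples.tsv"),
                               stringsAsFactors = FALSE)
  tracks <- lapply(seq_len(nrow(samples)), function(i) {
    tr <- read_bedgraph(p(sprintf("track_%s.bedGraph",
                                  samples$sample[i])),
                        bin_size = config$bin_size, units = "raw")
    # restore zero-tail bins dropped by bedGraph run-length encoding
    tr$values <- lapply(stats::setNames(nm = names(chrom_lengths)),
                        function(ch) {
      nb <- ceiling(chrom_lengths[[ch]] / config$bin_size)
      v <- tr$values[[ch]]
      if (is.null(v)) v <- numeric(0)
      c(v, numeric(nb - length(v)))
    })
    list(track = tr, total_mapped_reads = samples$total_mapped_reads[i],
         spikein_reads = samples$spikein_reads[i])
  })
  names(tracks) <- samples$sample
  peak_files <- list.files(dir, "^peaks_.*\\.bed$")
  peaksets <- list()
  for (f in peak_files) {
    bits <- strsplit(sub("\\.bed$", "", f), "_")[[1]]
    fac <- bits[2]; cl <- paste(bits[-(1:2)], collapse = "_")
    ps <- read_bed(p(f), kind = "peak", factor = fac, cell_line = cl)
    peaksets[[cl]][[fac]] <- ps
  }
  de_files <- list.files(dir, "^de_.*\\.tsv$")
  expression <- list()
  for (f in de_files) {
    bits <- strsplit(sub("\\.tsv$", "", f), "_")[[1]]
    con <- bits[2]; cl <- paste(bits[-(1:2)], collapse = "_")
    expression[[con]][[cl]] <-
      read_de_table(p(f), contrast = sprintf("%s vs control (%s)",
                                             con, cl))
  }
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth <- lapply(truth, function(x) if (is.list(x)) unlist(x) else x)
  list(config = config, chrom_lengths = chrom_lengths,
       genome = list(chrom_lengths = chrom_lengths, tads = tads,
                     genes = genes),
       peaksets = peaksets, truth = truth, tracks = tracks,
       expression = expression,
       gene_sets = read_gmt(p("gene_sets.gmt")))
}
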