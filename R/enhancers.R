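#' ROSE-style enhancer stitching
#'
#' Peaks lying entirely within a TSS exclusion window (`tss +/-
#' tss_exclusion` bp) are removed, then survivors within `max_gap` bp of
#' each other are merged into stitched enhancer regions — the standard
#' rank-ordering-of-super-enhancers preprocessing (12.5 kb stitch, 2.5 kb
#' promoter exclusion by default).
#'
#' @param peaks a [peak_set()] or interval data frame.
#' @param max_gap stitching distance in bp (default 12500).
#' @param tss_list data frame of genes/TSS intervals with a `tss` column,
#'   or `NULL` for no promoter exclusion.
#' @param tss_exclusion half-width of the promoter window (default 2500).
#' @return Data frame of stitched regions.
#' @export
stitch_peaks <- function(peaks, max_gap = 12500, tss_list = NULL,
                         tss_exclusion = 2500) {
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  if (is_peak_set(peaks)) peaks <- peaks$peaks
  validate_intervals(peaks, "peak")
  if (!is.null(tss_list) && nrow(peaks) && length(tss_list$tss)) {
    win <- data.frame(chrom = tss_list$chrom,
                      start = pmax(0, tss_list$tss - tss_exclusion),
                      end = tss_list$tss + tss_exclusion + 1)
    contained <- logical(nrow(peaks))
    for (ch in intersect(unique(peaks$chrom), unique(win$chrom))) {
      ip <- which(peaks$chrom == ch)
      iw <- which(win$chrom == ch)
      hits <- IRanges::findOverlaps(as_iranges0(peaks[ip, , drop = FALSE]),
                                    as_iranges0(win[iw, , drop = FALSE]),
                                    type = "within")
      contained[ip[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    peaks <- peaks[!contained, , drop = FALSE]
  }
  merge_intervals(peaks, min_gap = max_gap)
}

#' Background-subtracted signal per stitched region
#'
#' ROSE-style region score: the sum over the region's bins of treatment
#' minus control signal, floored at 0 per region. Both tracks must share
#' units (refuses to mix, e.g., RPM with RRPM).
#'
#' @param regions data frame of stitched regions.
#' @param treatment [signal_track()] carrying the ranking signal.
#' @param control matched input/background [signal_track()], or `NULL`.
#' @return Numeric vector of nonnegative region signals.
#' @export
score_stitched <- function(regions, treatment, control = NULL) {
  stopifnot(inherits(treatment, "signal_track"))
  t_sum <- region_counts(regions, treatment)
  if (is.null(control)) return(pmax(0, t_sum))
  stopifnot(inherits(control, "signal_track"))
  if (treatment$units != control$units)
    stop("unit mismatch: treatment is ", treatment$units, ", control is ",
         control$units, call. = FALSE)
  pmax(0, t_sum - region_counts(regions, control))
}

#' Hockey-stick cutoff separating super from typical enhancers
#'
#' Sorts signals ascending, min-max scales both rank and signal to
#' `[0, 1]`, and returns the (unscaled) signal at the first point whose
#' forward-difference slope exceeds 1 — the inflection of the
#' rank-vs-signal "hockey stick". Enhancers with signal strictly above
#' the cutoff are super. A flat or perfectly linear scaled curve never
#' crosses slope 1, giving cutoff `Inf` (no supers). A tangent-line
#' variant (`method = "tangent"`: cutoff at the point minimizing
#' `y - x` on the scaled curve, i.e. where a slope-1 line is tangent)
#' is available since published implementations differ slightly.
#'
#' @param signals numeric vector, length >= 3.
#' @param method `"forward"` (default) or `"tangent"`.
#' @return Scalar cutoff signal (`Inf` when the curve never steepens
#'   past slope 1).
#' @export
hockey_stick_cutoff <- function(signals, method = c("forward", "tangent")) {
  method <- match.arg(method)
  if (length(signals) < 3)
    stop("need >= 3 signals to place a cutoff; with fewer, treat all ",
         "enhancers as typical", call. = FALSE)
  s <- sort(signals)
  n <- length(s)
  if (s[n] == s[1]) return(Inf)  # flat curve: no super enhancers
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  if (method == "tangent") {
    i <- which.min(y - x)
    return(s[i])
  }
  slope <- diff(y) / diff(x)          # slope at points 1..n-1
  i <- which(slope > 1)[1]
  if (is.na(i)) return(Inf)
  s[i]
}

#' Call super enhancers (stitch, score, rank, cut)
#'
#' Composes [stitch_peaks()], [score_stitched()] and
#' [hockey_stick_cutoff()]: enhancer regions are stitched from peaks,
#' scored by background-subtracted signal, ranked ascending, and those
#' with signal strictly above the hockey-stick cutoff are called super
#' enhancers.
#'
#' @inheritParams stitch_peaks
#' @inheritParams score_stitched
#' @param cutoff_method passed to [hockey_stick_cutoff()].
#' @return Object of class `enhancer_ranking`: list with `enhancers`
#'   (data frame: interval, `n_constituents`, `signal`, `rank`,
#'   `is_super`), `cutoff_signal`, `n_super`, `n_typical`.
#' @export
call_super_enhancers <- function(peaks, treatment, control = NULL,
                                 tss_list = NULL, max_gap = 12500,
                                 tss_exclusion = 2500,
                                 cutoff_method = "forward") {
  regions <- stitch_peaks(peaks, max_gap, tss_list, tss_exclusion)
  if (is_peak_set(peaks)) peaks <- peaks$peaks
  if (!nrow(regions)) {
    enh <- cbind(genomic_intervals(character(), numeric(), numeric()),
                 n_constituents = integer(), signal = numeric(),
                 rank = integer(), is_super = logical())
    return(structure(list(enhancers = enh, cutoff_signal = Inf,
                          n_super = 0L, n_typical = 0L),
                     class = "enhancer_ranking"))
  }
  signal <- score_stitched(regions, treatment, control)
  n_con <- vapply(seq_len(nrow(regions)), function(i)
    sum(overlaps_any0(peaks, regions[i, , drop = FALSE])), 0L)
  cutoff <- if (nrow(regions) >= 3) hockey_stick_cutoff(signal,
                                                        cutoff_method)
  else Inf
  o <- order(signal, regions$chrom, regions$start)
  enh <- regions[o, c("chrom", "start", "end"), drop = FALSE]
  enh$n_constituents <- n_con[o]
  enh$signal <- signal[o]
  enh$rank <- seq_len(nrow(enh))
  enh$is_super <- enh$signal > cutoff
  rownames(enh) <- NULL
  structure(list(enhancers = enh, cutoff_signal = cutoff,
                 n_super = sum(enh$is_super),
                 n_typical = sum(!enh$is_super)),
            class = "enhancer_ranking")
}

#' @export
print.enhancer_ranking <- function(x, ...) {
  cat(sprintf("<enhancer_ranking> %d enhancers: %d super, %d typical ",
              nrow(x$enhancers), x$n_super, x$n_typical),
      sprintf("(cutoff %.4g)\n", x$cutoff_signal), sep = "")
  invisible(x)
}

#' Write an enhancer ranking as TSV (and the super enhancers as BED)
#'
#' @param ranking an `enhancer_ranking`.
#' @param tsv_path ranked-table output path.
#' @param se_bed_path optional BED path for the super enhancers only.
#' @return `tsv_path`, invisibly.
#' @export
write_enhancer_ranking <- function(ranking, tsv_path, se_bed_path = NULL) {
  stopifnot(inherits(ranking, "enhancer_ranking"))
  utils::write.table(ranking$enhancers, tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(se_bed_path)) {
    se <- ranking$enhancers[ranking$enhancers$is_super, , drop = FALSE]
    write_bed(se, se_bed_path)
  }
  invisible(tsv_path)
}
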