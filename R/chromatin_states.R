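#' Read a chromatin-state segmentation (BED4)
#'
#' A ChromHMM-style segmentation: 4-column BED whose fourth column is the
#' state label. Segments must be non-overlapping within a chromosome;
#' overlapping segments are rejected with the offending line numbers.
#'
#' @param path BED4 file path.
#' @param state_order optional priority order of labels used for
#'   tie-breaking in [assign_peak_state()]; defaults to order of first
#'   appearance.
#' @return An object of class `state_segmentation`: list with `segments`
#'   (data frame `chrom`, `start`, `end`, `state`) and `state_order`.
#' @export
read_segmentation <- function(path, state_order = NULL) {
  df <- read_bed(path, kind = "region")
  if (is.null(df$name))
    stop("segmentation requires 4 columns (chrom, start, end, state)",
         call. = FALSE)
  df$state <- df$name
  df$name <- NULL
  state_segmentation(df, state_order)
}

#' Construct a chromatin-state segmentation
#'
#' @param segments data frame with `chrom`, `start`, `end`, `state`.
#' @param state_order priority list of labels (ties in
#'   [assign_peak_state()] break toward the earlier label); defaults to
#'   first appearance order. Every label in `segments` must appear.
#' @return `state_segmentation` object.
#' @export
state_segmentation <- function(segments, state_order = NULL) {
  validate_intervals(segments, "segment")
  if (is.null(segments$state)) stop("segments need a state column",
                                    call. = FALSE)
  # reject overlap within a chromosome, naming offending rows
  for (i in split_by_chrom(segments)) {
    ir <- as_iranges0(segments[i, , drop = FALSE])
    ov <- IRanges::findOverlaps(ir, ir)
    ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
    if (length(ov))
      stop("overlapping segments at rows ",
           i[S4Vectors::queryHits(ov)[1]], " and ",
           i[S4Vectors::subjectHits(ov)[1]], call. = FALSE)
  }
  if (is.null(state_order)) state_order <- unique(segments$state)
  missing <- setdiff(unique(segments$state), state_order)
  if (length(missing))
    stop("labels absent from state_order: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(segments = segments, state_order = state_order),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf("<state_segmentation> %d segments, %d states (%s)\n",
              nrow(x$segments), length(x$state_order),
              paste(utils::head(x$state_order, 4), collapse = ", ")))
  invisible(x)
}

#' Assign peaks to chromatin states
#'
#' Each peak gets the label of the state with which it shares the most
#' bp; ties break toward the label earlier in `state_order`; peaks with
#' no overlap get `"unassigned"`.
#'
#' @param peaks data frame of intervals, or a [peak_set()].
#' @param seg a [state_segmentation()].
#' @return Character vector of labels, one per peak.
#' @export
assign_peak_state <- function(peaks, seg) {
  if (is_peak_set(peaks)) peaks <- peaks$peaks
  validate_intervals(peaks, "peak")
  stopifnot(inherits(seg, "state_segmentation"))
  out <- rep("unassigned", nrow(peaks))
  if (!nrow(peaks)) return(out)
  segs <- seg$segments
  rank <- stats::setNames(seq_along(seg$state_order), seg$state_order)
  for (ch in intersect(unique(peaks$chrom), unique(segs$chrom))) {
    ip <- which(peaks$chrom == ch)
    is <- which(segs$chrom == ch)
    irp <- as_iranges0(peaks[ip, , drop = FALSE])
    irs <- as_iranges0(segs[is, , drop = FALSE])
    ov <- IRanges::findOverlaps(irp, irs)
    if (!length(ov)) next
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(irp[q], irs[s]))
    lab <- segs$state[is[s]]
    # per (peak, label): total overlap bp, then max with priority tie-break
    key <- paste(q, lab, sep = "\r")
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    qi <- as.integer(vapply(parts, `[[`, "", 1L))
    li <- vapply(parts, `[[`, "", 2L)
    bp <- agg[, 1]
    for (pk in unique(qi)) {
      sel <- qi == pk
      best <- which(sel & bp == max(bp[sel]))
      best <- best[order(rank[li[best]])][1]
      out[ip[pk]] <- li[best]
    }
  }
  out
}

#' Peak density per chromatin state (peaks per Gb)
#'
#' Counts peaks per state via [assign_peak_state()] and normalizes each
#' count to the state's genomic footprint in Gb, the usual way of asking
#' which chromatin context a factor prefers once footprint size is
#' controlled for. States with a 0-bp footprint report density 0;
#' unassigned peaks are excluded from the rows but reported in the
#' `n_unassigned` attribute.
#'
#' @param peaks a [peak_set()] or interval data frame.
#' @param seg a [state_segmentation()].
#' @return Data frame (`state`, `n_peaks`, `state_bp`, `peaks_per_gb`)
#'   with one row per label in `state_order`, attribute `n_unassigned`.
#' @export
peaks_per_gb <- function(peaks, seg) {
  stopifnot(inherits(seg, "state_segmentation"))
  if (!nrow(seg$segments)) stop("empty segmentation", call. = FALSE)
  lab <- assign_peak_state(peaks, seg)
  segs <- seg$segments
  bp <- vapply(seg$state_order, function(s)
    sum(segs$end[segs$state == s] - segs$start[segs$state == s]), 0)
  n <- vapply(seg$state_order, function(s) sum(lab == s), 0L)
  stopifnot(all(bp > 0 | n == 0))  # peaks cannot land in a 0-bp state
  out <- data.frame(state = seg$state_order, n_peaks = n, state_bp = bp,
                    peaks_per_gb = ifelse(bp > 0, n / (bp / 1e9), 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_unassigned") <- sum(lab == "unassigned")
  out
}
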