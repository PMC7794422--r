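#' Genomic intervals and peak sets
#'
#' All coordinates in this package are 0-based half-open (BED dialect):
#' an interval covers bases `start, start+1, ..., end-1`. Intervals are
#' plain data frames with columns `chrom`, `start`, `end` and optionally
#' `strand` (defaulting to `"."`); peaks additionally carry `summit`
#' (absolute bp, or `NA`) and `score`. Conversion to 1-based closed
#' [IRanges::IRanges] happens only at the boundary with Bioconductor
#' machinery and is never exposed.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @return `genomic_intervals()` returns a validated data frame.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("intervals need columns chrom, start, end", call. = FALSE)
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop("empty chromosome name", call. = FALSE)
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("invalid %s (need 0 <= start < end) at row(s) %s",
                 what, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  invisible(df)
}

# 0-based half-open -> IRanges (1-based closed), per data frame
as_iranges0 <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# split a data frame of intervals by chromosome, preserving row indices
split_by_chrom <- function(df) {
  split(seq_len(nrow(df)), df$chrom)
}

#' Construct a peak set
#'
#' A peak set bundles the peaks of one ChIP experiment (one factor in one
#' cell line and condition) with its library metadata, including total
#' mapped reads and exogenous spike-in reads when a spike-in was used.
#'
#' @param peaks data frame with columns `chrom`, `start`, `end` and
#'   optionally `summit` (absolute bp within the peak) and `score`
#'   (nonnegative; caller signal or -log10 p).
#' @param factor ChIP'd factor name (e.g. `"SNAI2"`); required.
#' @param cell_line,condition optional experiment labels.
#' @param total_mapped_reads,spikein_reads optional library counts used by
#'   [rrpm_scale()] style normalization.
#' @return An object of class `peak_set`: a list with elements `peaks`
#'   (data frame) and `meta` (list).
#' @examples
#' ps <- peak_set(genomic_intervals("chr1", c(0, 500), c(100, 700)),
#'                factor = "SNAI2", cell_line = "RD")
#' ps
#' @export
peak_set <- function(peaks, factor, cell_line = NA_character_,
                     condition = NA_character_,
                     total_mapped_reads = NA_real_,
                     spikein_reads = NA_real_) {
  if (missing(factor) || !nzchar(factor))
    stop("peak_set requires a non-empty factor name", call. = FALSE)
  validate_intervals(peaks, "peak")
  if (is.null(peaks$summit)) peaks$summit <- rep(NA_real_, nrow(peaks))
  if (is.null(peaks$score)) peaks$score <- rep(0, nrow(peaks))
  ok <- is.na(peaks$summit) |
    (peaks$summit >= peaks$start & peaks$summit < peaks$end)
  if (!all(ok))
    stop("peak summit outside [start, end) at row(s) ",
         paste(utils::head(which(!ok), 5), collapse = ", "), call. = FALSE)
  if (any(peaks$score < 0, na.rm = TRUE))
    stop("peak scores must be nonnegative", call. = FALSE)
  o <- order(peaks$chrom, peaks$start, peaks$end)
  peaks <- peaks[o, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks,
                 meta = list(factor = factor, cell_line = cell_line,
                             condition = condition,
                             total_mapped_reads = total_mapped_reads,
                             spikein_reads = spikein_reads)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<peak_set> %s%s%s: %d peaks on %d chromosome(s)\n",
              m$factor,
              if (!is.na(m$cell_line)) paste0(" / ", m$cell_line) else "",
              if (!is.na(m$condition)) paste0(" / ", m$condition) else "",
              nrow(x$peaks), length(unique(x$peaks$chrom))))
  invisible(x)
}

#' @export
length.peak_set <- function(x) nrow(x$peaks)

is_peak_set <- function(x) inherits(x, "peak_set")

#' Read a BED file
#'
#' Parses BED3/BED5+ as 0-based half-open intervals. `track` and `browser`
#' header lines and `#` comments are tolerated. Column 4 becomes `name`,
#' column 5 `score` when present. Malformed lines (fewer than 3 columns,
#' non-numeric coordinates, or `start >= end`) raise an error naming the
#' offending line number. Chromosome names are not validated against a
#' genome.
#'
#' @param path file path.
#' @param kind `"region"` returns a data frame of intervals; `"peak"`
#'   wraps them in a [peak_set()] (requires `factor`).
#' @param factor,cell_line passed to [peak_set()] when `kind = "peak"`.
#' @return Data frame of intervals, or a `peak_set`.
#' @export
read_bed <- function(path, kind = c("region", "peak"), factor = "unknown",
                     cell_line = NA_character_) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    out <- genomic_intervals(character(), numeric(), numeric())
  } else {
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    ncol <- lengths(fields)
    if (any(ncol < 3))
      stop("fewer than 3 tab-separated columns at line ",
           idx[which(ncol < 3)[1]], call. = FALSE)
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- is.na(start) | is.na(end)
    if (any(bad))
      stop("non-numeric coordinates at line ", idx[which(bad)[1]],
           call. = FALSE)
    bad <- start >= end | start < 0
    if (any(bad))
      stop("invalid interval (start >= end or negative) at line ",
           idx[which(bad)[1]], call. = FALSE)
    field_or_na <- function(j)
      vapply(fields, function(f)
        if (length(f) >= j) f[[j]] else NA_character_, "")
    out <- data.frame(chrom = chrom, start = start, end = end,
                      strand = ".", stringsAsFactors = FALSE)
    if (any(ncol >= 4)) out$name <- field_or_na(4L)
    if (any(ncol >= 5))
      out$score <- suppressWarnings(as.numeric(field_or_na(5L)))
    if (any(ncol >= 6)) {
      s <- field_or_na(6L)
      out$strand <- ifelse(s %in% c("+", "-"), s, ".")
    }
  }
  if (kind == "region") return(out)
  peak_set(out, factor = factor, cell_line = cell_line)
}

#' Write intervals as BED
#'
#' @param df data frame of intervals (optionally with `name`, `score`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, format_coord(df$start), format_coord(df$end))
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
    if (!is.null(df$score)) cols <- c(cols, list(as.character(df$score)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Merge genomic intervals
#'
#' Sorts and merges intervals; two intervals merge when the gap between
#' them is at most `min_gap` bp (touching intervals have gap 0 and merge
#' whenever `min_gap >= 0`). The result is sorted and pairwise
#' non-overlapping.
#'
#' @param intervals data frame of intervals.
#' @param min_gap nonnegative merge distance in bp.
#' @return Data frame of merged intervals.
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(100, 150), c(200, 250)))
#' @export
merge_intervals <- function(intervals, min_gap = 0) {
  if (min_gap < 0) stop("min_gap must be >= 0", call. = FALSE)
  validate_intervals(intervals)
  if (nrow(intervals) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  pieces <- lapply(split_by_chrom(intervals), function(i) {
    r <- IRanges::reduce(as_iranges0(intervals[i, ]),
                         min.gapwidth = min_gap + 1)
    data.frame(chrom = intervals$chrom[i[1]],
               start = IRanges::start(r) - 1,
               end = IRanges::end(r),
               strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces[order(names(pieces))])
  rownames(out) <- NULL
  out
}

#' Consensus peaks supported by at least k of n experiments
#'
#' Each input set's peaks are first merged so one set contributes coverage
#' depth at most 1 anywhere; a consensus peak is a maximal region where at
#' least `k` distinct sets cover every base (`mode = "depth"`, the
#' default), or the union of the contributing per-set intervals around
#' such a region (`mode = "union"`). Each consensus peak records the names
#' of its supporting sets and the mean score of their overlapping peaks.
#'
#' @param peaksets list of [peak_set()] objects (named, or names taken
#'   from `meta$cell_line`).
#' @param k minimum number of supporting sets, `1 <= k <= length(peaksets)`.
#' @param mode consensus geometry, `"depth"` or `"union"` (see above).
#' @return A `peak_set` whose peaks carry `support` (comma-separated set
#'   names) and `n_support`; `meta$factor` is taken from the inputs.
#' @examples
#' a <- peak_set(genomic_intervals("chr1", 100, 200), "TF", "A")
#' b <- peak_set(genomic_intervals("chr1", 150, 250), "TF", "B")
#' consensus_peaks(list(a, b), k = 2)$peaks
#' @export
consensus_peaks <- function(peaksets, k, mode = c("depth", "union")) {
  mode <- match.arg(mode)
  n <- length(peaksets)
  if (!n || !all(vapply(peaksets, is_peak_set, TRUE)))
    stop("peaksets must be a non-empty list of peak_set objects",
         call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds number of peak sets (", n, ")",
                  call. = FALSE)
  facs <- unique(vapply(peaksets, function(p) p$meta$factor, ""))
  if (length(facs) > 1)
    warning("peak sets come from different factors: ",
            paste(facs, collapse = ", "))
  nms <- names(peaksets)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- vapply(seq_along(peaksets), function(i) {
      cl <- peaksets[[i]]$meta$cell_line
      if (!is.na(cl)) cl else paste0("set", i)
    }, "")
  merged <- lapply(peaksets, function(p) merge_intervals(p$peaks))
  chroms <- sort(unique(unlist(lapply(merged, function(m) m$chrom))))
  rows <- list()
  for (ch in chroms) {
    per_set <- lapply(merged, function(m) {
      as_iranges0(m[m$chrom == ch, , drop = FALSE])
    })
    maxend <- max(0, vapply(per_set, function(r)
      if (length(r)) max(IRanges::end(r)) else 0L, 0))
    if (maxend == 0) next
    covs <- lapply(per_set, IRanges::coverage, width = maxend)
    total <- Reduce(`+`, covs)
    sl <- IRanges::slice(total, lower = k, rangesOnly = TRUE)
    if (!length(sl)) next
    core <- sl
    if (mode == "union") {
      # widen each core to the union of per-set merged intervals hitting it
      uni <- lapply(seq_along(core), function(i) {
        pieces <- lapply(per_set, function(r) {
          r[IRanges::overlapsAny(r, core[i])]
        })
        all <- c(do.call(c, pieces), core[i])
        IRanges::IRanges(min(IRanges::start(all)),
                         max(IRanges::end(all)))
      })
      core <- IRanges::reduce(do.call(c, uni))
    }
    # supporting sets and mean supporting-peak score per consensus region
    sup_mat <- vapply(per_set, function(r)
      IRanges::overlapsAny(core, r), logical(length(core)))
    sup_mat <- matrix(sup_mat, nrow = length(core))
    support <- apply(sup_mat, 1, function(s)
      paste(nms[s], collapse = ","))
    score_sum <- numeric(length(core))
    score_n <- numeric(length(core))
    for (s in seq_along(peaksets)) {
      pk <- peaksets[[s]]$peaks
      pk <- pk[pk$chrom == ch, , drop = FALSE]
      if (!nrow(pk)) next
      ov <- IRanges::findOverlaps(core, as_iranges0(pk))
      q <- S4Vectors::queryHits(ov)
      keep <- sup_mat[q, s]  # only sets counted as supporting contribute
      q <- q[keep]
      sc <- pk$score[S4Vectors::subjectHits(ov)[keep]]
      if (length(q)) {
        score_sum <- score_sum + unname(rowsum_vec(sc, q, length(core)))
        score_n <- score_n + unname(rowsum_vec(rep(1, length(q)), q,
                                               length(core)))
      }
    }
    score <- ifelse(score_n > 0, score_sum / pmax(score_n, 1), 0)
    rows[[ch]] <- data.frame(chrom = ch,
                             start = IRanges::start(core) - 1,
                             end = IRanges::end(core),
                             strand = ".",
                             score = score,
                             support = support,
                             n_support = vapply(strsplit(support, ","),
                                                length, 0L),
                             stringsAsFactors = FALSE)
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    cbind(genomic_intervals(character(), numeric(), numeric()),
          score = numeric(), support = character(),
          n_support = integer())
  rownames(peaks) <- NULL
  peak_set(peaks, factor = facs[1],
           condition = sprintf("consensus>=%d/%d", k, n))
}

#' Classify co-occupancy of two peak sets
#'
#' Partitions the peaks of two factors into A-only, B-only and shared
#' classes (the Venn of, e.g., repressor-only, activator-only and
#' co-occupied sites). A peak of A is "shared" when it overlaps at least
#' one peak of B by at least `min_overlap` bp; the shared count is
#' reported from the A side (documented convention), and `b_only` holds
#' the peaks of B overlapping no peak of A.
#'
#' @param a,b [peak_set()] objects.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return An object of class `overlap_classification`: list with
#'   `a_only`, `b_only`, `shared` (peak sets) and `counts`.
#' @export
classify_cooccupancy <- function(a, b, min_overlap = 1) {
  if (!is_peak_set(a) || !is_peak_set(b))
    stop("a and b must be peak_set objects", call. = FALSE)
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  hit_a <- overlaps_any0(a$peaks, b$peaks, min_overlap)
  hit_b <- overlaps_any0(b$peaks, a$peaks, min_overlap)
  subset_ps <- function(p, keep, cond) {
    peak_set(p$peaks[keep, , drop = FALSE], factor = p$meta$factor,
             cell_line = p$meta$cell_line, condition = cond)
  }
  out <- list(a_only = subset_ps(a, !hit_a, "a_only"),
              b_only = subset_ps(b, !hit_b, "b_only"),
              shared = subset_ps(a, hit_a, "shared"),
              counts = c(n_a_only = sum(!hit_a),
                         n_b_only = sum(!hit_b),
                         n_shared = sum(hit_a)))
  class(out) <- "overlap_classification"
  out
}

# sum `x` into `n` bins indexed by `g`
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# row-wise: does each interval of x overlap any interval of y by >= minov bp?
overlaps_any0 <- function(x, y, minov = 1) {
  hit <- logical(nrow(x))
  if (!nrow(x) || !nrow(y)) return(hit)
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    ix <- which(x$chrom == ch)
    iy <- which(y$chrom == ch)
    ov <- IRanges::overlapsAny(as_iranges0(x[ix, , drop = FALSE]),
                               as_iranges0(y[iy, , drop = FALSE]),
                               minoverlap = minov)
    hit[ix] <- ov
  }
  hit
}

#' @export
print.overlap_classification <- function(x, ...) {
  cat(sprintf(paste0("<overlap_classification> %s vs %s: ",
                     "a_only=%d, b_only=%d, shared=%d (A-side)\n"),
              x$shared$meta$factor, x$b_only$meta$factor,
              x$counts["n_a_only"], x$counts["n_b_only"],
              x$counts["n_shared"]))
  invisible(x)
}
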