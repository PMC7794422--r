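#' Binned signal tracks
#'
#' A `signal_track` stores per-chromosome vectors of fixed-width bin
#' values with a unit tag: `"raw"` (read counts), `"RPM"` (reads per
#' million mapped reads) or `"RRPM"` (reference-adjusted RPM, i.e.
#' spike-in normalized). Bin `j` of a chromosome covers bp
#' `[(j-1)*bin_size, j*bin_size)`. All bins must be nonnegative; signed
#' condition differences live in a separate [delta_track()] class.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param bin_size bin width in bp (default 10).
#' @param units one of `"raw"`, `"RPM"`, `"RRPM"`.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size = 10,
                         units = c("raw", "RPM", "RRPM")) {
  units <- match.arg(units)
  stopifnot(is.list(values), length(names(values)) == length(values),
            bin_size >= 1)
  if (any(vapply(values, function(v) any(v < 0), TRUE)))
    stop("signal_track bins must be nonnegative (use delta_track for ",
         "signed differences)", call. = FALSE)
  structure(list(values = lapply(values, as.numeric),
                 bin_size = as.integer(bin_size), units = units),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d chromosome(s), bin %d bp, units %s\n",
              length(x$values), x$bin_size, x$units))
  invisible(x)
}

#' Spike-in (RRPM) scale factor
#'
#' Reference-adjusted reads per million mapped reads: sequencing-depth
#' normalization (per million mapped reads) multiplied by the ratio of
#' spike-in *fractions* between a reference library and the sample, so
#' that equal exogenous-chromatin recovery maps to equal scale. With
#' spike-in fraction `f = spikein_reads / total_mapped_reads`,
#'
#'   `scale = (1e6 / total_mapped_reads) * (f_reference / f_sample)`
#'
#' Using fractions (not raw spike-in counts) makes the normalized track
#' invariant to resequencing the same library deeper: multiplying a
#' sample's raw bins, total reads and spike-in reads jointly by any c
#' leaves its RRPM track unchanged. When `reference_total` is omitted it
#' defaults to the sample's own total, in which case the formula reduces
#' to `(1e6/total) * (reference_spikein/spikein_reads)`.
#'
#' @param total_mapped_reads,spikein_reads sample library counts (> 0).
#' @param reference_spikein,reference_total reference library counts; by
#'   convention the cohort sample with the smallest spike-in fraction
#'   (see [cohort_reference()]).
#' @return Scalar multiplier taking raw bin counts to RRPM.
#' @examples
#' rrpm_scale(10e6, 100e3, reference_spikein = 50e3)  # 0.05
#' @export
rrpm_scale <- function(total_mapped_reads, spikein_reads,
                       reference_spikein,
                       reference_total = total_mapped_reads) {
  if (is.na(spikein_reads) || spikein_reads <= 0)
    stop("spike-in reads absent or zero; use RPM normalization instead",
         call. = FALSE)
  stopifnot(total_mapped_reads > 0, reference_spikein > 0,
            reference_total > 0)
  (1e6 / total_mapped_reads) *
    (reference_spikein / reference_total) / (spikein_reads / total_mapped_reads)
}

#' Pick the cohort reference library for RRPM normalization
#'
#' Returns the index of the sample with the smallest spike-in fraction
#' (the default reference convention: every other sample is scaled down
#' toward it, never up).
#'
#' @param totals,spikeins parallel vectors of library counts.
#' @return Integer index of the reference sample.
#' @export
cohort_reference <- function(totals, spikeins) {
  stopifnot(length(totals) == length(spikeins), all(totals > 0),
            all(spikeins > 0))
  which.min(spikeins / totals)
}

#' Normalize a raw track to RPM or RRPM
#'
#' @param track raw-unit [signal_track()].
#' @param total_mapped_reads,spikein_reads sample library counts.
#' @param units `"RPM"` or `"RRPM"`.
#' @param reference_spikein,reference_total reference library for RRPM
#'   (see [rrpm_scale()]).
#' @return A `signal_track` in the requested units.
#' @export
normalize_track <- function(track, total_mapped_reads,
                            spikein_reads = NA,
                            units = c("RPM", "RRPM"),
                            reference_spikein = spikein_reads,
                            reference_total = total_mapped_reads) {
  units <- match.arg(units)
  stopifnot(inherits(track, "signal_track"))
  if (track$units != "raw")
    stop("normalize_track expects a raw-unit track", call. = FALSE)
  scale <- if (units == "RPM") 1e6 / total_mapped_reads else
    rrpm_scale(total_mapped_reads, spikein_reads, reference_spikein,
               reference_total)
  signal_track(lapply(track$values, `*`, scale), track$bin_size, units)
}

#' Per-region summed signal
#'
#' Sums bin values over each region (bins counted when they overlap the
#' region), times an optional scale factor — the binned analogue of
#' counting reads per region and normalizing per million mapped reads.
#' Overlapping regions are summed independently (no double-count
#' correction). Regions on chromosomes absent from the track, or beyond
#' its covered grid, contribute 0 with a warning.
#'
#' @param regions data frame of intervals.
#' @param track a [signal_track()].
#' @param scale multiplier applied to each sum (default 1).
#' @return Numeric vector, one sum per region.
#' @export
region_counts <- function(regions, track, scale = 1) {
  stopifnot(inherits(track, "signal_track"))
  validate_intervals(regions, "region")
  n <- nrow(regions)
  out <- numeric(n)
  if (!n) return(out)
  off_grid <- FALSE
  bs <- track$bin_size
  for (i in seq_len(n)) {
    v <- track$values[[regions$chrom[i]]]
    if (is.null(v)) { off_grid <- TRUE; next }
    lo <- floor(regions$start[i] / bs) + 1
    hi <- ceiling(regions$end[i] / bs)
    if (lo > length(v)) { off_grid <- TRUE; next }
    if (hi > length(v)) { off_grid <- TRUE; hi <- length(v) }
    out[i] <- sum(v[lo:hi])
  }
  if (off_grid) warning("some regions lie (partly) off the covered grid; ",
                        "missing bins counted as 0")
  out * scale
}

#' Composite (metagene) profile around centers
#'
#' Mean signal across centers at each offset in a symmetric window, the
#' usual composite plot of ChIP signal around peak summits. Windows that
#' run past a chromosome edge are zero-padded; the number of padded rows
#' is reported in the `n_padded` attribute.
#'
#' @param track a [signal_track()].
#' @param centers data frame with `chrom` and `pos` (bp), e.g. peak
#'   summits or midpoints.
#' @param flank half-window in bp (default 2000); must be a multiple of
#'   the track's bin size.
#' @param bin bin width; must equal the track's bin size.
#' @return Object of class `composite_profile`: data frame (`offset`,
#'   `mean_signal`) with attributes `n_regions`, `n_padded`. Offsets are
#'   bin left edges relative to the center.
#' @export
composite_profile <- function(track, centers, flank = 2000,
                              bin = track$bin_size) {
  m <- profile_matrix(track, centers, flank, bin, sort_track = NULL)
  out <- data.frame(offset = as.numeric(colnames(m)),
                    mean_signal = colMeans(m))
  rownames(out) <- NULL
  attr(out, "n_regions") <- nrow(m)
  attr(out, "n_padded") <- attr(m, "n_padded")
  class(out) <- c("composite_profile", "data.frame")
  out
}

#' Signal matrix around centers, optionally sorted (heatmap order)
#'
#' One row per center covering `[center - flank, center + flank)`; when
#' `sort_track` is given rows are ordered by descending per-row total of
#' that track over the same window (the "sorted by signal strength"
#' heatmap convention), ties broken by genomic coordinate; otherwise
#' input order is kept. Column means of the unsorted matrix equal
#' [composite_profile()].
#'
#' @inheritParams composite_profile
#' @param sort_track a [signal_track()] providing the row sort key, or
#'   `NULL` to keep input order.
#' @return Numeric matrix with `"chrom:start-end"` row names, offset
#'   column names, and attribute `n_padded`.
#' @export
profile_matrix <- function(track, centers, flank = 2000,
                           bin = track$bin_size, sort_track = NULL) {
  stopifnot(inherits(track, "signal_track"))
  if (!nrow(centers)) stop("no centers supplied", call. = FALSE)
  if (bin != track$bin_size)
    stop("bin must equal the track's bin size", call. = FALSE)
  if (flank %% bin != 0)
    stop("flank must be a multiple of the bin size", call. = FALSE)
  nf <- flank / bin
  n_padded <- 0L
  extract <- function(tr, chrom, pos) {
    v <- tr$values[[chrom]]
    ib <- floor(pos / bin) + 1
    idx <- (ib - nf):(ib + nf - 1)
    row <- numeric(2 * nf)
    ok <- idx >= 1 & idx <= length(v)
    if (!is.null(v)) row[ok] <- v[idx[ok]]
    if (is.null(v) || any(!ok)) n_padded <<- n_padded + 1L
    row
  }
  m <- t(vapply(seq_len(nrow(centers)), function(i)
    extract(track, centers$chrom[i], centers$pos[i]), numeric(2 * nf)))
  colnames(m) <- seq(-flank, flank - bin, by = bin)
  rownames(m) <- sprintf("%s:%s-%s", centers$chrom,
                         format_coord(pmax(0, centers$pos - flank)),
                         format_coord(centers$pos + flank))
  if (!is.null(sort_track)) {
    key <- vapply(seq_len(nrow(centers)), function(i)
      sum(extract(sort_track, centers$chrom[i], centers$pos[i])), 0)
    o <- order(-key, centers$chrom, centers$pos)
    m <- m[o, , drop = FALSE]
  }
  attr(m, "n_padded") <- n_padded
  m
}

#' Difference of two like-normalized tracks
#'
#' Binwise `a - b` (e.g. knockdown minus scramble control), a signed
#' product kept distinct from [signal_track()]. Both tracks must share
#' the bin grid and be normalized (`RPM` or `RRPM`, identically); raw
#' tracks are refused because depth differences would masquerade as
#' biology.
#'
#' @param a,b [signal_track()] objects on the same grid and units.
#' @param label description, default `"A minus B"`.
#' @return Object of class `delta_track`: list of signed per-bin vectors
#'   plus `bin_size`, `units`, `label`.
#' @export
delta_track <- function(a, b, label = "A minus B") {
  stopifnot(inherits(a, "signal_track"), inherits(b, "signal_track"))
  if (a$units == "raw" || b$units == "raw")
    stop("delta_track requires normalized tracks (RPM or RRPM)",
         call. = FALSE)
  if (a$units != b$units)
    stop("unit mismatch: ", a$units, " vs ", b$units, call. = FALSE)
  if (a$bin_size != b$bin_size ||
      !identical(sort(names(a$values)), sort(names(b$values))) ||
      !all(vapply(names(a$values), function(ch)
        length(a$values[[ch]]) == length(b$values[[ch]]), TRUE)))
    stop("bin grid mismatch between tracks", call. = FALSE)
  structure(list(values = lapply(names(a$values), function(ch)
    a$values[[ch]] - b$values[[ch]]) |> stats::setNames(names(a$values)),
    bin_size = a$bin_size, units = a$units, label = label),
    class = "delta_track")
}

#' Mean delta over regions
#'
#' Mean of a [delta_track()]'s bins across the bins covered by each
#' region, averaged over regions — used to compare, e.g., activator
#' signal gain at co-occupied versus activator-only sites.
#'
#' @param delta a [delta_track()].
#' @param regions data frame of intervals.
#' @return Scalar mean (NA for empty input).
#' @export
mean_delta <- function(delta, regions) {
  stopifnot(inherits(delta, "delta_track"))
  if (!nrow(regions)) return(NA_real_)
  bs <- delta$bin_size
  vals <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    v <- delta$values[[regions$chrom[i]]]
    if (is.null(v)) return(numeric())
    lo <- max(1, floor(regions$start[i] / bs) + 1)
    hi <- min(length(v), ceiling(regions$end[i] / bs))
    if (lo > hi) return(numeric())
    v[lo:hi]
  }))
  if (!length(vals)) NA_real_ else mean(vals)
}

#' Read a bedGraph into a binned track
#'
#' Accepts the variable-step 4-column dialect (`chrom start end value`,
#' 0-based half-open). Interval bounds must align to the bin grid; bins
#' not covered by any line are 0.
#'
#' @param path bedGraph path.
#' @param bin_size bin width in bp.
#' @param units unit tag for the resulting track.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, bin_size = 10, units = "raw") {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(f) < 4))
    stop("bedGraph needs 4 columns at line ",
         which(keep)[which(lengths(f) < 4)[1]], call. = FALSE)
  chrom <- vapply(f, `[[`, "", 1L)
  start <- as.numeric(vapply(f, `[[`, "", 2L))
  end <- as.numeric(vapply(f, `[[`, "", 3L))
  val <- as.numeric(vapply(f, `[[`, "", 4L))
  if (any(start %% bin_size != 0 | end %% bin_size != 0))
    stop("bedGraph intervals not aligned to ", bin_size, " bp bins",
         call. = FALSE)
  values <- lapply(split(seq_along(chrom), chrom), function(i) {
    v <- numeric(max(end[i]) / bin_size)
    for (j in i) v[(start[j] / bin_size + 1):(end[j] / bin_size)] <- val[j]
    v
  })
  signal_track(values, bin_size, units)
}

#' Write a track (or delta track) as bedGraph
#'
#' Runs of equal-valued bins are collapsed into one line; zero runs are
#' omitted for signal tracks and kept for delta tracks (whose zeros are
#' informative).
#'
#' @param track a [signal_track()] or [delta_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, c("signal_track", "delta_track")))
  keep_zero <- inherits(track, "delta_track")
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- keep_zero | r$values != 0
    if (!any(sel)) next
    writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                       format_coord(starts[sel] * bs),
                       format_coord(ends[sel] * bs),
                       format(r$values[sel], scientific = FALSE,
                              trim = TRUE, digits = 10)), con)
  }
  invisible(path)
}
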