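#' Scan a sequence for E-box motifs (CANNTG)
#'
#' Finds every (possibly overlapping) occurrence of the degenerate E-box
#' hexamer `CANNTG` — the consensus bound by basic helix-loop-helix
#' myogenic factors and by SNAIL-family repressors — and reports the NN
#' core dinucleotide as the hit's subtype (e.g. `GC` for `CAGCTG`). The
#' pattern is its own reverse complement as a degenerate class, so
#' scanning one strand finds every double-stranded occurrence; `N` in
#' the *sequence* never matches a pattern `N`.
#'
#' @param seqs character vector of DNA sequences over `{A,C,G,T,N}`
#'   (case-insensitive), optionally named.
#' @param pattern degenerate pattern; positions may be `A/C/G/T` (exact)
#'   or `N` (any base except sequence `N`). Default `"CANNTG"`.
#' @return Data frame (`sequence_id`, `offset` 0-based, `match`,
#'   `subtype`).
#' @examples
#' scan_ebox("CACATGTG")  # two overlapping hits
#' @export
scan_ebox <- function(seqs, pattern = "CANNTG") {
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  pat <- strsplit(toupper(pattern), "")[[1]]
  stopifnot(all(pat %in% c("A", "C", "G", "T", "N")))
  k <- length(pat)
  free <- which(pat == "N")
  rows <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    x <- strsplit(toupper(seqs[[s]]), "")[[1]]
    bad <- which(!x %in% c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop("invalid character '", x[bad[1]], "' at position ", bad[1],
           " of sequence ", ids[s], call. = FALSE)
    n <- length(x)
    if (n < k) next
    ok <- rep(TRUE, n - k + 1)
    for (j in seq_len(k)) {
      xj <- x[j:(n - k + j)]
      ok <- ok & if (j %in% free) xj != "N" else xj == pat[j]
    }
    off <- which(ok) - 1L
    if (!length(off)) next
    match6 <- vapply(off, function(o)
      paste(x[(o + 1):(o + k)], collapse = ""), "")
    rows[[s]] <- data.frame(sequence_id = ids[s], offset = off,
                            match = match6,
                            subtype = if (length(free))
                              substr(match6, min(free), max(free))
                            else "",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(sequence_id = character(), offset = integer(),
                      match = character(), subtype = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reverse complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' E-box presence/absence enrichment versus background
#'
#' A simplified known-motif enrichment: each region's sequence either
#' contains the motif (subtype-restricted or any) or it does not; the
#' foreground hit count is tested against the background hit *rate* with
#' an upper-tail binomial (`mode = "presence"`, default) or, in
#' hit-count mode, total hit counts are compared with an upper-tail
#' Poisson test at the background per-sequence rate. The background rate
#' is floored at `1/(bg_total + 1)` so a motif absent from the
#' background cannot produce a zero-rate degenerate test.
#'
#' @param fg_seqs,bg_seqs character vectors of foreground (e.g. peak)
#'   and background sequences; both non-empty.
#' @param subtype NN-core restriction (e.g. `"GC"`), or `"any"`.
#' @param mode `"presence"` (per-region presence/absence) or `"counts"`
#'   (total hits, Poisson).
#' @return Data frame of class `ebox_enrichment` with columns `subtype`,
#'   `fg_with_hit`, `fg_total`, `bg_with_hit`, `bg_total`, `fold`, `p`.
#' @export
ebox_enrichment <- function(fg_seqs, bg_seqs, subtype = "any",
                            mode = c("presence", "counts")) {
  mode <- match.arg(mode)
  if (!length(fg_seqs)) stop("empty foreground", call. = FALSE)
  if (!length(bg_seqs)) stop("empty background", call. = FALSE)
  count_hits <- function(seqs) {
    hits <- scan_ebox(seqs)
    if (subtype != "any")
      hits <- hits[hits$subtype == subtype, , drop = FALSE]
    ids <- names(seqs)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    tab <- table(factor(hits$sequence_id, levels = ids))
    as.integer(tab)
  }
  fg <- count_hits(fg_seqs)
  bg <- count_hits(bg_seqs)
  fg_total <- length(fg_seqs)
  bg_total <- length(bg_seqs)
  if (mode == "presence") {
    fg_with <- sum(fg > 0)
    bg_with <- sum(bg > 0)
    bg_rate <- max(bg_with / bg_total, 1 / (bg_total + 1))
    fold <- (fg_with / fg_total) / bg_rate
    p <- stats::pbinom(fg_with - 1, fg_total, bg_rate,
                       lower.tail = FALSE)
  } else {
    fg_with <- sum(fg)
    bg_with <- sum(bg)
    bg_rate <- max(bg_with / bg_total, 1 / (bg_total + 1))
    fold <- (fg_with / fg_total) / bg_rate
    p <- stats::ppois(fg_with - 1, bg_rate * fg_total,
                      lower.tail = FALSE)
  }
  out <- data.frame(subtype = subtype, fg_with_hit = fg_with,
                    fg_total = fg_total, bg_with_hit = bg_with,
                    bg_total = bg_total, fold = fold, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("ebox_enrichment", "data.frame")
  out
}

#' Read a FASTA file as named character sequences
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Extract interval sequences from a genome
#'
#' @param genome named character vector of chromosome sequences (e.g.
#'   from [read_fasta()]).
#' @param intervals data frame of 0-based half-open intervals.
#' @return Character vector of sequences named `"chrom:start-end"`.
#' @export
extract_sequences <- function(genome, intervals) {
  validate_intervals(intervals)
  vapply(seq_len(nrow(intervals)), function(i) {
    if (!intervals$chrom[i] %in% names(genome))
      stop("chromosome absent from genome: ", intervals$chrom[i],
           call. = FALSE)
    chr <- genome[[intervals$chrom[i]]]
    substr(chr, intervals$start[i] + 1, intervals$end[i])
  }, "") |>
    stats::setNames(sprintf("%s:%s-%s", intervals$chrom,
                            format_coord(intervals$start),
                            format_coord(intervals$end)))
}
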