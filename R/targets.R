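#' Read a TAD map (BED4, 4th column = TAD id)
#'
#' Topologically associated domains consumed as plain intervals. TADs
#' must be non-overlapping within a chromosome but need not tile it:
#' boundary gaps are allowed, and anchors falling in gaps are
#' "unassigned"/"excluded" downstream rather than silently dropped.
#'
#' @param path BED4 path.
#' @return Data frame (`chrom`, `start`, `end`, `tad_id`) of class
#'   `tad_map`.
#' @export
read_tads <- function(path) {
  df <- read_bed(path, kind = "region")
  if (is.null(df$name)) stop("TAD BED needs a 4th (tad_id) column",
                             call. = FALSE)
  tad_map(data.frame(chrom = df$chrom, start = df$start, end = df$end,
                     tad_id = df$name, stringsAsFactors = FALSE))
}

#' Construct a TAD map
#'
#' @param tads data frame with `chrom`, `start`, `end`, `tad_id`.
#' @return Validated `tad_map` data frame.
#' @export
tad_map <- function(tads) {
  validate_intervals(tads, "TAD")
  if (is.null(tads$tad_id)) stop("tads need a tad_id column", call. = FALSE)
  if (anyDuplicated(tads$tad_id)) stop("duplicate tad_id", call. = FALSE)
  for (i in split(seq_len(nrow(tads)), tads$chrom)) {
    ir <- as_iranges0(tads[i, , drop = FALSE])
    ov <- IRanges::findOverlaps(ir, ir)
    if (length(ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]))
      stop("overlapping TADs on ", tads$chrom[i[1]], call. = FALSE)
  }
  class(tads) <- c("tad_map", "data.frame")
  tads
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `symbol`, `chrom`, `start`, `end`,
#' `strand`. The TSS is derived from strand: `start` for `+`, `end - 1`
#' for `-` (0-based).
#'
#' @param path TSV path.
#' @return Data frame of genes with a `tss` column.
#' @export
read_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("gene table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  gene_table(df)
}

#' Construct/validate a gene table
#'
#' @param df data frame with `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`; `tss` is recomputed from strand.
#' @return Validated gene data frame.
#' @export
gene_table <- function(df) {
  validate_intervals(df, "gene")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be + or -", call. = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id", call. = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  stopifnot(all(df$tss >= df$start & df$tss < df$end))
  df
}

#' Assign anchor points to TADs
#'
#' Membership is decided by containment of a single anchor base — the
#' TSS for genes, the interval midpoint for peaks — under half-open
#' containment (`tad_start <= anchor < tad_end`), so an anchor exactly on
#' a TAD start belongs to that TAD. Anchors in boundary gaps map to `NA`.
#'
#' @param items data frame of genes (with `tss`) or intervals; or a
#'   [peak_set()].
#' @param tads a [tad_map()].
#' @param anchor `"auto"` (tss when present, else midpoint), `"tss"`, or
#'   `"midpoint"`.
#' @return Character vector of `tad_id` (NA when unassigned).
#' @export
assign_to_tads <- function(items, tads, anchor = c("auto", "tss",
                                                   "midpoint")) {
  anchor <- match.arg(anchor)
  if (is_peak_set(items)) items <- items$peaks
  stopifnot(inherits(tads, "tad_map"))
  if (anchor == "auto") anchor <- if (!is.null(items$tss)) "tss" else
    "midpoint"
  pos <- if (anchor == "tss") items$tss else
    floor((items$start + items$end) / 2)
  out <- rep(NA_character_, nrow(items))
  if (!nrow(items)) return(out)
  for (ch in intersect(unique(items$chrom), unique(tads$chrom))) {
    ii <- which(items$chrom == ch)
    it <- which(tads$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(pos[ii] + 1, pos[ii] + 1),
      as_iranges0(tads[it, , drop = FALSE]))
    out[ii[S4Vectors::queryHits(hits)]] <-
      tads$tad_id[it[S4Vectors::subjectHits(hits)]]
  }
  out
}

#' Classify candidate genes as direct or indirect targets
#'
#' The TAD-constrained direct/indirect partition for a repressor
#' knockdown: a candidate (e.g. consistently upregulated myogenic) gene
#' is a *direct* target when its TAD contains at least one
#' high-confidence peak of the factor, *indirect* when its TAD contains
#' none, and *excluded* when its TSS falls outside every TAD. Direct
#' calls record the supporting peak ids; the three classes partition the
#' candidates.
#'
#' @param candidate_genes character vector of gene ids (must all be
#'   known).
#' @param hc_peaks high-confidence (e.g. consensus) [peak_set()].
#' @param tads a [tad_map()].
#' @param genes gene table ([gene_table()]).
#' @param evidence optional named list of per-cell-line named log2FC
#'   vectors echoed into the output.
#' @param gene_anchor,peak_anchor anchor conventions passed to
#'   [assign_to_tads()].
#' @return Object of class `target_calls`: data frame (`gene_id`,
#'   `class`, `tad_id`, `supporting_peaks`, evidence columns) with a
#'   `counts` attribute `(n_direct, n_indirect, n_excluded)`.
#' @export
classify_targets <- function(candidate_genes, hc_peaks, tads, genes,
                             evidence = NULL, gene_anchor = "tss",
                             peak_anchor = "midpoint") {
  unknown <- setdiff(candidate_genes, genes$gene_id)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(utils::head(unknown, 10),
                                       collapse = ", "), call. = FALSE)
  gtad <- assign_to_tads(genes, tads, gene_anchor)
  names(gtad) <- genes$gene_id
  pk <- if (is_peak_set(hc_peaks)) hc_peaks$peaks else hc_peaks
  ptad <- assign_to_tads(pk, tads, peak_anchor)
  peak_id <- sprintf("%s:%s-%s", pk$chrom, format_coord(pk$start),
                     format_coord(pk$end))
  peaks_by_tad <- split(peak_id, ptad)
  tad <- gtad[candidate_genes]
  klass <- ifelse(is.na(tad), "excluded",
                  ifelse(tad %in% names(peaks_by_tad), "direct",
                         "indirect"))
  support <- vapply(seq_along(tad), function(i) {
    if (klass[i] != "direct") return("")
    paste(peaks_by_tad[[tad[i]]], collapse = ",")
  }, "")
  out <- data.frame(gene_id = candidate_genes, class = klass,
                    tad_id = tad, supporting_peaks = support,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(evidence))
    for (nm in names(evidence))
      out[[paste0("log2fc_", nm)]] <- unname(evidence[[nm]][candidate_genes])
  counts <- c(n_direct = sum(klass == "direct"),
              n_indirect = sum(klass == "indirect"),
              n_excluded = sum(klass == "excluded"))
  stopifnot(sum(counts) == length(candidate_genes))
  attr(out, "counts") <- counts
  class(out) <- c("target_calls", "data.frame")
  out
}

#' @export
print.target_calls <- function(x, ...) {
  ct <- attr(x, "counts")
  cat(sprintf("<target_calls> %d candidates: %d direct, %d indirect, %d excluded\n",
              nrow(x), ct["n_direct"], ct["n_indirect"], ct["n_excluded"]))
  invisible(x)
}

#' Write target calls as TSV and JSON
#'
#' @param calls a `target_calls` object.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return `tsv_path`, invisibly.
#' @export
write_target_calls <- function(calls, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(calls, "target_calls"))
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(calls), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(json_path))
    jsonlite::write_json(list(counts = as.list(attr(calls, "counts")),
                              calls = as.data.frame(calls)),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(tsv_path)
}
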