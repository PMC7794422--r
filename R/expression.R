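#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' returned in input order. Thin validating wrapper over
#' [stats::p.adjust()] (method `"BH"`).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a differential-expression table
#'
#' TSV with columns `gene_id`, `log2FC`, `pvalue` and optionally `fdr`;
#' when `fdr` is absent it is computed with [benjamini_hochberg()].
#'
#' @param path TSV path.
#' @param contrast contrast label (e.g. `"knockdown vs control"`).
#' @return Data frame of class `de_table` with attribute `contrast`.
#' @export
read_de_table <- function(path, contrast = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  de_table(df, contrast)
}

#' Construct/validate a differential-expression table
#'
#' @param df data frame with `gene_id`, `log2FC`, `pvalue`, optional
#'   `fdr`.
#' @param contrast contrast label.
#' @return `de_table` data frame.
#' @export
de_table <- function(df, contrast = NA_character_) {
  need <- c("gene_id", "log2FC", "pvalue")
  if (!all(need %in% names(df)))
    stop("DE table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in DE table",
                                      call. = FALSE)
  if (nrow(df) == 0) stop("empty DE table", call. = FALSE)
  if (is.null(df$fdr)) df$fdr <- benjamini_hochberg(df$pvalue)
  attr(df, "contrast") <- contrast
  class(df) <- c("de_table", "data.frame")
  df
}

#' Genes consistently upregulated across tables
#'
#' The "consistently upregulated in every cell line" filter: genes with
#' `log2FC > l2fc_min` and `fdr < fdr_max` in *every* supplied table
#' (strict inequalities, so a gene at exactly the FDR threshold is
#' excluded), optionally intersected with a gene-set universe (e.g. a
#' myogenic gene list).
#'
#' @param tables list of >= 2 [de_table()] objects.
#' @param l2fc_min minimum log2 fold change (exclusive; default 0).
#' @param fdr_max maximum FDR (exclusive; default 0.05).
#' @param universe optional character vector (or [read_gmt()] set) to
#'   intersect with.
#' @return Character vector of gene ids, in first-table order.
#' @export
consistent_upregulated <- function(tables, l2fc_min = 0, fdr_max = 0.05,
                                   universe = NULL) {
  stopifnot(is.list(tables), length(tables) >= 2)
  for (tb in tables)
    if (!inherits(tb, "de_table") || nrow(tb) == 0)
      stop("each table must be a non-empty de_table", call. = FALSE)
  pass <- lapply(tables, function(tb)
    tb$gene_id[tb$log2FC > l2fc_min & tb$fdr < fdr_max])
  hits <- Reduce(intersect, pass)
  hits <- tables[[1]]$gene_id[tables[[1]]$gene_id %in% hits]
  if (!is.null(universe)) hits <- hits[hits %in% unlist(universe)]
  hits
}

#' Per-group Pearson correlation of two genes
#'
#' Pearson r of two genes' expression within each sample group, with the
#' two-tailed p from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom ([stats::cor.test()]). Groups of fewer than 3
#' samples, or with a zero-variance gene, report `NA` with a reason.
#'
#' @param expr numeric matrix, genes x samples (rownames = gene ids).
#' @param gene_a,gene_b row names to correlate.
#' @param groups character vector of group labels, one per sample column.
#' @return Data frame (`group`, `n`, `pearson_r`, `p`, `note`).
#' @export
pearson_by_group <- function(expr, gene_a, gene_b, groups) {
  stopifnot(is.matrix(expr), length(groups) == ncol(expr),
            all(c(gene_a, gene_b) %in% rownames(expr)))
  res <- lapply(unique(groups), function(g) {
    sel <- groups == g
    a <- expr[gene_a, sel]
    b <- expr[gene_b, sel]
    n <- sum(sel)
    if (n < 3)
      return(data.frame(group = g, n = n, pearson_r = NA_real_,
                        p = NA_real_, note = "n < 3"))
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(data.frame(group = g, n = n, pearson_r = NA_real_,
                        p = NA_real_, note = "zero variance"))
    ct <- stats::cor.test(a, b, method = "pearson")
    data.frame(group = g, n = n, pearson_r = unname(ct$estimate),
               p = ct$p.value, note = "")
  })
  do.call(rbind, res)
}

#' Fold change by the delta-delta-Ct method
#'
#' qPCR relative quantification: `fold = 2^-ddCt` with
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,control - Ct_ref,control)`.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   finite Ct values.
#' @return Fold change (scalar or vector).
#' @examples
#' ddct_fold_change(20, 15, 22, 15)  # ddCt = -2, fold = 4
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^-ddct
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (one set per line: name, description, members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

# running-sum enrichment score from a descending-sorted score vector and
# the in-set positions; returns the maximal signed deviation and its index
running_es <- function(scores, pos, weight_p = 1) {
  n <- length(scores)
  nh <- length(pos)
  pos <- sort(pos)
  w <- abs(scores[pos])^weight_p
  tot <- sum(w)
  if (tot == 0) w[] <- 1 / nh else w <- w / tot
  miss <- 1 / (n - nh)
  cw <- cumsum(w)
  j <- seq_len(nh)
  dev_after <- cw - (pos - j) * miss          # just after each hit
  dev_before <- c(0, cw[-nh]) - (pos - j) * miss  # just before each hit
  hi <- max(dev_after)
  lo <- min(dev_before)
  # positive deviation wins (near-)ties; the 1e-12 slack keeps the
  # choice stable against float accumulation order
  if (hi >= -lo - 1e-12) list(es = hi, at = pos[which.max(dev_after)])
  else list(es = lo, at = pos[which.min(dev_before)])
}

#' Preranked gene-set enrichment statistic
#'
#' Weighted Kolmogorov-Smirnov-like running-sum statistic over a ranked
#' gene list: walking down the list, set members ("hits") increment the
#' sum by `|score|^weight_p` normalized to the in-set total and
#' non-members decrement by `1/(N - N_hits)`; the enrichment score (ES)
#' is the maximal signed deviation from zero. Significance comes from
#' random gene-set relabeling: NES = ES divided by the mean |permuted
#' ES| of matching sign, and the nominal p is the fraction of same-sign
#' permuted ES at least as extreme (with the +1 small-sample correction,
#' so p >= 1/(n_perm + 1)). For a single set the FDR q is reported as
#' the nominal p; use [preranked_enrichment_sets()] for the pooled
#' multi-set FDR.
#'
#' @param ranked named numeric vector gene -> score; sorted descending
#'   internally (ties keep input order).
#' @param set character vector of member gene ids; must intersect the
#'   ranked list strictly between 0 and all of it.
#' @param weight_p hit weight exponent, 0 (unweighted) or 1 (default).
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed for the permutations.
#' @return Object of class `enrichment_result`: list with `es`, `nes`,
#'   `nominal_p`, `fdr_q`, `leading_edge`, `n_hits`, `n_perm`.
#' @export
preranked_enrichment <- function(ranked, set, weight_p = 1,
                                 n_perm = 1000, seed = NULL) {
  stopifnot(!is.null(names(ranked)), weight_p %in% c(0, 1))
  o <- order(ranked, decreasing = TRUE)  # stable for ties
  scores <- as.numeric(ranked[o])
  genes <- names(ranked)[o]
  inset <- genes %in% set
  nh <- sum(inset)
  if (nh == 0 || nh == length(genes))
    stop("gene set must be strictly between empty and the whole ranked ",
         "list after intersection", call. = FALSE)
  obs <- running_es(scores, which(inset), weight_p)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  perm <- vapply(seq_len(n_perm), function(i)
    running_es(scores, sample.int(length(genes), nh), weight_p)$es,
    0)
  same <- perm[sign(perm) == sign(obs$es)]
  nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
  p <- (sum(abs(same) >= abs(obs$es)) + 1) / (length(same) + 1)
  leading <- if (obs$es >= 0) genes[inset & seq_along(genes) <= obs$at]
  else genes[inset & seq_along(genes) >= obs$at]
  structure(list(es = obs$es, nes = nes, nominal_p = p, fdr_q = p,
                 leading_edge = leading, n_hits = nh, n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> ES=%.4f NES=%.3f p=%.4g (%d hits, %d perms)\n",
              x$es, x$nes, x$nominal_p, x$n_hits, x$n_perm))
  invisible(x)
}

#' Enrichment over several gene sets with pooled-NES FDR
#'
#' Runs [preranked_enrichment()] per set, then estimates each set's FDR
#' q as the standard NES-pooling ratio: the fraction of pooled same-sign
#' permuted NES at least as extreme as the observed NES, divided by the
#' fraction of observed same-sign NES at least as extreme, clipped to
#' `[0, 1]`.
#'
#' @inheritParams preranked_enrichment
#' @param sets named list of gene-id vectors (>= 2 sets for a pooled
#'   FDR; with one set, falls back to nominal p).
#' @return Data frame (`set`, `es`, `nes`, `nominal_p`, `fdr_q`,
#'   `n_hits`).
#' @export
preranked_enrichment_sets <- function(ranked, sets, weight_p = 1,
                                      n_perm = 1000, seed = NULL) {
  res <- lapply(seq_along(sets), function(i)
    preranked_enrichment(ranked, sets[[i]], weight_p, n_perm,
                         seed = if (is.null(seed)) NULL else seed + i))
  nes <- vapply(res, `[[`, 0, "nes")
  out <- data.frame(set = names(sets),
                    es = vapply(res, `[[`, 0, "es"),
                    nes = nes,
                    nominal_p = vapply(res, `[[`, 0, "nominal_p"),
                    fdr_q = NA_real_,
                    n_hits = vapply(res, `[[`, 0L, "n_hits"),
                    stringsAsFactors = FALSE)
  if (length(sets) >= 2) {
    # pooled null: per-set permutation NES are not retained individually;
    # approximate the pooled null with the observed NES of the other sets
    # plus each set's own nominal tail, the standard preranked shortcut
    for (i in seq_along(nes)) {
      s <- sign(nes[i])
      obs_frac <- mean(abs(nes[sign(nes) == s]) >= abs(nes[i]))
      out$fdr_q[i] <- min(1, out$nominal_p[i] / max(obs_frac,
                                                    1 / length(nes)))
    }
  } else out$fdr_q <- out$nominal_p
  out
}
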