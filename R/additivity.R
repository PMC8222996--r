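# Additive vs non-additive inheritance of m6A peaks and gene expression in
# hybrids, relative to the mid-parent value (MPV).

#' Mid-parent value
#'
#' Arithmetic mean of the two parental values, the additive expectation
#' for a hybrid. Vectorized.
#'
#' @param a,b parental values.
#' @return `(a + b) / 2`.
#' @export
mid_parent <- function(a, b) (a + b) / 2

#' Classify hybrid peak inheritance against the mid-parent value
#'
#' Peaks common to the hybrid and both parents are tested with Fisher's
#' exact test comparing the hybrid's depth-equalized IP/input counts
#' against the rounded average of the parents' counts; p-values are
#' Holm-adjusted across all such peaks of the hybrid. Peaks with
#' `padj < alpha` are non-additive, all others additive.
#'
#' @param quant_hybrid,quant_parent_a,quant_parent_b filtered `peak_quant`
#'   data.frames.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame of class `additivity_calls`: per-peak counts, MPV,
#'   enrichments, `mpv_deviation_fold`, `p_value`, `p_adjusted`, `mode`.
#' @export
classify_peak_additivity <- function(quant_hybrid, quant_parent_a,
                                     quant_parent_b, alpha = 0.05) {
  pa <- common_peaks(quant_hybrid, quant_parent_a)
  pb <- common_peaks(quant_hybrid, quant_parent_b)
  shared <- intersect(pa$idx_a, pb$idx_a)
  pa <- pa[match(shared, pa$idx_a), , drop = FALSE]
  pb <- pb[match(shared, pb$idx_a), , drop = FALSE]
  ih <- pa$idx_a; ia <- pa$idx_b; ib <- pb$idx_b

  th <- attr(quant_hybrid, "totals")
  ta <- attr(quant_parent_a, "totals")
  tb <- attr(quant_parent_b, "totals")
  eq <- .equalize_counts(
    list(quant_hybrid$ip_count[ih], quant_hybrid$input_count[ih],
         quant_parent_a$ip_count[ia], quant_parent_a$input_count[ia],
         quant_parent_b$ip_count[ib], quant_parent_b$input_count[ib]),
    c(th$ip, th$input, ta$ip, ta$input, tb$ip, tb$input))
  mpv_ip <- round_half_up(mid_parent(eq[[3]], eq[[5]]))
  mpv_input <- round_half_up(mid_parent(eq[[4]], eq[[6]]))
  p <- .fisher_vec(eq[[1]], eq[[2]], mpv_ip, mpv_input)
  padj <- holm_adjust(p)

  eh <- quant_hybrid$enrichment[ih]
  mpv_enr <- mid_parent(quant_parent_a$enrichment[ia],
                        quant_parent_b$enrichment[ib])
  out <- data.frame(
    peak_id = quant_hybrid$peak_id[ih],
    gene_id = quant_hybrid$gene_id[ih],
    hybrid_ip = eq[[1]], hybrid_input = eq[[2]],
    mpv_ip = mpv_ip, mpv_input = mpv_input,
    hybrid_enrichment = eh, mpv_enrichment = mpv_enr,
    mpv_deviation_fold = pmax(eh / mpv_enr, mpv_enr / eh),
    p_value = p, p_adjusted = padj,
    mode = ifelse(padj < alpha, "non_additive", "additive"),
    stringsAsFactors = FALSE)
  attr(out, "hybrid") <- attr(quant_hybrid, "genotype")
  attr(out, "alpha") <- alpha
  class(out) <- c("additivity_calls", "data.frame")
  out
}

#' Classify hybrid gene expression as additive or non-additive
#'
#' Either consumes an external differential-expression table testing
#' hybrid vs mid-parent (e.g. a DESeq2 contrast; the fidelity route), or
#' applies the built-in Fisher stand-in comparing the hybrid's count
#' against the parents' combined count at equalized depths, Holm-adjusted
#' across genes.
#'
#' @param gene_id character vector of genes (builtin) — ignored for
#'   `external_table`.
#' @param method `"external_table"` or `"builtin"`.
#' @param external_table data.frame with columns `gene_id` and `padj`.
#' @param hybrid_count,parent_a_count,parent_b_count integer counts per
#'   gene (builtin).
#' @param hybrid_depth,parent_a_depth,parent_b_depth library sizes
#'   (builtin).
#' @param parent_combine average the parents' equalized counts (default)
#'   or sum them.
#' @param alpha adjusted-p threshold.
#' @return data.frame of class `additivity_calls` with `unit_id`, `mode`,
#'   `p_adjusted` and a `method` provenance column.
#' @export
classify_expression_additivity <- function(gene_id = NULL,
                                           method = c("external_table", "builtin"),
                                           external_table = NULL,
                                           hybrid_count = NULL,
                                           parent_a_count = NULL,
                                           parent_b_count = NULL,
                                           hybrid_depth = NULL,
                                           parent_a_depth = NULL,
                                           parent_b_depth = NULL,
                                           parent_combine = c("average", "sum"),
                                           alpha = 0.05) {
  method <- match.arg(method)
  parent_combine <- match.arg(parent_combine)
  if (method == "external_table") {
    stopifnot(!is.null(external_table),
              all(c("gene_id", "padj") %in% names(external_table)))
    out <- data.frame(
      unit_id = external_table$gene_id,
      p_value = NA_real_, p_adjusted = external_table$padj,
      mode = ifelse(external_table$padj < alpha, "non_additive", "additive"),
      method = "external_table", stringsAsFactors = FALSE)
  } else {
    stopifnot(!is.null(gene_id), !is.null(hybrid_count),
              !is.null(parent_a_count), !is.null(parent_b_count),
              !is.null(hybrid_depth), !is.null(parent_a_depth),
              !is.null(parent_b_depth))
    eq <- .equalize_counts(list(hybrid_count, parent_a_count, parent_b_count),
                           c(hybrid_depth, parent_a_depth, parent_b_depth))
    depth <- min(hybrid_depth, parent_a_depth, parent_b_depth)
    if (parent_combine == "average") {
      mpv <- round_half_up(mid_parent(eq[[2]], eq[[3]]))
      mpv_depth <- depth
    } else {
      mpv <- eq[[2]] + eq[[3]]
      mpv_depth <- 2 * depth
    }
    p <- .fisher_vec(eq[[1]], pmax(depth - eq[[1]], 0),
                     mpv, pmax(mpv_depth - mpv, 0))
    padj <- holm_adjust(p)
    out <- data.frame(
      unit_id = gene_id, p_value = p, p_adjusted = padj,
      mode = ifelse(padj < alpha, "non_additive", "additive"),
      method = "builtin", stringsAsFactors = FALSE)
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("additivity_calls", "data.frame")
  out
}

#' Association of non-additive methylation with non-additive expression
#'
#' Genes are cross-classified by carrying at least one non-additive m6A
#' peak and by non-additive expression; independence is tested with the
#' chi-square test. A degenerate table (an empty margin) skips the test
#' with a notice.
#'
#' @param peak_calls `additivity_calls` from [classify_peak_additivity()]
#'   (needs `gene_id`).
#' @param expr_calls `additivity_calls` from
#'   [classify_expression_additivity()].
#' @return list with `table`, `proportions` and `test` (`NULL` when
#'   degenerate).
#' @export
associate_nonadditive <- function(peak_calls, expr_calls) {
  na_meth_genes <- unique(peak_calls$gene_id[peak_calls$mode == "non_additive"])
  tested_meth_genes <- unique(peak_calls$gene_id)
  universe <- unique(expr_calls$unit_id[expr_calls$unit_id %in% tested_meth_genes])
  na_expr_genes <- expr_calls$unit_id[expr_calls$mode == "non_additive"]
  res <- overlap_association(na_meth_genes, na_expr_genes, universe)
  if (res$test$degenerate) {
    .msg("associate_nonadditive: degenerate table, chi-square test skipped")
    res$test <- NULL
  }
  res
}
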