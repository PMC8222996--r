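# Common-peak matching, Fisher-exact differential methylation with
# Bonferroni-Holm correction and fold criteria, plus the auxiliary
# statistics (Wilcoxon, chi-square, Pearson, set-overlap association).

#' Differential methylation criteria
#'
#' A peak is differentially methylated when its Holm-adjusted Fisher p is
#' below `max_padj` and the enrichment fold change strictly exceeds
#' `min_fold`.
#'
#' @param max_padj adjusted-p threshold (default 0.05).
#' @param min_fold fold-change threshold, strict (default 1.5).
#' @return list of class `dmp_criteria`.
#' @export
dmp_criteria <- function(max_padj = 0.05, min_fold = 1.5) {
  stopifnot(max_padj > 0, max_padj < 1, min_fold > 1)
  structure(list(max_padj = max_padj, min_fold = min_fold),
            class = "dmp_criteria")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p defined, as is conventional, as the sum of hypergeometric
#' probabilities (margins fixed) of all tables at most as probable as the
#' observed one. A table with a zero row or column margin is degenerate
#' and returns p = 1 with a flag.
#'
#' @param table 2x2 matrix of non-negative integer counts, or the vector
#'   `c(a, b, c, d)` filled row-wise.
#' @return list with `p_value` and `degenerate`.
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), nrow = 2, byrow = TRUE)
  stopifnot(dim(table) == c(2, 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p_value = 1, degenerate = TRUE))
  # fisher.test can exceed 1 by floating-point accumulation
  list(p_value = min(1, fisher.test(table)$p.value), degenerate = FALSE)
}

## vectorized Fisher over parallel count vectors (rows: a,b over c,d)
.fisher_vec <- function(a, b, c, d) {
  vapply(seq_along(a), function(i)
    fisher_exact(matrix(c(a[i], b[i], c[i], d[i]), 2, byrow = TRUE))$p_value,
    numeric(1))
}

#' Bonferroni-Holm step-down adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "holm")
}

#' Match common peaks between two samples
#'
#' Peaks from the two quantifications are paired when they intersect by at
#' least 1 nt; a peak with several intersecting partners is paired with
#' its largest-overlap partner (greedy one-to-one matching, ties broken by
#' coordinate). Each pair carries the union of the two intervals so both
#' samples' reads can be tallied over identical coordinates.
#'
#' @param quant_a,quant_b `peak_quant` data.frames (ideally filtered).
#' @return data.frame with indices `idx_a`, `idx_b`, the two peak ids,
#'   `overlap`, and merged `chrom`/`start`/`end`.
#' @export
common_peaks <- function(quant_a, quant_b) {
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      peak_a = character(), peak_b = character(),
                      overlap = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(quant_a) == 0 || nrow(quant_b) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(.as_granges(quant_a), .as_granges(quant_b),
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- interval_intersect(quant_a[qh, c("chrom", "start", "end")],
                           quant_b[sh, c("chrom", "start", "end")])
  o <- order(-ov, qh, sh)
  used_a <- logical(nrow(quant_a)); used_b <- logical(nrow(quant_b))
  keep <- logical(length(o))
  for (k in seq_along(o)) {
    i <- qh[o[k]]; j <- sh[o[k]]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; keep[k] <- TRUE
    }
  }
  sel <- o[keep]
  out <- data.frame(
    idx_a = qh[sel], idx_b = sh[sel],
    peak_a = quant_a$peak_id[qh[sel]], peak_b = quant_b$peak_id[sh[sel]],
    overlap = as.integer(ov[sel]),
    chrom = quant_a$chrom[qh[sel]],
    start = pmin(quant_a$start[qh[sel]], quant_b$start[sh[sel]]),
    end = pmax(quant_a$end[qh[sel]], quant_b$end[sh[sel]]),
    stringsAsFactors = FALSE)
  out[order(out$idx_a), , drop = FALSE]
}

## depth-equalized integer counts: scale each count to the smallest library
## group in the comparison, rounding halves up. Keeps Fisher conservative
## at modest sequencing depth (scaling factors <= 1).
.equalize_counts <- function(counts, totals) {
  tmin <- min(as.numeric(totals))
  lapply(seq_along(counts), function(i)
    round_half_up(as.numeric(counts[[i]]) * tmin / as.numeric(totals[[i]])))
}

#' Call differentially methylated peaks between two samples
#'
#' For every common peak a 2x2 table of depth-equalized IP and input read
#' counts (rows: samples; columns: IP, input) is tested with Fisher's
#' exact test; p-values are Holm-adjusted across all common peaks of the
#' comparison. A peak is significant when `padj < max_padj` and the
#' enrichment ratio between the samples strictly exceeds `min_fold`.
#'
#' @param quant_a,quant_b filtered `peak_quant` data.frames.
#' @param criteria [dmp_criteria()].
#' @param pairs optional precomputed [common_peaks()] result.
#' @return data.frame of class `dmp_results`: pair coordinates, per-sample
#'   counts and enrichments, `fold_change`, `direction` (genotype with the
#'   higher enrichment), `p_value`, `p_adjusted`, `significant`.
#' @export
call_dmps <- function(quant_a, quant_b, criteria = dmp_criteria(),
                      pairs = NULL) {
  if (is.null(pairs)) pairs <- common_peaks(quant_a, quant_b)
  gt_a <- attr(quant_a, "genotype"); gt_b <- attr(quant_b, "genotype")
  if (is.null(gt_a)) gt_a <- "A"
  if (is.null(gt_b)) gt_b <- "B"
  tot_a <- attr(quant_a, "totals"); tot_b <- attr(quant_b, "totals")
  ia <- pairs$idx_a; ib <- pairs$idx_b
  eq <- .equalize_counts(
    list(quant_a$ip_count[ia], quant_a$input_count[ia],
         quant_b$ip_count[ib], quant_b$input_count[ib]),
    c(tot_a$ip, tot_a$input, tot_b$ip, tot_b$input))
  p <- .fisher_vec(eq[[1]], eq[[2]], eq[[3]], eq[[4]])
  padj <- holm_adjust(p)
  ea <- quant_a$enrichment[ia]; eb <- quant_b$enrichment[ib]
  fold <- pmax(ea / eb, eb / ea)
  significant <- padj < criteria$max_padj & fold > criteria$min_fold
  out <- data.frame(
    peak_a = pairs$peak_a, peak_b = pairs$peak_b,
    gene_id = quant_a$gene_id[ia],
    chrom = pairs$chrom, start = pairs$start, end = pairs$end,
    ip_a = eq[[1]], input_a = eq[[2]], ip_b = eq[[3]], input_b = eq[[4]],
    enrichment_a = ea, enrichment_b = eb,
    fold_change = fold,
    direction = ifelse(ea >= eb, gt_a, gt_b),
    p_value = p, p_adjusted = padj, significant = significant,
    stringsAsFactors = FALSE)
  attr(out, "genotypes") <- c(gt_a, gt_b)
  attr(out, "criteria") <- criteria
  class(out) <- c("dmp_results", "data.frame")
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples without ties (n + m <= 12), normal
#' approximation with tie correction otherwise.
#'
#' @param x,y non-empty numeric samples.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  pooled <- c(x, y)
  if (all(pooled == pooled[1])) return(1)  # tie-corrected variance is zero
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && (length(x) + length(y) <= 12)
  suppressWarnings(wilcox.test(x, y, exact = exact)$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic without continuity correction by default, df = 1.
#' Tables with a zero margin are degenerate (statistic `NA`).
#'
#' @param table 2x2 matrix or vector `c(a, b, c, d)` row-wise.
#' @param correct apply Yates' continuity correction.
#' @return list with `statistic`, `p_value`, `degenerate`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, byrow = TRUE)
  stopifnot(dim(table) == c(2, 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE))
  tst <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(tst$statistic), p_value = unname(tst$p.value),
       degenerate = FALSE)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  cor(x, y)
}

#' Association between two gene sets over a universe
#'
#' Cross-classifies the universe by membership in the two sets and tests
#' independence with the Pearson chi-square test.
#'
#' @param set1,set2 character vectors of members (e.g. DEGs and DMGs).
#' @param universe character vector of all tested units.
#' @return list with `table` (2x2 counts: in/out of set1 by in/out of
#'   set2), `proportions` (fraction of set1/non-set1 members in set2) and
#'   `test` ([chi_square_2x2()] result).
#' @export
overlap_association <- function(set1, set2, universe) {
  in1 <- universe %in% set1
  in2 <- universe %in% set2
  tab <- matrix(c(sum(in1 & in2), sum(in1 & !in2),
                  sum(!in1 & in2), sum(!in1 & !in2)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_set1", "out_set1"),
                                c("in_set2", "out_set2")))
  prop <- c(set1_in_set2 = if (sum(in1) > 0) mean(in2[in1]) else NA_real_,
            others_in_set2 = if (sum(!in1) > 0) mean(in2[!in1]) else NA_real_)
  list(table = tab, proportions = prop, test = chi_square_2x2(tab))
}
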