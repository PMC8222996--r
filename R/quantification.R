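# Per-gene expression, per-peak IP/input quantification and enrichment,
# confidence filtering, summit calling, feature / codon-segment assignment
# and metagene profiles.

#' Peak confidence filter parameters
#'
#' Peaks are retained only on genes with `FPKM >= min_gene_fpkm` and when
#' the peak region itself reaches `input FPKM >= min_peak_input_fpkm`
#' (both boundaries inclusive).
#'
#' @param min_gene_fpkm minimum gene-level input FPKM (default 1).
#' @param min_peak_input_fpkm minimum peak-region input FPKM (default 5).
#' @return list of class `peak_filter_params`.
#' @export
peak_filter_params <- function(min_gene_fpkm = 1, min_peak_input_fpkm = 5) {
  stopifnot(min_gene_fpkm >= 0, min_peak_input_fpkm >= 0)
  structure(list(min_gene_fpkm = min_gene_fpkm,
                 min_peak_input_fpkm = min_peak_input_fpkm),
            class = "peak_filter_params")
}

#' Annotation parameters for summit assignment
#'
#' @param codon_segment_width width (nt, even) of the start/stop codon
#'   segments, centered on the codon anchors (default 200).
#' @param tier_order priority order for feature assignment; a summit
#'   falling in several annotated features gets the first matching tier.
#' @return list of class `annotation_params`.
#' @export
annotation_params <- function(codon_segment_width = 200L,
                              tier_order = c("utr3", "utr5", "cds")) {
  stopifnot(codon_segment_width > 0, codon_segment_width %% 2 == 0,
            setequal(tier_order, c("utr3", "utr5", "cds")))
  structure(list(codon_segment_width = as.integer(codon_segment_width),
                 tier_order = tier_order),
            class = "annotation_params")
}

#' Fragments per kilobase of exonic length per million mapped reads
#'
#' @param raw_count reads assigned to the gene (or region).
#' @param exonic_length exonic (or region) length in nt, > 0.
#' @param total_mapped library size, > 0.
#' @return FPKM value(s).
#' @export
compute_fpkm <- function(raw_count, exonic_length, total_mapped) {
  if (any(exonic_length <= 0)) stop("exonic_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  raw_count / (exonic_length / 1e3 * total_mapped / 1e6)
}

#' Assign peaks to genes by exonic overlap
#'
#' Each peak is attached to the gene whose representative (longest)
#' transcript it overlaps most; peaks overlapping no transcript get `NA`.
#'
#' @param peaks peak data.frame ([parse_bed6()]).
#' @param models a `transcript_models` object.
#' @return `peaks` with added `gene_id` and `transcript_id` columns.
#' @export
annotate_peaks <- function(peaks, models) {
  reps <- .representative_transcripts(models)
  if (nrow(peaks) == 0) {
    peaks$gene_id <- character(0); peaks$transcript_id <- character(0)
    return(peaks)
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(peaks), .as_granges(reps),
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- interval_intersect(peaks[qh, c("chrom", "start", "end")],
                           reps[sh, c("chrom", "start", "end")])
  best <- rep(NA_integer_, nrow(peaks))
  o <- order(qh, -ov, sh)
  qo <- qh[o]
  first <- !duplicated(qo)
  best[qo[first]] <- sh[o][first]
  peaks$gene_id <- reps$gene_id[best]
  peaks$transcript_id <- reps$transcript_id[best]
  peaks
}

## one representative (longest exonic length) transcript per gene
.representative_transcripts <- function(models) {
  tx <- models$transcripts
  o <- order(tx$gene_id, -tx$exonic_length, tx$transcript_id)
  tx <- tx[o, , drop = FALSE]
  tx[!duplicated(tx$gene_id), , drop = FALSE]
}

#' Per-gene expression counts and FPKM
#'
#' Counts reads overlapping the representative transcript of each gene,
#' per library of the requested assay, and converts to FPKM using the
#' transcript's exonic length.
#'
#' @param exp a `merip_experiment`.
#' @param assay `"input"` (default) or `"IP"`.
#' @param stranded count only same-strand reads (default `FALSE`; library
#'   strandedness is usually unknown).
#' @return long data.frame: `gene_id`, `sample_id`, `genotype`,
#'   `replicate`, `count`, `fpkm`.
#' @export
gene_expression <- function(exp, assay = "input", stranded = FALSE) {
  reps <- .representative_transcripts(exp$annotation)
  s <- exp$samples[exp$samples$assay == assay, , drop = FALSE]
  out <- lapply(seq_len(nrow(s)), function(i) {
    reads <- exp$alignments[[s$sample_id[i]]]
    cnt <- .count_overlaps(reps, reads, stranded)
    data.frame(gene_id = reps$gene_id, sample_id = s$sample_id[i],
               genotype = s$genotype[i], replicate = s$replicate[i],
               count = cnt,
               fpkm = compute_fpkm(cnt, reps$exonic_length, s$total_mapped[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Quantify peaks for one genotype
#'
#' For every peak: raw and depth-normalized (RPM) IP and input reads
#' (per-library RPM averaged across replicates), the IP/input enrichment
#' ratio (input floored at a 0.5 RPM pseudocount, flagged `low_coverage`
#' when engaged), the summit of the replicate-merged IP-minus-input
#' coverage residual, the tiered feature assignment of the summit, its
#' codon-segment membership, and the gene/peak-level FPKM filter values.
#'
#' @param exp a `merip_experiment` with annotation and peaks.
#' @param genotype genotype whose IP and input libraries are used.
#' @param filter_params [peak_filter_params()].
#' @param annot_params [annotation_params()].
#' @param stranded same-strand-only counting (default `FALSE`).
#' @param compute_summits set `FALSE` to skip summit/feature assignment
#'   (faster when only counts are needed).
#' @param pseudocount RPM floor for the enrichment denominator.
#' @return data.frame of class `peak_quant`, one row per peak, with
#'   attributes `genotype` and `totals` (summed library sizes per assay).
#' @export
quantify_peaks <- function(exp, genotype,
                           filter_params = peak_filter_params(),
                           annot_params = annotation_params(),
                           stranded = FALSE, compute_summits = TRUE,
                           pseudocount = 0.5) {
  peaks <- exp$peaks
  if (is.null(peaks)) stop("experiment has no peaks")
  if (is.null(peaks$gene_id)) peaks <- annotate_peaks(peaks, exp$annotation)
  ip_s <- .samples_of(exp, genotype, "IP")
  in_s <- .samples_of(exp, genotype, "input")
  if (nrow(ip_s) == 0 || nrow(in_s) == 0)
    stop("genotype ", genotype, " needs at least one IP and one input library")

  count_mat <- function(s) {
    m <- vapply(s$sample_id,
                function(id) .count_overlaps(peaks, exp$alignments[[id]], stranded),
                integer(nrow(peaks)))
    matrix(m, nrow = nrow(peaks), ncol = nrow(s),
           dimnames = list(NULL, s$sample_id))
  }
  ip_counts <- count_mat(ip_s)      # peaks x replicates
  in_counts <- count_mat(in_s)
  ip_rpm <- sweep(ip_counts, 2, ip_s$total_mapped, function(cnt, tt)
    normalize_count(cnt, tt))
  in_rpm <- sweep(in_counts, 2, in_s$total_mapped, function(cnt, tt)
    normalize_count(cnt, tt))
  ip_norm <- rowMeans(ip_rpm)
  input_norm <- rowMeans(in_rpm)
  low_coverage <- input_norm < pseudocount
  enrichment <- ip_norm / pmax(input_norm, pseudocount)

  peak_len <- peaks$end - peaks$start
  peak_input_fpkm <- rowMeans(matrix(vapply(seq_len(nrow(in_s)), function(j)
    compute_fpkm(in_counts[, j], peak_len, in_s$total_mapped[j]),
    numeric(nrow(peaks))), nrow = nrow(peaks), ncol = nrow(in_s)))
  gx <- gene_expression(exp, assay = "input", stranded = stranded)
  gx <- gx[gx$genotype == genotype, , drop = FALSE]
  gene_fpkm_tab <- tapply(gx$fpkm, gx$gene_id, mean)
  gene_fpkm <- as.numeric(gene_fpkm_tab[peaks$gene_id])

  summit <- rep(NA_integer_, nrow(peaks))
  summit_degenerate <- rep(NA, nrow(peaks))
  feature <- rep(NA_character_, nrow(peaks))
  codon_segments <- rep(NA_character_, nrow(peaks))
  if (compute_summits && nrow(peaks) > 0) {
    ip_all <- do.call(rbind, lapply(ip_s$sample_id, function(id)
      exp$alignments[[id]][, c("chrom", "start", "end")]))
    in_all <- do.call(rbind, lapply(in_s$sample_id, function(id)
      exp$alignments[[id]][, c("chrom", "start", "end")]))
    ip_cov <- .read_coverage(ip_all)
    in_cov <- .read_coverage(in_all)
    for (i in seq_len(nrow(peaks))) {
      ipv <- .coverage_window(ip_cov, peaks$chrom[i], peaks$start[i], peaks$end[i])
      inv <- .coverage_window(in_cov, peaks$chrom[i], peaks$start[i], peaks$end[i])
      sm <- call_summit(ipv, inv)
      summit[i] <- peaks$start[i] + sm$offset
      summit_degenerate[i] <- sm$degenerate
      feature[i] <- assign_feature(summit[i], exp$annotation, peaks$gene_id[i],
                                   annot_params)
      segs <- assign_codon_segment(summit[i], exp$annotation,
                                   peaks$transcript_id[i], annot_params)
      codon_segments[i] <- paste(segs, collapse = ",")
    }
  }

  out <- data.frame(
    peak_id = peaks$peak_id, gene_id = peaks$gene_id,
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    ip_count = as.integer(rowSums(ip_counts)),
    input_count = as.integer(rowSums(in_counts)),
    ip_norm = ip_norm, input_norm = input_norm,
    enrichment = enrichment, low_coverage = low_coverage,
    summit = summit, summit_degenerate = summit_degenerate,
    feature = feature, codon_segments = codon_segments,
    gene_fpkm = gene_fpkm, peak_input_fpkm = peak_input_fpkm,
    stringsAsFactors = FALSE)
  out$passes_filter <- !is.na(out$gene_fpkm) &
    out$gene_fpkm >= filter_params$min_gene_fpkm &
    out$peak_input_fpkm >= filter_params$min_peak_input_fpkm
  attr(out, "genotype") <- genotype
  attr(out, "totals") <- list(ip = sum(ip_s$total_mapped),
                              input = sum(in_s$total_mapped))
  class(out) <- c("peak_quant", "data.frame")
  out
}

#' Apply the peak confidence filter
#'
#' Retains peaks whose gene input FPKM and peak-region input FPKM both meet
#' their (inclusive) thresholds.
#'
#' @param quant a `peak_quant` data.frame ([quantify_peaks()]).
#' @param params [peak_filter_params()].
#' @return the retained subset, attributes preserved.
#' @export
filter_peaks <- function(quant, params = peak_filter_params()) {
  keep <- !is.na(quant$gene_fpkm) &
    quant$gene_fpkm >= params$min_gene_fpkm &
    quant$peak_input_fpkm >= params$min_peak_input_fpkm
  out <- quant[keep, , drop = FALSE]
  attr(out, "genotype") <- attr(quant, "genotype")
  attr(out, "totals") <- attr(quant, "totals")
  class(out) <- class(quant)
  out
}

#' Call a peak summit from coverage residuals
#'
#' The summit is the position maximizing the replicate-merged IP minus
#' input coverage; ties are broken by the leftmost position and a fully
#' flat residual is flagged degenerate.
#'
#' @param ip_cov,input_cov numeric per-base coverage over the peak.
#' @return list with `offset` (0-based within the peak) and `degenerate`.
#' @export
call_summit <- function(ip_cov, input_cov) {
  stopifnot(length(ip_cov) == length(input_cov), length(ip_cov) > 0)
  residual <- ip_cov - input_cov
  list(offset = which.max(residual) - 1L,
       degenerate = all(residual == residual[1]))
}

#' Tiered feature assignment of a summit
#'
#' Returns the first tier (by default 3'UTR, then 5'UTR, then CDS) whose
#' annotated intervals, pooled over all transcripts of the gene, contain
#' the position. `NA` with a warning when no annotated feature covers it
#' (e.g. annotation mismatch).
#'
#' @param pos genomic position (0-based).
#' @param models `transcript_models`.
#' @param gene_id gene whose transcripts are consulted.
#' @param params [annotation_params()].
#' @return `"UTR3"`, `"UTR5"`, `"CDS"`, or `NA`.
#' @export
assign_feature <- function(pos, models, gene_id,
                           params = annotation_params()) {
  ids <- models$transcripts$transcript_id[models$transcripts$gene_id == gene_id]
  fx <- models$features[models$features$transcript_id %in% ids, , drop = FALSE]
  labels <- c(utr3 = "UTR3", utr5 = "UTR5", cds = "CDS")
  for (tier in params$tier_order) {
    f <- fx[fx$type == tier, , drop = FALSE]
    if (nrow(f) > 0 && any(pos >= f$start & pos < f$end))
      return(unname(labels[tier]))
  }
  warning("position ", pos, " falls in no annotated feature of ", gene_id)
  NA_character_
}

## 0-based transcript coordinate of a genomic position (NA if intronic)
.genomic_to_tx <- function(models, transcript_id, pos) {
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  ex <- models$features[models$features$transcript_id == transcript_id &
                          models$features$type == "exon", , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  w <- ex$end - ex$start
  hit <- which(pos >= ex$start & pos < ex$end)
  if (length(hit) == 0) return(NA_integer_)
  plus_coord <- sum(w[seq_len(hit - 1L)]) + (pos - ex$start[hit])
  if (tx$strand == "-") sum(w) - 1L - plus_coord else plus_coord
}

#' Codon-segment membership of a summit
#'
#' A summit belongs to the start (stop) codon segment when its distance to
#' the start (stop) codon anchor, measured in transcript coordinates, is at
#' most half the segment width; short transcripts can put it in both.
#'
#' @param pos genomic position (0-based).
#' @param models `transcript_models`.
#' @param transcript_id transcript providing anchors and coordinates.
#' @param params [annotation_params()].
#' @return character vector, a subset of `c("start", "stop")`.
#' @export
assign_codon_segment <- function(pos, models, transcript_id,
                                 params = annotation_params()) {
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  if (nrow(tx) == 0) stop("unknown transcript ", transcript_id)
  half <- params$codon_segment_width / 2
  tpos <- .genomic_to_tx(models, transcript_id, pos)
  if (is.na(tpos)) return(character(0))
  out <- character(0)
  for (seg in c("start", "stop")) {
    anchor <- tx[[paste0(seg, "_codon_pos")]]
    if (is.na(anchor)) next
    ta <- .genomic_to_tx(models, transcript_id, anchor)
    if (!is.na(ta) && abs(tpos - ta) <= half) out <- c(out, seg)
  }
  out
}

#' Metagene coverage profile over 5'UTR / CDS / 3'UTR bins
#'
#' Each transcript with all three features is divided into the three
#' non-overlapping features, each rescaled to `bins_per_feature` bins, and
#' per-base RPM coverage is averaged per bin across transcripts.
#' Transcripts lacking a feature are excluded (and counted in the
#' `n_excluded` attribute). In the default `per_transcript` mode each
#' transcript's profile is scaled to mean 1 before averaging so highly
#' expressed genes do not dominate; `global` averages raw RPM coverage.
#'
#' @param exp a `merip_experiment`.
#' @param sample_ids libraries to profile (default: all).
#' @param bins_per_feature bins per feature (default 100).
#' @param mode `"per_transcript"` or `"global"`.
#' @return matrix (samples x 3*bins) with a `feature` attribute labelling
#'   the columns `UTR5`, `CDS`, `UTR3` in 5'->3' order.
#' @export
metagene_profile <- function(exp, sample_ids = NULL, bins_per_feature = 100L,
                             mode = c("per_transcript", "global")) {
  mode <- match.arg(mode)
  if (is.null(sample_ids)) sample_ids <- exp$samples$sample_id
  models <- exp$annotation
  tx <- models$transcripts
  fx <- models$features

  ## per-transcript base positions (5'->3') and bin assignment
  tx_bins <- list()
  n_excluded <- 0L
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    f <- fx[fx$transcript_id == id, , drop = FALSE]
    pieces <- lapply(c("utr5", "cds", "utr3"), function(tt) {
      p <- f[f$type == tt, , drop = FALSE]
      if (nrow(p) == 0) return(NULL)
      p <- p[order(p$start), , drop = FALSE]
      unlist(lapply(seq_len(nrow(p)), function(j) seq(p$start[j], p$end[j] - 1L)))
    })
    if (any(vapply(pieces, is.null, logical(1)))) {
      n_excluded <- n_excluded + 1L
      next
    }
    # pieces are already (utr5, cds, utr3) by type; on the minus strand the
    # transcript 5'->3' order runs right-to-left within each feature
    if (tx$strand[i] == "-") pieces <- lapply(pieces, rev)
    bins <- unlist(lapply(seq_along(pieces), function(k) {
      n <- length(pieces[[k]])
      within <- pmin(bins_per_feature - 1L,
                     ((seq_len(n) - 1L) * bins_per_feature) %/% n)
      (k - 1L) * bins_per_feature + within + 1L
    }))
    tx_bins[[id]] <- list(chrom = tx$chrom[i], pos = unlist(pieces), bin = bins)
  }
  if (length(tx_bins) == 0) stop("no transcript has all three features")

  nb <- 3L * bins_per_feature
  out <- matrix(0, nrow = length(sample_ids), ncol = nb,
                dimnames = list(sample_ids, NULL))
  s <- exp$samples
  for (si in seq_along(sample_ids)) {
    id <- sample_ids[si]
    total <- s$total_mapped[s$sample_id == id]
    cov <- .read_coverage(exp$alignments[[id]])
    acc <- numeric(nb); cnt <- numeric(nb)
    for (tb in tx_bins) {
      if (!tb$chrom %in% names(cov)) v <- numeric(length(tb$pos))
      else {
        cv <- cov[[tb$chrom]]
        idx <- tb$pos + 1L
        ok <- idx <= length(cv)
        v <- numeric(length(idx))
        if (any(ok)) v[ok] <- as.numeric(cv[idx[ok]])
      }
      v <- normalize_count(v, total)
      sums <- rowsum(v, tb$bin)
      ub <- as.integer(rownames(sums))
      full <- numeric(nb)
      full[ub] <- sums[, 1] / tabulate(tb$bin, nbins = nb)[ub]
      if (mode == "per_transcript") {
        m <- mean(full)
        if (m > 0) full <- full / m
      }
      acc <- acc + full
      cnt <- cnt + 1
    }
    out[si, ] <- acc / cnt
  }
  attr(out, "feature") <- rep(c("UTR5", "CDS", "UTR3"), each = bins_per_feature)
  attr(out, "n_excluded") <- n_excluded
  out
}
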