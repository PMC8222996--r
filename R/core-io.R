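# Readers/writers for the standard formats, interval arithmetic and count
# normalization shared by all analysis stages.
#
# Internal coordinate convention: 0-based half-open ([start, end)),
# identical to BED. GTF (1-based closed) is converted at the boundary.

.FEATURE_TYPES <- c("exon", "utr5", "cds", "utr3")

#' Construct a transcript model set
#'
#' Bundles a per-transcript summary table and a per-feature interval table
#' into the container used by all annotation-aware operations.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `exonic_length`, `start_codon_pos`,
#'   `stop_codon_pos` (codon positions are the genomic 0-based positions of
#'   the 5'-most / 3'-most CDS base, `NA` for non-coding models).
#' @param features data.frame with columns `transcript_id`, `type` (one of
#'   `exon`, `utr5`, `cds`, `utr3`), `start`, `end` (0-based half-open).
#' @return An object of class `transcript_models`.
#' @export
transcript_models <- function(transcripts, features) {
  need_t <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end",
              "exonic_length", "start_codon_pos", "stop_codon_pos")
  need_f <- c("transcript_id", "type", "start", "end")
  stopifnot(all(need_t %in% names(transcripts)), all(need_f %in% names(features)))
  if (nrow(features) > 0 && !all(features$type %in% .FEATURE_TYPES))
    stop("unknown feature type(s): ",
         paste(setdiff(unique(features$type), .FEATURE_TYPES), collapse = ", "))
  transcripts <- transcripts[.corder(transcripts$transcript_id), need_t, drop = FALSE]
  features <- features[.corder(features$transcript_id,
                               match(features$type, .FEATURE_TYPES),
                               features$start), need_f, drop = FALSE]
  for (cc in c("start", "end")) {
    transcripts[[cc]] <- as.integer(transcripts[[cc]])
    features[[cc]] <- as.integer(features[[cc]])
  }
  transcripts$exonic_length <- as.integer(transcripts$exonic_length)
  transcripts$start_codon_pos <- as.integer(transcripts$start_codon_pos)
  transcripts$stop_codon_pos <- as.integer(transcripts$stop_codon_pos)
  rownames(transcripts) <- NULL
  rownames(features) <- NULL
  if (nrow(features) > 0 && any(features$start >= features$end))
    stop("feature with start >= end")
  structure(list(transcripts = transcripts, features = features),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x$transcripts), "transcripts,",
      nrow(x$features), "feature intervals\n")
  invisible(x)
}

#' Validate transcript model invariants
#'
#' Checks that 5'UTR, CDS and 3'UTR partition the exonic space without
#' overlap, that the exonic length equals the summed exon widths, and that
#' codon anchors fall inside an exon.
#'
#' @param models a `transcript_models` object.
#' @return `TRUE` (invisibly); stops with a message on the first violation.
#' @export
validate_transcript_models <- function(models) {
  tx <- models$transcripts
  fx <- models$features
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    f <- fx[fx$transcript_id == id, , drop = FALSE]
    exlen <- sum(f$end[f$type == "exon"] - f$start[f$type == "exon"])
    if (exlen != tx$exonic_length[i])
      stop(id, ": exonic_length ", tx$exonic_length[i],
           " != summed exon widths ", exlen)
    parts <- f[f$type != "exon", , drop = FALSE]
    if (nrow(parts) > 0) {
      o <- order(parts$start)
      ps <- parts$start[o]; pe <- parts$end[o]
      if (any(ps[-1] < pe[-length(pe)]))
        stop(id, ": utr5/cds/utr3 intervals overlap")
      if (sum(pe - ps) != exlen)
        stop(id, ": utr5/cds/utr3 do not partition the exonic space")
    }
    ex <- f[f$type == "exon", , drop = FALSE]
    for (anchor in c("start_codon_pos", "stop_codon_pos")) {
      p <- tx[[anchor]][i]
      if (!is.na(p) && !any(p >= ex$start & p < ex$end))
        stop(id, ": ", anchor, " outside exons")
    }
  }
  invisible(TRUE)
}

.gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, ' "([^"]*)"'), attr))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

#' Parse a GTF/GFF annotation into transcript models
#'
#' Reads exon/CDS (and, when present, explicit UTR and codon) features with
#' `rtracklayer` and assembles one model per transcript. When UTR features
#' are absent they are derived as the exonic space outside the CDS, split
#' 5'/3' by strand. 1-based closed coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param path path to a GTF (or GFF3 with `transcript_id`-style tags) file.
#' @return A `transcript_models` object.
#' @export
parse_gtf <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf < 9))
    stop("malformed annotation line ", body[which(nf < 9)[1]], " in ", path,
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (is.null(df$transcript_id)) {
    if (!is.null(df$Parent)) {
      df$transcript_id <- sub("^transcript:", "",
                              vapply(df$Parent, function(p)
                                if (length(p)) as.character(p[1]) else NA_character_,
                                character(1)))
    } else stop("annotation lacks transcript_id attributes")
  }
  if (is.null(df$gene_id)) df$gene_id <- df$transcript_id
  type_map <- c(exon = "exon", CDS = "cds",
                five_prime_utr = "utr5", five_prime_UTR = "utr5",
                three_prime_utr = "utr3", three_prime_UTR = "utr3")
  df$ftype <- unname(type_map[as.character(df$type)])
  df <- df[!is.na(df$ftype) & !is.na(df$transcript_id), , drop = FALSE]
  if (nrow(df) == 0)
    return(transcript_models(
      data.frame(transcript_id = character(), gene_id = character(),
                 chrom = character(), strand = character(),
                 start = integer(), end = integer(), exonic_length = integer(),
                 start_codon_pos = integer(), stop_codon_pos = integer()),
      data.frame(transcript_id = character(), type = character(),
                 start = integer(), end = integer())))

  tx_rows <- list(); feat_rows <- list()
  for (id in unique(df$transcript_id)) {
    d <- df[df$transcript_id == id, , drop = FALSE]
    chrom <- as.character(d$seqnames[1])
    strand <- as.character(d$strand[1])
    if (!strand %in% c("+", "-")) strand <- "."
    seg <- function(tt) {
      s <- d[d$ftype == tt, c("start", "end"), drop = FALSE]
      if (nrow(s) == 0) return(s)
      s$start <- s$start - 1L            # to 0-based half-open
      s[order(s$start), , drop = FALSE]
    }
    ex <- seg("exon"); cds <- seg("cds")
    if (nrow(ex) == 0 && nrow(cds) > 0) ex <- cds  # CDS-only record
    if (nrow(ex) == 0) next
    u5 <- seg("utr5"); u3 <- seg("utr3")
    if (nrow(cds) > 0 && nrow(u5) == 0 && nrow(u3) == 0) {
      utr <- .interval_setdiff(ex, cds)
      cds_lo <- min(cds$start); cds_hi <- max(cds$end)
      left <- utr[utr$end <= cds_lo, , drop = FALSE]
      right <- utr[utr$start >= cds_hi, , drop = FALSE]
      if (strand == "-") { u5 <- right; u3 <- left } else { u5 <- left; u3 <- right }
      if (nrow(utr) > 0 && nrow(u5) + nrow(u3) == 0)
        warning("transcript ", id, ": UTRs could not be resolved; left empty")
      if (nrow(utr) == 0)
        warning("transcript ", id, ": CDS covers all exons; UTRs left empty")
    }
    anchors <- c(NA_integer_, NA_integer_)
    if (nrow(cds) > 0) {
      if (strand == "-") {
        anchors <- c(max(cds$end) - 1L, min(cds$start))
      } else {
        anchors <- c(min(cds$start), max(cds$end) - 1L)
      }
    }
    tx_rows[[id]] <- data.frame(
      transcript_id = id, gene_id = d$gene_id[1], chrom = chrom,
      strand = strand, start = min(ex$start), end = max(ex$end),
      exonic_length = sum(ex$end - ex$start),
      start_codon_pos = anchors[1], stop_codon_pos = anchors[2],
      stringsAsFactors = FALSE)
    fr <- rbind(
      if (nrow(ex)) cbind(type = "exon", ex),
      if (nrow(u5)) cbind(type = "utr5", u5),
      if (nrow(cds)) cbind(type = "cds", cds),
      if (nrow(u3)) cbind(type = "utr3", u3))
    fr$transcript_id <- id
    feat_rows[[id]] <- fr
  }
  transcript_models(do.call(rbind, tx_rows), do.call(rbind, feat_rows))
}

## setdiff of two sorted 0-based interval data.frames (start/end columns)
.interval_setdiff <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  ia <- IRanges::IRanges(a$start + 1L, a$end)
  ib <- IRanges::IRanges(b$start + 1L, b$end)
  d <- IRanges::setdiff(ia, ib)
  data.frame(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}

#' Write transcript models as GTF
#'
#' Emits exon, CDS and explicit UTR features (1-based closed coordinates)
#' such that [parse_gtf()] recovers the models exactly.
#'
#' @param models a `transcript_models` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  fx <- models$features
  tx <- models$transcripts
  type_out <- c(exon = "exon", cds = "CDS",
                utr5 = "five_prime_utr", utr3 = "three_prime_utr")
  idx <- match(fx$transcript_id, tx$transcript_id)
  lines <- sprintf(
    "%s\tmeripherit\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    tx$chrom[idx], type_out[fx$type], fx$start + 1L, fx$end,
    tx$strand[idx], tx$gene_id[idx], fx$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Parse a BED6 peak file
#'
#' BED's 0-based half-open coordinates are preserved verbatim; the name
#' column becomes `peak_id`.
#'
#' @param path BED6 file.
#' @return data.frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `score`, `strand`.
#' @export
parse_bed6 <- function(path) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_id = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED file ", path,
                                          ": ", conditionMessage(e)))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    peak_id = if (!is.null(gr$name)) gr$name else paste0("peak_", seq_along(gr)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  if (any(df$start >= df$end))
    stop("BED record with start >= end at line ", which(df$start >= df$end)[1])
  df
}

#' Write peaks as BED6
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `peak_id` and
#'   optional `score`, `strand` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(peaks, path) {
  score <- if ("score" %in% names(peaks)) peaks$score else rep(0, nrow(peaks))
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep(".", nrow(peaks))
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", peaks$chrom,
                   as.integer(peaks$start), as.integer(peaks$end),
                   peaks$peak_id, score, strand)
  writeLines(lines, path)
  invisible(path)
}

.empty_alignments <- function(with_seq = FALSE) {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   strand = character(), read_id = character(),
                   allele = character(), stringsAsFactors = FALSE)
  if (with_seq) df$seq <- character()
  df
}

#' Load aligned reads
#'
#' Reads alignments from SAM/BAM (via `Rsamtools`/`GenomicAlignments`) or
#' from the plain tab-separated dialect (columns `chrom`, `start`, `end`,
#' `strand`, `read_id` and optional `allele`, `seq`; 0-based half-open).
#' Only primary, uniquely mapped records (NH tag absent or 1) are retained
#' from SAM/BAM; secondary, supplementary and unmapped records are dropped.
#'
#' @param path alignment file.
#' @param dialect `"auto"` (by extension), `"sam"`, `"bam"` or `"tsv"`.
#' @param with_seq also return the read sequence (SAM/BAM; TSV if present).
#' @return data.frame of reads with attributes `n_total` (records seen) and
#'   `n_retained`.
#' @export
load_alignments <- function(path, dialect = c("auto", "sam", "bam", "tsv"),
                            with_seq = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, sam = "sam", bam = "bam",
                      tsv = "tsv", txt = "tsv",
                      stop("cannot infer alignment dialect from extension '",
                           ext, "'"))
  }
  if (dialect == "tsv") {
    if (file.size(path) == 0) {
      out <- .empty_alignments(with_seq)
      attr(out, "n_total") <- 0L; attr(out, "n_retained") <- 0L
      return(out)
    }
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "read_id")
    if (!all(need %in% names(df)))
      stop("TSV alignment dialect requires columns: ",
           paste(need, collapse = ", "))
    df$chrom <- as.character(df$chrom)
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    if (is.null(df$allele)) df$allele <- NA_character_
    keep <- c(need[1:3], "strand", "read_id", "allele",
              if (with_seq && "seq" %in% names(df)) "seq")
    out <- df[, keep, drop = FALSE]
    attr(out, "n_total") <- nrow(df); attr(out, "n_retained") <- nrow(out)
    return(out)
  }
  bam <- path
  if (dialect == "sam") {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                     indexDestination = FALSE),
                    error = function(e) stop("failed to read SAM file ", path,
                                             ": ", conditionMessage(e)))
  }
  what <- c("qname", if (with_seq) "seq")
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = what, tag = c("NH", "XV"))
  ga <- tryCatch(GenomicAlignments::readGAlignments(bam, param = param),
                 error = function(e) stop("failed to read alignments from ",
                                          path, ": ", conditionMessage(e)))
  n_total <- length(Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = "qname"))[[1]]$qname)
  mc <- S4Vectors::mcols(ga)
  nh <- mc$NH
  keep <- if (is.null(nh)) rep(TRUE, length(ga)) else (is.na(nh) | nh == 1L)
  ga <- ga[keep]
  mc <- S4Vectors::mcols(ga)
  strand <- as.character(GenomicAlignments::strand(ga))
  strand[!strand %in% c("+", "-")] <- "."
  out <- data.frame(
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = strand,
    read_id = mc$qname,
    allele = if (!is.null(mc$XV)) as.character(mc$XV) else NA_character_,
    stringsAsFactors = FALSE)
  if (with_seq) out$seq <- as.character(mc$seq)
  attr(out, "n_total") <- n_total
  attr(out, "n_retained") <- nrow(out)
  out
}

#' Write reads in the TSV alignment dialect
#'
#' @param reads alignment data.frame (see [load_alignments()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(reads, path) {
  keep <- intersect(c("chrom", "start", "end", "strand", "read_id",
                      "allele", "seq"), names(reads))
  write.table(reads[, keep, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap length of two genomic intervals
#'
#' Half-open arithmetic: `max(0, min(end) - max(start))`, zero when the
#' chromosomes differ. Vectorized over both arguments.
#'
#' @param a,b lists or data.frames with elements `chrom` (optional),
#'   `start`, `end`.
#' @return numeric overlap length(s) in nt.
#' @export
interval_intersect <- function(a, b) {
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  if (!is.null(a$chrom) && !is.null(b$chrom)) ov <- ov * (a$chrom == b$chrom)
  ov
}

#' Depth-normalize a read count
#'
#' Reads-per-million uniquely mapped reads: `count * scale / total_mapped`.
#'
#' @param count raw read count(s).
#' @param total_mapped library size (uniquely mapped reads), > 0.
#' @param scale normalization constant (default 1e6, i.e. RPM).
#' @return normalized count(s).
#' @export
normalize_count <- function(count, total_mapped, scale = 1e6) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  count * scale / total_mapped
}

#' Assemble a MeRIP experiment container
#'
#' @param samples data.frame with columns `sample_id`, `genotype`, `assay`
#'   (`IP` or `input`), `replicate`, `total_mapped`.
#' @param alignments named list of alignment data.frames, one per
#'   `sample_id`.
#' @param annotation a `transcript_models` object.
#' @param peaks peak data.frame as from [parse_bed6()].
#' @param genomes optional named `DNAStringSet`-like list with parental
#'   genome sequences (`A`, `B`).
#' @param truth optional ground-truth list (synthetic data).
#' @return An object of class `merip_experiment`.
#' @export
merip_experiment <- function(samples, alignments, annotation = NULL,
                             peaks = NULL, genomes = NULL, truth = NULL) {
  need <- c("sample_id", "genotype", "assay", "replicate", "total_mapped")
  stopifnot(all(need %in% names(samples)))
  if (!all(samples$assay %in% c("IP", "input")))
    stop("assay must be 'IP' or 'input'")
  if (any(samples$total_mapped <= 0)) stop("total_mapped must be > 0")
  key <- paste(samples$genotype, samples$assay, samples$replicate)
  if (anyDuplicated(key)) stop("duplicate (genotype, assay, replicate)")
  if (!all(samples$sample_id %in% names(alignments)))
    stop("missing alignments for: ",
         paste(setdiff(samples$sample_id, names(alignments)), collapse = ", "))
  structure(list(samples = samples, alignments = alignments,
                 annotation = annotation, peaks = peaks,
                 genomes = genomes, truth = truth),
            class = "merip_experiment")
}

#' @export
print.merip_experiment <- function(x, ...) {
  cat("merip_experiment:", nrow(x$samples), "libraries (",
      paste(unique(x$samples$genotype), collapse = ", "), ")\n")
  if (!is.null(x$annotation))
    cat("  ", nrow(x$annotation$transcripts), "transcripts\n")
  if (!is.null(x$peaks)) cat("  ", nrow(x$peaks), "peaks\n")
  if (!is.null(x$truth)) cat("   ground truth attached\n")
  invisible(x)
}

## samples of one genotype/assay, ordered by replicate
.samples_of <- function(exp, genotype, assay) {
  s <- exp$samples
  s <- s[s$genotype == genotype & s$assay == assay, , drop = FALSE]
  s[order(s$replicate), , drop = FALSE]
}
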