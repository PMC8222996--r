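# Shared internal helpers: interval containers, overlap counting, coverage.

#' Round half away from zero
#'
#' Contingency tables require integer counts; fractional normalized reads
#' are rounded with halves going up (0.5 -> 1), unlike [base::round()]'s
#' banker's rounding.
#'
#' @param x numeric vector, non-negative.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

## Build a GRanges from an internal 0-based half-open interval data.frame.
## `stranded = FALSE` collapses strand to "*" so overlaps ignore it.
.as_granges <- function(df, stranded = FALSE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if (stranded && "strand" %in% names(df)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

## Count reads overlapping each interval (>= 1 nt overlap).
.count_overlaps <- function(intervals, reads, stranded = FALSE) {
  if (nrow(reads) == 0L) return(integer(nrow(intervals)))
  GenomicRanges::countOverlaps(
    .as_granges(intervals, stranded),
    .as_granges(reads, stranded),
    ignore.strand = !stranded
  )
}

## Per-chromosome coverage (RleList) of a read data.frame, optionally
## multiplied by a scale factor. Width accommodates `seqlen` hints.
.read_coverage <- function(reads, seqlengths = NULL) {
  gr <- .as_granges(reads)
  if (!is.null(seqlengths)) {
    GenomicRanges::coverage(gr, width = seqlengths)
  } else {
    GenomicRanges::coverage(gr)
  }
}

## Extract the per-base coverage vector of one 0-based half-open interval
## from an RleList, zero-padding beyond the covered range.
.coverage_window <- function(cov, chrom, start, end) {
  n <- end - start
  if (!chrom %in% names(cov)) return(numeric(n))
  v <- cov[[chrom]]
  lo <- start + 1L
  hi <- end
  avail <- length(v)
  out <- numeric(n)
  if (lo <= avail) {
    hi2 <- min(hi, avail)
    out[seq_len(hi2 - lo + 1L)] <- as.numeric(v[lo:hi2])
  }
  out
}

.msg <- function(...) {
  if (isTRUE(getOption("meripherit.verbose", TRUE))) message(...)
  invisible(NULL)
}

## Stable, locale-independent ordering helper for character keys.
.corder <- function(...) order(..., method = "radix")
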