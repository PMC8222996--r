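# Allele-specific expression and methylation: in-silico cross-mapping SNP
# discovery between two parental genomes, allelic read counting within
# peaks, and the Fisher allele-specific methylation test.

#' SNP discovery and filtering parameters
#'
#' @param fragment_length in-silico fragment length (nt, default 100).
#' @param shift fragment start step (nt, default 1).
#' @param min_coverage minimum pileup depth at a site (default 90).
#' @param min_mutant_ratio minimum mutants/covered-reads ratio (default
#'   0.90); also the per-parent support required by the homozygosity
#'   filter.
#' @param max_bias maximum relative difference of hybrid reads mapped to
#'   the corresponding site on the two references (default 0.10, strict).
#' @param max_mismatches mismatch budget per 100 nt for the built-in
#'   ungapped mapper (default 5).
#' @param bias_denominator normalize the read difference by the larger
#'   count (`"max"`, default) or by the mean.
#' @return list of class `snp_calling_params`.
#' @export
snp_calling_params <- function(fragment_length = 100L, shift = 1L,
                               min_coverage = 90L, min_mutant_ratio = 0.90,
                               max_bias = 0.10, max_mismatches = 5L,
                               bias_denominator = c("max", "mean")) {
  stopifnot(fragment_length > 0, shift >= 1,
            min_mutant_ratio > 0, min_mutant_ratio <= 1, max_bias >= 0)
  structure(list(fragment_length = as.integer(fragment_length),
                 shift = as.integer(shift),
                 min_coverage = as.integer(min_coverage),
                 min_mutant_ratio = min_mutant_ratio,
                 max_bias = max_bias,
                 max_mismatches = as.integer(max_mismatches),
                 bias_denominator = match.arg(bias_denominator)),
            class = "snp_calling_params")
}

.as_seq_string <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- x[[1]]
  toupper(as.character(x))
}

#' Fragment a genome into overlapping windows
#'
#' Cuts the sequence into `fragment_length`-nt fragments advanced by
#' `shift` nt; fragment i covers `[i, i + fragment_length)`.
#'
#' @param sequence a `DNAString`(Set) or character scalar.
#' @param params [snp_calling_params()].
#' @return list with `start` (0-based fragment starts) and `fragments`
#'   (character vector).
#' @export
fragment_genome <- function(sequence, params = snp_calling_params()) {
  s <- .as_seq_string(sequence)
  fl <- params$fragment_length
  L <- nchar(s)
  if (L < fl) stop("sequence shorter than fragment_length")
  starts <- seq.int(0L, L - fl, by = params$shift)
  list(start = starts, fragments = substring(s, starts + 1L, starts + fl))
}

#' Cross-map fragments of one genome onto the other and pile up mismatches
#'
#' Fragments of the query genome are placed on the target with a built-in
#' ungapped unique-best-hit mapper: exact 16-mer seeds at six offsets
#' locate candidate placements (pigeonhole guarantees a seed hit for any
#' fragment within the mismatch budget), mismatches are counted per
#' candidate, fragments with several equally best placements are
#' discarded, and placements exceeding `max_mismatches` (per 100 nt) are
#' dropped. For every target site covered by a mismatch the pileup
#' reports depth, mismatching-read count and the majority alternate base.
#'
#' @param query,target genome sequences (`DNAString`(Set) or character).
#' @param params [snp_calling_params()].
#' @return data.frame with `pos` (0-based on target), `ref_base`,
#'   `alt_base`, `depth`, `mismatch`, `mutant_ratio`; attributes
#'   `n_fragments`, `n_placed`, `n_multi`, `n_unplaced` and `depth_cov`
#'   (coverage Rle over the target).
#' @export
cross_map_pileup <- function(query, target, params = snp_calling_params()) {
  q <- .as_seq_string(query); t <- .as_seq_string(target)
  fl <- params$fragment_length
  k <- 16L
  max_mm <- as.integer(ceiling(params$max_mismatches * fl / 100))
  Lq <- nchar(q); Lt <- nchar(t)
  if (Lq < fl || Lt < fl) stop("genome shorter than fragment_length")

  t_kmers <- substring(t, seq_len(Lt - k + 1L), seq_len(Lt - k + 1L) + k - 1L)
  dup <- duplicated(t_kmers) | duplicated(t_kmers, fromLast = TRUE)
  starts <- seq.int(0L, Lq - fl, by = params$shift)
  offs <- seq.int(0L, fl - k, by = k)
  cand <- matrix(NA_integer_, length(starts), length(offs))
  for (j in seq_along(offs)) {
    o <- offs[j]
    seeds <- substring(q, starts + o + 1L, starts + o + k)
    m <- match(seeds, t_kmers)
    m[!is.na(m) & dup[m]] <- NA_integer_
    cand[, j] <- m - 1L - o
  }
  cand[cand < 0 | cand > (Lt - fl)] <- NA_integer_

  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  tv <- strsplit(t, "", fixed = TRUE)[[1]]
  colinear_ok <- (Lq == Lt)
  if (colinear_ok) cs <- c(0L, cumsum(qv != tv))
  nm_direct <- function(i, cc) sum(qv[(i + 1L):(i + fl)] != tv[(cc + 1L):(cc + fl)])
  nm_at <- function(i, cc) {
    if (colinear_ok && cc == i) cs[i + fl + 1L] - cs[i + 1L] else nm_direct(i, cc)
  }

  cmin <- do.call(pmin, c(lapply(seq_along(offs), function(j) cand[, j]),
                          list(na.rm = TRUE)))
  cmax <- do.call(pmax, c(lapply(seq_along(offs), function(j) cand[, j]),
                          list(na.rm = TRUE)))
  placement <- rep(NA_integer_, length(starts))
  n_multi <- 0L
  single <- !is.na(cmin) & cmin == cmax
  ## fast path: unambiguous colinear placements
  if (colinear_ok) {
    co <- single & cmin == starts
    nm_co <- cs[starts[co] + fl + 1L] - cs[starts[co] + 1L]
    ok <- nm_co <= max_mm
    placement[which(co)[ok]] <- starts[co][ok]
    rest <- which(single & !co)
  } else rest <- which(single)
  for (i in rest) {
    if (nm_at(starts[i], cmin[i]) <= max_mm) placement[i] <- cmin[i]
  }
  for (i in which(!is.na(cmin) & cmin != cmax)) {
    cc <- unique(cand[i, !is.na(cand[i, ])])
    nm <- vapply(cc, function(x) nm_at(starts[i], x), numeric(1))
    best <- min(nm)
    if (best > max_mm) next
    if (sum(nm == best) > 1L) { n_multi <- n_multi + 1L; next }
    placement[i] <- cc[which.min(nm)]
  }

  placed <- !is.na(placement)
  p_start <- placement[placed]; f_start <- starts[placed]
  depth_cov <- IRanges::coverage(IRanges::IRanges(p_start + 1L, p_start + fl),
                                 width = Lt)

  ## mismatch tallies: colinear placements in bulk, the rest individually
  mm_pos <- integer(0); mm_alt <- character(0); mm_n <- integer(0)
  colin <- colinear_ok & (p_start == f_start)
  if (any(colin)) {
    cov_colin <- IRanges::coverage(
      IRanges::IRanges(p_start[colin] + 1L, p_start[colin] + fl), width = Lt)
    dsites <- which(qv != tv) - 1L
    nn <- as.integer(cov_colin[dsites + 1L])
    keep <- nn > 0L
    mm_pos <- dsites[keep]; mm_alt <- qv[dsites[keep] + 1L]; mm_n <- nn[keep]
  }
  extra <- which(!colin)
  if (length(extra)) {
    acc <- list()
    for (i in extra) {
      fs <- f_start[i]; ps <- p_start[i]
      d <- which(qv[(fs + 1L):(fs + fl)] != tv[(ps + 1L):(ps + fl)])
      if (length(d))
        acc[[length(acc) + 1L]] <- data.frame(pos = ps + d - 1L,
                                              alt = qv[fs + d],
                                              stringsAsFactors = FALSE)
    }
    if (length(acc)) {
      ex <- do.call(rbind, acc)
      agg <- stats::aggregate(list(n = rep(1L, nrow(ex))),
                              by = list(pos = ex$pos, alt = ex$alt), FUN = sum)
      ## merge with colinear counts, majority alternate base per site
      comb <- rbind(data.frame(pos = mm_pos, alt = mm_alt, n = mm_n,
                               stringsAsFactors = FALSE),
                    agg[, c("pos", "alt", "n")])
      tot <- stats::aggregate(list(n = comb$n), by = list(pos = comb$pos), FUN = sum)
      o <- order(comb$pos, -comb$n)
      comb <- comb[o, ]
      first <- !duplicated(comb$pos)
      mm_pos <- comb$pos[first][order(comb$pos[first])]
      idx <- match(mm_pos, comb$pos)
      mm_alt <- comb$alt[idx]
      mm_n <- tot$n[match(mm_pos, tot$pos)]
    }
  }

  out <- data.frame(pos = mm_pos,
                    ref_base = tv[mm_pos + 1L],
                    alt_base = mm_alt,
                    depth = as.integer(depth_cov[mm_pos + 1L]),
                    mismatch = as.integer(mm_n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out$mutant_ratio <- ifelse(out$depth > 0, out$mismatch / out$depth, 0)
  attr(out, "n_fragments") <- length(starts)
  attr(out, "n_placed") <- sum(placed)
  attr(out, "n_multi") <- n_multi
  attr(out, "n_unplaced") <- length(starts) - sum(placed) - n_multi
  attr(out, "depth_cov") <- depth_cov
  out
}

#' Call candidate SNPs from reciprocal pileups
#'
#' A site is a candidate when, in both mapping directions, its pileup
#' depth reaches `min_coverage` and its mutant ratio reaches
#' `min_mutant_ratio` (both inclusive), and the reciprocal calls agree on
#' the two alleles. Coordinates are linked positionally (the in-silico
#' scheme compares colinear, substitution-diverged references).
#'
#' @param pileup_on_b pileup of genome-A fragments on genome B
#'   ([cross_map_pileup()]); allele A is its `alt_base`.
#' @param pileup_on_a pileup of genome-B fragments on genome A.
#' @param params [snp_calling_params()].
#' @param chrom sequence name attached to the records (default `"seq1"`).
#' @return data.frame of candidate SNPs: `chrom`, `pos_a`, `pos_b`,
#'   `allele_a`, `allele_b`, `cov_a`, `cov_b`, `mutant_ratio_a`,
#'   `mutant_ratio_b`.
#' @export
call_candidate_snps <- function(pileup_on_b, pileup_on_a,
                                params = snp_calling_params(),
                                chrom = "seq1") {
  pass <- function(p) p[p$depth >= params$min_coverage &
                          p$mutant_ratio >= params$min_mutant_ratio, ,
                        drop = FALSE]
  pb <- pass(pileup_on_b)   # sites on B: ref = allele_b, alt = allele_a
  pa <- pass(pileup_on_a)   # sites on A: ref = allele_a, alt = allele_b
  m <- match(pb$pos, pa$pos)
  ok <- !is.na(m) &
    pb$ref_base == pa$alt_base[m] &
    pb$alt_base == pa$ref_base[m]
  pb <- pb[ok, , drop = FALSE]; pa <- pa[m[ok], , drop = FALSE]
  data.frame(chrom = if (nrow(pb)) chrom else character(0),
             pos_a = pa$pos, pos_b = pb$pos,
             allele_a = pa$ref_base, allele_b = pb$ref_base,
             cov_a = pa$depth, cov_b = pb$depth,
             mutant_ratio_a = pa$mutant_ratio,
             mutant_ratio_b = pb$mutant_ratio,
             stringsAsFactors = FALSE)
}

#' Discover candidate SNPs between two parental genomes
#'
#' Runs the in-silico fragmentation and cross-mapping in both directions
#' and calls reciprocally supported candidate sites.
#'
#' @param genome_a,genome_b parental genome sequences.
#' @param params [snp_calling_params()].
#' @return candidate SNP data.frame (see [call_candidate_snps()]).
#' @export
discover_snps <- function(genome_a, genome_b, params = snp_calling_params()) {
  chrom <- if (inherits(genome_a, "DNAStringSet") &&
               length(names(genome_a))) names(genome_a)[1] else "seq1"
  on_b <- cross_map_pileup(genome_a, genome_b, params)
  on_a <- cross_map_pileup(genome_b, genome_a, params)
  call_candidate_snps(on_b, on_a, params, chrom = chrom)
}

## reads covering a 0-based site per chromosome
.site_depth <- function(reads, chrom, pos) {
  sites <- data.frame(chrom = chrom, start = pos, end = pos + 1L)
  .count_overlaps(sites, reads)
}

#' Exclude SNPs with reference-biased hybrid mapping
#'
#' Compares, per candidate site, the number of hybrid reads covering the
#' corresponding coordinate when mapped to each reference; sites whose
#' relative difference exceeds `max_bias` (strictly) are excluded.
#'
#' @param snps candidate SNP data.frame.
#' @param hybrid_reads_on_a,hybrid_reads_on_b hybrid alignments mapped to
#'   reference A / B.
#' @param params [snp_calling_params()].
#' @return retained SNPs with added `n_a`, `n_b`, `bias` columns; the
#'   excluded records are kept in the `excluded` attribute.
#' @export
bias_filter <- function(snps, hybrid_reads_on_a, hybrid_reads_on_b,
                        params = snp_calling_params()) {
  n_a <- .site_depth(hybrid_reads_on_a, snps$chrom, snps$pos_a)
  n_b <- .site_depth(hybrid_reads_on_b, snps$chrom, snps$pos_b)
  denom <- switch(params$bias_denominator,
                  max = pmax(n_a, n_b),
                  mean = (n_a + n_b) / 2)
  bias <- ifelse(denom > 0, abs(n_a - n_b) / denom, 0)
  snps$n_a <- n_a; snps$n_b <- n_b; snps$bias <- bias
  keep <- bias <= params$max_bias
  out <- snps[keep, , drop = FALSE]
  attr(out, "excluded") <- snps[!keep, , drop = FALSE]
  out
}

## allele votes of reads at SNP sites: data.frame(read, site, vote)
## vote from the read sequence when present, else from the allele tag.
.votes_at_sites <- function(reads, snps, pos_col = "pos_a") {
  sites <- data.frame(chrom = snps$chrom, start = snps[[pos_col]],
                      end = snps[[pos_col]] + 1L)
  if (nrow(reads) == 0 || nrow(snps) == 0)
    return(data.frame(read = integer(), site = integer(), vote = character()))
  hits <- GenomicRanges::findOverlaps(.as_granges(sites), .as_granges(reads),
                                      ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
  if ("seq" %in% names(reads)) {
    off <- snps[[pos_col]][si] - reads$start[ri] + 1L
    base <- substring(reads$seq[ri], off, off)
    vote <- ifelse(base == snps$allele_a[si], "A",
                   ifelse(base == snps$allele_b[si], "B", NA_character_))
  } else {
    vote <- reads$allele[ri]
    vote[!vote %in% c("A", "B")] <- NA_character_
  }
  data.frame(read = ri, site = si, vote = vote, stringsAsFactors = FALSE)
}

#' Keep only SNPs homozygous in both parent lines
#'
#' Each parent's own reads must support its own allele at the site in at
#' least `min_mutant_ratio` of the covering, informative reads; sites
#' without informative coverage in either parent are dropped.
#'
#' @param snps candidate SNP data.frame.
#' @param parent_a_reads,parent_b_reads parental alignments (with `seq` or
#'   `allele` information).
#' @param params [snp_calling_params()].
#' @return retained SNPs with `support_a`, `support_b` columns; excluded
#'   records in the `excluded` attribute.
#' @export
homozygosity_filter <- function(snps, parent_a_reads, parent_b_reads,
                                params = snp_calling_params()) {
  support <- function(reads, want) {
    v <- .votes_at_sites(reads, snps)
    v <- v[!is.na(v$vote), , drop = FALSE]
    n <- tabulate(v$site, nbins = nrow(snps))
    good <- tabulate(v$site[v$vote == want], nbins = nrow(snps))
    ifelse(n > 0, good / n, NA_real_)
  }
  sa <- support(parent_a_reads, "A")
  sb <- support(parent_b_reads, "B")
  snps$support_a <- sa; snps$support_b <- sb
  keep <- !is.na(sa) & !is.na(sb) &
    sa >= params$min_mutant_ratio & sb >= params$min_mutant_ratio
  out <- snps[keep, , drop = FALSE]
  attr(out, "excluded") <- snps[!keep, , drop = FALSE]
  out
}

#' Count allele-specific reads over peaks
#'
#' Reads covering at least one confident SNP inside a peak vote for the
#' allele they carry; reads with conflicting votes across SNPs are
#' discarded (counted in the `discarded` attribute) and tallies are kept
#' per peak and assay.
#'
#' @param ip_reads,input_reads hybrid alignments (replicates concatenated).
#' @param snps confident SNP data.frame (coordinates on reference A).
#' @param peaks peak data.frame with `chrom`, `start`, `end`, `peak_id`.
#' @return data.frame with `peak_id`, `n_snps`, `ip_A`, `ip_B`,
#'   `input_A`, `input_B` for peaks containing at least one SNP; attribute
#'   `discarded` = conflicting-read counts per assay.
#' @export
count_allelic_reads <- function(ip_reads, input_reads, snps, peaks) {
  sites <- data.frame(chrom = snps$chrom, start = snps$pos_a,
                      end = snps$pos_a + 1L)
  hit <- GenomicRanges::findOverlaps(.as_granges(sites), .as_granges(peaks),
                                     ignore.strand = TRUE)
  snp_peak <- rep(NA_integer_, nrow(snps))
  snp_peak[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  in_peak <- which(!is.na(snp_peak))
  snps_in <- snps[in_peak, , drop = FALSE]
  peak_of <- snp_peak[in_peak]

  tally <- function(reads) {
    v <- .votes_at_sites(reads, snps_in)
    v <- v[!is.na(v$vote), , drop = FALSE]
    if (nrow(v) == 0)
      return(list(A = integer(nrow(peaks)), B = integer(nrow(peaks)),
                  discarded = 0L))
    key <- paste(v$read, peak_of[v$site], sep = "_")
    hasA <- tapply(v$vote == "A", key, any)
    hasB <- tapply(v$vote == "B", key, any)
    pk <- as.integer(sub(".*_", "", names(hasA)))
    conflict <- hasA & hasB
    list(A = tabulate(pk[hasA & !conflict], nbins = nrow(peaks)),
         B = tabulate(pk[hasB & !conflict], nbins = nrow(peaks)),
         discarded = sum(conflict))
  }
  ip <- tally(ip_reads)
  inp <- tally(input_reads)
  n_snps <- tabulate(peak_of, nbins = nrow(peaks))
  keep <- which(n_snps > 0)
  out <- data.frame(peak_id = peaks$peak_id[keep],
                    n_snps = n_snps[keep],
                    ip_A = ip$A[keep], ip_B = ip$B[keep],
                    input_A = inp$A[keep], input_B = inp$B[keep],
                    stringsAsFactors = FALSE)
  attr(out, "discarded") <- c(IP = ip$discarded, input = inp$discarded)
  out
}

#' Test allele-specific methylation per peak
#'
#' Fills, per peak, the 2x2 table of (optionally depth-equalized) allelic
#' IP and input reads, applies Fisher's exact test, Holm-adjusts across
#' all tested peaks and flags peaks with `p_adjusted < alpha` as
#' allele-specific.
#'
#' @param counts [count_allelic_reads()] output.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param ip_total,input_total optional assay library sizes used to
#'   equalize IP and input depths before rounding.
#' @return data.frame of class `asm_results` with `p_value`, `p_adjusted`,
#'   `allele_specific`, `direction` and the allelic enrichment ratio.
#' @export
asm_test <- function(counts, alpha = 0.05, ip_total = NULL,
                     input_total = NULL) {
  ipA <- counts$ip_A; ipB <- counts$ip_B
  inA <- counts$input_A; inB <- counts$input_B
  if (!is.null(ip_total) && !is.null(input_total)) {
    tmin <- min(as.numeric(ip_total), as.numeric(input_total))
    ipA <- as.numeric(ipA); ipB <- as.numeric(ipB)
    inA <- as.numeric(inA); inB <- as.numeric(inB)
    ipA <- round_half_up(ipA * tmin / ip_total)
    ipB <- round_half_up(ipB * tmin / ip_total)
    inA <- round_half_up(inA * tmin / input_total)
    inB <- round_half_up(inB * tmin / input_total)
  }
  p <- .fisher_vec(ipA, inA, ipB, inB)
  padj <- holm_adjust(p)
  enr_ratio <- ((ipA + 0.5) / (inA + 0.5)) / ((ipB + 0.5) / (inB + 0.5))
  out <- data.frame(peak_id = counts$peak_id,
                    ip_A = ipA, input_A = inA, ip_B = ipB, input_B = inB,
                    allelic_enrichment_ratio = enr_ratio,
                    p_value = p, p_adjusted = padj,
                    allele_specific = padj < alpha,
                    direction = ifelse(enr_ratio >= 1, "A", "B"),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("asm_results", "data.frame")
  out
}

#' Allelic log2 ratio distributions
#'
#' Per unit, the log2 allelic expression ratio
#' `log2((input_A + pc) / (input_B + pc))` and the log2 allelic
#' methylation-enrichment ratio (ratio of the two alleles' IP/input
#' ratios), with the fraction of units falling inside (-1, 1).
#'
#' @param counts [count_allelic_reads()] output.
#' @param pseudocount added to every count (default 1).
#' @return list with `ratios` (per-unit data.frame) and `summary`
#'   (per-metric mean and fraction within (-1, 1)).
#' @export
allelic_ratio_distribution <- function(counts, pseudocount = 1) {
  pc <- pseudocount
  expr <- log2((counts$input_A + pc) / (counts$input_B + pc))
  meth <- log2(((counts$ip_A + pc) / (counts$input_A + pc)) /
                 ((counts$ip_B + pc) / (counts$input_B + pc)))
  ratios <- data.frame(peak_id = counts$peak_id,
                       log2_expression = expr,
                       log2_methylation = meth,
                       stringsAsFactors = FALSE)
  summary <- data.frame(
    metric = c("expression", "methylation"),
    mean = c(mean(expr), mean(meth)),
    frac_within_unit = c(mean(expr > -1 & expr < 1),
                         mean(meth > -1 & meth < 1)),
    stringsAsFactors = FALSE)
  list(ratios = ratios, summary = summary)
}
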