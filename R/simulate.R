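# Synthetic MeRIP-seq experiment generator: colinear parental genomes with
# planted substitutions, a single-exon transcriptome, and IP/input read
# libraries for the two parents and the reciprocal hybrids with planted
# enrichments, differential peaks, non-additive peaks and allele-specific
# methylation. All ground truth is recorded for downstream recovery tests.

#' Simulation configuration
#'
#' Parameters of the synthetic experiment. Defaults target the qualitative
#' regime of a two-accession MeRIP-seq inheritance study at desk scale:
#' most peaks shared and additive, a ~16% minority of differential peaks
#' skewed toward one genotype, rare allele-specific peaks, and a globally
#' lower IP yield for the second parent (exercising depth normalization).
#'
#' @param seed integer RNG seed; all randomness derives from it.
#' @param n_transcripts number of single-exon transcripts (default 300).
#' @param utr5_mean,utr5_sd,utr5_min 5'UTR length distribution (nt).
#' @param cds_mean,cds_sd,cds_min CDS length distribution (rounded to
#'   codon multiples).
#' @param utr3_mean,utr3_sd,utr3_min 3'UTR length distribution.
#' @param intergenic gap between transcripts (nt).
#' @param snp_rate substitution rate per nt between the haplotypes.
#' @param n_het_sites,n_biased_sites isolated SNP sites additionally
#'   planted as heterozygous-like in parent A / mapping-biased in the
#'   hybrid (for filter tests; default 0).
#' @param bias_drop fraction of hybrid reads over a biased site missing
#'   from the second reference's mapping (default 0.3).
#' @param read_length single-end read length (nt).
#' @param replicates libraries per genotype and assay (default 2).
#' @param expr_meanlog,expr_sdlog log-normal gene expression rates
#'   (default median 900 reads/library/gene).
#' @param dispersion gamma rate-variation parameter: gene rates are
#'   multiplied by a shared `gamma(1/dispersion, scale = dispersion)`
#'   draw, giving a negative-binomial count marginal while keeping the
#'   realized rates identical across genotypes and libraries.
#' @param peak_width planted peak width (nt).
#' @param n_peaks number of peaks, at most one per transcript (default =
#'   `n_transcripts`).
#' @param feature_mix named fractions of peaks planted in utr3/cds/utr5.
#' @param enrichment_median,enrichment_sdlog log-normal baseline IP/input
#'   enrichment (default median 3).
#' @param summit_dispersion half-width (nt) of the triangular IP read-center
#'   bump around the planted summit.
#' @param dmp_fraction,dmp_fold,dmp_bias fraction of peaks planted as
#'   differential between the parents, their enrichment fold (applied as
#'   +/- sqrt(fold) around baseline), and the probability the higher side
#'   is parent A.
#' @param nonadditive_fraction,nonadditive_fold fraction of peaks whose
#'   hybrid enrichment deviates from the mid-parent value, and the factor.
#' @param asm_fraction,asm_fold fraction of peaks with allele-specific
#'   methylation and the planted IP allelic odds (A:B or B:A).
#' @param ler_ip_scale multiplier on parent B's IP library size.
#' @param genotypes genotypes to simulate libraries for; the first two
#'   names are the parents (alleles A and B), the rest hybrids.
#' @param chrom chromosome name.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 300L,
                       utr5_mean = 150, utr5_sd = 30, utr5_min = 60,
                       cds_mean = 660, cds_sd = 90, cds_min = 300,
                       utr3_mean = 350, utr3_sd = 60, utr3_min = 150,
                       intergenic = 200L,
                       snp_rate = 0.004,
                       n_het_sites = 0L, n_biased_sites = 0L,
                       bias_drop = 0.3,
                       read_length = 100L,
                       replicates = 2L,
                       expr_meanlog = log(900), expr_sdlog = 0.25,
                       dispersion = 0.1,
                       peak_width = 180L,
                       n_peaks = n_transcripts,
                       feature_mix = c(utr3 = 0.70, cds = 0.25, utr5 = 0.05),
                       enrichment_median = 3, enrichment_sdlog = 0.3,
                       summit_dispersion = 60L,
                       dmp_fraction = 0.16, dmp_fold = 2, dmp_bias = 0.97,
                       nonadditive_fraction = 0.05, nonadditive_fold = 2.5,
                       asm_fraction = 0.02, asm_fold = 3,
                       ler_ip_scale = 0.8,
                       genotypes = c("Col0", "Ler", "F1CL", "F1LC"),
                       chrom = "chr1") {
  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              utr5_mean = utr5_mean, utr5_sd = utr5_sd, utr5_min = utr5_min,
              cds_mean = cds_mean, cds_sd = cds_sd, cds_min = cds_min,
              utr3_mean = utr3_mean, utr3_sd = utr3_sd, utr3_min = utr3_min,
              intergenic = as.integer(intergenic), snp_rate = snp_rate,
              n_het_sites = as.integer(n_het_sites),
              n_biased_sites = as.integer(n_biased_sites),
              bias_drop = bias_drop,
              read_length = as.integer(read_length),
              replicates = as.integer(replicates),
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              dispersion = dispersion, peak_width = as.integer(peak_width),
              n_peaks = as.integer(n_peaks), feature_mix = feature_mix,
              enrichment_median = enrichment_median,
              enrichment_sdlog = enrichment_sdlog,
              summit_dispersion = as.integer(summit_dispersion),
              dmp_fraction = dmp_fraction, dmp_fold = dmp_fold,
              dmp_bias = dmp_bias,
              nonadditive_fraction = nonadditive_fraction,
              nonadditive_fold = nonadditive_fold,
              asm_fraction = asm_fraction, asm_fold = asm_fold,
              ler_ip_scale = ler_ip_scale, genotypes = genotypes,
              chrom = chrom)
  stopifnot(cfg$n_transcripts >= 0, cfg$n_peaks <= cfg$n_transcripts,
            cfg$snp_rate >= 0, cfg$snp_rate < 1,
            cfg$dmp_fraction >= 0, cfg$dmp_fraction <= 1,
            cfg$nonadditive_fraction >= 0, cfg$nonadditive_fraction <= 1,
            cfg$asm_fraction >= 0, cfg$asm_fraction <= 1,
            abs(sum(cfg$feature_mix) - 1) < 1e-8,
            all(names(cfg$feature_mix) %in% c("utr3", "cds", "utr5")),
            cfg$dmp_fold >= 1, cfg$nonadditive_fold >= 1, cfg$asm_fold >= 1,
            cfg$replicates >= 1, cfg$read_length > 0,
            length(cfg$genotypes) >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields in the file override [sim_config()] defaults; the
#' `feature_mix` mapping is converted to a named vector.
#'
#' @param path YAML file.
#' @return `sim_config` list.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$feature_mix)) raw$feature_mix <- unlist(raw$feature_mix)
  if (!is.null(raw$genotypes)) raw$genotypes <- unlist(raw$genotypes)
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

## truncated-normal integer lengths
.sim_len <- function(n, mean, sd, min, codon = FALSE) {
  v <- pmax(round(rnorm(n, mean, sd)), min)
  if (codon) v <- round(v / 3) * 3
  as.integer(v)
}

#' Simulate a single-exon transcriptome annotation
#'
#' Draws non-overlapping plus/minus-strand transcripts, each a single exon
#' split into 5'UTR, CDS and 3'UTR, laid head to tail along one chromosome
#' with fixed intergenic gaps.
#'
#' @param config [sim_config()].
#' @param seed seed to apply (default `config$seed`); `NULL` continues the
#'   current RNG stream.
#' @return list with `models` (a `transcript_models` object) and
#'   `genome_length`.
#' @export
simulate_annotation <- function(config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_transcripts
  u5 <- .sim_len(n, config$utr5_mean, config$utr5_sd, config$utr5_min)
  cds <- .sim_len(n, config$cds_mean, config$cds_sd, config$cds_min, codon = TRUE)
  u3 <- .sim_len(n, config$utr3_mean, config$utr3_sd, config$utr3_min)
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  len <- u5 + cds + u3
  pad <- 100L + config$intergenic   # keeps all transcript bases >= 100 nt
  start <- pad + c(0L, cumsum(len + config$intergenic))[seq_len(n)]
  end <- start + len
  genome_length <- (if (n) max(end) else pad) + pad

  if (n == 0) {
    empty_tx <- data.frame(transcript_id = character(), gene_id = character(),
                           chrom = character(), strand = character(),
                           start = integer(), end = integer(),
                           exonic_length = integer(),
                           start_codon_pos = integer(),
                           stop_codon_pos = integer(),
                           stringsAsFactors = FALSE)
    empty_fx <- data.frame(transcript_id = character(), type = character(),
                           start = integer(), end = integer())
    return(list(models = transcript_models(empty_tx, empty_fx),
                genome_length = 2L * (100L + config$intergenic)))
  }
  gene_id <- sprintf("g%04d", seq_len(n))
  tx_id <- paste0(gene_id, ".1")
  ## genomic sub-intervals: on "-" the 5'UTR sits at the right end
  left1 <- ifelse(strand == "+", u5, u3)
  u5_s <- ifelse(strand == "+", start, end - u5)
  u3_s <- ifelse(strand == "+", end - u3, start)
  cds_s <- start + left1
  anchors_start <- ifelse(strand == "+", cds_s, cds_s + cds - 1L)
  anchors_stop <- ifelse(strand == "+", cds_s + cds - 1L, cds_s)

  transcripts <- data.frame(
    transcript_id = tx_id, gene_id = gene_id, chrom = config$chrom,
    strand = strand, start = start, end = end, exonic_length = len,
    start_codon_pos = as.integer(anchors_start),
    stop_codon_pos = as.integer(anchors_stop), stringsAsFactors = FALSE)
  features <- rbind(
    data.frame(transcript_id = tx_id, type = "exon", start = start, end = end),
    data.frame(transcript_id = tx_id, type = "utr5", start = u5_s, end = u5_s + u5),
    data.frame(transcript_id = tx_id, type = "cds", start = cds_s, end = cds_s + cds),
    data.frame(transcript_id = tx_id, type = "utr3", start = u3_s, end = u3_s + u3))
  if (n == 0)
    features <- data.frame(transcript_id = character(), type = character(),
                           start = integer(), end = integer())
  list(models = transcript_models(transcripts, features),
       genome_length = as.integer(genome_length))
}

## plant peaks: feature assignment per mixture, summit inside the planted
## feature with margins that keep the triangular bump clear of transcript
## ends (summit_dispersion + read_length/2) and the summit neighborhood
## inside the feature.
.sim_peaks <- function(config, annotation) {
  tx <- annotation$models$transcripts
  fx <- annotation$models$features
  n_pk <- config$n_peaks
  if (n_pk == 0)
    return(data.frame(peak_id = character(), transcript_id = character(),
                      gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      summit = integer(), feature = character(),
                      stringsAsFactors = FALSE))
  edge <- config$summit_dispersion + config$read_length %/% 2L
  inner <- 15L
  window_of <- function(i, type) {
    f <- fx[fx$transcript_id == tx$transcript_id[i] & fx$type == type, ]
    lo <- max(f$start + inner, tx$start[i] + edge)
    hi <- min(f$end - inner, tx$end[i] - edge) - 1L
    c(lo, hi)
  }
  wins <- list()
  for (type in c("utr3", "cds", "utr5")) {
    w <- vapply(seq_len(nrow(tx)), window_of, numeric(2), type = type)
    wins[[type]] <- w
  }
  mix <- config$feature_mix[c("utr3", "cds", "utr5")]
  mix[is.na(mix)] <- 0
  want <- round_half_up(mix * n_pk)
  want[1] <- n_pk - sum(want[-1])   # make counts total n_pk
  names(want) <- names(mix)

  host <- sample.int(nrow(tx), n_pk)   # transcripts carrying a peak
  assigned <- rep(NA_character_, n_pk)
  remaining <- seq_len(n_pk)
  for (type in c("utr5", "cds", "utr3")) {   # scarce features first
    k <- want[[type]]
    if (k == 0) next
    ok <- remaining[wins[[type]][1, host[remaining]] <=
                      wins[[type]][2, host[remaining]]]
    if (length(ok) < k) {
      warning("only ", length(ok), " transcripts eligible for ", type,
              " peaks (wanted ", k, "); reassigning the rest to utr3")
      k <- length(ok)
    }
    pick <- if (length(ok) == 1 && k == 1) ok else sample(ok, k)
    assigned[pick] <- type
    remaining <- setdiff(remaining, pick)
  }
  assigned[remaining] <- "utr3"

  lo <- vapply(seq_len(n_pk), function(j) wins[[assigned[j]]][1, host[j]],
               numeric(1))
  hi <- vapply(seq_len(n_pk), function(j) wins[[assigned[j]]][2, host[j]],
               numeric(1))
  summit <- as.integer(lo + floor(runif(n_pk) * (hi - lo + 1)))
  half <- config$peak_width %/% 2L
  ps <- pmax(summit - half, tx$start[host])
  pe <- pmin(summit + half, tx$end[host])
  ord <- order(host)
  data.frame(peak_id = sprintf("peak_%04d", seq_len(n_pk)),
             transcript_id = tx$transcript_id[host],
             gene_id = tx$gene_id[host], chrom = config$chrom,
             start = as.integer(ps), end = as.integer(pe),
             strand = tx$strand[host], summit = summit,
             feature = assigned, stringsAsFactors = FALSE)[ord, ]
}

## per-peak enrichment plan for parents and hybrids, plus DMP /
## non-additive / ASM labels (exact planted counts)
.sim_enrichment <- function(config, peaks) {
  n <- nrow(peaks)
  e0 <- rlnorm(n, log(config$enrichment_median), config$enrichment_sdlog)
  pick <- function(frac) {
    k <- round_half_up(frac * n)
    is <- logical(n); if (k > 0) is[sample.int(n, k)] <- TRUE
    is
  }
  is_dmp <- pick(config$dmp_fraction)
  dmp_dir <- ifelse(is_dmp,
                    ifelse(runif(n) < config$dmp_bias, "A", "B"),
                    NA_character_)
  s <- sqrt(config$dmp_fold)
  enr_a <- e0 * ifelse(is_dmp, ifelse(dmp_dir == "A", s, 1 / s), 1)
  enr_b <- e0 * ifelse(is_dmp, ifelse(dmp_dir == "A", 1 / s, s), 1)
  mpv <- (enr_a + enr_b) / 2
  is_na_pk <- pick(config$nonadditive_fraction)
  na_dir <- ifelse(is_na_pk, ifelse(runif(n) < 0.5, "up", "down"),
                   NA_character_)
  enr_h <- mpv * ifelse(is_na_pk,
                        ifelse(na_dir == "up", config$nonadditive_fold,
                               1 / config$nonadditive_fold), 1)
  is_asm <- pick(config$asm_fraction)
  asm_allele <- ifelse(is_asm, ifelse(runif(n) < 0.5, "A", "B"),
                       NA_character_)
  cbind(peaks,
        data.frame(base_enrichment = e0, enr_parent_a = enr_a,
                   enr_parent_b = enr_b, enr_hybrid = enr_h,
                   is_dmp = is_dmp, dmp_direction = dmp_dir,
                   is_nonadditive = is_na_pk, nonadditive_direction = na_dir,
                   is_asm = is_asm, asm_allele = asm_allele,
                   stringsAsFactors = FALSE))
}

#' Simulate the two parental genome haplotypes
#'
#' Genome A is a uniform random sequence; genome B is A with Bernoulli
#' (`snp_rate`) substitutions restricted to positions at least 100 nt from
#' the ends (so the fragment scheme saturates every site). Optional
#' isolated sites are additionally planted and flagged heterozygous-like
#' or mapping-biased; `ensure_snp_windows` intervals (e.g. allele-specific
#' peaks) each receive at least one substitution.
#'
#' @param config [sim_config()].
#' @param genome_length genome length (nt); defaults to the length implied
#'   by [simulate_annotation()] with the same seed.
#' @param ensure_snp_windows optional data.frame of 0-based `start`/`end`
#'   windows that must contain a SNP.
#' @param seed seed (default `config$seed`); `NULL` continues the stream.
#' @return list with `genome_a`, `genome_b` (named `DNAStringSet`) and
#'   `snps` truth data.frame (`chrom`, `pos_a`, `pos_b`, `allele_a`,
#'   `allele_b`, `het_like`, `biased`).
#' @export
simulate_genomes <- function(config = sim_config(), genome_length = NULL,
                             ensure_snp_windows = NULL, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genome_length))
    genome_length <- simulate_annotation(config, seed = NULL)$genome_length
  L <- as.integer(genome_length)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, L, replace = TRUE)
  interior <- 100L   # fragment scheme saturates depth >= 100 nt from ends
  lo <- interior; hi <- L - interior - 1L
  pos <- integer(0)
  if (config$snp_rate > 0 && hi >= lo) {
    cand <- lo:hi
    pos <- cand[runif(length(cand)) < config$snp_rate]
  }
  if (!is.null(ensure_snp_windows) && nrow(ensure_snp_windows) > 0) {
    for (i in seq_len(nrow(ensure_snp_windows))) {
      ws <- max(ensure_snp_windows$start[i], lo)
      we <- min(ensure_snp_windows$end[i], hi + 1L)
      if (we > ws && !any(pos >= ws & pos < we))
        pos <- c(pos, as.integer(ws + (we - ws) %/% 2L))
    }
  }
  ## isolated special sites (>= read_length from any other substitution)
  n_special <- config$n_het_sites + config$n_biased_sites
  special <- integer(0)
  iso <- max(config$read_length, interior)
  if (n_special > 0) {
    guard <- 0L
    while (length(special) < n_special && guard < 10000L) {
      p <- as.integer(lo + floor(runif(1) * (hi - lo + 1)))
      if (all(abs(p - c(pos, special)) >= iso)) special <- c(special, p)
      guard <- guard + 1L
    }
    if (length(special) < n_special)
      stop("could not place isolated special SNP sites; genome too small")
  }
  pos <- sort(unique(c(pos, special)))
  alt <- vapply(pos, function(p) sample(setdiff(bases, a[p + 1L]), 1),
                character(1))
  b <- a
  b[pos + 1L] <- alt
  het <- pos %in% special[seq_len(config$n_het_sites)]
  biased <- pos %in% special[config$n_het_sites + seq_len(config$n_biased_sites)]
  ga <- Biostrings::DNAStringSet(paste(a, collapse = ""))
  gb <- Biostrings::DNAStringSet(paste(b, collapse = ""))
  names(ga) <- names(gb) <- config$chrom
  snps <- data.frame(chrom = rep(config$chrom, length(pos)),
                     pos_a = pos, pos_b = pos,
                     allele_a = a[pos + 1L], allele_b = alt,
                     het_like = het, biased = biased,
                     stringsAsFactors = FALSE)
  list(genome_a = ga, genome_b = gb, snps = snps)
}

## uniform reads along transcripts: n[i] reads from transcript i
.reads_uniform <- function(n, tx, read_length) {
  gi <- rep.int(seq_along(n), n)
  leff <- tx$end - tx$start - read_length + 1L
  start <- tx$start[gi] + floor(runif(sum(n)) * leff[gi])
  data.frame(gene = gi, start = as.integer(start), stringsAsFactors = FALSE)
}

## triangular bump reads: n[j] reads with centers summit[j] +/- hw,
## clamped into the host transcript
.reads_bump <- function(n, summit, tx_start, tx_end, host, read_length, hw) {
  pi <- rep.int(seq_along(n), n)
  total <- sum(n)
  d <- round((runif(total) + runif(total) - 1) * hw)
  start <- summit[pi] + d - read_length %/% 2L
  start <- pmax(start, tx_start[host][pi])
  start <- pmin(start, tx_end[host][pi] - read_length)
  data.frame(gene = host[pi], peak = pi, start = as.integer(start),
             stringsAsFactors = FALSE)
}

#' Simulate IP and input read libraries
#'
#' Input coverage is gamma-Poisson around per-gene expression rates shared
#' across genotypes and libraries; IP libraries superimpose a uniform
#' background at level `b` and a triangular read-center bump around each
#' planted summit, with `b` solved analytically so the expected IP library
#' mass equals the input mass (measured enrichment then matches the
#' planted enrichment in expectation). Hybrid reads draw a haplotype
#' Bernoulli(0.5), except IP reads of allele-specific genes which are
#' skewed to `asm_fold : 1` odds; parent A reads covering a planted
#' heterozygous-like site flip their allele with probability 0.5.
#'
#' @param config [sim_config()].
#' @param annotation [simulate_annotation()] output.
#' @param peaks_truth peak truth with enrichment columns (internal plan).
#' @param gene_rates per-gene expression rates (reads/library).
#' @param snps SNP truth from [simulate_genomes()].
#' @param seed seed (default `NULL`: continue the current RNG stream).
#' @return list with `samples` (data.frame) and `alignments` (named list
#'   of read data.frames).
#' @export
simulate_libraries <- function(config, annotation, peaks_truth, gene_rates,
                               snps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tx <- annotation$models$transcripts
  rl <- config$read_length
  hw <- config$summit_dispersion
  leff <- tx$end - tx$start - rl + 1L
  host <- match(peaks_truth$transcript_id, tx$transcript_id)
  ## expected input reads whose span overlaps each peak
  s_lo <- pmax(peaks_truth$start - rl + 1L, tx$start[host])
  s_hi <- pmin(peaks_truth$end - 1L, tx$end[host] - rl)
  w <- pmax(s_hi - s_lo + 1L, 0L)
  p_mass <- gene_rates[host] * w / leff[host]

  parents <- config$genotypes[config$genotypes %in% c("Col0", "Ler")]
  enr_of <- function(genotype) {
    if (genotype == "Col0") peaks_truth$enr_parent_a
    else if (genotype == "Ler") peaks_truth$enr_parent_b
    else peaks_truth$enr_hybrid
  }
  asm_genes <- host[peaks_truth$is_asm]
  asm_p_a <- ifelse(peaks_truth$asm_allele[peaks_truth$is_asm] == "A",
                    config$asm_fold / (1 + config$asm_fold),
                    1 / (1 + config$asm_fold))
  het_pos <- snps$pos_a[snps$het_like]

  samples <- list(); alignments <- list()
  for (genotype in config$genotypes) {
    enr <- enr_of(genotype)
    lam_pk <- gene_rates[host]
    b <- (sum(lam_pk) - sum(enr * p_mass)) / (sum(lam_pk) - sum(p_mass))
    b <- min(max(b, 0.02), 1)
    bump_rate <- pmax(enr - b, 0) * p_mass
    bg_rate <- gene_rates
    bg_rate[host] <- b * gene_rates[host]   # peakless genes stay at rate 1x
    ip_scale <- if (genotype == "Ler") config$ler_ip_scale else 1
    is_hybrid <- !genotype %in% c("Col0", "Ler")

    for (assay in c("IP", "input")) {
      for (rep_i in seq_len(config$replicates)) {
        if (assay == "input") {
          rd <- .reads_uniform(rpois(nrow(tx), gene_rates), tx, rl)
        } else {
          bg <- .reads_uniform(rpois(nrow(tx), bg_rate * ip_scale), tx, rl)
          bp <- .reads_bump(rpois(length(bump_rate), bump_rate * ip_scale),
                            peaks_truth$summit, tx$start, tx$end, host, rl, hw)
          rd <- data.frame(gene = c(bg$gene, bp$gene),
                           start = c(bg$start, bp$start))
        }
        n <- nrow(rd)
        if (is_hybrid) {
          p_a <- rep(0.5, n)
          if (assay == "IP" && length(asm_genes)) {
            m <- match(rd$gene, asm_genes)
            p_a[!is.na(m)] <- asm_p_a[m[!is.na(m)]]
          }
          allele <- ifelse(runif(n) < p_a, "A", "B")
        } else {
          allele <- rep(if (genotype == "Col0") "A" else "B", n)
          if (genotype == "Col0" && length(het_pos)) {
            for (p in het_pos) {
              covered <- which(rd$start <= p & rd$start + rl > p)
              flip <- covered[runif(length(covered)) < 0.5]
              allele[flip] <- "B"
            }
          }
        }
        sid <- paste(genotype, assay, rep_i, sep = "_")
        alignments[[sid]] <- data.frame(
          chrom = rep(config$chrom, n), start = rd$start,
          end = rd$start + rl, strand = tx$strand[rd$gene],
          read_id = paste0(sid, "_", seq_len(n)), allele = allele,
          stringsAsFactors = FALSE)
        samples[[sid]] <- data.frame(
          sample_id = sid, genotype = genotype, assay = assay,
          replicate = rep_i, total_mapped = n, stringsAsFactors = FALSE)
      }
    }
  }
  list(samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
       alignments = alignments)
}

#' Simulate a complete MeRIP experiment
#'
#' Orchestrates annotation, peak planting, enrichment planning, genome and
#' library simulation from one seed and assembles a `merip_experiment`
#' with full ground truth attached.
#'
#' @param config [sim_config()].
#' @return `merip_experiment` whose `truth` holds `peaks`, `genes`,
#'   `snps`, the `config`, and (when biased sites are planted)
#'   `hybrid_map` with the per-reference hybrid read sets.
#' @export
simulate_experiment <- function(config = sim_config()) {
  set.seed(config$seed)
  annotation <- simulate_annotation(config, seed = NULL)
  peaks <- .sim_peaks(config, annotation)
  plan <- .sim_enrichment(config, peaks)
  gene_rates <- rlnorm(config$n_transcripts, config$expr_meanlog,
                       config$expr_sdlog) *
    rgamma(config$n_transcripts, shape = 1 / config$dispersion,
           scale = config$dispersion)
  ensure <- plan[plan$is_asm, c("start", "end"), drop = FALSE]
  genomes <- simulate_genomes(config, annotation$genome_length,
                              ensure_snp_windows = ensure, seed = NULL)
  libs <- simulate_libraries(config, annotation, plan, gene_rates,
                             genomes$snps, seed = NULL)
  truth <- list(
    peaks = plan,
    genes = data.frame(gene_id = annotation$models$transcripts$gene_id,
                       rate = gene_rates, stringsAsFactors = FALSE),
    snps = genomes$snps,
    config = config)
  ## per-reference hybrid mappings for the bias filter: reads over a
  ## biased site are under-represented on reference B
  if (config$n_biased_sites > 0) {
    hybrids <- setdiff(config$genotypes, c("Col0", "Ler"))
    truth$hybrid_map <- list()
    bpos <- genomes$snps$pos_a[genomes$snps$biased]
    for (g in hybrids) {
      ids <- libs$samples$sample_id[libs$samples$genotype == g]
      all_reads <- do.call(rbind, libs$alignments[ids])
      drop <- rep(FALSE, nrow(all_reads))
      for (p in bpos) {
        covered <- which(all_reads$start <= p & all_reads$end > p)
        drop[covered[runif(length(covered)) < config$bias_drop]] <- TRUE
      }
      truth$hybrid_map[[g]] <- list(on_a = all_reads,
                                    on_b = all_reads[!drop, , drop = FALSE])
    }
  }
  bed <- plan[, c("chrom", "start", "end", "peak_id", "strand")]
  bed$score <- 0
  merip_experiment(samples = libs$samples, alignments = libs$alignments,
                   annotation = annotation$models, peaks = bed,
                   genomes = list(A = genomes$genome_a, B = genomes$genome_b),
                   truth = truth)
}

#' Write ground-truth tables
#'
#' @param truth truth list from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return paths of the written TSVs, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peaks = file.path(dir, "truth_peaks.tsv"),
             genes = file.path(dir, "truth_genes.tsv"),
             snps = file.path(dir, "truth_snps.tsv"))
  for (nm in names(paths))
    write.table(truth[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(paths)
}

#' Read ground-truth tables written by [write_truth()]
#'
#' @param dir directory holding the truth TSVs.
#' @return list with `peaks`, `genes`, `snps` data.frames.
#' @export
read_truth <- function(dir) {
  rd <- function(f) read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  list(peaks = rd("truth_peaks.tsv"), genes = rd("truth_genes.tsv"),
       snps = rd("truth_snps.tsv"))
}

#' Write a simulated experiment to standard files
#'
#' Emits the parental genomes (FASTA), the annotation (GTF), the peaks
#' (BED6), per-sample alignments (TSV dialect), the sample sheet and the
#' ground-truth tables.
#'
#' @param exp `merip_experiment` from [simulate_experiment()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(exp$genomes)) {
    Biostrings::writeXStringSet(exp$genomes$A, file.path(dir, "genomeA.fa"))
    Biostrings::writeXStringSet(exp$genomes$B, file.path(dir, "genomeB.fa"))
  }
  if (!is.null(exp$annotation))
    write_gtf(exp$annotation, file.path(dir, "annotation.gtf"))
  if (!is.null(exp$peaks))
    write_bed6(exp$peaks, file.path(dir, "peaks.bed"))
  write.table(exp$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (sid in exp$samples$sample_id)
    write_alignments_tsv(exp$alignments[[sid]],
                         file.path(dir, paste0(sid, ".tsv")))
  if (!is.null(exp$truth)) write_truth(exp$truth, dir)
  invisible(dir)
}
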