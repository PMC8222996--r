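make_models <- function() {
  transcript_models(
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
               strand = "+", start = 0L, end = 1000L, exonic_length = 1000L,
               start_codon_pos = 300L, stop_codon_pos = 899L),
    data.frame(transcript_id = "t1",
               type = c("exon", "utr5", "cds", "utr3"),
               start = c(0L, 0L, 300L, 900L),
               end = c(1000L, 300L, 900L, 1000L)))
}

make_exp <- function(ip_reads, input_reads, total = 1e6) {
  samples <- data.frame(sample_id = c("s_ip", "s_in"), genotype = "Col0",
                        assay = c("IP", "input"), replicate = 1L,
                        total_mapped = total)
  rd <- function(starts) data.frame(
    chrom = "chr1", start = starts, end = starts + 100L, strand = "+",
    read_id = paste0("r", seq_along(starts)), allele = NA_character_,
    stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = 400L, end = 600L,
                      peak_id = "p1", score = 0, strand = "+")
  merip_experiment(samples, list(s_ip = rd(ip_reads), s_in = rd(input_reads)),
                   annotation = make_models(), peaks = peaks)
}

test_that("compute_fpkm follows the standard formula", {
  expect_equal(compute_fpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_fpkm(0, 500, 1e6), 0)
  expect_equal(compute_fpkm(10, 500, 5e5), 2 * compute_fpkm(10, 500, 1e6))
  expect_error(compute_fpkm(1, 0, 1e6))
  expect_error(compute_fpkm(1, 100, 0))
})

test_that("quantify_peaks computes normalized counts and enrichment", {
  exp <- make_exp(rep(450L, 30), rep(450L, 10))
  q <- quantify_peaks(exp, "Col0")
  expect_equal(q$ip_norm, 30)
  expect_equal(q$input_norm, 10)
  expect_equal(q$enrichment, 3)
  expect_false(q$low_coverage)
  expect_equal(q$feature, "CDS")

  # equal reads -> enrichment 1
  q1 <- quantify_peaks(make_exp(rep(450L, 10), rep(450L, 10)), "Col0")
  expect_equal(q1$enrichment, 1)

  # no overlapping input reads -> pseudocount + low-coverage flag
  q0 <- quantify_peaks(make_exp(rep(450L, 10), rep(10L, 10)), "Col0")
  expect_true(q0$low_coverage)
  expect_equal(q0$enrichment, q0$ip_norm / 0.5)
})

test_that("enrichment is invariant to scaling all library depths", {
  exp1 <- make_exp(rep(450L, 30), rep(450L, 10), total = 1e6)
  exp2 <- make_exp(rep(450L, 30), rep(450L, 10), total = 2e6)
  expect_equal(quantify_peaks(exp1, "Col0")$enrichment,
               quantify_peaks(exp2, "Col0")$enrichment)
})

test_that("filter_peaks applies inclusive thresholds and is monotone", {
  q <- data.frame(peak_id = c("a", "b", "c", "d"),
                  gene_fpkm = c(0.5, 1.0, 2.0, 3.0),
                  peak_input_fpkm = c(10, 5.0, 4.9, 50))
  kept <- filter_peaks(q, peak_filter_params())
  expect_equal(kept$peak_id, c("b", "d"))
  stricter <- filter_peaks(q, peak_filter_params(2, 10))
  expect_true(all(stricter$peak_id %in% kept$peak_id))
})

test_that("call_summit takes the argmax residual, leftmost on ties", {
  s <- call_summit(c(1, 5, 9, 5, 1), c(1, 2, 3, 2, 1))
  expect_equal(s$offset, 2L)
  expect_false(s$degenerate)
  tie <- call_summit(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tie$offset, 0L)
  expect_true(tie$degenerate)
})

test_that("assign_feature is tiered UTR3 > UTR5 > CDS", {
  m <- make_models()
  expect_equal(assign_feature(950L, m, "g1"), "UTR3")
  expect_equal(assign_feature(100L, m, "g1"), "UTR5")
  expect_equal(assign_feature(500L, m, "g1"), "CDS")
  expect_warning(res <- assign_feature(5000L, m, "g1"),
                 "no annotated feature")
  expect_true(is.na(res))

  # overlapping isoforms: utr3 of one beats cds of another
  two <- transcript_models(
    rbind(m$transcripts,
          data.frame(transcript_id = "t2", gene_id = "g1", chrom = "chr1",
                     strand = "+", start = 0L, end = 1000L,
                     exonic_length = 1000L, start_codon_pos = 0L,
                     stop_codon_pos = 999L)),
    rbind(m$features,
          data.frame(transcript_id = "t2", type = c("exon", "cds"),
                     start = c(0L, 0L), end = c(1000L, 1000L))))
  expect_equal(assign_feature(950L, two, "g1"), "UTR3")
})

test_that("assign_codon_segment uses 200 nt centered windows", {
  m <- make_models()
  expect_equal(assign_codon_segment(979L, m, "t1"), "stop")   # 80 nt away
  expect_equal(assign_codon_segment(500L, m, "t1"), character(0))
  expect_equal(assign_codon_segment(401L, m, "t1"), character(0)) # 101 nt
  expect_equal(assign_codon_segment(400L, m, "t1"), "start")      # 100 nt
  close_m <- transcript_models(
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
               strand = "+", start = 0L, end = 400L, exonic_length = 400L,
               start_codon_pos = 100L, stop_codon_pos = 250L),
    data.frame(transcript_id = "t1",
               type = c("exon", "utr5", "cds", "utr3"),
               start = c(0L, 0L, 100L, 251L),
               end = c(400L, 100L, 251L, 400L)))
  expect_setequal(assign_codon_segment(175L, close_m, "t1"),
                  c("start", "stop"))
})

test_that("metagene profile is flat under uniform coverage and logs exclusions", {
  models <- transcript_models(
    data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
               chrom = "chr1", strand = "+", start = c(0L, 1000L),
               end = c(300L, 1300L), exonic_length = 300L,
               start_codon_pos = c(100L, NA), stop_codon_pos = c(199L, NA)),
    rbind(data.frame(transcript_id = "t1",
                     type = c("exon", "utr5", "cds", "utr3"),
                     start = c(0L, 0L, 100L, 200L),
                     end = c(300L, 100L, 200L, 300L)),
          data.frame(transcript_id = "t2", type = c("exon", "cds"),
                     start = c(1000L, 1000L), end = c(1300L, 1300L))))
  samples <- data.frame(sample_id = "s1", genotype = "Col0", assay = "IP",
                        replicate = 1L, total_mapped = 300)
  reads <- data.frame(chrom = "chr1", start = 0:299, end = 1:300,
                      strand = "+", read_id = paste0("r", 1:300),
                      allele = NA_character_)
  exp <- merip_experiment(samples, list(s1 = reads), annotation = models)
  prof <- metagene_profile(exp, "s1", bins_per_feature = 10)
  expect_equal(dim(prof), c(1L, 30L))
  v <- as.numeric(prof)
  expect_true(all(abs(v - v[1]) < 1e-9))          # flat
  expect_equal(attr(prof, "n_excluded"), 1L)      # t2 lacks UTRs
  expect_equal(attr(prof, "feature"),
               rep(c("UTR5", "CDS", "UTR3"), each = 10))
})

test_that("planted enrichment 4 is recovered within [3.2, 4.8]", {
  cfg <- sim_config(seed = 3, n_transcripts = 100, expr_meanlog = log(400),
                    enrichment_median = 4, enrichment_sdlog = 0,
                    dmp_fraction = 0, nonadditive_fraction = 0,
                    asm_fraction = 0, genotypes = "Col0")
  exp <- simulate_experiment(cfg)
  q <- quantify_peaks(exp, "Col0", compute_summits = FALSE)
  expect_gt(median(q$enrichment), 3.2)
  expect_lt(median(q$enrichment), 4.8)
})
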