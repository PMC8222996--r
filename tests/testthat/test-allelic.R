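rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("fragment_genome produces shifted fragments", {
  s <- rand_seq(150, 1)
  fr <- fragment_genome(s)
  expect_equal(length(fr$fragments), 51L)
  expect_equal(fr$start, 0:50)
  one <- fragment_genome(substr(s, 1, 100))
  expect_equal(one$fragments, substr(s, 1, 100))
  # concatenating first bases reproduces the prefix
  expect_equal(paste(substr(fr$fragments, 1, 1), collapse = ""),
               substr(s, 1, 51))
  expect_error(fragment_genome(substr(s, 1, 50)))
})

test_that("cross_map_pileup: identical genomes give zero mismatches", {
  g <- rand_seq(400, 2)
  p <- cross_map_pileup(g, g)
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "n_placed"), attr(p, "n_fragments"))
  expect_equal(as.integer(attr(p, "depth_cov")[151]), 100L)
})

test_that("cross_map_pileup localizes substitutions exactly", {
  g <- rand_seq(400, 3)
  v <- strsplit(g, "")[[1]]
  v[201] <- setdiff(c("A", "C", "G", "T"), v[201])[1]   # 0-based pos 200
  p <- cross_map_pileup(paste(v, collapse = ""), g)
  expect_equal(p$pos, 200L)
  expect_equal(p$mismatch, p$depth)
  expect_equal(p$mutant_ratio, 1)
  expect_equal(p$alt_base, v[201])

  # 20 planted substitutions -> sites exactly at the planted positions
  g2 <- rand_seq(3000, 4)
  v2 <- strsplit(g2, "")[[1]]
  pos <- seq(150, by = 140, length.out = 20)
  for (q in pos) v2[q + 1] <- setdiff(c("A", "C", "G", "T"), v2[q + 1])[1]
  p2 <- cross_map_pileup(paste(v2, collapse = ""), g2)
  expect_equal(p2$pos, as.integer(pos))
})

test_that("call_candidate_snps enforces inclusive thresholds and reciprocity", {
  mk <- function(pos, ref, alt, depth, mism)
    data.frame(pos = pos, ref_base = ref, alt_base = alt, depth = depth,
               mismatch = mism, mutant_ratio = mism / depth,
               stringsAsFactors = FALSE)
  on_b <- mk(c(10L, 20L, 30L), "C", "A", c(95L, 89L, 100L), c(90L, 89L, 89L))
  on_a <- mk(c(10L, 20L, 30L), "A", "C", 100L, 100L)
  snps <- call_candidate_snps(on_b, on_a)
  expect_equal(snps$pos_a, 10L)   # 20: coverage 89 < 90; 30: ratio 0.89
  expect_equal(snps$allele_a, "A")
  expect_equal(snps$allele_b, "C")
  # non-reciprocal site dropped
  snps2 <- call_candidate_snps(on_b, on_a[0, ])
  expect_equal(nrow(snps2), 0L)
  # lowering min_coverage never removes calls
  relaxed <- call_candidate_snps(on_b, on_a, snp_calling_params(min_coverage = 50))
  expect_true(all(snps$pos_a %in% relaxed$pos_a))
})

test_that("swapping the references swaps allele labels, no call changes", {
  g <- rand_seq(600, 5)
  v <- strsplit(g, "")[[1]]
  for (q in c(200, 400)) v[q + 1] <- setdiff(c("A", "C", "G", "T"), v[q + 1])[1]
  ga <- g; gb <- paste(v, collapse = "")
  s_ab <- discover_snps(ga, gb)
  s_ba <- discover_snps(gb, ga)
  expect_equal(s_ab$pos_a, s_ba$pos_b)
  expect_equal(s_ab$allele_a, s_ba$allele_b)
  expect_equal(s_ab$allele_b, s_ba$allele_a)
  expect_true(all(s_ab$allele_a != s_ab$allele_b))
})

mk_snps <- function(pos, allele_a = "A", allele_b = "G")
  data.frame(chrom = "chr1", pos_a = pos, pos_b = pos,
             allele_a = allele_a, allele_b = allele_b,
             stringsAsFactors = FALSE)

mk_reads <- function(starts, allele = NA_character_, seq = NULL, rl = 100L) {
  df <- data.frame(chrom = "chr1", start = starts, end = starts + rl,
                   strand = "+", read_id = paste0("r", seq_along(starts)),
                   allele = allele, stringsAsFactors = FALSE)
  if (!is.null(seq)) df$seq <- seq
  df
}

test_that("bias_filter excludes sites with > 10% mapping difference", {
  snps <- mk_snps(c(150L, 450L))
  on_a <- mk_reads(c(rep(100L, 100), rep(400L, 100)))
  on_b <- mk_reads(c(rep(100L, 100), rep(400L, 89)))
  kept <- bias_filter(snps, on_a, on_b)
  expect_equal(kept$pos_a, 150L)
  expect_equal(kept$bias, 0)
  excl <- attr(kept, "excluded")
  expect_equal(excl$pos_a, 450L)
  expect_equal(excl$bias, 0.11, tolerance = 1e-9)
  # mean denominator: |100-89|/94.5 = 0.116 -> still excluded
  kept_m <- bias_filter(snps, on_a, on_b,
                        snp_calling_params(bias_denominator = "mean"))
  expect_equal(kept_m$pos_a, 150L)
})

test_that("homozygosity_filter keeps only parent-homozygous sites", {
  snps <- mk_snps(c(150L, 450L))
  pa <- mk_reads(c(rep(100L, 20), rep(400L, 20)),
                 allele = c(rep("A", 19), "B",          # 95% own allele
                            rep("A", 12), rep("B", 8))) # 60/40 split
  pb <- mk_reads(c(rep(100L, 20), rep(400L, 20)), allele = "B")
  kept <- homozygosity_filter(snps, pa, pb)
  expect_equal(kept$pos_a, 150L)
  expect_equal(kept$support_a, 0.95)
  expect_equal(attr(kept, "excluded")$pos_a, 450L)
  # site with no informative parent coverage is dropped too
  kept2 <- homozygosity_filter(mk_snps(5000L), pa, pb)
  expect_equal(nrow(kept2), 0L)
})

test_that("count_allelic_reads votes per read and discards conflicts", {
  snps <- mk_snps(150L)
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 300L,
                      peak_id = "p1", stringsAsFactors = FALSE)
  ip <- mk_reads(rep(100L, 10), allele = "A")
  input <- mk_reads(rep(100L, 6), allele = c(rep("A", 3), rep("B", 3)))
  cnt <- count_allelic_reads(ip, input, snps, peaks)
  expect_equal(cnt$ip_A, 10L)
  expect_equal(cnt$ip_B, 0L)
  expect_equal(cnt$input_A, 3L)
  expect_equal(cnt$input_B, 3L)
  expect_equal(unname(attr(cnt, "discarded")), c(0L, 0L))

  # read spanning two SNPs with discordant bases is discarded (seq votes)
  snps2 <- mk_snps(c(150L, 160L))
  sq <- strrep("T", 100)
  substr(sq, 51, 51) <- "A"   # matches allele_a at pos 150 (start 100)
  substr(sq, 61, 61) <- "G"   # matches allele_b at pos 160
  ip2 <- mk_reads(100L, seq = sq)
  cnt2 <- count_allelic_reads(ip2, input, snps2, peaks)
  expect_equal(cnt2$ip_A + cnt2$ip_B, 0L)
  expect_equal(unname(attr(cnt2, "discarded")["IP"]), 1L)
})

test_that("asm_test flags skewed peaks and not symmetric ones", {
  sym <- data.frame(peak_id = "p1", ip_A = 40L, ip_B = 40L,
                    input_A = 40L, input_B = 40L)
  r <- asm_test(sym)
  expect_equal(r$p_value, 1)
  expect_false(r$allele_specific)

  skew <- data.frame(peak_id = "p1", ip_A = 80L, ip_B = 10L,
                     input_A = 40L, input_B = 40L)
  r2 <- asm_test(skew)
  expect_lt(r2$p_adjusted, 0.05)
  expect_true(r2$allele_specific)
  expect_equal(r2$direction, "A")
  # shared statistical core: p equals fisher_exact + holm_adjust
  expect_equal(r2$p_value,
               fisher_exact(matrix(c(80, 40, 10, 40), 2, byrow = TRUE))$p_value)
})

test_that("allelic_ratio_distribution computes log2 ratios", {
  eq <- data.frame(peak_id = c("p1", "p2"), ip_A = c(10L, 20L),
                   ip_B = c(10L, 20L), input_A = c(5L, 8L),
                   input_B = c(5L, 8L))
  r <- allelic_ratio_distribution(eq)
  expect_true(all(r$ratios$log2_expression == 0))
  expect_true(all(r$ratios$log2_methylation == 0))
  expect_equal(r$summary$frac_within_unit, c(1, 1))
  r2 <- allelic_ratio_distribution(
    data.frame(peak_id = "p1", ip_A = 0L, ip_B = 0L,
               input_A = 400L, input_B = 100L), pseudocount = 1e-9)
  expect_equal(r2$ratios$log2_expression, 2, tolerance = 1e-6)
})
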