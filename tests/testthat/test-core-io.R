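test_that("parse_gtf derives UTRs and converts coordinates", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t101\t250\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  m <- parse_gtf(gtf)
  fx <- m$features
  expect_equal(fx[fx$type == "utr5", c("start", "end")],
               data.frame(start = 0L, end = 100L), ignore_attr = TRUE)
  expect_equal(fx[fx$type == "cds", c("start", "end")],
               data.frame(start = 100L, end = 250L), ignore_attr = TRUE)
  expect_equal(fx[fx$type == "utr3", c("start", "end")],
               data.frame(start = 250L, end = 300L), ignore_attr = TRUE)
  expect_equal(m$transcripts$exonic_length, 300L)
  expect_true(validate_transcript_models(m))
})

test_that("parse_gtf: minus strand puts utr3 left of the CDS", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t300\t.\t-\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t101\t250\t.\t-\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  m <- parse_gtf(gtf)
  fx <- m$features
  expect_equal(fx$start[fx$type == "utr3"], 0L)
  expect_equal(fx$start[fx$type == "utr5"], 250L)
  expect_equal(m$transcripts$start_codon_pos, 249L)
  expect_equal(m$transcripts$stop_codon_pos, 100L)
})

test_that("malformed GTF line errors with its line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1 broken line"), gtf)
  expect_error(parse_gtf(gtf), "line 2")
})

test_that("GTF round-trips through write_gtf/parse_gtf", {
  exp <- small_experiment()
  path <- tempfile(fileext = ".gtf")
  write_gtf(exp$annotation, path)
  again <- parse_gtf(path)
  expect_equal(again$transcripts, exp$annotation$transcripts)
  expect_equal(again$features, exp$annotation$features)
})

test_that("BED6 parses verbatim and round-trips byte-identically", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tpeak1\t0\t+", bed)
  p <- parse_bed6(bed)
  expect_equal(p$start, 100L)
  expect_equal(p$end, 200L)
  expect_equal(p$peak_id, "peak1")
  expect_equal(p$strand, "+")

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(parse_bed6(empty)), 0L)

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t200\t100\tpeak1\t0\t+", bad)
  expect_error(parse_bed6(bad))

  exp <- small_experiment()
  out1 <- tempfile(fileext = ".bed"); out2 <- tempfile(fileext = ".bed")
  write_bed6(exp$peaks, out1)
  write_bed6(parse_bed6(out1), out2)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("load_alignments filters secondary records and matches TSV", {
  sam <- tempfile(fileext = ".sam")
  recs <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000")
  for (i in 1:10) {
    flag <- if (i <= 2) 256L else 0L   # two secondary records
    recs <- c(recs, sprintf(
      "r%d\t%d\tchr1\t%d\t60\t10M\t*\t0\t0\tACGTACGTAC\t*\tNH:i:1\tXV:A:A",
      i, flag, i * 10))
  }
  writeLines(recs, sam)
  al <- load_alignments(sam)
  expect_equal(attr(al, "n_total"), 10L)
  expect_equal(nrow(al), 8L)
  expect_true(all(al$allele == "A"))

  tsv <- tempfile(fileext = ".tsv")
  write_alignments_tsv(al, tsv)
  al2 <- load_alignments(tsv)
  expect_equal(al2$chrom, al$chrom)
  expect_equal(al2$start, al$start)
  expect_equal(al2$end, al$end)
  expect_equal(al2$read_id, al$read_id)
  expect_equal(al2$allele, al$allele)

  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(load_alignments(empty)), 0L)
  expect_error(load_alignments("x.unknown"), "dialect")
})

test_that("interval_intersect follows half-open arithmetic", {
  expect_equal(interval_intersect(list(start = 100, end = 200),
                                  list(start = 150, end = 250)), 50)
  expect_equal(interval_intersect(list(start = 100, end = 200),
                                  list(start = 200, end = 300)), 0)
  expect_equal(interval_intersect(list(start = 100, end = 200),
                                  list(start = 100, end = 200)), 100)
  expect_equal(interval_intersect(
    list(chrom = "chr1", start = 100, end = 200),
    list(chrom = "chr2", start = 100, end = 200)), 0)
  # symmetry and bound
  a <- list(start = 10, end = 120); b <- list(start = 100, end = 400)
  expect_equal(interval_intersect(a, b), interval_intersect(b, a))
  expect_lte(interval_intersect(a, b), min(a$end - a$start, b$end - b$start))
})

test_that("normalize_count is reads-per-million", {
  expect_equal(normalize_count(100, 1e6), 100)
  expect_equal(normalize_count(0, 123), 0)
  expect_equal(normalize_count(50, 2e5), normalize_count(100, 4e5))
  expect_error(normalize_count(1, 0))
})

test_that("merip_experiment validates its sample sheet", {
  s <- data.frame(sample_id = c("a", "b"), genotype = "Col0",
                  assay = c("IP", "input"), replicate = 1L, total_mapped = 10)
  al <- list(a = data.frame(), b = data.frame())
  expect_s3_class(merip_experiment(s, al), "merip_experiment")
  s2 <- s; s2$assay <- c("IP", "IP")
  expect_error(merip_experiment(s2, al), "duplicate")
  s3 <- s; s3$total_mapped <- c(10, 0)
  expect_error(merip_experiment(s3, al), "total_mapped")
  expect_error(merip_experiment(s, al[1]), "missing alignments")
})
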