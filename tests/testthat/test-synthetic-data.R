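test_that("simulate_genomes is deterministic and respects snp_rate", {
  cfg <- small_config(seed = 5)
  g1 <- simulate_genomes(cfg, genome_length = 20000L)
  g2 <- simulate_genomes(cfg, genome_length = 20000L)
  expect_identical(as.character(g1$genome_a), as.character(g2$genome_a))
  expect_identical(as.character(g1$genome_b), as.character(g2$genome_b))
  expect_identical(g1$snps, g2$snps)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(g1$genome_a, f1)
  Biostrings::writeXStringSet(g2$genome_a, f2)
  expect_identical(readLines(f1), readLines(f2))

  g0 <- simulate_genomes(small_config(seed = 5, snp_rate = 0),
                         genome_length = 20000L)
  expect_identical(as.character(g0$genome_a), as.character(g0$genome_b))
  expect_equal(nrow(g0$snps), 0L)

  # planted count within 3 sigma of the binomial expectation
  gl <- 100000L
  gr <- simulate_genomes(small_config(seed = 6, snp_rate = 1e-3),
                         genome_length = gl)
  n_int <- gl - 200L
  expect_lt(abs(nrow(gr$snps) - n_int * 1e-3), 3 * sqrt(n_int * 1e-3))
  # substitutions really are substitutions at the recorded positions
  va <- strsplit(as.character(gr$genome_a), "")[[1]]
  vb <- strsplit(as.character(gr$genome_b), "")[[1]]
  expect_equal(which(va != vb) - 1L, gr$snps$pos_a)
  expect_equal(va[gr$snps$pos_a + 1L], gr$snps$allele_a)
  expect_equal(vb[gr$snps$pos_b + 1L], gr$snps$allele_b)
})

test_that("simulate_annotation yields valid models; empty config works", {
  ann <- simulate_annotation(small_config(seed = 7))
  expect_true(validate_transcript_models(ann$models))
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann$models, path)
  again <- parse_gtf(path)
  expect_equal(again$transcripts, ann$models$transcripts)
  expect_equal(again$features, ann$models$features)
  # feature lengths behave like the configured distributions
  fx <- ann$models$features
  u3 <- fx$end[fx$type == "utr3"] - fx$start[fx$type == "utr3"]
  expect_lt(abs(mean(u3) - 350), 4 * 60 / sqrt(length(u3)) + 5)
  cds <- fx$end[fx$type == "cds"] - fx$start[fx$type == "cds"]
  expect_true(all(cds %% 3 == 0))

  empty <- simulate_annotation(sim_config(seed = 1, n_transcripts = 0,
                                          n_peaks = 0))
  expect_equal(nrow(empty$models$transcripts), 0L)
})

test_that("simulated experiment passes all upstream parsers", {
  exp <- small_experiment()
  dir <- tempfile(); dir.create(dir)
  write_experiment(exp, dir)
  models <- parse_gtf(file.path(dir, "annotation.gtf"))
  expect_true(validate_transcript_models(models))
  peaks <- parse_bed6(file.path(dir, "peaks.bed"))
  expect_equal(nrow(peaks), nrow(exp$peaks))
  sid <- exp$samples$sample_id[1]
  al <- load_alignments(file.path(dir, paste0(sid, ".tsv")))
  expect_equal(nrow(al), exp$samples$total_mapped[1])
  ga <- Biostrings::readDNAStringSet(file.path(dir, "genomeA.fa"))
  expect_equal(as.character(ga[[1]]), as.character(exp$genomes$A[[1]]))
})

test_that("truth tables round-trip and match config fractions", {
  exp <- small_experiment()
  dir <- tempfile(); dir.create(dir)
  write_truth(exp$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$peaks$peak_id, exp$truth$peaks$peak_id)
  expect_equal(back$peaks$is_dmp, exp$truth$peaks$is_dmp)
  expect_equal(back$snps$pos_a, exp$truth$snps$pos_a)
  expect_equal(back$genes$rate, exp$truth$genes$rate, tolerance = 1e-8)
  # planted label counts are exact per config
  cfg <- exp$truth$config
  expect_equal(sum(back$peaks$is_dmp), round(cfg$dmp_fraction * cfg$n_peaks))
  expect_equal(sum(back$peaks$is_nonadditive),
               round(cfg$nonadditive_fraction * cfg$n_peaks))
  expect_equal(sum(back$peaks$is_asm), round(cfg$asm_fraction * cfg$n_peaks))

  # empty truth -> headers only
  dir2 <- tempfile(); dir.create(dir2)
  empty <- list(peaks = exp$truth$peaks[0, ], genes = exp$truth$genes[0, ],
                snps = exp$truth$snps[0, ])
  write_truth(empty, dir2)
  expect_equal(length(readLines(file.path(dir2, "truth_peaks.tsv"))), 1L)
  back0 <- read_truth(dir2)
  expect_equal(nrow(back0$peaks), 0L)
})

test_that("planted feature mixture and library scaling are honored", {
  exp <- small_experiment()
  tr <- exp$truth$peaks
  mix <- table(tr$feature) / nrow(tr)
  expect_lt(abs(mix[["utr3"]] - 0.70), 0.051)
  expect_lt(abs(mix[["cds"]] - 0.25), 0.051)
  # Ler IP libraries are scaled down
  s <- exp$samples
  ler_ip <- sum(s$total_mapped[s$genotype == "Ler" & s$assay == "IP"])
  col_ip <- sum(s$total_mapped[s$genotype == "Col0" & s$assay == "IP"])
  expect_lt(ler_ip / col_ip, 0.9)
})

test_that("null enrichment config centers measured enrichment at 1", {
  cfg <- sim_config(seed = 8, n_transcripts = 60, expr_meanlog = log(400),
                    enrichment_median = 1, enrichment_sdlog = 0,
                    dmp_fraction = 0, nonadditive_fraction = 0,
                    asm_fraction = 0, genotypes = "Col0")
  exp <- simulate_experiment(cfg)
  q <- quantify_peaks(exp, "Col0", compute_summits = FALSE)
  expect_gt(median(q$enrichment), 0.9)
  expect_lt(median(q$enrichment), 1.1)
})

test_that("read_sim_config merges YAML over defaults", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "n_transcripts: 12", "snp_rate: 0.01",
               "genotypes:", "  - Col0", "  - Ler"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$n_transcripts, 12L)
  expect_equal(cfg$genotypes, c("Col0", "Ler"))
  expect_equal(cfg$replicates, 2L)   # default retained
  writeLines("nonsense_field: 1", path)
  expect_error(read_sim_config(path), "unknown config field")
})
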