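# End-to-end pipeline: simulate (or accept) an experiment, quantify and
# filter peaks per genotype, call differential peaks between the parents,
# classify hybrid additivity, and run the allelic branch (SNP discovery,
# filters, allelic counts, ASM tests).

#' Run the full analysis pipeline on an experiment
#'
#' Stages run in a fixed order; stages whose inputs are absent (e.g. no
#' hybrid genotypes, no genome sequences) are skipped and returned as
#' `NULL`. With a `sim_config` as input the experiment is simulated first,
#' so one seed determines every number in the result.
#'
#' @param x a `merip_experiment` or a `sim_config`.
#' @param filter_params [peak_filter_params()].
#' @param annot_params [annotation_params()].
#' @param criteria [dmp_criteria()].
#' @param snp_params [snp_calling_params()]; `min_coverage` should match
#'   the fragment scheme depth (the in-silico default saturates at 100).
#' @param alpha adjusted-p threshold for additivity and ASM calls.
#' @param compute_summits compute per-peak summits (the slowest step).
#' @param discover_snps_flag run the allelic branch (needs genomes).
#' @return list with `experiment`, per-genotype `quant` (filtered
#'   quantifications), `dmps`, per-hybrid `additivity`,
#'   `expression_additivity`, `association`, `snps`, and per-hybrid
#'   `allelic` (counts, ASM results, ratio distributions).
#' @export
run_pipeline <- function(x,
                         filter_params = peak_filter_params(),
                         annot_params = annotation_params(),
                         criteria = dmp_criteria(),
                         snp_params = snp_calling_params(),
                         alpha = 0.05,
                         compute_summits = TRUE,
                         discover_snps_flag = TRUE) {
  exp <- if (inherits(x, "sim_config")) simulate_experiment(x) else x
  stopifnot(inherits(exp, "merip_experiment"))
  genotypes <- unique(exp$samples$genotype)
  parents <- intersect(c("Col0", "Ler"), genotypes)
  hybrids <- setdiff(genotypes, parents)

  quant <- lapply(genotypes, function(g)
    filter_peaks(quantify_peaks(exp, g, filter_params, annot_params,
                                compute_summits = compute_summits),
                 filter_params))
  names(quant) <- genotypes

  dmps <- if (length(parents) == 2)
    call_dmps(quant[[parents[1]]], quant[[parents[2]]], criteria) else NULL

  additivity <- NULL; expression_additivity <- NULL; association <- NULL
  if (length(parents) == 2 && length(hybrids) > 0) {
    additivity <- lapply(hybrids, function(h)
      classify_peak_additivity(quant[[h]], quant[[parents[1]]],
                               quant[[parents[2]]], alpha = alpha))
    names(additivity) <- hybrids
    ge <- gene_expression(exp)
    depth_of <- function(g) {
      s <- exp$samples[exp$samples$genotype == g &
                         exp$samples$assay == "input", ]
      sum(s$total_mapped)
    }
    count_of <- function(g) {
      d <- ge[ge$genotype == g, , drop = FALSE]
      rowsum(d$count, d$gene_id)[, 1]
    }
    genes <- sort(unique(ge$gene_id))
    expression_additivity <- lapply(hybrids, function(h)
      classify_expression_additivity(
        gene_id = genes, method = "builtin",
        hybrid_count = count_of(h)[genes],
        parent_a_count = count_of(parents[1])[genes],
        parent_b_count = count_of(parents[2])[genes],
        hybrid_depth = depth_of(h),
        parent_a_depth = depth_of(parents[1]),
        parent_b_depth = depth_of(parents[2]),
        alpha = alpha))
    names(expression_additivity) <- hybrids
    association <- lapply(hybrids, function(h)
      associate_nonadditive(additivity[[h]], expression_additivity[[h]]))
    names(association) <- hybrids
  }

  snps <- NULL; allelic <- NULL
  if (discover_snps_flag && !is.null(exp$genomes) && length(hybrids) > 0) {
    snps <- discover_snps(exp$genomes$A, exp$genomes$B, snp_params)
    reads_of <- function(g, assay = NULL) {
      s <- exp$samples[exp$samples$genotype == g, , drop = FALSE]
      if (!is.null(assay)) s <- s[s$assay == assay, , drop = FALSE]
      do.call(rbind, exp$alignments[s$sample_id])
    }
    allelic <- list()
    for (h in hybrids) {
      hyb_all <- reads_of(h)
      map <- exp$truth$hybrid_map[[h]]
      if (is.null(map)) map <- list(on_a = hyb_all, on_b = hyb_all)
      kept <- bias_filter(snps, map$on_a, map$on_b, snp_params)
      if (length(parents) == 2)
        kept <- homozygosity_filter(kept, reads_of(parents[1]),
                                    reads_of(parents[2]), snp_params)
      ip <- reads_of(h, "IP"); input <- reads_of(h, "input")
      counts <- count_allelic_reads(ip, input, kept, exp$peaks)
      asm <- asm_test(counts, alpha = alpha,
                      ip_total = nrow(ip), input_total = nrow(input))
      allelic[[h]] <- list(snps = kept, counts = counts, asm = asm,
                           ratios = allelic_ratio_distribution(counts))
    }
  }

  list(experiment = exp, quant = quant, dmps = dmps,
       additivity = additivity,
       expression_additivity = expression_additivity,
       association = association, snps = snps, allelic = allelic)
}

#' Write the pipeline's result tables
#'
#' One TSV per stage (quantifications, DMPs, additivity calls, SNPs,
#' allelic counts and ASM results), written deterministically so two runs
#' of the same seed produce byte-identical files.
#'
#' @param results [run_pipeline()] output.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_pipeline_outputs <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (g in names(results$quant))
    put(results$quant[[g]], paste0("quant_", g, ".tsv"))
  if (!is.null(results$dmps)) put(results$dmps, "dmps.tsv")
  for (h in names(results$additivity))
    put(results$additivity[[h]], paste0("additivity_", h, ".tsv"))
  for (h in names(results$expression_additivity))
    put(results$expression_additivity[[h]],
        paste0("expression_additivity_", h, ".tsv"))
  if (!is.null(results$snps)) put(results$snps, "snps.tsv")
  for (h in names(results$allelic)) {
    put(results$allelic[[h]]$counts, paste0("allelic_counts_", h, ".tsv"))
    put(results$allelic[[h]]$asm, paste0("asm_", h, ".tsv"))
  }
  invisible(paths)
}
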