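## End-to-end orchestration on synthetic data with truth scoring.

#' Run the full pipeline on a seeded synthetic data set
#'
#' simulate -> window test -> ROC calibration -> call -> synteny
#' polarization -> expression effects -> allele bias -> homology ->
#' enrichment -> diversity, with truth-recovery metrics at every stage
#' that has planted truth.  Re-running with the same configuration
#' produces an identical report.
#'
#' @param cfg a [sim_config()]; the master seed lives there.
#' @param max_fpr admissible FPR for threshold calibration.
#' @param fdr FDR level for the allele-bias stage.
#' @param out_dir optional directory; when given, the report is written
#'   to `report.json` and calls to `calls.bed` there.
#' @return the report as a nested list (invisibly if `out_dir` given).
#' @export
run_pipeline <- function(cfg = sim_config(), max_fpr = 0.05, fdr = 0.05,
                         out_dir = NULL) {
  gen <- simulate_genome(cfg)
  truth <- plant_svs(cfg, gen$assembly)
  counts <- simulate_window_counts(cfg, gen$assembly, truth,
                                   windows = make_windows(
                                     gen$assembly, cfg$window_size,
                                     cfg$window_size %/% 2))
  stats <- window_stats(counts)
  cal <- calibrate_and_call(stats, truth, strain = "sim", max_fpr = max_fpr)
  calls <- cal$calls
  rec <- recovery_metrics(calls, truth)

  # synteny: rearranged outgroup order, block recovery, polarization
  orders <- simulate_gene_orders(cfg, gen$genes)
  blocks <- collinear_blocks(orders$order_A, orders$order_B,
                             orders$ortholog_map, genes_A = gen$genes)
  calls <- polarize_svs(calls, blocks)

  # expression effects
  expr <- simulate_expression(cfg, gen$genes, truth)
  e_ref <- setNames(expr$fpkm[expr$sample == "ref"],
                    expr$gene_id[expr$sample == "ref"])
  e_test <- setNames(expr$fpkm[expr$sample == "test"],
                     expr$gene_id[expr$sample == "test"])
  status <- assign_sv_genes(calls, gen$genes, mode = "complete")
  deleted <- status$gene_id[status$status == "deleted"]
  duplicated_g <- status$gene_id[status$status == "duplicated"]
  unaffected <- status$gene_id[status$status == "unaffected"]
  loe <- if (length(deleted) > 0 && length(unaffected) > 0)
    loss_of_expression_test(deleted, unaffected, e_test) else NULL
  dfc <- tryCatch(
    dosage_fold_change_test(duplicated_g, unaffected, e_ref, e_test),
    error = function(e) NULL)
  rho <- transcriptome_correlation(e_ref, e_test)

  # allele bias on duplicated genes
  tstat <- gene_truth_status(gen$genes, truth)
  dup_genes <- gen$genes[tstat == "duplicated", , drop = FALSE]
  sites <- simulate_segregating_sites(cfg, dup_genes)
  bias <- allele_bias(sites, fdr = fdr)
  bias_truth <- unique(sites[, c("gene_id", "true_biased")])
  bias_power <- if (nrow(bias) > 0) {
    tb <- bias_truth$gene_id[bias_truth$true_biased]
    if (length(tb) > 0)
      mean(bias$biased[bias$gene_id %in% tb]) else NA_real_
  } else NA_real_

  # homology + enrichment
  hom <- simulate_homology(cfg)
  cls <- classify_homology(hom$hits,
                           data.frame(gene_id = hom$genes, species = "Ppa"),
                           "Ppa", "Cel")
  hom_agree <- mean(cls$class[match(hom$truth$gene_id, cls$gene_id)] ==
                      hom$truth$class)

  # diversity stratification on the 100 kb tiling
  div_wins <- make_windows(gen$assembly, 1e5, 1e5)
  div <- simulate_diversity(cfg, div_wins, calls)
  div_res <- tryCatch(diversity_by_sv(div, calls), error = function(e) NULL)

  report <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    calling = list(
      policies = cal$policies,
      n_calls = nrow(calls),
      recovery = rec,
      genome_fraction_total = list(
        deleted = sum(calls$end[calls$sv_type == "deletion"] -
                        calls$start[calls$sv_type == "deletion"]),
        duplicated = sum(calls$end[calls$sv_type == "duplication"] -
                           calls$start[calls$sv_type == "duplication"]))),
    synteny = list(n_blocks = length(blocks),
                   n_polarized = sum(calls$polarized)),
    expression = list(
      n_deleted_genes = length(deleted),
      n_duplicated_genes = length(duplicated_g),
      loss_of_expression = if (is.null(loe)) NULL else
        list(odds_ratio = loe$odds_ratio, p_value = loe$p_value),
      dosage_fold_change = dfc,
      spearman_rho = rho),
    allele_bias = list(n_genes_tested = nrow(bias),
                       n_biased = if (nrow(bias)) sum(bias$biased) else 0L,
                       power_on_truth = bias_power),
    homology = list(truth_agreement = hom_agree,
                    class_counts = as.list(table(cls$class))),
    diversity = div_res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(calls, file.path(out_dir, "calls.bed"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    return(invisible(report))
  }
  report
}
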