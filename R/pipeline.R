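# Orchestration: chain the footprint, enrichment, meta-regulator,
# methylation, differential-expression and network stages over in-memory
# inputs (real or simulated), with stage toggles, a funnel log, provenance
# headers on written outputs, and planted-truth recovery metrics for
# simulated runs.

#' Default pipeline options
#'
#' @param threshold footprint log2 mean FPKM cut-off, or `"auto"` for the
#'   lower-tail quantile rule.
#' @param q lower-tail fraction when `threshold = "auto"`.
#' @param biotype_filter biotype retained in the footprint (NULL = all).
#' @param alpha per-window scan significance.
#' @param q_tfbs per-configuration BH cutoff of the TFBS enrichment.
#' @param rrs_runs random reference sets in the consensus vote.
#' @param q_fpkm,q_counts per-engine DE q thresholds (asymmetric).
#' @param n_random_meth random TF control sets in the methylation stage.
#' @param detp_cutoff CpG detection-p filter.
#' @param stages character vector of stages to run, any of
#'   `"footprint"`, `"geneset"`, `"motifs"`, `"methyl"`, `"de"`,
#'   `"network"` (footprint always runs; others depend on it).
#' @param seed integer seed for every stochastic stage.
#' @param out_dir optional directory for TSV outputs with provenance
#'   headers.
#' @return options list.
#' @export
run_options <- function(threshold = 2, q = 0.05,
                        biotype_filter = "protein_coding",
                        alpha = 1e-4, q_tfbs = 0.05, rrs_runs = 10,
                        q_fpkm = 0.05, q_counts = 0.001,
                        n_random_meth = 3, detp_cutoff = 0.01,
                        stages = c("footprint", "geneset", "motifs",
                                   "methyl", "de", "network"),
                        seed = 1L, out_dir = NULL) {
  list(threshold = threshold, q = q, biotype_filter = biotype_filter,
       alpha = alpha, q_tfbs = q_tfbs, rrs_runs = rrs_runs,
       q_fpkm = q_fpkm, q_counts = q_counts,
       n_random_meth = n_random_meth, detp_cutoff = detp_cutoff,
       stages = stages, seed = as.integer(seed), out_dir = out_dir)
}

.prov_header <- function(opts) {
  sprintf("# mscportrait %s | seed=%d | threshold=%s | alpha=%g",
          as.character(utils::packageVersion("mscportrait")),
          opts$seed, paste(opts$threshold, collapse = ""), opts$alpha)
}

.write_stage <- function(df, name, opts) {
  if (is.null(opts$out_dir)) return(invisible(NULL))
  dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(opts$out_dir, paste0(name, ".tsv"))
  writeLines(.prov_header(opts), path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full characterization pipeline
#'
#' Chains: expression footprint -> gene-set enrichment -> TFBS consensus
#' and meta-regulator selection -> methylation comparison -> two-engine DE
#' consensus -> TF network. Each stage is re-runnable from its inputs; a
#' funnel log records record counts in and out of every filter.
#'
#' @param inputs list with elements `fpkm`, `counts`
#'   ([expression_matrix()]), `annotation` (gene_id, biotype, is_tf, ...),
#'   and, per stage: `gene_sets` (named list), `promoter_configs` (list of
#'   named sequence vectors, one per scanning configuration), `pssms`,
#'   `tf_map`, `methylation` (table as in [gen_methylation()]),
#'   `ppi_edges`, `paralogs`, optional `splicing_genes`.
#' @param opts a [run_options()] list.
#' @return report list with one element per executed stage plus `funnel`
#'   and `opts`.
#' @export
run_all <- function(inputs, opts = run_options()) {
  report <- list(opts = opts)
  funnel <- list()
  st <- function(s) s %in% opts$stages

  ## footprint ---------------------------------------------------------
  summ <- summarize_expression(inputs$fpkm)
  funnel$genes_total <- nrow(summ)
  funnel$genes_detected <- sum(summ$detected)
  fp_all <- call_footprint(summ, opts$threshold, q = opts$q)
  fp <- if (!is.null(opts$biotype_filter))
    call_footprint(summ, opts$threshold, inputs$annotation,
                   opts$biotype_filter, q = opts$q) else fp_all
  funnel$footprint_all_biotypes <- length(fp_all$genes)
  funnel$footprint <- length(fp$genes)
  report$summary <- summ
  report$footprint <- fp
  .write_stage(fp$table, "footprint", opts)

  tf_ids <- if (!is.null(inputs$gene_sets$TF)) inputs$gene_sets$TF
            else inputs$annotation$gene_id[inputs$annotation$is_tf]
  expressed_tfs <- intersect(fp$genes, tf_ids)
  funnel$tfs_known <- length(tf_ids)
  funnel$tfs_expressed <- length(expressed_tfs)
  report$expressed_tfs <- expressed_tfs

  ## gene-set enrichment -----------------------------------------------
  if (st("geneset") && !is.null(inputs$gene_sets)) {
    enr <- enrich_sets(inputs$gene_sets, fp, inputs$annotation$gene_id)
    report$enrichment <- enr
    .write_stage(enr, "enrichment", opts)
  }

  ## TFBS consensus and meta-regulators --------------------------------
  if (st("motifs") && !is.null(inputs$promoter_configs)) {
    hits <- lapply(inputs$promoter_configs, scan_hit_matrix,
                   pssms = inputs$pssms, alpha = opts$alpha)
    first <- tfbs_consensus(hits, inputs$tf_map, fp$genes,
                            q_cutoff = opts$q_tfbs,
                            rrs_runs = opts$rrs_runs, seed = opts$seed)
    meta <- meta_regulators(first, hits, inputs$tf_map, expressed_tfs,
                            q_cutoff = opts$q_tfbs,
                            rrs_runs = opts$rrs_runs, seed = opts$seed)
    funnel$tfs_first_pass <- sum(first$selected)
    funnel$meta_regulators <- length(meta$meta_regulators)
    report$consensus <- first
    report$meta_regulators <- meta$meta_regulators
    report$second_pass <- meta$second_pass
    .write_stage(first, "tfbs_consensus", opts)
  }

  ## methylation --------------------------------------------------------
  if (st("methyl") && !is.null(inputs$methylation) &&
      nrow(inputs$methylation)) {
    filt <- filter_detection(inputs$methylation, opts$detp_cutoff)
    funnel$cpgs_total <- nrow(inputs$methylation)
    funnel$cpgs_detected <- nrow(filt)
    not_expressed_tfs <- setdiff(tf_ids, expressed_tfs)
    if (length(not_expressed_tfs) >= length(expressed_tfs) &&
        length(expressed_tfs)) {
      report$methylation <- compare_tf_sets(
        filt, expressed_tfs, not_expressed_tfs,
        n_random = opts$n_random_meth, seed = opts$seed)
      .write_stage(report$methylation, "methylation", opts)
    }
  }

  ## differential expression --------------------------------------------
  if (st("de")) {
    res_f <- fpkm_engine(inputs$fpkm)
    res_c <- count_engine(inputs$counts)
    cons <- consensus_de(res_f, res_c, opts$q_fpkm, opts$q_counts)
    report$de <- cons
    funnel$de_fpkm_engine <- cons$summary$n_sig_fpkm
    funnel$de_count_engine <- cons$summary$n_sig_counts
    funnel$de_consensus <- cons$summary$n_consensus
    if (!is.null(inputs$splicing_genes))
      report$isoform_overlap <- isoform_overlap(
        inputs$splicing_genes, cons$table$gene[cons$table$consensus], fp)
    .write_stage(cons$table, "de_consensus", opts)
  }

  ## TF network ----------------------------------------------------------
  if (st("network") && !is.null(inputs$ppi_edges)) {
    net <- build_tf_network(expressed_tfs, inputs$ppi_edges)
    if (!is.null(inputs$paralogs))
      net <- add_paralogs(net, inputs$paralogs, expressed_tfs)
    report$network <- net
    report$network_summary <- summarize_network(net)
    funnel$network_nodes <- report$network_summary$n_nodes
    funnel$network_edges <- report$network_summary$n_edges
    .write_stage(net$edges, "network_edges", opts)
  }

  report$funnel <- funnel
  report
}

#' Simulate a full study and run the pipeline on it
#'
#' Generates every input from a [sim_config()], builds three scanning
#' configurations as nested sub-windows of the simulated promoters, runs
#' [run_all()], and scores recovery of the planted ground truth.
#'
#' @param sim_cfg a [sim_config()].
#' @param opts a [run_options()] list (its seed defaults to the
#'   simulation's).
#' @return the [run_all()] report with an extra `recovery` element
#'   (footprint jaccard, regulator precision/recall, DE FDR/power,
#'   methylation separation) and the `truth`.
#' @export
simulate_and_run <- function(sim_cfg, opts = NULL) {
  if (is.null(opts)) opts <- run_options(seed = sim_cfg$seed)
  sim <- gen_expression(sim_cfg)
  pssms <- gen_pssms(sim$truth$tf_ids, width = sim_cfg$motif_width,
                     seed = sim_cfg$seed)
  prom <- gen_promoters(sim_cfg, pssms, sim$truth, alpha = opts$alpha)
  meth <- gen_methylation(sim_cfg, sim$truth)
  ppi <- gen_ppi(sim_cfg, sim$truth$tf_ids)

  seqs <- as.character(prom$sequences)
  L <- sim_cfg$promoter_length
  configs <- list(
    config1 = seqs,
    config2 = vapply(seqs, substr, character(1), 1L, ceiling(0.6 * L)),
    config3 = vapply(seqs, substr, character(1), floor(0.4 * L) + 1L, L))
  tf_map <- data.frame(matrix_id = names(pssms),
                       tf = vapply(pssms, `[[`, character(1), "tf"),
                       stringsAsFactors = FALSE, row.names = NULL)
  gene_sets <- list(TF = sim$truth$tf_ids)

  inputs <- list(fpkm = sim$fpkm, counts = sim$counts,
                 annotation = sim$annotation, gene_sets = gene_sets,
                 promoter_configs = configs, pssms = pssms, tf_map = tf_map,
                 methylation = meth, ppi_edges = ppi$edges,
                 paralogs = ppi$paralogs)
  report <- run_all(inputs, opts)
  report$truth <- sim$truth
  report$recovery <- recovery_metrics(report, sim$truth)
  report
}

#' Score a pipeline report against planted ground truth
#'
#' @param report a [run_all()] report.
#' @param truth the `truth` element from [gen_expression()].
#' @return list of recovery metrics (NULL entries for skipped stages).
#' @export
recovery_metrics <- function(report, truth) {
  out <- list()
  fp <- report$footprint$genes
  tp <- length(intersect(fp, truth$expressed_gene_ids))
  out$footprint_precision <- if (length(fp)) tp / length(fp) else NA_real_
  out$footprint_recall <- tp / max(1, length(truth$expressed_gene_ids))
  if (!is.null(report$consensus)) {
    sel <- report$consensus$tf[report$consensus$selected]
    tr <- truth$regulator_tf_ids
    out$regulator_precision <- if (length(sel))
      length(intersect(sel, tr)) / length(sel) else NA_real_
    out$regulator_recall <- if (length(tr))
      length(intersect(sel, tr)) / length(tr) else NA_real_
  }
  if (!is.null(report$de)) {
    called <- report$de$table$gene[report$de$table$consensus]
    fp_de <- setdiff(called, truth$de_gene_ids)
    out$de_called <- length(called)
    out$de_fdr <- if (length(called)) length(fp_de) / length(called) else 0
    out$de_power <- if (length(truth$de_gene_ids))
      length(intersect(called, truth$de_gene_ids)) /
        length(truth$de_gene_ids) else NA_real_
  }
  if (!is.null(report$methylation)) {
    all_rows <- report$methylation[report$methylation$region == "all", ]
    out$methyl_max_p <- max(all_rows$p)
    out$methyl_hypomethylated <- all(all_rows$median_target <
                                       all_rows$median_control)
  }
  out
}
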