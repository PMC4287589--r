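# Seeded generators for every input the pipeline consumes, with planted
# ground truth so downstream modules can be tested for recovery.
#
# All generators draw from an isolated RNG stream (withr::with_seed) using
# cfg$seed plus a fixed per-generator offset, so the same SimConfig always
# yields byte-identical output and generators do not perturb the caller's RNG.

.SEED_EXPR <- 0L
.SEED_PSSM <- 1L
.SEED_PROM <- 2L
.SEED_METH <- 3L
.SEED_PPI  <- 4L

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults describe
#' a two-tissue (bone marrow vs placenta) MSC experiment with three
#' replicates per tissue and a bimodal log2 FPKM distribution whose expressed
#' and unexpressed components are well separated, so that an expression
#' cut-off behaves as it does on real bulk RNA-seq density plots.
#'
#' @param n_genes total number of gene loci.
#' @param n_samples_per_group biological replicates per tissue group.
#' @param groups two tissue labels; first is the reference in fold changes.
#' @param expressed_fraction fraction of genes drawn from the expressed
#'   component.
#' @param expressed_log2fpkm_mean,expressed_log2fpkm_sd location/spread of
#'   per-gene mean log2 FPKM for expressed genes.
#' @param unexpressed_log2fpkm_mean,unexpressed_log2fpkm_sd same for the
#'   unexpressed component.
#' @param sample_log2_sd replicate-to-replicate noise on log2 FPKM.
#' @param n_de_genes number of expressed genes given a planted fold change.
#' @param de_log2fc magnitude of the planted log2 fold change (sign is
#'   random per gene; applied to the second group).
#' @param n_tfs number of genes annotated as transcription factors.
#' @param n_regulator_tfs TFs whose binding motifs are planted in promoters.
#' @param motif_width planted motif width in bases.
#' @param motif_planting_rate fraction of expressed-gene promoters that carry
#'   a planted site per regulator.
#' @param promoter_length promoter sequence length in bases.
#' @param n_cpg_per_gene CpG probes simulated per TF gene.
#' @param hypomethyl_beta_mean expected Beta value of CpGs on the
#'   hypomethylated (expressed-TF) genes.
#' @param control_beta_mean expected Beta value on remaining TF genes.
#' @param beta_sd per-sample noise on the Beta scale.
#' @param ppi_edge_prob probability that a TF pair has a reported
#'   protein-protein interaction.
#' @param seed integer seed controlling every generator.
#' @return a `SimConfig` list (validated).
#' @export
sim_config <- function(n_genes = 10000,
                       n_samples_per_group = 3,
                       groups = c("BM", "PL"),
                       expressed_fraction = 0.5,
                       expressed_log2fpkm_mean = 5,
                       expressed_log2fpkm_sd = 1.5,
                       unexpressed_log2fpkm_mean = -3,
                       unexpressed_log2fpkm_sd = 1,
                       sample_log2_sd = 0.25,
                       n_de_genes = 100,
                       de_log2fc = 3,
                       n_tfs = 20,
                       n_regulator_tfs = 5,
                       motif_width = 10,
                       motif_planting_rate = 0.5,
                       promoter_length = 2000,
                       n_cpg_per_gene = 5,
                       hypomethyl_beta_mean = 0.1,
                       control_beta_mean = 0.6,
                       beta_sd = 0.05,
                       ppi_edge_prob = 0.1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              groups = as.character(groups),
              expressed_fraction = expressed_fraction,
              expressed_log2fpkm_mean = expressed_log2fpkm_mean,
              expressed_log2fpkm_sd = expressed_log2fpkm_sd,
              unexpressed_log2fpkm_mean = unexpressed_log2fpkm_mean,
              unexpressed_log2fpkm_sd = unexpressed_log2fpkm_sd,
              sample_log2_sd = sample_log2_sd,
              n_de_genes = as.integer(n_de_genes),
              de_log2fc = de_log2fc,
              n_tfs = as.integer(n_tfs),
              n_regulator_tfs = as.integer(n_regulator_tfs),
              motif_width = as.integer(motif_width),
              motif_planting_rate = motif_planting_rate,
              promoter_length = as.integer(promoter_length),
              n_cpg_per_gene = as.integer(n_cpg_per_gene),
              hypomethyl_beta_mean = hypomethyl_beta_mean,
              control_beta_mean = control_beta_mean,
              beta_sd = beta_sd,
              ppi_edge_prob = ppi_edge_prob,
              seed = as.integer(seed))
  props <- c("expressed_fraction", "motif_planting_rate", "ppi_edge_prob",
             "hypomethyl_beta_mean", "control_beta_mean")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must lie in [0, 1]", p))
  }
  counts <- c("n_genes", "n_samples_per_group", "n_de_genes", "n_tfs",
              "n_regulator_tfs", "motif_width", "promoter_length",
              "n_cpg_per_gene")
  for (p in counts) {
    if (is.na(cfg[[p]]) || cfg[[p]] < 0)
      stop(sprintf("'%s' must be a non-negative count", p))
  }
  if (length(cfg$groups) != 2L) stop("'groups' must be a pair of labels")
  if (cfg$n_regulator_tfs > cfg$n_tfs)
    stop("n_regulator_tfs must not exceed n_tfs")
  if (cfg$n_tfs > cfg$n_genes) stop("n_tfs must not exceed n_genes")
  class(cfg) <- "SimConfig"
  cfg
}

#' Expression matrix container
#'
#' A thin wrapper pairing a non-negative gene x sample value matrix (FPKM or
#' read counts) with the tissue-group label of each sample.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param groups character vector of group labels, one per column.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values))) stop("values must carry gene ids as rownames")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (length(groups) != ncol(values))
    stop("one group label per sample required")
  structure(list(values = values,
                 groups = stats::setNames(as.character(groups),
                                          colnames(values))),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Generate FPKM and count matrices with planted ground truth
#'
#' Each gene's mean log2 FPKM is drawn from one of two Gaussian components
#' (expressed / unexpressed); replicate values add i.i.d. noise. Planted DE
#' genes receive a signed `de_log2fc` shift in the second group. Counts are
#' derived as `round(FPKM * gene_length_kb * library_size_millions)` with
#' per-sample library sizes, so the FPKM and count matrices describe the
#' same underlying experiment. FPKM below 2^-6 is floored to zero to mimic
#' undetected loci.
#'
#' @param cfg a [sim_config()] object.
#' @return list with elements `fpkm` and `counts` ([expression_matrix()]),
#'   `annotation` (gene_id, biotype, chrom, strand, tss, length_kb, is_tf)
#'   and `truth` (ground-truth ids and planted effects).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(cfg$seed + .SEED_EXPR, {
    n <- cfg$n_genes
    gene_ids <- sprintf("G%05d", seq_len(n))
    n_expr <- round(cfg$expressed_fraction * n)
    expressed <- sort(sample(n, n_expr))
    is_expr <- seq_len(n) %in% expressed
    if (cfg$n_de_genes > n_expr)
      stop("n_de_genes exceeds the number of expressed genes")

    mu <- ifelse(is_expr,
                 stats::rnorm(n, cfg$expressed_log2fpkm_mean,
                              cfg$expressed_log2fpkm_sd),
                 stats::rnorm(n, cfg$unexpressed_log2fpkm_mean,
                              cfg$unexpressed_log2fpkm_sd))

    de_idx <- if (cfg$n_de_genes > 0) sample(expressed, cfg$n_de_genes)
              else integer(0)
    de_sign <- sample(c(-1, 1), length(de_idx), replace = TRUE)
    de_shift <- numeric(n)
    de_shift[de_idx] <- de_sign * cfg$de_log2fc

    k <- cfg$n_samples_per_group
    sample_ids <- c(paste0(cfg$groups[1], "_", seq_len(k)),
                    paste0(cfg$groups[2], "_", seq_len(k)))
    groups <- rep(cfg$groups, each = k)

    log2fpkm <- matrix(mu, n, 2 * k) +
      matrix(stats::rnorm(n * 2 * k, 0, cfg$sample_log2_sd), n, 2 * k)
    # planted shift applied to the second tissue group only
    log2fpkm[, groups == cfg$groups[2]] <-
      log2fpkm[, groups == cfg$groups[2]] + de_shift
    fpkm <- 2^log2fpkm
    fpkm[fpkm < 2^-6] <- 0
    dimnames(fpkm) <- list(gene_ids, sample_ids)

    length_kb <- stats::runif(n, 0.5, 10)
    lib_m <- stats::runif(2 * k, 20, 50)           # library sizes, millions
    counts <- round(sweep(fpkm * length_kb, 2, lib_m, `*`))
    dimnames(counts) <- dimnames(fpkm)

    # TFs: at least n_regulator_tfs expressed; half from each component
    n_tf_expr <- max(cfg$n_regulator_tfs, ceiling(cfg$n_tfs / 2))
    n_tf_expr <- min(n_tf_expr, cfg$n_tfs, n_expr)
    tf_expr <- if (n_tf_expr > 0) sample(expressed, n_tf_expr) else integer(0)
    unexpr_pool <- setdiff(seq_len(n), expressed)
    n_tf_un <- min(cfg$n_tfs - n_tf_expr, length(unexpr_pool))
    tf_un <- if (n_tf_un > 0) sample(unexpr_pool, n_tf_un) else integer(0)
    tf_idx <- c(tf_expr, tf_un)
    regulators <- if (cfg$n_regulator_tfs > 0) tf_expr[seq_len(cfg$n_regulator_tfs)]
                  else integer(0)

    biotype <- ifelse(stats::runif(n) < 0.8, "protein_coding", "lincRNA")
    biotype[tf_idx] <- "protein_coding"
    annotation <- data.frame(
      gene_id = gene_ids,
      biotype = biotype,
      chrom = "chr1",
      strand = sample(c("+", "-"), n, replace = TRUE),
      tss = 100000L + (seq_len(n) - 1L) * 20000L,
      length_kb = length_kb,
      is_tf = seq_len(n) %in% tf_idx,
      stringsAsFactors = FALSE)

    truth <- list(
      gene_ids = gene_ids,
      expressed_gene_ids = gene_ids[expressed],
      de_gene_ids = gene_ids[de_idx],
      de_log2fc = stats::setNames(de_sign * cfg$de_log2fc, gene_ids[de_idx]),
      tf_ids = gene_ids[tf_idx],
      expressed_tf_ids = gene_ids[tf_expr],
      regulator_tf_ids = gene_ids[regulators],
      hypomethylated_gene_ids = gene_ids[tf_expr])

    list(fpkm = expression_matrix(fpkm, groups),
         counts = expression_matrix(counts, groups),
         annotation = annotation,
         truth = truth)
  })
}

#' Generate informative random motif matrices
#'
#' Produces JASPAR-style count matrices, one per TF, with a dominant base
#' per column (multinomial counts around an 85% dominant frequency), giving
#' roughly 1.2 bits of information per column — enough for confident
#' promoter scanning at typical widths.
#'
#' @param tf_ids TF identifiers; one matrix (`M001`, ...) is built per TF.
#' @param width motif width in bases.
#' @param seed integer seed.
#' @return named list of [build_pssm()] objects (names = matrix ids).
#' @export
gen_pssms <- function(tf_ids, width = 10, seed = 1L) {
  withr::with_seed(as.integer(seed) + .SEED_PSSM, {
    pssms <- list()
    for (i in seq_along(tf_ids)) {
      counts <- sapply(seq_len(width), function(j) {
        dom <- sample(4, 1)
        pr <- rep(0.05, 4); pr[dom] <- 0.85
        stats::rmultinom(1, 100, pr)[, 1]
      })
      rownames(counts) <- c("A", "C", "G", "T")
      id <- sprintf("M%03d", i)
      pssms[[id]] <- build_pssm(counts, id = id, tf = tf_ids[i])
    }
    pssms
  })
}

#' Generate promoter sequences with planted regulator binding sites
#'
#' Background bases are i.i.d. uniform over A/C/G/T. For every regulator TF
#' (a TF in `truth$regulator_tf_ids` with a matrix in `pssms`), a site is
#' sampled from its PSSM base frequencies — redrawn until it scores at or
#' above the default scan threshold — and planted at a recorded position and
#' strand in `motif_planting_rate` of the expressed-gene promoters.
#' Overlapping planted sites are resolved by position re-draw (at most 100
#' attempts, then error). Non-regulator motifs are never planted.
#'
#' @param cfg a [sim_config()] object.
#' @param pssms named list of PSSMs (from [gen_pssms()] or [read_jaspar()]).
#' @param truth ground truth from [gen_expression()].
#' @param alpha scan significance used to vet planted sites.
#' @param targets_by_tf optional named list (tf id -> gene ids) overriding
#'   the promoters a regulator's sites are planted into; the default is the
#'   expressed-gene set for every regulator.
#' @return list with `sequences` (named [Biostrings::DNAStringSet]) and
#'   `sites` (data.frame: gene, tf, matrix_id, position, strand).
#' @export
gen_promoters <- function(cfg, pssms, truth, alpha = 1e-4,
                          targets_by_tf = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$motif_width > cfg$promoter_length)
    stop("motif_width must not exceed promoter_length")
  withr::with_seed(cfg$seed + .SEED_PROM, {
    L <- cfg$promoter_length
    genes <- truth$gene_ids
    seqs <- vapply(genes, function(g)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))

    reg_pssms <- Filter(function(p) p$tf %in% truth$regulator_tf_ids, pssms)
    occupied <- lapply(stats::setNames(vector("list", length(genes)), genes),
                       function(x) integer(0))
    sites <- list()
    for (p in reg_pssms) {
      w <- p$width
      thr <- pssm_threshold(score_pvalue_table(p), alpha)
      pool <- if (!is.null(targets_by_tf) && p$tf %in% names(targets_by_tf))
        targets_by_tf[[p$tf]] else truth$expressed_gene_ids
      n_t <- round(cfg$motif_planting_rate * length(pool))
      targets <- if (n_t > 0) sample(pool, n_t) else character(0)
      for (g in targets) {
        site <- .draw_site(p, thr)
        pos <- NA_integer_
        for (attempt in seq_len(100)) {
          cand <- sample.int(L - w + 1L, 1)
          span <- cand:(cand + w - 1L)
          if (!any(span %in% occupied[[g]])) { pos <- cand; break }
        }
        if (is.na(pos))
          stop("could not place a non-overlapping site after 100 re-draws")
        occupied[[g]] <- c(occupied[[g]], pos:(pos + w - 1L))
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") site else .revcomp_chr(site)
        substr(seqs[[g]], pos, pos + w - 1L) <- ins
        sites[[length(sites) + 1L]] <- data.frame(
          gene = g, tf = p$tf, matrix_id = p$id, position = pos,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    sites <- if (length(sites)) do.call(rbind, sites)
             else data.frame(gene = character(0), tf = character(0),
                             matrix_id = character(0), position = integer(0),
                             strand = character(0))
    list(sequences = Biostrings::DNAStringSet(seqs), sites = sites)
  })
}

# sample a site from PSSM column frequencies; require score >= thr
# (scores quantized as in scan_pssm so the vetting matches the scanner)
.draw_site <- function(pssm, thr, granularity = 0.01) {
  qlo <- round(pssm$logodds / granularity) * granularity
  for (i in seq_len(100)) {
    idx <- apply(pssm$freq, 2, function(f) sample(4, 1, prob = f))
    sc <- sum(qlo[cbind(idx, seq_len(pssm$width))])
    if (sc >= thr)
      return(paste(c("A", "C", "G", "T")[idx], collapse = ""))
  }
  stop("could not draw a site above the scan threshold in 100 attempts")
}

.revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Generate an Illumina 450k-style methylation table
#'
#' Simulates `n_cpg_per_gene` CpG probes for every TF gene over five array
#' samples. A CpG's target Beta is its gene's class mean (hypomethylated
#' for expressed TFs, control otherwise) plus per-sample noise; intensities
#' are solved from the Illumina relation `Beta = M / (M + U + 100)` at a
#' fixed total intensity `M + U = 2000`, so the recomputed Beta of every
#' record equals its target. About 1% of CpGs receive detection p > 0.01.
#'
#' @param cfg a [sim_config()] object.
#' @param truth ground truth from [gen_expression()].
#' @param n_arrays number of array samples.
#' @return data.frame with columns `cpg`, `gene`, `region`, then
#'   `M_i`, `U_i`, `detp_i` for each sample i.
#' @export
gen_methylation <- function(cfg, truth, n_arrays = 5) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(cfg$seed + .SEED_METH, {
    genes <- rep(truth$tf_ids, each = cfg$n_cpg_per_gene)
    ncpg <- length(genes)
    regions <- c("island", "N-shore", "S-shore", "N-shelf", "S-shelf",
                 "open-sea")
    out <- data.frame(
      cpg = sprintf("cg%07d", seq_len(ncpg)),
      gene = genes,
      region = if (ncpg) sample(regions, ncpg, replace = TRUE,
                                prob = c(.3, .15, .15, .1, .1, .2))
               else character(0),
      stringsAsFactors = FALSE)
    target <- ifelse(genes %in% truth$hypomethylated_gene_ids,
                     cfg$hypomethyl_beta_mean, cfg$control_beta_mean)
    total <- 2000
    for (s in seq_len(n_arrays)) {
      b <- pmin(pmax(target + stats::rnorm(ncpg, 0, cfg$beta_sd), 0), 0.95)
      M <- round(b * (total + 100))
      out[[paste0("M_", s)]] <- M
      out[[paste0("U_", s)]] <- total - M
      fail <- stats::runif(ncpg) < 0.01
      out[[paste0("detp_", s)]] <- ifelse(fail,
                                          stats::runif(ncpg, 0.011, 0.5),
                                          stats::runif(ncpg, 0, 0.009))
    }
    out
  })
}

#' Generate a TF-TF protein-interaction edge list and paralogy table
#'
#' Every unordered TF pair becomes an edge with probability `ppi_edge_prob`;
#' evidence counts are `1 + Poisson(1.5)`. A small random paralogy table
#' over the same TFs is returned alongside.
#'
#' @param cfg a [sim_config()] object.
#' @param tf_ids TF identifiers to wire.
#' @return list with `edges` (tf_a, tf_b, evidence) and `paralogs`
#'   (tf_a, tf_b).
#' @export
gen_ppi <- function(cfg, tf_ids) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(cfg$seed + .SEED_PPI, {
    if (length(tf_ids) < 2) {
      return(list(edges = data.frame(tf_a = character(0), tf_b = character(0),
                                     evidence = integer(0)),
                  paralogs = data.frame(tf_a = character(0),
                                        tf_b = character(0))))
    }
    pairs <- t(utils::combn(tf_ids, 2))
    keep <- stats::runif(nrow(pairs)) < cfg$ppi_edge_prob
    edges <- data.frame(tf_a = pairs[keep, 1], tf_b = pairs[keep, 2],
                        evidence = 1L + stats::rpois(sum(keep), 1.5),
                        stringsAsFactors = FALSE)
    n_par <- max(1L, length(tf_ids) %/% 5L)
    par_pairs <- pairs[sample(nrow(pairs), min(n_par, nrow(pairs))), ,
                       drop = FALSE]
    list(edges = edges,
         paralogs = data.frame(tf_a = par_pairs[, 1], tf_b = par_pairs[, 2],
                               stringsAsFactors = FALSE))
  })
}
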