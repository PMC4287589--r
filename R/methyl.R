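# Illumina 450k Beta-value profiling: the Beta formula, detection-p
# filtering, per-CpG medians, island sub-region stratification, and the
# comparison of a target TF set against random TF control sets.

#' Illumina Beta value
#'
#' `Beta = M / (M + U + 100)`, the standard offset formula; always in
#' `[0, 1)` for non-negative intensities.
#'
#' @param M methylated signal intensity (>= 0).
#' @param U unmethylated signal intensity (>= 0).
#' @return numeric Beta value(s).
#' @export
beta_value <- function(M, U) {
  if (any(M < 0) || any(U < 0)) stop("intensities must be non-negative")
  M / (M + U + 100)
}

.meth_cols <- function(records, prefix) {
  grep(paste0("^", prefix, "_[0-9]+$"), names(records), value = TRUE)
}

#' Filter CpGs by detection p-value
#'
#' Removes CpG rows whose detection p-value exceeds the cutoff in any
#' sample (boundary kept: only p strictly greater than the cutoff is
#' removed).
#'
#' @param records methylation table as produced by [gen_methylation()]
#'   (columns `cpg`, `gene`, `region`, then per-sample `M_i`, `U_i`,
#'   `detp_i`).
#' @param cutoff detection p cutoff.
#' @return the filtered table.
#' @export
filter_detection <- function(records, cutoff = 0.01) {
  dcols <- .meth_cols(records, "detp")
  if (!nrow(records) || !length(dcols)) return(records)
  bad <- Reduce(`|`, lapply(dcols, function(cl) records[[cl]] > cutoff))
  records[!bad, , drop = FALSE]
}

#' Per-CpG Beta values and cross-sample medians
#'
#' @param records methylation table (see [filter_detection()]).
#' @return data.frame `cpg`, `gene`, `region`, per-sample `beta_i` columns,
#'   and `beta_median` (even sample counts use the mean of the central
#'   pair).
#' @export
median_beta <- function(records) {
  mcols <- .meth_cols(records, "M")
  out <- records[, c("cpg", "gene", "region"), drop = FALSE]
  betas <- sapply(seq_along(mcols), function(i)
    beta_value(records[[paste0("M_", i)]], records[[paste0("U_", i)]]))
  if (nrow(records) == 1) betas <- matrix(betas, nrow = 1)
  if (!nrow(records)) {
    out$beta_median <- numeric(0)
    return(out)
  }
  colnames(betas) <- paste0("beta_", seq_along(mcols))
  out <- cbind(out, as.data.frame(betas))
  out$beta_median <- apply(betas, 1, stats::median)
  out
}

#' Compare methylation of a target TF set against random TF control sets
#'
#' Draws `n_random` control sets of the same size as the target, without
#' replacement, from the non-target TF universe; compares per-CpG median
#' Beta values with two-sided Wilcoxon rank-sum tests, overall and within
#' each CpG island sub-region (island, shores, shelves, open sea).
#'
#' @param records methylation table (apply [filter_detection()] first).
#' @param target_tf_genes gene ids of the target (e.g. expressed) TFs.
#' @param universe_tf_genes gene ids of the TFs the controls are drawn
#'   from; targets are excluded automatically. Supply the not-expressed
#'   TFs for the stricter control mode, or all TFs for the loose mode.
#' @param n_random number of control sets (> 0).
#' @param seed integer seed for the control draws.
#' @return data.frame: `region`, `control_set`, sizes, median Beta of each
#'   side, `W`, `p`.
#' @export
compare_tf_sets <- function(records, target_tf_genes, universe_tf_genes,
                            n_random = 3, seed = 1L) {
  if (n_random < 1) stop("at least one random control set is required")
  pool <- setdiff(unique(universe_tf_genes), target_tf_genes)
  target_tf_genes <- unique(target_tf_genes)
  if (length(pool) < length(target_tf_genes))
    stop("fewer non-target TFs than targets; cannot draw control sets")
  med <- median_beta(records)
  regions <- c("all", sort(unique(med$region)))
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (r in seq_len(n_random)) {
      ctrl <- sample(pool, length(target_tf_genes))
      for (reg in regions) {
        sub <- if (reg == "all") med else med[med$region == reg, , drop = FALSE]
        tb <- sub$beta_median[sub$gene %in% target_tf_genes]
        cb <- sub$beta_median[sub$gene %in% ctrl]
        if (!length(tb) || !length(cb)) next
        # normal approximation with tie correction: intensity-derived Beta
        # medians are quantized, so ties are structural
        wt <- stats::wilcox.test(tb, cb, alternative = "two.sided",
                                 exact = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          region = reg, control_set = r, n_target = length(tb),
          n_control = length(cb),
          median_target = stats::median(tb),
          median_control = stats::median(cb),
          W = unname(wt$statistic), p = wt$p.value,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
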