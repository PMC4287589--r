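# Expression-footprint calling: per-tissue FPKM summaries, the lower-tail
# quantile (or fixed) threshold on log2 mean FPKM, and the footprint set.

#' Summarize an FPKM matrix per tissue and across all samples
#'
#' Per gene: `log2` of the FPKM sum within each tissue group, and `log2` of
#' the mean FPKM across all samples. Zero aggregates cannot be represented
#' on the log scale and are reported as `NA` with `detected = FALSE`
#' (a "not detected" sentinel excluded from density and quantile work).
#'
#' @param mat an [expression_matrix()] of FPKM values.
#' @return data.frame with `gene_id`, one `log2_sum_<group>` column per
#'   group, `log2_mean`, and `detected`.
#' @export
summarize_expression <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  grp <- mat$groups
  labels <- unique(grp)
  out <- data.frame(gene_id = rownames(mat$values),
                    stringsAsFactors = FALSE)
  for (g in labels) {
    s <- rowSums(mat$values[, grp == g, drop = FALSE])
    out[[paste0("log2_sum_", g)]] <- ifelse(s > 0, log2(s), NA_real_)
  }
  m <- rowMeans(mat$values)
  out$log2_mean <- ifelse(m > 0, log2(m), NA_real_)
  out$detected <- m > 0
  out
}

#' Lower-tail quantile threshold on positive log2 mean FPKM
#'
#' The threshold retaining the upper `1 - q` of the distribution of log2
#' mean FPKM, computed only over genes with positive log2 means (i.e. mean
#' FPKM > 1). Linear interpolation between order statistics.
#'
#' @param log2_means numeric vector of per-gene log2 mean FPKM (NAs allowed).
#' @param q lower-tail fraction to exclude.
#' @return numeric threshold.
#' @export
quantile_threshold <- function(log2_means, q = 0.05) {
  x <- log2_means[!is.na(log2_means) & log2_means > 0]
  if (!length(x)) stop("no positive log2 mean values to threshold")
  unname(stats::quantile(x, probs = q, type = 7))
}

#' Call the expression footprint
#'
#' Genes whose log2 mean FPKM is at or above the threshold (boundary
#' inclusive), optionally restricted to a biotype (typically
#' `"protein_coding"`).
#'
#' @param summary output of [summarize_expression()].
#' @param threshold numeric log2 mean FPKM cut-off (the fixed value 2
#'   corresponds to 4 FPKM, roughly one transcript per cell), or `"auto"`
#'   to apply [quantile_threshold()] at `q`.
#' @param annotation optional data.frame with `gene_id` and `biotype`,
#'   required when `biotype_filter` is given.
#' @param biotype_filter optional biotype to keep.
#' @param q lower-tail fraction for `threshold = "auto"`.
#' @return a `Footprint` object: list with `genes`, `table`, `threshold`,
#'   `biotype_filter`.
#' @export
call_footprint <- function(summary, threshold = 2, annotation = NULL,
                           biotype_filter = NULL, q = 0.05) {
  if (identical(threshold, "auto"))
    threshold <- quantile_threshold(summary$log2_mean, q)
  keep <- !is.na(summary$log2_mean) & summary$log2_mean >= threshold
  tab <- summary[keep, , drop = FALSE]
  if (!is.null(biotype_filter)) {
    if (is.null(annotation)) stop("biotype filtering requires an annotation")
    missing <- setdiff(tab$gene_id, annotation$gene_id)
    if (length(missing))
      stop("annotation does not cover all footprint genes")
    bt <- annotation$biotype[match(tab$gene_id, annotation$gene_id)]
    tab <- tab[bt == biotype_filter, , drop = FALSE]
  }
  structure(list(genes = tab$gene_id, table = tab, threshold = threshold,
                 biotype_filter = biotype_filter),
            class = "Footprint")
}

#' @export
print.Footprint <- function(x, ...) {
  cat(sprintf("Footprint: %d genes at log2 mean FPKM >= %.3f%s\n",
              length(x$genes), x$threshold,
              if (!is.null(x$biotype_filter))
                paste0(" (", x$biotype_filter, ")") else ""))
  invisible(x)
}

#' Report per-tissue log2 FPKM sums for marker genes
#'
#' @param summary output of [summarize_expression()].
#' @param marker_ids gene ids to report.
#' @return data.frame, one row per marker, with the `log2_sum_*` columns
#'   and `detected`; markers absent from the summary get all-NA rows with
#'   `detected = FALSE`.
#' @export
report_markers <- function(summary, marker_ids) {
  idx <- match(marker_ids, summary$gene_id)
  cols <- grep("^log2_sum_", names(summary), value = TRUE)
  out <- data.frame(gene_id = marker_ids, stringsAsFactors = FALSE)
  for (cl in cols) out[[cl]] <- summary[[cl]][idx]
  out$detected <- ifelse(is.na(idx), FALSE, summary$detected[idx])
  out
}
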