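# Two independent differential-expression engines (an FPKM-scale moderated
# t on log2(FPKM + 1), and a negative-binomial count engine with
# median-of-ratios size factors), BH adjustment, the asymmetric-threshold
# consensus intersection with direction checks, and isoform-overlap
# statistics.

.two_group <- function(mat) {
  labels <- unique(mat$groups)
  if (length(labels) != 2) stop("exactly two groups required")
  labels
}

#' FPKM-scale differential expression engine
#'
#' Per gene, a Welch two-sample t test on `log2(FPKM + pseudo)`; the fold
#' change is `log2(mean_B + pseudo) - log2(mean_A + pseudo)` on the FPKM
#' scale (second group over first). The pseudocount bounds fold changes of
#' near-zero genes; its default of 0.25 FPKM sits at the detection-floor
#' scale, small enough to keep planted fold changes nearly unattenuated in
#' the expressed component. Genes with no variance and no mean difference
#' get p = 1.
#'
#' @param mat an [expression_matrix()] of FPKM values.
#' @param pseudo pseudo-FPKM added before the log transform.
#' @return data.frame: `gene`, `engine`, `log2fc`, `p`, `q`.
#' @export
fpkm_engine <- function(mat, pseudo = 0.25) {
  labels <- .two_group(mat)
  a <- mat$values[, mat$groups == labels[1], drop = FALSE]
  b <- mat$values[, mat$groups == labels[2], drop = FALSE]
  la <- log2(a + pseudo); lb <- log2(b + pseudo)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  se2 <- va / na + vb / nb
  t_stat <- (mb - ma) / sqrt(pmax(se2, 1e-16))
  df <- se2^2 / pmax(va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)),
                     1e-300)
  df[!is.finite(df) | df <= 0] <- 1        # zero-variance degenerate genes
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[se2 < 1e-16 & abs(mb - ma) < 1e-12] <- 1
  p <- pmin(p, 1)
  data.frame(gene = rownames(mat$values), engine = "fpkm_engine",
             log2fc = log2(rowMeans(b) + pseudo) -
               log2(rowMeans(a) + pseudo),
             p = p, q = bh_adjust(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Median-of-ratios size factors
#'
#' Per sample, the median across genes of the ratio of its counts to the
#' per-gene geometric mean; genes with a zero anywhere are excluded from
#' the reference.
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) stop("no gene has all-positive counts")
  apply(counts[use, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - loggeo[use])))
}

#' Negative-binomial count engine
#'
#' Size factors by median-of-ratios; per-gene dispersion by method of
#' moments on normalized counts, pooled across the two groups; the test is
#' an exact-style two-sided negative-binomial tail on the group A count sum
#' under the pooled rate (twice the smaller tail, capped at 1). Dispersion
#' zero reduces to a Poisson tail.
#'
#' @param mat an [expression_matrix()] of read counts.
#' @return data.frame: `gene`, `engine`, `log2fc`, `p`, `q`; size factors
#'   in attribute `"size_factors"`.
#' @export
count_engine <- function(mat) {
  labels <- .two_group(mat)
  counts <- mat$values
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  ia <- mat$groups == labels[1]; ib <- mat$groups == labels[2]

  base_mean <- rowMeans(norm)
  wa <- apply(norm[, ia, drop = FALSE], 1, stats::var)
  wb <- apply(norm[, ib, drop = FALSE], 1, stats::var)
  w <- (wa + wb) / 2                       # pooled within-group variance
  z <- base_mean * mean(1 / sf)            # expected shot-noise variance
  disp <- pmax((w - z) / base_mean^2, 1e-8)
  disp[!is.finite(disp)] <- 1e-8

  ka <- rowSums(counts[, ia, drop = FALSE])
  kb <- rowSums(counts[, ib, drop = FALSE])
  sa <- sum(sf[ia]); sb <- sum(sf[ib])
  q0 <- (ka + kb) / (sa + sb)              # pooled normalized rate
  mu_a <- q0 * sa
  # variance of the group A sum: shot noise plus overdispersion per sample
  var_a <- q0 * sa + disp * q0^2 * sum(sf[ia]^2)
  size_a <- ifelse(var_a > mu_a, mu_a^2 / (var_a - mu_a), Inf)

  p_lo <- ifelse(is.finite(size_a),
                 stats::pnbinom(ka, mu = mu_a, size = size_a),
                 stats::ppois(ka, mu_a))
  p_hi <- ifelse(is.finite(size_a),
                 stats::pnbinom(ka - 1, mu = mu_a, size = size_a,
                                lower.tail = FALSE),
                 stats::ppois(ka - 1, mu_a, lower.tail = FALSE))
  p <- pmin(1, 2 * pmin(p_lo, p_hi))
  p[ka + kb == 0] <- 1

  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  out <- data.frame(gene = rownames(counts), engine = "count_engine",
                    log2fc = log2((mean_b + 0.5) / (mean_a + 0.5)),
                    p = p, q = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "size_factors") <- sf
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j>=i) m p_(j) / j`, capped at 1,
#' in the input order.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Consensus of the two differential-expression engines
#'
#' The consensus set holds genes significant in both engines at per-engine
#' q thresholds (asymmetric by default: the count engine is far less
#' stringent, so its cut-off is tighter). Direction is taken from the FPKM
#' engine; genes whose engines disagree in sign are kept but flagged.
#'
#' @param res_fpkm,res_counts outputs of [fpkm_engine()] and
#'   [count_engine()].
#' @param q_fpkm,q_counts per-engine q-value thresholds.
#' @return list with `table` (per-gene merged results, `consensus` and
#'   `direction_disagreement` flags) and `summary` (counts: per-engine
#'   significant, consensus size, overlap percentage of the FPKM-engine
#'   set, up/down in the second group, disagreements).
#' @export
consensus_de <- function(res_fpkm, res_counts, q_fpkm = 0.05,
                         q_counts = 0.001) {
  m <- merge(res_fpkm[, c("gene", "log2fc", "p", "q")],
             res_counts[, c("gene", "log2fc", "p", "q")],
             by = "gene", suffixes = c("_fpkm", "_counts"))
  m$sig_fpkm <- m$q_fpkm < q_fpkm
  m$sig_counts <- m$q_counts < q_counts
  m$consensus <- m$sig_fpkm & m$sig_counts
  m$direction <- sign(m$log2fc_fpkm)
  m$direction_disagreement <- m$consensus &
    sign(m$log2fc_fpkm) * sign(m$log2fc_counts) < 0
  n_a <- sum(m$sig_fpkm); n_b <- sum(m$sig_counts)
  n_c <- sum(m$consensus)
  summary <- list(
    n_sig_fpkm = n_a,
    n_sig_counts = n_b,
    n_consensus = n_c,
    pct_of_fpkm_engine = if (n_a > 0) 100 * n_c / n_a else NA_real_,
    n_up_second_group = sum(m$consensus & m$log2fc_fpkm > 0),
    n_down_second_group = sum(m$consensus & m$log2fc_fpkm < 0),
    n_direction_disagreement = sum(m$direction_disagreement),
    q_fpkm = q_fpkm, q_counts = q_counts)
  list(table = m, summary = summary)
}

#' Overlap of differential-splicing genes with footprint and DE signature
#'
#' Pure set intersections with percentages: the footprint overlap is
#' expressed relative to the footprint, the signature overlap relative to
#' the consensus DE set.
#'
#' @param splicing_genes genes with differential isoform usage.
#' @param consensus_genes the consensus DE signature.
#' @param footprint_genes the expression footprint (or a
#'   [call_footprint()] object).
#' @return list of counts and percentages.
#' @export
isoform_overlap <- function(splicing_genes, consensus_genes,
                            footprint_genes) {
  if (inherits(footprint_genes, "Footprint"))
    footprint_genes <- footprint_genes$genes
  splicing_genes <- unique(splicing_genes)
  in_fp <- intersect(splicing_genes, footprint_genes)
  in_sig <- intersect(splicing_genes, consensus_genes)
  list(n_splicing = length(splicing_genes),
       n_in_footprint = length(in_fp),
       pct_of_footprint = if (length(footprint_genes))
         100 * length(in_fp) / length(footprint_genes) else 0,
       n_in_signature = length(in_sig),
       pct_of_signature = if (length(consensus_genes))
         100 * length(in_sig) / length(consensus_genes) else 0)
}
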