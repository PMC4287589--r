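# Gene-set handling: GMT IO, hypergeometric over-representation of reference
# sets (housekeeping, stem-cell, transcription-factor) in the footprint, and
# rank-sum comparison of expression levels between functional categories.

#' Read a GMT gene-set file
#' @param path file path.
#' @return named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param source description field (second GMT column).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, source = "mscportrait") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, source, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a gene set in the footprint
#'
#' Upper-tail test of the overlap `k` between a reference set (size `n`)
#' and the footprint (size `K`) within a universe of `N` genes:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. Ids outside the
#' universe are dropped (count reported in the result).
#'
#' @param set character vector of member gene ids (or a named list element).
#' @param footprint character vector of footprint gene ids, or a
#'   [call_footprint()] object.
#' @param universe character vector of all annotated gene ids.
#' @param name label for the output row.
#' @return one-row data.frame: `set`, `N`, `K`, `n`, `k`, `dropped`, `p`.
#' @export
hypergeom_test <- function(set, footprint, universe, name = "set") {
  if (inherits(footprint, "Footprint")) footprint <- footprint$genes
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  set <- unique(set)
  dropped <- sum(!set %in% universe)
  set <- intersect(set, universe)
  fp <- intersect(unique(footprint), universe)
  k <- length(intersect(set, fp))
  N <- length(universe); K <- length(fp); n <- length(set)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(set = name, N = N, K = K, n = n, k = k, dropped = dropped,
             p = p, stringsAsFactors = FALSE)
}

#' Test several gene sets against the footprint
#'
#' Runs [hypergeom_test()] per set and adds Benjamini-Hochberg `q` values
#' across sets (raw `p` is retained alongside).
#'
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param footprint footprint genes or [call_footprint()] object.
#' @param universe all annotated gene ids.
#' @return data.frame, one row per set, with `p` and `q`.
#' @export
enrich_sets <- function(sets, footprint, universe) {
  rows <- mapply(function(s, nm) hypergeom_test(s, footprint, universe, nm),
                 sets, names(sets), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out
}

#' Compare expression distributions between functional categories
#'
#' Pairwise two-sided Wilcoxon rank-sum tests between the log2 expression
#' values of each category (exact for small samples without ties, normal
#' approximation with continuity and tie correction otherwise).
#'
#' @param values_by_category named list of numeric vectors (e.g. log2 mean
#'   FPKM of housekeeping, stem-cell and TF genes).
#' @return data.frame: `set_a`, `set_b`, `n_a`, `n_b`, `W`, `p`.
#' @export
compare_categories <- function(values_by_category) {
  nms <- names(values_by_category)
  if (length(nms) < 2) stop("need at least two categories")
  pairs <- utils::combn(nms, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- values_by_category[[pr[1]]]; b <- values_by_category[[pr[2]]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    wt <- stats::wilcox.test(a, b, alternative = "two.sided")
    data.frame(set_a = pr[1], set_b = pr[2], n_a = length(a),
               n_b = length(b), W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
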