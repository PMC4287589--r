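# Position-specific scoring matrices: construction from counts, JASPAR
# round-trip, the exact score distribution under the background model
# (dynamic programming on discretized log-odds), and promoter scanning.

.BASES <- c("A", "C", "G", "T")

#' Build a PSSM from a base-count matrix
#'
#' Frequencies use background-proportional pseudocounts:
#' `freq(b,i) = (count(b,i) + pc * bg(b)) / (colsum(i) + pc)`; log-odds are
#' `log2(freq / bg)`.
#'
#' @param counts 4 x w numeric matrix of non-negative base counts; rows
#'   A, C, G, T (rownames optional in that order).
#' @param background base composition, length 4 summing to 1.
#' @param pseudocount_total total pseudocount mass per column.
#' @param id,tf matrix identifier and the TF the matrix belongs to.
#' @return a `Pssm` object (counts, background, freq, logodds, width).
#' @export
build_pssm <- function(counts, background = rep(0.25, 4),
                       pseudocount_total = 1.0, id = NA_character_,
                       tf = NA_character_) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!isTRUE(all.equal(sum(background), 1)))
    stop("background must sum to 1")
  if (!is.null(rownames(counts)) && !identical(rownames(counts), .BASES))
    counts <- counts[.BASES, , drop = FALSE]
  rownames(counts) <- .BASES
  colsums <- colSums(counts)
  freq <- sweep(counts + pseudocount_total * background, 2,
                colsums + pseudocount_total, `/`)
  logodds <- log2(freq / background)
  structure(list(id = id, tf = tf, width = ncol(counts), counts = counts,
                 background = background, freq = freq, logodds = logodds),
            class = "Pssm")
}

#' @export
print.Pssm <- function(x, ...) {
  cat(sprintf("Pssm %s (TF %s): width %d, IC %.1f bits\n",
              x$id, x$tf, x$width, pssm_ic(x)))
  invisible(x)
}

#' Total information content of a PSSM in bits
#' @param pssm a [build_pssm()] object.
#' @return numeric scalar.
#' @export
pssm_ic <- function(pssm) {
  sum(pssm$freq * pssm$logodds)
}

#' Reverse-complement a PSSM
#' @param pssm a [build_pssm()] object.
#' @return the PSSM of the opposite strand.
#' @export
pssm_revcomp <- function(pssm) {
  counts <- pssm$counts[4:1, rev(seq_len(pssm$width)), drop = FALSE]
  rownames(counts) <- .BASES
  build_pssm(counts, background = pssm$background[4:1],
             id = pssm$id, tf = pssm$tf)
}

#' Read a JASPAR-format motif file
#'
#' Accepts the standard bracketed layout:
#' \preformatted{>MA0004.1 ARNT
#' A [ 4 19 0 0 0 0 ]
#' ...}
#'
#' @param path file path.
#' @param background,pseudocount_total passed to [build_pssm()].
#' @return named list of PSSMs (names = matrix ids).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4),
                        pseudocount_total = 1.0) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no JASPAR records found in ", path)
  out <- list()
  for (h in seq_along(headers)) {
    i <- headers[h]
    fields <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]]
    id <- fields[1]
    tf <- if (length(fields) > 1) fields[2] else NA_character_
    rows <- lines[(i + 1):(i + 4)]
    counts <- t(vapply(rows, function(r) {
      nums <- gsub("[][A-Za-z]", " ", r)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub("[][A-Za-z]", " ", rows[1])),
                               "\\s+")[[1]]))))
    rownames(counts) <- toupper(substr(trimws(rows), 1, 1))
    out[[id]] <- build_pssm(counts[.BASES, , drop = FALSE],
                            background = background,
                            pseudocount_total = pseudocount_total,
                            id = id, tf = tf)
  }
  out
}

#' Write PSSM count matrices in JASPAR format
#' @param pssms list of PSSMs.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pssms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pssms) {
    writeLines(sprintf(">%s %s", p$id, p$tf), con)
    for (b in .BASES)
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Exact score distribution of a PSSM under its background
#'
#' Dynamic programming over motif positions on log-odds scores discretized
#' to a fixed granularity: the probability mass function of the score of a
#' random background word of the motif's width.
#'
#' @param pssm a [build_pssm()] object.
#' @param granularity score discretization step in log-odds (log2) units.
#' @return list with `score` (ascending grid), `pmf`, and `granularity`.
#' @export
score_pvalue_table <- function(pssm, granularity = 0.01) {
  ilo <- round(pssm$logodds / granularity)   # integer scores per base/column
  lo_min <- cumsum(apply(ilo, 2, min))
  lo_max <- cumsum(apply(ilo, 2, max))
  # pmf over integer grid, tracked with explicit offset
  pmf <- 1
  offset <- 0                                # score of pmf[1]
  for (j in seq_len(pssm$width)) {
    new_off <- offset + min(ilo[, j])
    new_len <- (offset + max(ilo[, j])) - new_off + length(pmf)
    acc <- numeric(new_len)
    for (b in 1:4) {
      sh <- offset + ilo[b, j] - new_off
      idx <- seq_along(pmf) + sh
      acc[idx] <- acc[idx] + pssm$background[b] * pmf
    }
    pmf <- acc
    offset <- new_off
  }
  keep <- pmf > 0
  list(score = (offset + which(keep) - 1L) * granularity,
       pmf = pmf[keep],
       granularity = granularity)
}

#' Score threshold at a tail probability
#'
#' Smallest score `s` on the table's grid with `P(score >= s) <= alpha`.
#' `alpha = 1` returns the minimum attainable score.
#'
#' @param table output of [score_pvalue_table()].
#' @param alpha upper-tail probability.
#' @return numeric threshold (log-odds units).
#' @export
pssm_threshold <- function(table, alpha) {
  surv <- rev(cumsum(rev(table$pmf)))        # P(score >= score[i])
  if (alpha >= surv[1]) return(table$score[1])
  ok <- which(surv <= alpha + 1e-12)
  if (!length(ok)) return(table$score[length(table$score)] +
                            table$granularity)
  table$score[ok[1]]
}

#' Upper-tail p-value of a score
#' @param table output of [score_pvalue_table()].
#' @param score numeric score(s), log-odds units.
#' @return `P(score' >= score)` under the background model.
#' @export
score_pvalue <- function(table, score) {
  surv <- rev(cumsum(rev(table$pmf)))
  idx <- findInterval(score - table$granularity / 2, table$score) + 1L
  out <- ifelse(idx > length(surv), 0, surv[pmin(idx, length(surv))])
  pmin(out, 1)
}

# integer encoding; N and anything else -> 5
.encode_seq <- function(s) {
  m <- match(strsplit(toupper(s), "")[[1]], .BASES)
  m[is.na(m)] <- 5L
  m
}

# forward-strand window scores of one encoded sequence; NA where any N
.window_scores <- function(logodds, enc, w) {
  L <- length(enc)
  if (L < w) return(numeric(0))
  P <- L - w + 1L
  lo5 <- rbind(logodds, NA_real_)             # row 5 catches N
  sc <- numeric(P)
  for (j in seq_len(w))
    sc <- sc + lo5[cbind(enc[j:(j + P - 1L)], j)]
  sc
}

#' Scan a sequence with a PSSM on both strands
#'
#' Windows score against the log-odds matrix quantized to the score
#' distribution's granularity (so scores live exactly on the grid the
#' threshold was derived from); a hit is any window scoring at or above the
#' exact-distribution threshold for `alpha`. The reverse strand is the scan
#' of the reverse complement; its hits are reported at the
#' forward-coordinate offset of the site's leftmost base. Windows containing
#' N are skipped.
#'
#' @param pssm a [build_pssm()] object.
#' @param sequence single character string over A/C/G/T/N.
#' @param alpha upper-tail significance of a hit.
#' @param table optional precomputed [score_pvalue_table()].
#' @param both_strands scan the reverse strand too.
#' @return data.frame of hits: `offset` (1-based), `strand`, `score`,
#'   `pvalue`.
#' @export
scan_pssm <- function(pssm, sequence, alpha = 1e-4, table = NULL,
                      both_strands = TRUE) {
  if (is.null(table)) table <- score_pvalue_table(pssm)
  thr <- pssm_threshold(table, alpha)
  qlo <- round(pssm$logodds / table$granularity) * table$granularity
  w <- pssm$width
  L <- nchar(sequence)
  hits <- list()
  enc <- .encode_seq(sequence)
  sc <- .window_scores(qlo, enc, w)
  fwd <- which(!is.na(sc) & sc >= thr - 1e-9)
  if (length(fwd))
    hits$fwd <- data.frame(offset = fwd, strand = "+", score = sc[fwd])
  if (both_strands && L >= w) {
    enc_rc <- rev(5L - enc)
    enc_rc[enc_rc == 0L] <- 5L                # rc of N stays N
    sc_rc <- .window_scores(qlo, enc_rc, w)
    rev_hit <- which(!is.na(sc_rc) & sc_rc >= thr - 1e-9)
    if (length(rev_hit))
      hits$rev <- data.frame(offset = L - (rev_hit + w - 1L) + 1L,
                             strand = "-", score = sc_rc[rev_hit])
  }
  if (!length(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), pvalue = numeric(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out$pvalue <- score_pvalue(table, out$score)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Gene x matrix hit table for a promoter collection
#'
#' Scans every sequence with every PSSM and records whether each gene's
#' promoter carries at least one hit (presence/absence, the gene-level
#' counting the enrichment tests use).
#'
#' @param sequences named character vector or `DNAStringSet` of promoters.
#' @param pssms named list of PSSMs.
#' @param alpha per-window significance of a hit.
#' @return logical matrix, genes x matrices.
#' @export
scan_hit_matrix <- function(sequences, pssms, alpha = 1e-4) {
  nms <- names(sequences)
  seqs <- stats::setNames(as.character(sequences), nms)
  if (is.null(names(seqs))) stop("sequences must be named by gene")
  hit <- matrix(FALSE, length(seqs), length(pssms),
                dimnames = list(names(seqs), names(pssms)))
  for (m in names(pssms)) {
    p <- pssms[[m]]
    tab <- score_pvalue_table(p)
    thr <- pssm_threshold(tab, alpha)
    qlo <- round(p$logodds / tab$granularity) * tab$granularity
    w <- p$width
    for (g in names(seqs)) {
      enc <- .encode_seq(seqs[[g]])
      sc <- .window_scores(qlo, enc, w)
      found <- any(!is.na(sc) & sc >= thr - 1e-9)
      if (!found) {
        enc_rc <- rev(5L - enc)
        enc_rc[enc_rc == 0L] <- 5L
        sc <- .window_scores(qlo, enc_rc, w)
        found <- any(!is.na(sc) & sc >= thr - 1e-9)
      }
      hit[g, m] <- found
    }
  }
  hit
}
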