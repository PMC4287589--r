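# The meta-regulator engine: promoter window extraction, per-configuration
# TFBS over-representation, consensus voting across configurations with a
# random-reference-set (RRS) penalty, and the two-pass selection that
# nominates TFs enriched both in all footprint promoters and in the
# footprint's TF-gene promoters.

#' Promoter window presets
#'
#' The three scanning configurations, as offsets relative to the TSS
#' (negative = upstream; the TSS itself is position +1, there is no
#' position 0): `preset1` = (-2000, -1), `preset2` = (-5000, -800),
#' `preset3` = (-5000, +200).
#'
#' @param preset `"preset1"`, `"preset2"` or `"preset3"`.
#' @return integer vector `c(start, end)`.
#' @export
promoter_window <- function(preset = c("preset1", "preset2", "preset3")) {
  preset <- match.arg(preset)
  switch(preset,
         preset1 = c(-2000L, -1L),
         preset2 = c(-5000L, -800L),
         preset3 = c(-5000L, 200L))
}

#' Extract promoter windows from a genome
#'
#' Coordinates are 1-based inclusive. For a plus-strand gene with window
#' offsets `(start, end)` the genomic range is `TSS + start .. TSS + end`
#' for upstream ends and `TSS + end - 1` when `end > 0` (position +1 is the
#' TSS base itself). Minus-strand genes take the mirror range and are
#' reverse-complemented. Windows running past a contig end are truncated
#' with a warning.
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `strand`, `tss`.
#' @param genome named [Biostrings::DNAStringSet] of contigs.
#' @param window offsets `c(start, end)` or a preset name.
#' @return named character vector of promoter sequences (5' to 3' of the
#'   gene).
#' @export
extract_promoters <- function(annotation, genome, window = "preset1") {
  if (is.character(window) && length(window) == 1)
    window <- promoter_window(window)
  if (window[1] >= window[2]) stop("window start must precede end")
  seqs <- character(nrow(annotation))
  truncated <- 0L
  for (i in seq_len(nrow(annotation))) {
    chrom <- annotation$chrom[i]
    if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
    clen <- Biostrings::width(genome[chrom])
    tss <- annotation$tss[i]
    if (annotation$strand[i] == "+") {
      gstart <- tss + window[1]
      gend <- tss + window[2] - (window[2] > 0)
    } else {
      gstart <- tss - window[2] + (window[2] > 0)
      gend <- tss - window[1]
    }
    if (gstart < 1 || gend > clen) {
      truncated <- truncated + 1L
      gstart <- max(1L, gstart); gend <- min(clen, gend)
    }
    if (gstart > gend) { seqs[i] <- ""; next }
    s <- Biostrings::subseq(genome[[chrom]], gstart, gend)
    if (annotation$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  if (truncated > 0)
    warning(truncated, " promoter window(s) truncated at contig ends")
  stats::setNames(seqs, annotation$gene_id)
}

#' TFBS over-representation of one matrix in a target gene set
#'
#' A gene counts as "hit" if its promoter carries at least one scan hit.
#' Upper-tail hypergeometric test of hit genes in the target set against
#' the target-plus-background universe.
#'
#' @param hit_genes gene ids whose promoters carry a hit.
#' @param target_genes target set.
#' @param background_genes background set (disjoint from target).
#' @return upper-tail p-value.
#' @export
tfbs_enrichment <- function(hit_genes, target_genes, background_genes) {
  universe <- union(target_genes, background_genes)
  hit <- intersect(unique(hit_genes), universe)
  k <- length(intersect(hit, target_genes))
  stats::phyper(k - 1, length(hit), length(universe) - length(hit),
                length(intersect(target_genes, universe)),
                lower.tail = FALSE)
}

# per-matrix enrichment table for one configuration's hit matrix
.enrich_config <- function(hits, target_genes, q_cutoff = 0.05) {
  universe <- rownames(hits)
  target <- intersect(target_genes, universe)
  background <- setdiff(universe, target)
  p <- vapply(colnames(hits), function(m)
    tfbs_enrichment(universe[hits[, m]], target, background), numeric(1))
  q <- bh_adjust(p)
  data.frame(matrix_id = colnames(hits), p = p, q = q,
             significant = q < q_cutoff, stringsAsFactors = FALSE,
             row.names = NULL)
}

# per-TF flag from a per-matrix table: TRUE if any of the TF's matrices is
# significant, NA if the TF has no matrix in the map
.tf_flags <- function(enr, tf_map, tfs) {
  vapply(tfs, function(tf) {
    mats <- tf_map$matrix_id[tf_map$tf == tf]
    mats <- intersect(mats, enr$matrix_id)
    if (!length(mats)) return(NA)
    any(enr$significant[enr$matrix_id %in% mats])
  }, logical(1))
}

#' Consensus TFBS over-representation vote across configurations
#'
#' For each scanning configuration (promoter window), every matrix is
#' tested for over-representation in the target promoters and flagged at
#' BH `q < q_cutoff`; a TF is significant in a configuration if any of its
#' matrices is, and NA when it has no matrix there. The consensus score is
#' the number of significant configurations minus a single -1 penalty if
#' the TF is significant on any random reference set (RRS) — `rrs_runs`
#' fresh uniformly drawn gene sets of the target's size, evaluated on the
#' first configuration. TFs with score >= 2 are selected ("found in at
#' least two of the three searches").
#'
#' @param hits_list list of logical gene x matrix hit tables (one per
#'   configuration, from [scan_hit_matrix()]).
#' @param tf_map data.frame `matrix_id`, `tf` linking matrices to TFs.
#' @param target_genes target gene set (promoter universe rows not in the
#'   target act as background).
#' @param q_cutoff per-configuration BH significance cutoff.
#' @param rrs_runs number of random reference sets (0 disables the
#'   penalty).
#' @param seed integer seed for the RRS draws.
#' @return data.frame, one row per TF: `config<i>` flags, `n_significant`,
#'   `rrs_hits`, `score`, `selected`; with attribute `"per_matrix"` holding
#'   the per-configuration matrix-level tables.
#' @export
tfbs_consensus <- function(hits_list, tf_map, target_genes, q_cutoff = 0.05,
                           rrs_runs = 10, seed = 1L) {
  tfs <- unique(tf_map$tf)
  enr <- lapply(hits_list, .enrich_config, target_genes = target_genes,
                q_cutoff = q_cutoff)
  flags <- sapply(enr, .tf_flags, tf_map = tf_map, tfs = tfs)
  if (length(tfs) == 1) flags <- matrix(flags, nrow = 1)
  colnames(flags) <- paste0("config", seq_along(hits_list))
  rownames(flags) <- tfs

  rrs_hits <- stats::setNames(integer(length(tfs)), tfs)
  if (rrs_runs > 0) {
    hits1 <- hits_list[[1]]
    universe <- rownames(hits1)
    size <- length(intersect(target_genes, universe))
    withr::with_seed(as.integer(seed), {
      for (r in seq_len(rrs_runs)) {
        rt <- sample(universe, size)
        renr <- .enrich_config(hits1, rt, q_cutoff)
        rf <- .tf_flags(renr, tf_map, tfs)
        rrs_hits <- rrs_hits + ifelse(is.na(rf), 0L, as.integer(rf))
      }
    })
  }
  votes <- lapply(seq_along(tfs), function(i)
    consensus_score(flags[i, ], rrs_hits[i] > 0))
  out <- data.frame(tf = tfs, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(flags))) out[[colnames(flags)[j]]] <- flags[, j]
  out$n_significant <- vapply(votes, `[[`, integer(1), "n_significant")
  out$rrs_hits <- as.integer(rrs_hits)
  out$score <- vapply(votes, `[[`, integer(1), "score")
  out$selected <- vapply(votes, `[[`, logical(1), "selected")
  attr(out, "per_matrix") <- enr
  out
}

#' Consensus vote arithmetic for one TF
#'
#' Score = number of significant configurations (NA configurations, where
#' no matrix was available, are excluded from the count) minus a single -1
#' penalty if the TF was significant on any random reference set. A TF is
#' selected when the score reaches 2.
#'
#' @param flags logical vector of per-configuration significance (NA
#'   allowed).
#' @param rrs_hit was the TF significant in any RRS run?
#' @return list: `n_significant`, `score`, `selected`.
#' @export
consensus_score <- function(flags, rrs_hit = FALSE) {
  n_sig <- sum(flags, na.rm = TRUE)
  score <- n_sig - as.integer(isTRUE(rrs_hit))
  list(n_significant = as.integer(n_sig), score = as.integer(score),
       selected = score >= 2)
}

#' Second-pass meta-regulator selection
#'
#' Reruns the consensus vote with the TF-gene promoters as the target set
#' and returns the TFs selected in both passes — the "meta-regulators"
#' whose binding sites are over-represented in all footprint promoters and
#' again in the footprint's TF-gene promoters.
#'
#' @param first_pass output of [tfbs_consensus()] for the full footprint
#'   target.
#' @param hits_list the configuration hit tables (same promoter universe).
#' @param tf_map matrix-to-TF map.
#' @param tf_target_genes the TF-gene target set for the second pass.
#' @param ... passed on to [tfbs_consensus()] (`q_cutoff`, `rrs_runs`,
#'   `seed`).
#' @return list with `meta_regulators` (character), `second_pass` (the
#'   second consensus table).
#' @export
meta_regulators <- function(first_pass, hits_list, tf_map, tf_target_genes,
                            ...) {
  sel1 <- first_pass$tf[first_pass$selected]
  if (!length(sel1))
    return(list(meta_regulators = character(0), second_pass = NULL))
  second <- tfbs_consensus(hits_list, tf_map, tf_target_genes, ...)
  sel2 <- second$tf[second$selected]
  list(meta_regulators = intersect(sel1, sel2), second_pass = second)
}
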