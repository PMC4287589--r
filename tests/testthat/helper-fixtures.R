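# Shared fixtures, all built in code.

# a small config sized for fast recovery tests
small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 300, expressed_fraction = 0.5, n_de_genes = 30,
         n_tfs = 15, n_regulator_tfs = 4, promoter_length = 600,
         motif_planting_rate = 0.5, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# an exact-match PSSM for a consensus word (counts concentrated on it)
word_pssm <- function(word, id = "MX", tf = "TFX") {
  bases <- strsplit(word, "")[[1]]
  counts <- sapply(bases, function(b) {
    cl <- rep(0, 4); cl[match(b, c("A", "C", "G", "T"))] <- 100; cl
  })
  rownames(counts) <- c("A", "C", "G", "T")
  build_pssm(counts, id = id, tf = tf)
}

# naive all-window, all-strand scan oracle (independent of scan_pssm);
# uses the same 0.01 log-odds quantization convention as the scanner
naive_scan <- function(pssm, sequence, threshold, granularity = 0.01) {
  bases <- c("A", "C", "G", "T")
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]),
                                      collapse = ""))
  qlo <- round(pssm$logodds / granularity) * granularity
  w <- pssm$width
  L <- nchar(sequence)
  score_word <- function(word) {
    idx <- match(strsplit(word, "")[[1]], bases)
    if (anyNA(idx)) return(NA_real_)
    sum(qlo[cbind(idx, seq_len(w))])
  }
  out <- list()
  for (i in seq_len(max(0, L - w + 1))) {
    word <- substr(sequence, i, i + w - 1)
    sf <- score_word(word)
    if (!is.na(sf) && sf >= threshold - 1e-9)
      out[[length(out) + 1]] <- data.frame(offset = i, strand = "+",
                                           score = sf)
    sr <- score_word(revcomp(word))
    if (!is.na(sr) && sr >= threshold - 1e-9)
      out[[length(out) + 1]] <- data.frame(offset = i, strand = "-",
                                           score = sr)
  }
  if (!length(out))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

# random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
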