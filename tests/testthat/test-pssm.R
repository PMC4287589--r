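test_that("pssm construction arithmetic is exact", {
  # uniform counts, uniform background -> all log-odds zero
  p <- build_pssm(matrix(5, 4, 3))
  expect_true(all(abs(p$logodds) < 1e-12))

  # column (10,0,0,0), uniform bg, pseudocount 1:
  # freq_A = 10.25/11, log-odds_A = log2((10.25/11)/0.25)
  p2 <- build_pssm(matrix(c(10, 0, 0, 0), 4, 1))
  expect_equal(unname(p2$freq["A", 1]), 10.25 / 11)
  expect_equal(unname(p2$logodds["A", 1]), log2((10.25 / 11) / 0.25))
  expect_equal(unname(round(p2$logodds["A", 1], 3)), 1.898)
  expect_true(all(is.finite(p2$logodds)))

  expect_error(build_pssm(matrix(-1, 4, 2)), "non-negative")
  expect_error(build_pssm(matrix(1, 4, 2), background = c(1, 1, 1, 1)),
               "sum to 1")
})

test_that("jaspar round-trip is the identity", {
  pssms <- gen_pssms(c("TFA", "TFB"), width = 6, seed = 2)
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pssms, path)
  back <- read_jaspar(path)
  expect_identical(names(back), names(pssms))
  for (nm in names(pssms)) {
    expect_identical(back[[nm]]$counts, pssms[[nm]]$counts)
    expect_identical(back[[nm]]$tf, pssms[[nm]]$tf)
  }
  # write -> parse -> write reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("score pmf equals exhaustive enumeration over all words", {
  gran <- 0.01
  for (seed in 1:3) {
    pssms <- gen_pssms("TFX", width = 5, seed = seed)
    p <- pssms[[1]]
    tab <- score_pvalue_table(p, granularity = gran)
    expect_equal(sum(tab$pmf), 1, tolerance = 1e-9)

    # brute force: all 4^w words, discretized the same way
    ilo <- round(p$logodds / gran)
    words <- as.matrix(expand.grid(rep(list(1:4), p$width)))
    scores <- rowSums(matrix(ilo[cbind(as.vector(words),
                                       rep(seq_len(p$width),
                                           each = nrow(words)))],
                             nrow(words)))
    probs <- apply(words, 1, function(ix) prod(p$background[ix]))
    enum <- tapply(probs, scores, sum)
    grid <- round(tab$score / gran)
    expect_setequal(as.integer(names(enum)), grid)
    expect_equal(as.numeric(enum[as.character(grid)]), tab$pmf,
                 tolerance = 1e-12)
  }
})

test_that("thresholds are monotone in alpha and hit the extremes", {
  p <- gen_pssms("TFX", width = 8, seed = 4)[[1]]
  tab <- score_pvalue_table(p)
  expect_equal(pssm_threshold(tab, 1), min(tab$score))   # alpha = 1
  alphas <- c(0.5, 0.1, 0.01, 1e-3, 1e-4)
  thr <- vapply(alphas, function(a) pssm_threshold(tab, a), numeric(1))
  expect_true(all(diff(thr) >= 0))
  # tail probability at the threshold really is <= alpha
  for (i in seq_along(alphas))
    expect_lte(score_pvalue(tab, thr[i]), alphas[i] + 1e-12)

  # width-1 motif: P(score = top) = background of the top base
  p1 <- build_pssm(matrix(c(10, 0, 0, 0), 4, 1), pseudocount_total = 0.01)
  t1 <- score_pvalue_table(p1)
  expect_equal(t1$pmf[length(t1$pmf)], 0.25)
})

test_that("scanning finds a palindromic exact match on both strands", {
  p <- word_pssm("ACGT")
  hits <- scan_pssm(p, "AAACGTTT", alpha = 0.05)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  expect_true(3 %in% fwd$offset)
  expect_true(3 %in% rev$offset)   # ACGT is its own reverse complement
  # empty and too-short sequences give no hits
  expect_identical(nrow(scan_pssm(p, "", alpha = 0.05)), 0L)
  expect_identical(nrow(scan_pssm(p, "AC", alpha = 0.05)), 0L)
})

test_that("scan equals the naive all-window all-strand oracle", {
  set.seed(11)
  for (i in 1:3) {
    p <- gen_pssms("TFX", width = 7, seed = i)[[1]]
    tab <- score_pvalue_table(p)
    thr <- pssm_threshold(tab, 0.01)     # permissive alpha -> many hits
    seqs <- replicate(20, rand_dna(300))
    for (s in seqs[1:5]) {
      got <- scan_pssm(p, s, alpha = 0.01, table = tab)
      want <- naive_scan(p, s, thr)
      got <- got[order(got$offset, got$strand), ]
      want <- want[order(want$offset, want$strand), ]
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("windows containing N are skipped", {
  p <- word_pssm("ACGT")
  hits <- scan_pssm(p, "ACNTACGT", alpha = 0.05)
  expect_true(all(hits$offset >= 4))
})

test_that("strand symmetry: motif on S mirrors revcomp motif on revcomp S", {
  set.seed(13)
  p <- gen_pssms("TFX", width = 6, seed = 3)[[1]]
  prc <- pssm_revcomp(p)
  s <- rand_dna(200)
  src <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  h1 <- scan_pssm(p, s, alpha = 0.01)
  h2 <- scan_pssm(prc, src, alpha = 0.01)
  # same number of sites, scores multiset-identical
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
})

test_that("hit matrix agrees with per-sequence scans", {
  pssms <- gen_pssms(c("TFA", "TFB"), width = 6, seed = 9)
  set.seed(9)
  seqs <- setNames(replicate(15, rand_dna(150)), sprintf("g%02d", 1:15))
  hm <- scan_hit_matrix(seqs, pssms, alpha = 0.01)
  for (m in names(pssms)) {
    tab <- score_pvalue_table(pssms[[m]])
    manual <- vapply(seqs, function(s)
      nrow(scan_pssm(pssms[[m]], s, alpha = 0.01, table = tab)) > 0,
      logical(1))
    expect_identical(unname(hm[, m]), unname(manual))
  }
})
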