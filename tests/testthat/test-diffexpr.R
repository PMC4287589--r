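make_em <- function(values, groups = rep(c("BM", "PL"), each = 3)) {
  rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, groups)
}

test_that("bh adjustment equals the direct step-up definition", {
  # hand-computed example
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # oracle: direct definition q_(i) = min_{j>=i} m p_(j) / j
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(q_sorted, 1)[order(o)]
  }
  set.seed(30)
  for (n in c(1, 10, 1000, 10000)) {
    p <- runif(n)^2
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("fpkm engine: identical groups give null results", {
  vals <- matrix(rep(c(4, 4, 4), 2 * 10), 10, 6, byrow = TRUE)
  r <- fpkm_engine(make_em(vals))
  expect_true(all(r$log2fc == 0))
  expect_true(all(r$p == 1))
})

test_that("fpkm engine p is close to the exact permutation p", {
  set.seed(31)
  vals <- 2^matrix(rnorm(20 * 6, 4, 1), 20, 6)
  vals[1:5, 4:6] <- vals[1:5, 4:6] * 8
  em <- make_em(vals)
  r <- fpkm_engine(em)
  lv <- log2(vals + 1)
  perms <- combn(6, 3)
  for (i in c(1, 3, 11, 17)) {
    t_obs <- abs(mean(lv[i, 4:6]) - mean(lv[i, 1:3]))
    t_all <- apply(perms, 2, function(ix)
      abs(mean(lv[i, ix]) - mean(lv[i, -ix])))
    p_perm <- mean(t_all >= t_obs - 1e-12)
    # t reference should land within 2x of the exact permutation p
    # (permutation granularity at 3v3 is 1/10)
    expect_lt(r$p[i], min(1, 2.5 * p_perm + 0.05))
    expect_gt(r$p[i], p_perm / 20)
  }
})

test_that("planted fold changes are estimated with small bias", {
  cfg <- sim_config(n_genes = 1000, n_de_genes = 60, de_log2fc = 3,
                    seed = 32)
  sim <- gen_expression(cfg)
  r <- fpkm_engine(sim$fpkm)
  est <- r$log2fc[match(sim$truth$de_gene_ids, r$gene)]
  truth <- sim$truth$de_log2fc[sim$truth$de_gene_ids]
  expect_lt(median(abs(est) - 3), 0.5)
  expect_lt(abs(mean(est - truth)), 0.2)   # signed bias
  expect_true(all(sign(est) == sign(truth)))
})

test_that("count engine: size factors and null behaviour", {
  # flat counts -> unit size factors, p ~ 1
  vals <- matrix(50, 10, 6)
  r <- count_engine(make_em(vals))
  expect_equal(unname(attr(r, "size_factors")), rep(1, 6))
  expect_true(all(r$p > 0.9))
  # doubling half the samples doubles their size factors relative to the
  # untouched half (size factors are defined up to a common scale)
  cfg <- sim_config(n_genes = 500, n_de_genes = 0, seed = 33)
  sim <- gen_expression(cfg)
  cts <- sim$counts$values + 1
  sf0 <- size_factors(cts)
  cts2 <- cts; cts2[, 4:6] <- cts2[, 4:6] * 2
  sf2 <- size_factors(cts2)
  ratio <- (sf2[4:6] / sf2[1:3]) / (sf0[4:6] / sf0[1:3])
  expect_equal(unname(ratio), rep(2, 3), tolerance = 0.01)
})

test_that("size factors agree with an established implementation", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(n_genes = 400, n_de_genes = 20, seed = 34)
  sim <- gen_expression(cfg)
  cts <- sim$counts$values + 1
  ref <- DESeq2::estimateSizeFactorsForMatrix(cts)
  expect_equal(unname(size_factors(cts)), unname(ref), tolerance = 1e-6)
})

test_that("count engine type-I error is near nominal under the null", {
  cfg <- sim_config(n_genes = 3000, n_de_genes = 0, seed = 35)
  sim <- gen_expression(cfg)
  r <- count_engine(sim$counts)
  # calibration is assessed where the test has resolution: expressed genes
  # (near-zero counts make the discrete tail conservative by construction)
  expr <- rowMeans(sim$fpkm$values) > 1
  rate <- mean(r$p[expr] < 0.05)
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.075)
  expect_lte(mean(r$p < 0.05), 0.075)    # never anti-conservative overall
})

test_that("consensus intersection, asymmetric thresholds and flags", {
  resA <- data.frame(gene = c("a", "b", "c", "d"), engine = "fpkm_engine",
                     log2fc = c(2, -1, 3, 1),
                     p = c(1e-4, 1e-4, 0.5, 1e-4),
                     q = c(0.01, 0.01, 0.9, 0.01))
  resB <- data.frame(gene = c("a", "b", "c", "d"), engine = "count_engine",
                     log2fc = c(2, 1, 3, 1),
                     p = c(1e-6, 1e-6, 1e-6, 0.5),
                     q = c(1e-4, 1e-4, 1e-4, 0.9))
  cons <- consensus_de(resA, resB)
  tab <- cons$table
  expect_setequal(tab$gene[tab$consensus], c("a", "b"))
  # direction from the FPKM engine; disagreement flagged, gene retained
  expect_true(tab$direction_disagreement[tab$gene == "b"])
  expect_identical(cons$summary$n_direction_disagreement, 1L)
  expect_identical(cons$summary$n_consensus, 2L)

  # disjoint significant sets -> empty consensus
  resB2 <- resB; resB2$q <- c(0.9, 0.9, 1e-4, 0.9)
  expect_identical(consensus_de(resA, resB2)$summary$n_consensus, 0L)

  # monotone: relaxing either threshold never removes a consensus gene
  c1 <- consensus_de(resA, resB, q_fpkm = 0.02, q_counts = 1e-3)
  c2 <- consensus_de(resA, resB, q_fpkm = 0.05, q_counts = 1e-3)
  expect_true(all(c1$table$gene[c1$table$consensus] %in%
                  c2$table$gene[c2$table$consensus]))
})

test_that("venn arithmetic reproduces printed overlap percentages", {
  # 203 consensus genes out of an engine-A set of 232 -> 87.5%
  genes <- sprintf("g%04d", 1:2000)
  a_set <- genes[1:232]
  b_set <- c(genes[30:232], genes[500:1684])   # 203 overlap, 1388 total
  resA <- data.frame(gene = genes, engine = "fpkm_engine", log2fc = 1,
                     p = 0.5, q = ifelse(genes %in% a_set, 0.01, 0.9))
  resB <- data.frame(gene = genes, engine = "count_engine", log2fc = 1,
                     p = 0.5, q = ifelse(genes %in% b_set, 1e-4, 0.9))
  cons <- consensus_de(resA, resB)
  expect_identical(cons$summary$n_sig_fpkm, 232L)
  expect_identical(cons$summary$n_sig_counts, 1388L)
  expect_identical(cons$summary$n_consensus, 203L)
  expect_equal(cons$summary$pct_of_fpkm_engine, 87.5, tolerance = 1e-3)
})

test_that("planted DE genes are recovered with controlled FDR", {
  cfg <- sim_config(n_genes = 2000, n_de_genes = 100, de_log2fc = 3,
                    seed = 36)
  sim <- gen_expression(cfg)
  cons <- consensus_de(fpkm_engine(sim$fpkm), count_engine(sim$counts))
  called <- cons$table$gene[cons$table$consensus]
  expect_gt(length(called), 30)
  fdr <- length(setdiff(called, sim$truth$de_gene_ids)) /
    max(1, length(called))
  expect_lte(fdr, 0.10)
})

test_that("isoform overlap percentages use the stated denominators", {
  fp <- sprintf("f%04d", 1:5271)
  sig <- sprintf("s%03d", 1:203)
  spl <- c(fp[1:16], sig[1:141], sprintf("x%03d", 1:140))
  ov <- isoform_overlap(spl, sig, fp)
  expect_identical(ov$n_splicing, 297L)
  expect_identical(ov$n_in_footprint, 16L)
  expect_equal(ov$pct_of_footprint, 100 * 16 / 5271)
  expect_equal(round(ov$pct_of_footprint, 1), 0.3)
  expect_identical(ov$n_in_signature, 141L)
  expect_equal(round(ov$pct_of_signature, 1), 69.5)
  # empty splicing set -> zeros
  z <- isoform_overlap(character(0), sig, fp)
  expect_identical(z$n_splicing, 0L)
  expect_identical(z$n_in_footprint, 0L)
})
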