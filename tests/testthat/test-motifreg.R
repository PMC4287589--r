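test_that("promoter extraction arithmetic matches the coordinate rules", {
  genome <- Biostrings::DNAStringSet(c(chrT = rand_dna(20000, seed = 1)))
  gseq <- as.character(genome[[1]])
  ann <- data.frame(gene_id = c("plus", "minus"), chrom = "chrT",
                    strand = c("+", "-"), tss = c(10001L, 5000L))
  prom <- extract_promoters(ann, genome, c(-2000L, -1L))
  # plus strand, TSS 10001, window (-2000, -1) -> genomic 8001..10000
  expect_identical(prom[["plus"]], substr(gseq, 8001, 10000))
  # minus strand, TSS 5000 -> genomic 5001..7000, reverse-complemented
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(substr(gseq, 5001, 7000), "")[[1]]),
                     collapse = ""))
  expect_identical(prom[["minus"]], rc)
  expect_identical(unname(nchar(prom)), c(2000L, 2000L))

  # downstream end: position +1 is the TSS base itself (no position 0)
  p3 <- extract_promoters(ann[1, ], genome, c(-10L, 2L))
  expect_identical(nchar(p3[["plus"]]), 12L)
  expect_identical(substr(p3[["plus"]], 11, 11), substr(gseq, 10001, 10001))

  # truncation at contig edge
  ann2 <- data.frame(gene_id = "edge", chrom = "chrT", strand = "+",
                     tss = 100L)
  expect_warning(pe <- extract_promoters(ann2, genome, c(-2000L, -1L)),
                 "truncated")
  expect_identical(nchar(pe[["edge"]]), 99L)
})

test_that("extraction recovers planted sites at their recorded offsets", {
  cfg <- small_cfg(seed = 12, motif_planting_rate = 1)
  sim <- gen_expression(cfg)
  pssms <- gen_pssms(sim$truth$tf_ids, width = 10, seed = 12)
  prom <- gen_promoters(cfg, pssms, sim$truth)
  sites <- prom$sites[sample(nrow(prom$sites), 10), ]
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    p <- pssms[[s$matrix_id]]
    hits <- scan_pssm(p, as.character(prom$sequences[[s$gene]]),
                      alpha = 1e-4)
    expect_true(any(hits$offset == s$position & hits$strand == s$strand))
  }
})

test_that("tfbs enrichment matches enumeration and handles extremes", {
  target <- sprintf("t%02d", 1:5)
  background <- sprintf("b%02d", 1:15)
  # all targets hit, no background hit -> 1 / C(20, 5)
  expect_equal(tfbs_enrichment(target, target, background), 1 / 15504)
  # zero hits anywhere -> p = 1
  expect_equal(tfbs_enrichment(character(0), target, background), 1)
  # null draws give approximately uniform p
  set.seed(17)
  uni <- sprintf("g%03d", 1:200)
  hit <- sample(uni, 80)
  ps2 <- replicate(500, {
    tg <- sample(uni, 50)
    tfbs_enrichment(hit, tg, setdiff(uni, tg))
  })
  expect_lte(mean(ps2 <= 0.05), 0.08)
})

test_that("consensus vote arithmetic follows the 2-of-3 + penalty rule", {
  v <- consensus_score(c(TRUE, TRUE, FALSE), rrs_hit = FALSE)
  expect_identical(v$score, 2L); expect_true(v$selected)
  v <- consensus_score(c(TRUE, TRUE, TRUE), rrs_hit = TRUE)
  expect_identical(v$score, 2L); expect_true(v$selected)
  v <- consensus_score(c(TRUE, TRUE, FALSE), rrs_hit = TRUE)
  expect_identical(v$score, 1L); expect_false(v$selected)
  v <- consensus_score(c(FALSE, FALSE, FALSE), rrs_hit = FALSE)
  expect_identical(v$score, 0L); expect_false(v$selected)
  # NA configurations are excluded from the count
  v <- consensus_score(c(TRUE, TRUE, NA), rrs_hit = FALSE)
  expect_identical(v$n_significant, 2L); expect_true(v$selected)
})

test_that("consensus engine selects planted regulators and the second pass
           is idempotent on the same target", {
  cfg <- small_cfg(seed = 20, n_tfs = 40, n_regulator_tfs = 4,
                   motif_planting_rate = 0.6)
  sim <- gen_expression(cfg)
  pssms <- gen_pssms(sim$truth$tf_ids, width = 10, seed = 20)
  prom <- gen_promoters(cfg, pssms, sim$truth)
  seqs <- setNames(as.character(prom$sequences), names(prom$sequences))
  hits <- list(scan_hit_matrix(seqs, pssms, 1e-4))
  hits <- rep(hits, 3)   # identical configurations
  tf_map <- data.frame(matrix_id = names(pssms),
                       tf = vapply(pssms, `[[`, character(1), "tf"))
  cons <- tfbs_consensus(hits, tf_map, sim$truth$expressed_gene_ids,
                         rrs_runs = 5, seed = 20)
  sel <- cons$tf[cons$selected]
  expect_setequal(sel, sim$truth$regulator_tf_ids)

  # second pass on the same target set -> identical selection
  meta <- meta_regulators(cons, hits, tf_map,
                          sim$truth$expressed_gene_ids,
                          rrs_runs = 5, seed = 20)
  expect_setequal(meta$meta_regulators, sel)

  # empty first pass -> empty result
  empty <- cons; empty$selected <- FALSE
  expect_length(meta_regulators(empty, hits, tf_map,
                                sim$truth$expressed_gene_ids)$meta_regulators,
                0)
})

test_that("TFs without matrices get NA flags that do not block others", {
  hits <- list(matrix(c(TRUE, FALSE), 2, 1,
                      dimnames = list(c("g1", "g2"), "M1")))
  tf_map <- data.frame(matrix_id = c("M1", "M9"), tf = c("A", "B"))
  cons <- tfbs_consensus(hits, tf_map, "g1", rrs_runs = 0)
  expect_true(is.na(cons$config1[cons$tf == "B"]))
  expect_false(cons$selected[cons$tf == "B"])
})

test_that("regulators planted only in TF promoters survive both passes", {
  cfg <- small_cfg(seed = 31, n_tfs = 60, n_regulator_tfs = 5,
                   motif_planting_rate = 0.8)
  sim <- gen_expression(cfg)
  pssms <- gen_pssms(sim$truth$tf_ids, width = 10, seed = 31)
  # two regulators target all expressed genes; two only TF genes; one none
  regs <- sim$truth$regulator_tf_ids
  targets <- list()
  targets[[regs[1]]] <- sim$truth$expressed_gene_ids
  targets[[regs[2]]] <- sim$truth$expressed_gene_ids
  targets[[regs[3]]] <- sim$truth$expressed_tf_ids
  targets[[regs[4]]] <- sim$truth$expressed_tf_ids
  targets[[regs[5]]] <- character(0)
  prom <- gen_promoters(cfg, pssms, sim$truth, targets_by_tf = targets)
  seqs <- setNames(as.character(prom$sequences), names(prom$sequences))
  hits <- rep(list(scan_hit_matrix(seqs, pssms, 1e-4)), 3)
  tf_map <- data.frame(matrix_id = names(pssms),
                       tf = vapply(pssms, `[[`, character(1), "tf"))
  second <- tfbs_consensus(hits, tf_map, sim$truth$expressed_tf_ids,
                           rrs_runs = 5, seed = 31)
  sel2 <- second$tf[second$selected]
  # the TF-promoter-only regulators are found in the TF-set pass
  expect_true(all(regs[3:4] %in% sel2))
  # the unplanted regulator is not
  expect_false(regs[5] %in% sel2)
})
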