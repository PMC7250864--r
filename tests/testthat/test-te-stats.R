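test_that("two-sided Fisher p follows the point-probability convention on known tables", {
  # [[2,0],[0,2]]: support a in {0,1,2} with probs 1/6, 4/6, 1/6 -> p = 1/3
  r <- fisher_two_sided(rbind(c(2, 0), c(0, 2)))
  expect_equal(r$p, 1 / 3)
  expect_true(r$or_unbounded)
  # perfect independence
  r2 <- fisher_two_sided(rbind(c(5, 5), c(5, 5)))
  expect_equal(r2$p, 1)
  expect_equal(r2$odds_ratio, 1)
  # zero margin: degenerate, p = 1
  r3 <- fisher_two_sided(rbind(c(0, 0), c(3, 4)))
  expect_true(r3$degenerate)
  expect_equal(r3$p, 1)
  # sample odds ratio, not the conditional MLE
  expect_equal(fisher_two_sided(rbind(c(6, 2), c(3, 9)))$odds_ratio,
               (6 * 9) / (2 * 3))
})

test_that("Fisher p agrees with enumeration and stats::fisher.test on random tables", {
  set.seed(404)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    mine <- fisher_two_sided(tab)
    expect_equal(mine$p, fisher_enum_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(mine$p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant to transposing the table", {
  set.seed(17)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 5) + 1, 2, 2)
    expect_equal(fisher_two_sided(tab)$p, fisher_two_sided(t(tab))$p,
                 tolerance = 1e-12)
  }
})

test_that("annotation enrichment detects planted signal-peptide bias and degenerates cleanly", {
  cfg <- ribo_sim_config(n_genes = 2000, depth = 6e5, n_planted_down = 60,
                         planted_sp_weight = 8, seed = 55,
                         cds_length_range = c(80, 200))
  study <- simulate_ribo_study(cfg)
  te <- call_differential_te(compute_te(study$counts))
  enr <- annotation_enrichment(te, study$transcripts)
  sp_down <- enr[enr$flag == "signal_peptide" & enr$direction == "down", ]
  expect_gt(sp_down$odds_ratio, 1)
  expect_lt(sp_down$p, 0.05)
  # all genes flagged -> zero column margin -> degenerate, p = 1
  tx_all <- study$transcripts
  tx_all$has_signal_peptide <- TRUE
  enr_all <- annotation_enrichment(te, tx_all, flags = "signal_peptide")
  expect_true(all(enr_all$degenerate))
  expect_true(all(enr_all$p == 1))
})

test_that("codon usage comparison is exact on identity and finds a planted codon shift", {
  set.seed(99)
  mk_gene <- function(id, gaa_heavy) {
    pool <- if (gaa_heavy) c(FILLER_CODONS, rep("GAA", 8)) else
      c(FILLER_CODONS, "GAA")
    fixture_transcript(id, sample(pool, 120, replace = TRUE))
  }
  genes_a <- do.call(rbind, lapply(1:15, function(i) mk_gene(paste0("a", i), TRUE)))
  genes_b <- do.call(rbind, lapply(1:15, function(i) mk_gene(paste0("b", i), FALSE)))
  tx <- rbind(genes_a, genes_b)
  class(tx) <- c("transcript_table", "data.frame")
  # identity: same set on both sides
  same <- codon_usage_compare(tx, genes_a$transcript_id, genes_a$transcript_id)
  expect_true(all(same$log2_ratio[is.finite(same$log2_ratio)] == 0))
  expect_true(all(same$p == 1))
  expect_equal(sum(same$freq_a), 1)
  # planted GAA enrichment is flagged after BH
  cmp <- codon_usage_compare(tx, genes_a$transcript_id, genes_b$transcript_id)
  expect_lt(cmp$q[cmp$codon == "GAA"], 0.05)
  expect_gt(cmp$log2_ratio[cmp$codon == "GAA"], 0)
  expect_true(all(cmp$q >= cmp$p))
  expect_error(codon_usage_compare(tx, character(0), genes_b$transcript_id),
               "empty")
})

test_that("codon usage comparison stays null-calibrated on exchangeable sets", {
  set.seed(123)
  pool <- c(FILLER_CODONS, "GAA", "GAC", "GAG", "GAT")
  tx <- do.call(rbind, lapply(1:30, function(i) {
    fixture_transcript(paste0("n", i), sample(pool, 100, replace = TRUE))
  }))
  class(tx) <- c("transcript_table", "data.frame")
  hits <- vapply(1:20, function(r) {
    pick <- sample(tx$transcript_id, 15)
    cmp <- codon_usage_compare(tx, pick, setdiff(tx$transcript_id, pick))
    sum(cmp$q < 0.05)
  }, numeric(1))
  # same generator on both sides: discoveries in at most a run or two
  expect_gte(mean(hits == 0), 0.9)
})
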