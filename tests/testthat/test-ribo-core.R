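test_that("footprint filter applies length, uniqueness, CDS and frame rules", {
  tx <- fixture_transcript("t1", rep("AAA", 40))  # cds_start 21, cds_end 141
  mk <- function(fp, len = 30L, uniq = TRUE) {
    data.frame(read_id = "r", transcript_id = "t1", five_prime_pos = fp,
               read_length = len, is_unique = uniq, stringsAsFactors = FALSE)
  }
  # boundary: A site exactly at cds_start, frame 0 -> retained
  expect_identical(nrow(filter_rpfs(mk(21L - 15L), tx)), 1L)
  # one nt later: frame 1 -> rejected
  expect_identical(nrow(filter_rpfs(mk(21L - 15L + 1L), tx)), 0L)
  # 27 nt: length rejected even though in frame
  expect_identical(nrow(filter_rpfs(mk(21L - 15L, len = 27L), tx)), 0L)
  # multimapper rejected
  expect_identical(nrow(filter_rpfs(mk(21L - 15L, uniq = FALSE), tx)), 0L)
  # A site beyond cds_end -> outside_cds
  expect_identical(nrow(filter_rpfs(mk(141L - 15L), tx)), 0L)
  # unknown transcript skipped with count
  alien <- mk(6L); alien$transcript_id <- "nope"
  out <- filter_rpfs(rbind(mk(6L), alien), tx)
  expect_identical(unname(attr(out, "filter_report")["unknown_transcript"]), 1L)
  # idempotence
  many <- do.call(rbind, lapply(0:60, function(p) mk(p)))
  once <- filter_rpfs(many, tx)
  twice <- filter_rpfs(once, tx)
  expect_identical(once$five_prime_pos, twice$five_prime_pos)
  rep1 <- attr(once, "filter_report")
  expect_identical(unname(rep1["retained"]),
                   unname(attr(twice, "filter_report")["retained"]))
  expect_identical(sum(rep1[c("unknown_transcript", "not_unique", "length",
                              "outside_cds", "frame")]) + rep1[["retained"]],
                   rep1[["input"]])
})

test_that("A-site assignment maps the 15-nt offset onto codon indices and codons", {
  codons <- FILLER_CODONS[1:16]
  tx <- fixture_transcript("t1", codons)
  aln <- fixture_reads_at(tx, "t1", c(5L, 15L, 0L))
  aln$five_prime_pos[3] <- tx$cds_start  # fp = cds_start -> codon 5
  asg <- assign_a_sites(filter_rpfs(aln, tx), tx)
  expect_identical(asg$codon_index, c(5L, 15L, 5L))
  expect_identical(asg$codon, codons[c(6, 16, 6)])
  expect_identical(asg$near_stop, c(FALSE, TRUE, FALSE))
  # contract: unfiltered (off-frame) input is refused
  bad <- aln; bad$five_prime_pos <- bad$five_prime_pos + 1L
  expect_error(assign_a_sites(bad, tx), "filter_rpfs")
})

test_that("codon occupancy is exactly 1 under uniform coverage (self-normalization)", {
  tx <- rbind(fixture_transcript("t1", FILLER_CODONS[1:12]),
              fixture_transcript("t2", FILLER_CODONS[5:16]))
  class(tx) <- c("transcript_table", "data.frame")
  aln <- rbind(fixture_reads_at(tx, "t1", 0:11, count = 3L),
               fixture_reads_at(tx, "t2", 0:11, count = 7L))
  asg <- assign_a_sites(filter_rpfs(aln, tx), tx)
  occ <- codon_occupancy(asg, tx)
  observed <- occ$occupancy[occ$n_events > 0]
  expect_true(all(abs(observed - 1) < 1e-9))
})

test_that("codon occupancy matches the hand-computed positional fixture", {
  # 12-codon gene; GAA planted at codon indices 2 and 6. Positional A-site
  # counts: pos2=4, pos3..5=2, pos6=6, pos7..9=3, pos10..11=0.
  # Hand-computed per-event ratios (count / mean of +1..+3 counts):
  #   pos2: 4/2 = 2      pos3: 2/(10/3) = 0.6   pos4: 2/(11/3) = 6/11
  #   pos5: 2/4 = 0.5    pos6: 6/3 = 2          pos7: 3/2 = 1.5
  #   pos8: 3/1 = 3      pos9: near stop, excluded (as are 10, 11)
  codons <- c("AAA", "AAC", "GAA", "ACA", "ACC", "ACG", "GAA", "AGA",
              "AGC", "AGG", "ATA", "ATC")
  tx <- fixture_transcript("t1", codons)
  aln <- fixture_reads_at(tx, "t1", c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
                          count = c(4L, 2L, 2L, 2L, 6L, 3L, 3L, 3L))
  asg <- assign_a_sites(filter_rpfs(aln, tx), tx)
  occ <- codon_occupancy(asg, tx)
  val <- function(codon) occ$occupancy[occ$codon == codon]
  expect_equal(val("GAA"), 2)
  expect_equal(val("ACA"), 0.6)
  expect_equal(val("ACC"), 6 / 11)
  expect_equal(val("ACG"), 0.5)
  expect_equal(val("AGA"), 1.5)
  expect_equal(val("AGC"), 3)
  expect_true(is.na(val("AGG")))  # only near-stop events
  expect_identical(unname(attr(occ, "excluded")["near_stop"]), 3L)
  expect_identical(occ$n_events[occ$codon == "GAA"], 10L)
})

test_that("empty assignment input yields an empty occupancy table with a warning", {
  tx <- fixture_transcript("t1", FILLER_CODONS[1:8])
  asg <- assign_a_sites(filter_rpfs(fixture_reads_at(tx, "t1", 0L)[0, ], tx), tx)
  expect_warning(occ <- codon_occupancy(asg, tx), "no A-site events")
  expect_true(all(is.na(occ$occupancy)))
})

test_that("metagene profiles are per-gene normalized and bin as specified", {
  # 100-codon CDS, one read per codon -> every bin holds 2 codons = 0.02
  tx <- fixture_transcript("t1", c("ATG", rep("AAA", 98), "AAC"))
  aln <- fixture_reads_at(tx, "t1", 0:99)
  asg <- assign_a_sites(filter_rpfs(aln, tx), tx)
  mg <- metagene_profile(asg, tx, "t1")
  expect_equal(mg$mean_density, rep(0.02, 50))
  expect_equal(sum(mg$mean_density), 1, tolerance = 1e-9)

  # all reads on the first codon -> bin 0 carries everything
  aln1 <- fixture_reads_at(tx, "t1", 0L, count = 40L)
  asg1 <- assign_a_sites(filter_rpfs(aln1, tx), tx)
  mg1 <- metagene_profile(asg1, tx, "t1")
  expect_equal(mg1$mean_density, c(1, rep(0, 49)))

  # genes below min_rpf are dropped; empty set errors
  expect_error(metagene_profile(asg1, tx, "t1", min_rpf = 1000L), "min_rpf|>=")
  # short gene flagged but allowed
  tx2 <- fixture_transcript("t2", FILLER_CODONS[1:10])
  txb <- rbind(tx, tx2); class(txb) <- c("transcript_table", "data.frame")
  aln2 <- fixture_reads_at(txb, "t2", rep(0:9, 4))
  asg2 <- assign_a_sites(filter_rpfs(aln2, txb), txb)
  mg2 <- metagene_profile(asg2, txb, "t2", min_rpf = 10L)
  expect_identical(attr(mg2, "genes_shorter_than_bins"), "t2")
  expect_equal(sum(mg2$mean_density), 1, tolerance = 1e-9)
})

make_te_counts <- function(ctrl_rpf, ko_rpf, ctrl_mrna, ko_mrna) {
  genes <- paste0("g", seq_along(ctrl_rpf))
  m <- cbind(RPF_CTRL_1 = ctrl_rpf, RPF_KO_1 = ko_rpf,
             mRNA_CTRL_1 = ctrl_mrna, mRNA_KO_1 = ko_mrna)
  rownames(m) <- genes
  libs <- data.frame(library_id = colnames(m),
                     assay = c("RPF", "RPF", "mRNA", "mRNA"),
                     condition = c("CTRL", "KO", "CTRL", "KO"),
                     replicate = 1L, stringsAsFactors = FALSE)
  count_table(m, libs)
}

test_that("translation efficiency reproduces constructed ratios", {
  # identical KO and CTRL libraries -> log2 ratio 0 everywhere
  rpf <- c(200L, rep(100L, 10))
  mrna <- c(100L, rep(110L, 10))
  te0 <- compute_te(make_te_counts(rpf, rpf, mrna, mrna))
  expect_true(all(abs(te0$log2_te_ratio) < 1e-12))
  # gene 1: te_CTRL = 2, te_KO = 1 (library totals equal by construction,
  # so CPM scaling cancels) -> log2 ratio -1
  te1 <- compute_te(make_te_counts(c(200L, rep(100L, 10)),
                                   c(100L, rep(110L, 10)),
                                   c(100L, rep(110L, 10)),
                                   c(100L, rep(110L, 10))))
  expect_equal(te1$te_CTRL[1], 2, tolerance = 1e-3)
  expect_equal(te1$te_KO[1], 1, tolerance = 1e-3)
  expect_equal(te1$log2_te_ratio[1], -1, tolerance = 1e-3)
  # low-count genes are not testable
  te2 <- compute_te(make_te_counts(c(5L, rep(100L, 10)),
                                   c(5L, rep(100L, 10)),
                                   c(3L, rep(110L, 10)),
                                   c(3L, rep(110L, 10))))
  expect_false(te2$testable[1])
  # a missing condition is a configuration error
  m <- cbind(RPF_CTRL_1 = rpf, mRNA_CTRL_1 = mrna)
  rownames(m) <- paste0("g", seq_along(rpf))
  libs <- data.frame(library_id = colnames(m), assay = c("RPF", "mRNA"),
                     condition = "CTRL", replicate = 1L,
                     stringsAsFactors = FALSE)
  expect_error(compute_te(count_table(m, libs)), "condition KO")
})

test_that("differential calls use the strict 2-fold threshold", {
  te <- data.frame(gene = c("a", "b", "c", "d"),
                   log2_te_ratio = c(-1.0, -0.99, 1.0, 0.2),
                   testable = c(TRUE, TRUE, TRUE, FALSE))
  out <- call_differential_te(te)
  expect_identical(out$call, c("down", "unchanged", "up", "not_testable"))
  expect_error(call_differential_te(te, threshold = 1), "> 1")
})
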