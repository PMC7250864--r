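test_that("junction location finds the 3' terminus and 5' anchor in a constructed read", {
  ref <- fixture_crace_reference()
  mat <- ref$mature_seq
  # 3' segment = last 50 mature nt, 6-U tail, 30 nt of the 5' end
  read <- paste0(substr(mat, 251, 300), strrep("T", 6), substr(mat, 1, 30))
  j <- locate_junction(read, ref)
  expect_true(j$junction_found)
  expect_identical(j$end_in_read, 50L)
  expect_identical(j$five_prime_start_in_read, 56L)
  expect_identical(j$ref_end, 300L)

  # no junction: a bare 5' fragment
  j2 <- locate_junction(substr(mat, 1, 30), ref)
  expect_false(j2$junction_found)
  expect_identical(j2$reason, "no_anchor_pair")

  # two 5'-anchor occurrences: ambiguous, discarded
  anchor <- substr(mat, 1, ref$five_prime_anchor_len)
  j3 <- locate_junction(paste0(substr(mat, 251, 300), anchor, anchor), ref)
  expect_false(j3$junction_found)
  expect_identical(j3$reason, "ambiguous")

  # 3' segment that matches nothing in the reference
  j4 <- locate_junction(paste0(strrep("ACT", 10), substr(mat, 1, 30)), ref)
  expect_false(j4$junction_found)
  expect_identical(j4$reason, "no_ref_match")
})

test_that("greedy templated-first rule separates the 4-U terminator from real U tails", {
  ref <- fixture_crace_reference()  # genomic extension starts TTTT, then non-T
  mat <- ref$mature_seq
  anchor <- substr(mat, 1, 30)
  seg <- substr(mat, 251, 300)

  # ...[canonical end] TTTT [anchor]: all four U's are templated read-through
  r1 <- call_tail(paste0(seg, "TTTT", anchor), ref)
  expect_identical(r1$end_offset, 4L)
  expect_identical(r1$tail_seq, "")
  expect_false(r1$is_uridylated)

  # five U's: four templated + one non-templated U; still not uridylated
  r2 <- call_tail(paste0(seg, "TTTTT", anchor), ref)
  expect_identical(r2$end_offset, 4L)
  expect_identical(r2$tail_seq, "U")
  expect_false(r2$is_uridylated)

  # nine U's: four templated + UUUUU tail -> uridylated
  r3 <- call_tail(paste0(seg, strrep("T", 9), anchor), ref)
  expect_identical(r3$end_offset, 4L)
  expect_identical(r3$tail_seq, "UUUUU")
  expect_true(r3$is_uridylated)

  # truncated ~20 nt with a 7-U tail at a tail-stable position (next
  # templated base is not U, so nothing is absorbed)
  d <- 20L
  while (substr(mat, 300L - d + 1L, 300L - d + 1L) == "T") d <- d + 1L
  segd <- substr(mat, 300L - d - 49L, 300L - d)
  r4 <- call_tail(paste0(segd, strrep("T", 7), anchor), ref)
  expect_identical(r4$end_offset, -d)
  expect_identical(r4$tail_seq, "UUUUUUU")
  expect_true(r4$is_uridylated)

  # the same tail drawn one base into a templated U is partially absorbed
  du <- 20L
  while (substr(mat, 300L - du + 1L, 300L - du + 1L) != "T") du <- du + 1L
  segu <- substr(mat, 300L - du - 49L, 300L - du)
  r5 <- call_tail(paste0(segu, strrep("T", 7), anchor), ref)
  expect_gt(r5$end_offset, -du)            # terminus slid into the U run
  expect_lt(nchar(r5$tail_seq), 7L)        # absorbed U's left the tail

  # the tail never starts with a base that continues the template
  stopifnot(r2$junction_found)
  next_templ <- substr(paste0(ref$mature_seq, ref$genomic_extension),
                       300 + r2$end_offset + 1, 300 + r2$end_offset + 1)
  expect_false(substr(r2$tail_seq, 1, 1) == chartr("T", "U", next_templ))
})

test_that("tail spectrum aggregates offsets and uridylation fractions", {
  calls <- data.frame(
    read_id = paste0("r", 1:5),
    junction_found = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    end_offset = c(-10L, -10L, 0L, -10L, NA),
    tail_seq = c("UUUUU", "", "UU", "UUUUUU", NA),
    is_uridylated = c(TRUE, FALSE, FALSE, TRUE, NA),
    reason = c("", "", "", "", "no_anchor_pair"),
    stringsAsFactors = FALSE
  )
  sp <- tail_spectrum(calls)
  expect_identical(sp$end_offset, c(-10L, 0L))
  expect_identical(sp$n_reads, c(3L, 1L))
  expect_identical(sp$n_uridylated, c(2L, 0L))
  expect_equal(attr(sp, "overall_frac_uridylated"), 0.5)
  expect_identical(attr(sp, "n_failed"), 1L)
})

test_that("tail calls reproduce the simulator truth table exactly per read", {
  ref <- fixture_crace_reference()
  cfg <- crace_sim_config(n_reads = 400, seed = 71)
  sim <- simulate_crace_reads(ref, cfg)
  tc <- call_tails(sim$reads, ref)
  expect_true(all(tc$junction_found))
  expect_identical(tc$read_id, sim$truth$read_id)
  expect_identical(tc$end_offset, sim$truth$end_offset)
  expect_identical(tc$tail_seq, sim$truth$tail_seq)
  expect_identical(tc$is_uridylated, sim$truth$is_uridylated)
  # truncation spectrum is mostly below the canonical end
  sp <- tail_spectrum(tc)
  expect_gt(sum(sp$n_reads[sp$end_offset < 0]), sum(sp$n_reads[sp$end_offset >= 0]))
})

test_that("simulated reads are seed-reproducible and substitution errors only lose reads", {
  ref <- fixture_crace_reference()
  cfg <- crace_sim_config(n_reads = 100, seed = 13)
  expect_identical(simulate_crace_reads(ref, cfg),
                   simulate_crace_reads(ref, cfg))
  noisy <- simulate_crace_reads(ref, crace_sim_config(n_reads = 200,
                                                      substitution_rate = 0.02,
                                                      seed = 13))
  tc <- call_tails(noisy$reads, ref)
  expect_true(any(!tc$junction_found))          # errors do break some junctions
  found <- tc$junction_found
  # but never produce a call violating the tail-call invariants
  expect_true(all(tc$end_offset[found] >= -ref$canonical_end))
  expect_true(all(tc$is_uridylated[found] ==
                    grepl("UUUUU", tc$tail_seq[found], fixed = TRUE)))
})

test_that("raw-segment uridylation is reported alongside, not merged", {
  ref <- fixture_crace_reference()
  anchor <- substr(ref$mature_seq, 1, 30)
  seg <- substr(ref$mature_seq, 251, 300)
  # five U's at the canonical end: templated-first says not uridylated,
  # the literal whole-segment criterion says uridylated
  r <- call_tail(paste0(seg, "TTTTT", anchor), ref)
  expect_false(r$is_uridylated)
  expect_true(r$raw_segment_uridylated)
})

test_that("one-mismatch anchor tolerance rescues a substituted anchor unambiguously", {
  base <- fixture_crace_reference()
  ref1 <- crace_reference(base$mature_seq, base$genomic_extension,
                          max_anchor_mismatch = 1L)
  anchor <- substr(base$mature_seq, 1, base$five_prime_anchor_len)
  substr(anchor, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substr(anchor, 10, 10))[1]
  read <- paste0(substr(base$mature_seq, 251, 300), "TTTTTTT", anchor)
  expect_false(locate_junction(read, base)$junction_found)
  j <- locate_junction(read, ref1)
  expect_true(j$junction_found)
  expect_identical(j$end_in_read, 50L)
  expect_error(crace_reference(base$mature_seq, base$genomic_extension,
                               max_anchor_mismatch = 2L), "0 or 1")
})

test_that("anchor shorter than the junction-detection minimum is a config error", {
  ref <- fixture_crace_reference()
  expect_error(simulate_crace_reads(ref, crace_sim_config(anchor_copy_len = 10)),
               "junction-detection minimum")
})
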