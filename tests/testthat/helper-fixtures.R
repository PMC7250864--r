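# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A transcript whose CDS codons are given explicitly (start/stop included
# in `codons` if wanted); UTRs are fixed-sequence so tests are deterministic.
fixture_transcript <- function(id, codons, utr5 = 21L, utr3 = 21L,
                               sp = FALSE, tm = FALSE) {
  utr5_seq <- paste0(rep("C", utr5), collapse = "")
  utr3_seq <- paste0(rep("G", utr3), collapse = "")
  transcript_table(
    transcript_id = id,
    sequence = paste0(utr5_seq, paste0(codons, collapse = ""), utr3_seq),
    cds_start = utr5,
    cds_end = utr5 + 3L * length(codons),
    has_signal_peptide = sp,
    has_transmembrane = tm
  )
}

# Alignments placing `count` in-frame 30-nt footprints with the A site on
# codon `codon_index` of `transcript` (0-based within the CDS).
fixture_reads_at <- function(transcripts, transcript_id, codon_index,
                             count = 1L, read_length = 30L, offset = 15L) {
  i <- match(transcript_id, transcripts$transcript_id)
  fp <- transcripts$cds_start[i] + 3L * codon_index - offset
  idx <- rep(seq_along(codon_index), times = count)
  data.frame(
    read_id = paste0(transcript_id, "_", seq_along(idx)),
    transcript_id = transcript_id,
    five_prime_pos = fp[idx],
    read_length = read_length,
    is_unique = TRUE,
    stringsAsFactors = FALSE
  )
}

# Distinct filler codons (no stops, no GAA which several tests plant).
FILLER_CODONS <- c("AAA", "AAC", "ACA", "ACC", "ACG", "AGA", "AGC", "AGG",
                   "ATA", "ATC", "ATT", "CAA", "CAC", "CAG", "CAT", "CCA")

# Small deterministic cRACE reference with a non-U mature 3' end and a
# 4-U genomic terminator, built from a fixed seed.
fixture_crace_reference <- function(length = 300L, seed = 5L) {
  synthetic_crace_reference(length = length, seed = seed)
}

# Independent two-sided Fisher p by explicit enumeration of all tables
# with the observed margins, probabilities from first principles
# (lchoose), point-probability criterion.
fisher_enum_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  total <- m + n
  lp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(total, k)
  }
  support <- max(0, k - n):min(k, m)
  probs <- exp(lp(support))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}

# Logistic log-likelihood used by the grid-search oracle.
logistic_loglik <- function(beta0, beta1, x, y) {
  eta <- beta0 + beta1 * x
  sum(y * eta - log1p(exp(eta)))
}

# Grid-search MLE oracle: shrinking lattice, re-centering at each step
# size until the maximum is interior to the window (the likelihood is
# concave, so this converges to the global optimum).
grid_mle <- function(x, y, steps = c(0.5, 0.05, 5e-3, 5e-4, 1e-4),
                     half_width = 12L) {
  center <- c(0, 0)
  for (step in steps) {
    repeat {
      b0 <- center[1] + step * (-half_width:half_width)
      b1 <- center[2] + step * (-half_width:half_width)
      ll <- outer(b0, b1, Vectorize(function(p, q) logistic_loglik(p, q, x, y)))
      best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
      center <- c(b0[best[1]], b1[best[2]])
      interior <- all(best > 1 & best < 2 * half_width + 1)
      if (interior) break
    }
  }
  center
}
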