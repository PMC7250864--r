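#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value follows the point-probability convention: the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (with the customary 1 + 1e-7 relative tolerance against floating-point
#' ties). The odds ratio reported is the sample odds ratio
#' `(a*d)/(b*c)`; zero or infinite ratios are returned as such and
#' flagged. A table with a zero margin carries no information: p = 1
#' with the `degenerate` flag set.
#'
#' @param table 2x2 matrix of non-negative integers, orientation
#'   `rbind(c(a, b), c(c, d))`.
#' @return List: `odds_ratio`, `p`, `degenerate`, `or_unbounded`.
#' @export
fisher_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    stop("fisher_two_sided needs a 2x2 table of non-negative integers")
  }
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m <- a + b      # row-1 margin
  n <- c_ + d     # row-2 margin
  k <- a + c_     # column-1 margin
  or <- (a * d) / (b * c_)
  unbounded <- b == 0 || c_ == 0
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(list(odds_ratio = if (is.nan(or)) NA_real_ else or, p = 1,
                degenerate = TRUE, or_unbounded = unbounded))
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p = p, degenerate = FALSE, or_unbounded = unbounded)
}

#' Enrichment of annotation flags among differentially translated genes
#'
#' For each direction (`down`, `up`) a 2x2 table is built over the
#' testable genes — called vs not-called against flagged vs unflagged —
#' and tested with [fisher_two_sided()]. The background is testable
#' genes only, since non-testable genes cannot be called. Three flag
#' modes mirror the usual presentation: signal peptide, transmembrane,
#' and their union.
#'
#' @param te_records Output of [call_differential_te()].
#' @param transcripts A `transcript_table` carrying the annotation flags.
#' @param flags Which flag modes to test.
#' @return data.frame: `flag`, `direction`, `n_called_flagged`,
#'   `n_called_unflagged`, `n_other_flagged`, `n_other_unflagged`,
#'   `odds_ratio`, `p`, `degenerate`.
#' @export
annotation_enrichment <- function(te_records, transcripts,
                                  flags = c("signal_peptide", "transmembrane",
                                            "either")) {
  flags <- match.arg(flags, several.ok = TRUE)
  if (is.null(te_records$call)) stop("run call_differential_te first")
  te <- te_records[te_records$testable, , drop = FALSE]
  if (nrow(te) == 0L) stop("annotation_enrichment: no testable genes")
  idx <- match(te$gene, transcripts$transcript_id)
  if (anyNA(idx)) stop("annotation_enrichment: genes missing from transcripts")
  flag_vec <- function(mode) {
    switch(mode,
      signal_peptide = transcripts$has_signal_peptide[idx],
      transmembrane = transcripts$has_transmembrane[idx],
      either = transcripts$has_signal_peptide[idx] |
        transcripts$has_transmembrane[idx]
    )
  }
  rows <- list()
  for (mode in flags) {
    fl <- flag_vec(mode)
    for (direction in c("down", "up")) {
      called <- te$call == direction
      tab <- rbind(c(sum(called & fl), sum(called & !fl)),
                   c(sum(!called & fl), sum(!called & !fl)))
      ft <- fisher_two_sided(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        flag = mode, direction = direction,
        n_called_flagged = tab[1, 1], n_called_unflagged = tab[1, 2],
        n_other_flagged = tab[2, 1], n_other_unflagged = tab[2, 2],
        odds_ratio = ft$odds_ratio, p = ft$p, degenerate = ft$degenerate,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare codon-usage frequencies between two gene sets
#'
#' Codon usage of a set is the frequency of each sense codon among all
#' CDS codons of the set's transcripts (stop codons excluded; the
#' frequencies of each set sum to 1). Each codon is tested with a
#' two-proportion chi-squared test (no continuity correction) and the 61
#' p-values are Benjamini-Hochberg adjusted.
#'
#' @param transcripts A `transcript_table`.
#' @param set_a,set_b Character vectors of transcript ids (non-empty).
#' @return data.frame: `codon`, `freq_a`, `freq_b`, `log2_ratio`, `p`,
#'   `q`.
#' @export
codon_usage_compare <- function(transcripts, set_a, set_b) {
  count_codons <- function(ids) {
    sel <- transcripts[transcripts$transcript_id %in% ids, , drop = FALSE]
    if (nrow(sel) == 0L) stop("codon_usage_compare: empty gene set")
    codons <- unlist(lapply(seq_len(nrow(sel)), function(i) {
      s <- sel$sequence[i]
      starts <- seq.int(sel$cds_start[i] + 1L, sel$cds_end[i] - 2L, by = 3L)
      substring(s, starts, starts + 2L)
    }), use.names = FALSE)
    tab <- table(factor(codons, levels = SENSE_CODONS))
    as.integer(tab)
  }
  ca <- count_codons(set_a)
  cb <- count_codons(set_b)
  na <- sum(ca); nb <- sum(cb)
  if (na == 0L || nb == 0L) stop("codon_usage_compare: set with zero sense codons")
  fa <- ca / na; fb <- cb / nb
  p <- vapply(seq_along(SENSE_CODONS), function(i) {
    if (ca[i] + cb[i] == 0L || (ca[i] == na && cb[i] == nb)) return(1)
    suppressWarnings(stats::prop.test(c(ca[i], cb[i]), c(na, nb),
                                      correct = FALSE)$p.value)
  }, numeric(1))
  p[identical_sets_p1(ca, cb, na, nb)] <- 1
  data.frame(
    codon = SENSE_CODONS,
    freq_a = fa, freq_b = fb,
    log2_ratio = log2(fa / fb),
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
}

# prop.test returns NaN-free p=1 only asymptotically for identical
# proportions; force exact 1 when the two sets have identical counts.
identical_sets_p1 <- function(ca, cb, na, nb) {
  if (na == nb && all(ca == cb)) rep(TRUE, length(ca)) else rep(FALSE, length(ca))
}
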