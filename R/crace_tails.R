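#' Reference description for circularization-RACE tail calling
#'
#' Circularization-RACE (cRACE) self-ligates an RNA's 3' end to its 5'
#' end; divergent PCR across the junction yields chimeric reads laid out
#' as \[3'-terminal reference segment\]\[non-templated tail\]\[reference
#' 5' prefix\]. Reconstructing the 3' terminus therefore needs the
#' mature reference sequence, the genomic sequence immediately
#' downstream of the canonical 3' end (to recognize templated
#' extensions, e.g. an RNA-polymerase-III 4-U terminator read-through),
#' and the anchor lengths used for junction detection.
#'
#' @param mature_seq Mature RNA sequence (U or T accepted; canonical 3'
#'   end is its last base).
#' @param genomic_extension Genomic sequence downstream of the canonical
#'   end (non-empty).
#' @param five_prime_anchor_len Length of the reference 5' prefix used
#'   to locate the junction (exact match by default).
#' @param min_anchor Minimum exact templated match (nt) required to
#'   place the 3' segment on the reference.
#' @param max_anchor_mismatch Substitutions tolerated when locating the
#'   5' anchor (0 = exact, the default; at most 1). Ambiguity still
#'   discards the read.
#' @return List of class `crace_reference` with fields `mature_seq`,
#'   `canonical_end` (0-based exclusive = `nchar(mature_seq)`),
#'   `genomic_extension`, `five_prime_anchor_len`, `min_anchor`,
#'   `max_anchor_mismatch`.
#' @export
crace_reference <- function(mature_seq, genomic_extension,
                            five_prime_anchor_len = 20L, min_anchor = 12L,
                            max_anchor_mismatch = 0L) {
  mature_seq <- normalize_nt(mature_seq)
  genomic_extension <- normalize_nt(genomic_extension)
  if (!nzchar(genomic_extension)) stop("genomic_extension must be non-empty")
  if (nchar(mature_seq) < five_prime_anchor_len + min_anchor) {
    stop("mature_seq shorter than anchor requirements")
  }
  if (!max_anchor_mismatch %in% c(0L, 1L)) {
    stop("max_anchor_mismatch must be 0 or 1")
  }
  structure(list(
    mature_seq = mature_seq,
    canonical_end = nchar(mature_seq),
    genomic_extension = genomic_extension,
    five_prime_anchor_len = as.integer(five_prime_anchor_len),
    min_anchor = as.integer(min_anchor),
    max_anchor_mismatch = as.integer(max_anchor_mismatch)
  ), class = "crace_reference")
}

# 1-based start positions where `pattern` occurs in `x` with at most
# `k` substitutions (no indels)
approx_matches <- function(x, pattern, k) {
  n <- nchar(x); m <- nchar(pattern)
  if (n < m) return(integer(0))
  xi <- utf8ToInt(x)
  pi_ <- utf8ToInt(pattern)
  starts <- seq_len(n - m + 1L)
  mm <- vapply(starts, function(s) sum(xi[s:(s + m - 1L)] != pi_), integer(1))
  starts[mm <= k]
}

# length of common prefix of two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ai <- utf8ToInt(substr(a, 1L, n))
  bi <- utf8ToInt(substr(b, 1L, n))
  neq <- which(ai != bi)
  if (length(neq)) neq[1] - 1L else n
}

#' Locate the 3'-5' junction within one cRACE read
#'
#' Finds the unique exact occurrence of the reference 5' prefix in the
#' read; everything before it is the 3'-terminal segment plus any
#' non-templated tail. The segment is placed on the mature sequence by
#' seeding with its first `min_anchor` nt and extending the exact match
#' maximally (capped at the canonical end); continuation into the
#' genomic extension is [call_tail()]'s job.
#'
#' @param read Read sequence (U or T).
#' @param reference A [crace_reference()].
#' @return List: `junction_found`; on success `end_in_read` (0-based
#'   exclusive position of the templated 3' terminus in the read),
#'   `five_prime_start_in_read` (0-based), `ref_end` (1-based inclusive
#'   terminus position within the mature sequence); on failure `reason`
#'   in `no_anchor_pair`, `ambiguous`, `no_ref_match`.
#' @export
locate_junction <- function(read, reference) {
  read <- normalize_nt(read)
  not_found <- function(reason) list(junction_found = FALSE, reason = reason)
  anchor <- substr(reference$mature_seq, 1L, reference$five_prime_anchor_len)
  hits <- gregexpr(anchor, read, fixed = TRUE)[[1]]
  if (hits[1] == -1L && (reference$max_anchor_mismatch %||% 0L) > 0L) {
    hits <- approx_matches(read, anchor, reference$max_anchor_mismatch)
    if (length(hits) == 0L) hits <- -1L
  }
  if (hits[1] == -1L) return(not_found("no_anchor_pair"))
  if (length(hits) > 1L) return(not_found("ambiguous"))
  segment <- substr(read, 1L, hits - 1L)
  if (nchar(segment) < reference$min_anchor) return(not_found("no_anchor_pair"))
  seed <- substr(segment, 1L, reference$min_anchor)
  seed_hits <- gregexpr(seed, reference$mature_seq, fixed = TRUE)[[1]]
  if (seed_hits[1] == -1L) return(not_found("no_ref_match"))
  ext <- vapply(as.integer(seed_hits), function(q) {
    common_prefix_len(segment, substr(reference$mature_seq, q,
                                      reference$canonical_end))
  }, integer(1))
  best <- max(ext)
  if (best < reference$min_anchor) return(not_found("no_ref_match"))
  if (sum(ext == best) > 1L) return(not_found("ambiguous"))
  q <- as.integer(seed_hits)[which.max(ext)]
  list(
    junction_found = TRUE,
    end_in_read = best,
    five_prime_start_in_read = as.integer(hits) - 1L,
    ref_end = q + best - 1L
  )
}

#' Call the 3' terminus and non-templated tail of one cRACE read
#'
#' Applies [locate_junction()]; when the matched terminus reaches the
#' canonical end, remaining read bases that continue to match the
#' genomic extension are consumed as templated read-through
#' (greedy templated-first rule). The call reports the signed 3'-end
#' offset relative to the canonical end (negative = truncated, positive
#' = genomically extended), the non-templated tail in the RNA alphabet,
#' and the uridylation verdict: a read is uridylated iff its
#' non-templated tail contains at least 5 consecutive U. Because
#' templated bases are consumed greedily first, a read ending in exactly
#' the four genomically templated U's carries no tail and is not
#' uridylated — the rule that separates genuine U-tails from polymerase
#' read-through.
#'
#' @param read Read sequence.
#' @param reference A [crace_reference()].
#' @param read_id Identifier carried into the result.
#' @return One-row data.frame: `read_id`, `junction_found`,
#'   `end_offset`, `tail_seq` (RNA alphabet), `is_uridylated`,
#'   `raw_segment_uridylated` (the literal criterion applied to the
#'   whole pre-anchor read segment, templated bases included — reported
#'   alongside for comparison, never merged into `is_uridylated`),
#'   `reason`.
#' @export
call_tail <- function(read, reference, read_id = NA_character_) {
  call_tails(stats::setNames(read, read_id), reference)
}

# lean per-read worker shared by call_tail/call_tails
call_tail_core <- function(read, reference) {
  j <- locate_junction(read, reference)
  if (!j$junction_found) {
    return(list(FALSE, NA_integer_, NA_character_, j$reason, NA))
  }
  read <- normalize_nt(read)
  segment <- substr(read, 1L, j$five_prime_start_in_read)
  tail_dna <- substr(read, j$end_in_read + 1L, j$five_prime_start_in_read)
  templ_ext <- 0L
  if (j$ref_end == reference$canonical_end) {
    # read-through past the canonical end: consume templated genomic bases
    templ_ext <- common_prefix_len(tail_dna, reference$genomic_extension)
    tail_dna <- substr(tail_dna, templ_ext + 1L, nchar(tail_dna))
  }
  list(TRUE, j$ref_end + templ_ext - reference$canonical_end, tail_dna, "",
       grepl("TTTTT", segment, fixed = TRUE))
}

#' Call tails for a set of reads
#'
#' @param reads Named character vector of read sequences (names become
#'   read ids).
#' @param reference A [crace_reference()].
#' @return data.frame with one row per read (see [call_tail()]).
#' @export
call_tails <- function(reads, reference) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  res <- lapply(reads, call_tail_core, reference = reference)
  tail_dna <- vapply(res, `[[`, "", 3L)
  data.frame(
    read_id = ids,
    junction_found = vapply(res, `[[`, NA, 1L),
    end_offset = vapply(res, `[[`, NA_integer_, 2L),
    tail_seq = as_rna(tail_dna),
    is_uridylated = ifelse(is.na(tail_dna), NA,
                           grepl("TTTTT", tail_dna, fixed = TRUE)),
    raw_segment_uridylated = vapply(res, `[[`, NA, 5L),
    reason = vapply(res, `[[`, "", 4L),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Spectrum of 3'-end offsets and uridylation per offset
#'
#' @param tail_calls Output of [call_tails()].
#' @return data.frame: `end_offset`, `n_reads`, `n_uridylated`,
#'   `frac_uridylated`, sorted by offset; attribute
#'   `overall_frac_uridylated` and `n_failed` (junction not found).
#' @export
tail_spectrum <- function(tail_calls) {
  ok <- tail_calls[tail_calls$junction_found, , drop = FALSE]
  if (nrow(ok) == 0L) stop("tail_spectrum: no successful tail calls")
  agg <- stats::aggregate(
    cbind(n_reads = rep(1L, nrow(ok)), n_uridylated = as.integer(ok$is_uridylated)),
    by = list(end_offset = ok$end_offset), FUN = sum)
  agg <- agg[order(agg$end_offset), , drop = FALSE]
  agg$frac_uridylated <- agg$n_uridylated / agg$n_reads
  rownames(agg) <- NULL
  attr(agg, "overall_frac_uridylated") <- mean(ok$is_uridylated)
  attr(agg, "n_failed") <- sum(!tail_calls$junction_found)
  agg
}
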