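#' Configuration for the cRACE read simulator
#'
#' Emulates a circularization-RACE library for one small RNA: each read
#' is a reference suffix ending at a sampled 3' terminus, a sampled
#' non-templated oligo(U) tail, then a copy of the reference 5' end
#' (the ligation junction). Termini are drawn from a mixture of
#' geometric truncation and short templated genomic extension;
#' uridylation is Bernoulli with probability
#' `logistic(beta0 + beta1 * truncation_nt)`.
#'
#' @param n_reads Number of reads.
#' @param beta0,beta1 Logistic intercept and slope (log-odds and
#'   log-odds per nt of truncation) of the uridylation model.
#' @param trunc_p Geometric parameter of the truncation depth (nt below
#'   the canonical end; mass at 0 = ends at the canonical end).
#' @param trunc_max Cap on truncation depth (nt).
#' @param p_extension Probability that a read is genomically extended
#'   instead of truncated; extensions model full read-through of the
#'   templated 4-U terminator run.
#' @param tail_geom_p Geometric parameter for U-tail length beyond the
#'   5-U minimum of uridylated reads.
#' @param p_short_tail Probability that a non-uridylated read carries a
#'   short (1-4 nt) U tail.
#' @param fragment_len Target length (nt) of the templated 3' segment.
#' @param anchor_copy_len Length of the reference 5' prefix copied into
#'   each read; must be at least the reference's
#'   `five_prime_anchor_len`.
#' @param substitution_rate Per-base uniform substitution error rate
#'   (0 = error-free; errors stress junction detection).
#' @param seed Integer seed.
#' @return List of class `crace_sim_config`.
#' @export
crace_sim_config <- function(n_reads = 1000L,
                             beta0 = -3, beta1 = 0.25,
                             trunc_p = 0.08, trunc_max = 60L,
                             p_extension = 0.1,
                             tail_geom_p = 0.35, p_short_tail = 0.3,
                             fragment_len = 50L, anchor_copy_len = 30L,
                             substitution_rate = 0, seed = 1L) {
  cfg <- list(n_reads = as.integer(n_reads), beta0 = beta0, beta1 = beta1,
              trunc_p = trunc_p, trunc_max = as.integer(trunc_max),
              p_extension = p_extension,
              tail_geom_p = tail_geom_p, p_short_tail = p_short_tail,
              fragment_len = as.integer(fragment_len),
              anchor_copy_len = as.integer(anchor_copy_len),
              substitution_rate = substitution_rate, seed = as.integer(seed))
  stopifnot(is.finite(cfg$beta0), is.finite(cfg$beta1),
            cfg$n_reads >= 0L, cfg$trunc_p > 0, cfg$trunc_p <= 1,
            cfg$p_extension >= 0, cfg$p_extension <= 1,
            cfg$substitution_rate >= 0, cfg$substitution_rate < 1)
  class(cfg) <- "crace_sim_config"
  cfg
}

#' Synthetic small-RNA reference for cRACE simulation
#'
#' A random reference standing in for a real small RNA (e.g. the ~300-nt
#' SRP RNA): random mature sequence whose genomic extension begins with
#' the templated 4-U run of an RNA-polymerase-III terminator. Purely
#' synthetic — no real sequence is embedded.
#'
#' @param length Mature length in nt.
#' @param extension_len Genomic-extension length in nt (>= 4).
#' @param seed Integer seed.
#' @inheritParams crace_reference
#' @return A [crace_reference()].
#' @export
synthetic_crace_reference <- function(length = 300L, extension_len = 20L,
                                      five_prime_anchor_len = 20L,
                                      min_anchor = 12L, seed = 1L) {
  stopifnot(extension_len >= 4L)
  with_seed(seed, {
    # extension after the U-run avoids T so the templated U-tract is exactly 4
    ext_rest <- paste0(sample(c("A", "C", "G"), extension_len - 4L,
                              replace = TRUE), collapse = "")
    # keep the mature 3' end non-T so offset-0 termini are unambiguous
    # except through the genuine templated U-tract
    mature <- random_seq(length - 1L)
    mature <- paste0(mature, sample(c("A", "C", "G"), 1L))
    crace_reference(mature, paste0("TTTT", ext_rest),
                    five_prime_anchor_len = five_prime_anchor_len,
                    min_anchor = min_anchor)
  })
}

#' Simulate cRACE reads with a per-read truth table
#'
#' Because templated nucleotides are consumed greedily before any tail
#' base, a U tail drawn at a terminus immediately upstream of a
#' templated U is partially indistinguishable from read-through — the
#' sampled and the observable 3' end would differ. To keep the
#' generative state identifiable, termini are therefore sampled at
#' tail-stable positions only: any sampled terminus whose next
#' templated base is U slides forward to the end of that templated
#' U-run (genomic extensions, in particular, are modeled as full
#' read-through of the 4-U terminator). The truth table then records
#' exactly the call an exact caller produces; with
#' `substitution_rate = 0`, [call_tails()] must reproduce it per read.
#'
#' @param reference A [crace_reference()].
#' @param config A [crace_sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List: `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `end_offset`, `tail_seq` (RNA alphabet),
#'   `is_uridylated`).
#' @export
simulate_crace_reads <- function(reference, config, seed = config$seed) {
  stopifnot(inherits(reference, "crace_reference"),
            inherits(config, "crace_sim_config"))
  if (config$anchor_copy_len < reference$five_prime_anchor_len) {
    stop("anchor_copy_len below the reference's junction-detection minimum")
  }
  ref_full <- paste0(reference$mature_seq, reference$genomic_extension)
  ref_chars <- strsplit(ref_full, "", fixed = TRUE)[[1]]
  # leading templated U-run of the genomic extension (Pol III terminator)
  ext_chars <- strsplit(reference$genomic_extension, "", fixed = TRUE)[[1]]
  t_run <- match(FALSE, ext_chars == "T", nomatch = length(ext_chars) + 1L) - 1L
  with_seed(seed, {
    n <- config$n_reads
    extended <- stats::runif(n) < config$p_extension
    offset <- integer(n)
    offset[extended] <- t_run
    offset[!extended] <- -pmin(stats::rgeom(sum(!extended), config$trunc_p),
                               config$trunc_max)
    terminus <- reference$canonical_end + offset   # 1-based inclusive in ref_full
    # slide each terminus to the end of any templated U-run so the
    # position is tail-stable (next templated base != U)
    repeat {
      can_slide <- terminus < nchar(ref_full) &
        ref_chars[pmin(terminus + 1L, nchar(ref_full))] == "T"
      if (!any(can_slide)) break
      terminus[can_slide] <- terminus[can_slide] + 1L
    }
    offset <- terminus - reference$canonical_end
    truncation <- -offset
    p_u <- stats::plogis(config$beta0 + config$beta1 * truncation)
    urid <- stats::runif(n) < p_u
    tail_len <- integer(n)
    tail_len[urid] <- 5L + stats::rgeom(sum(urid), config$tail_geom_p)
    short <- !urid & stats::runif(n) < config$p_short_tail
    tail_len[short] <- sample.int(4L, sum(short), replace = TRUE)
    frag_start <- pmax(1L, terminus - config$fragment_len + 1L)
    templated <- substr(rep(ref_full, n), frag_start, terminus)
    tail <- strrep("T", tail_len)
    anchor <- substr(reference$mature_seq, 1L, config$anchor_copy_len)
    reads <- paste0(templated, tail, anchor)
    if (config$substitution_rate > 0) {
      reads <- vapply(reads, mutate_seq, character(1),
                      rate = config$substitution_rate, USE.NAMES = FALSE)
    }
    ids <- sprintf("cr%06d", seq_len(n))
    names(reads) <- ids
    # tail-stable sampling makes greedy canonicalization the identity;
    # run it anyway as an internal consistency check
    canon <- canonicalize_tail(offset, tail_len, reference)
    stopifnot(identical(canon$end_offset, offset))
    truth <- data.frame(
      read_id = ids,
      end_offset = offset,
      tail_seq = as_rna(strrep("T", tail_len)),
      is_uridylated = tail_len >= 5L,
      stringsAsFactors = FALSE
    )
    list(reads = reads, truth = truth)
  })
}

# Re-express a sampled (offset, U-tail) pair under the greedy
# templated-first rule: leading tail U's that coincide with templated T's
# immediately downstream of the sampled terminus are absorbed into the
# templated segment. Tails here are pure U, so absorption runs while the
# next reference base is T.
canonicalize_tail <- function(offset, tail_len, reference) {
  ref_full <- paste0(reference$mature_seq, reference$genomic_extension)
  ref_len <- nchar(ref_full)
  terminus <- reference$canonical_end + offset
  for (i in seq_along(offset)) {
    while (tail_len[i] > 0L && terminus[i] < ref_len &&
           substr(ref_full, terminus[i] + 1L, terminus[i] + 1L) == "T") {
      terminus[i] <- terminus[i] + 1L
      tail_len[i] <- tail_len[i] - 1L
    }
  }
  list(end_offset = terminus - reference$canonical_end, tail_len = tail_len)
}

mutate_seq <- function(s, rate) {
  n <- nchar(s)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste0(chars, collapse = "")
}
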