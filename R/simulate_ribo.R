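#' Configuration for the ribosome-profiling simulator
#'
#' The generator emulates the structure of a two-condition (control vs
#' knockout) Ribo-seq experiment: per-gene mRNA abundances shared across
#' conditions, per-gene translation-efficiency (TE) ratios that are
#' log-normal around 1 except for a planted set of translationally
#' downregulated genes, and — on signal-peptide genes in the knockout —
#' a ribosome stall modeled as a multiplicative footprint-density factor
#' over the first `stall_codons` codons. The stall reweights positions
#' within a gene and is renormalized, so gene totals reflect TE only and
#' metagene shape and TE calling stay decoupled.
#'
#' @param n_genes Number of transcripts.
#' @param cds_length_range Min/max CDS length in codons (inclusive).
#' @param fraction_sp_genes Fraction of genes flagged signal-peptide
#'   (assigned exactly, rounded).
#' @param fraction_tm_genes Fraction flagged transmembrane (independent).
#' @param te_sdlog Natural-log SD of null per-gene KO/CTRL TE ratios.
#' @param n_planted_down Number of genes planted translationally down.
#' @param planted_te_ratio Exact KO/CTRL TE ratio of planted genes
#'   (must be <= 0.5 so the planted set is unambiguously 2-fold down).
#' @param planted_sp_weight Sampling weight multiplier for signal-peptide
#'   genes when drawing the planted-down set (1 = unbiased; >1 emulates
#'   the observed over-representation of ER-targeted transcripts among
#'   downregulated genes).
#' @param stall_strength Footprint-density multiplier over the first
#'   `stall_codons` codons of signal-peptide genes in the knockout.
#' @param stall_codons Length of the stall window in codons.
#' @param depth Reads per library.
#' @param read_length_probs Named probabilities over footprint lengths
#'   28-31 nt.
#' @param offlen_fraction Fraction of reads given an out-of-window length
#'   (26, 27, 32 or 33 nt) so the length filter has work to do.
#' @param frame_fidelity Probability that a footprint 5' end falls in
#'   frame 0; the remainder is shifted +/-1 nt.
#' @param multimap_fraction Fraction of reads flagged non-unique.
#' @param mrna_sdlog Natural-log SD of per-gene mRNA abundances.
#' @param utr5,utr3 UTR lengths in nt (5' UTR must accommodate the
#'   15-nt A-site offset for start-codon footprints).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return List of class `ribo_sim_config`.
#' @export
ribo_sim_config <- function(n_genes = 2000,
                            cds_length_range = c(100L, 400L),
                            fraction_sp_genes = 0.3,
                            fraction_tm_genes = 0.15,
                            te_sdlog = 0.15,
                            n_planted_down = 20,
                            planted_te_ratio = 0.4,
                            planted_sp_weight = 1,
                            stall_strength = 5,
                            stall_codons = 25L,
                            depth = 2e6,
                            read_length_probs = c("28" = 0.2, "29" = 0.3,
                                                  "30" = 0.3, "31" = 0.2),
                            offlen_fraction = 0.05,
                            frame_fidelity = 0.9,
                            multimap_fraction = 0.02,
                            mrna_sdlog = 1,
                            utr5 = 30L, utr3 = 45L,
                            seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    cds_length_range = as.integer(cds_length_range),
    fraction_sp_genes = fraction_sp_genes,
    fraction_tm_genes = fraction_tm_genes,
    te_sdlog = te_sdlog,
    n_planted_down = as.integer(n_planted_down),
    planted_te_ratio = planted_te_ratio,
    planted_sp_weight = planted_sp_weight,
    stall_strength = stall_strength,
    stall_codons = as.integer(stall_codons),
    depth = depth,
    read_length_probs = read_length_probs,
    offlen_fraction = offlen_fraction,
    frame_fidelity = frame_fidelity,
    multimap_fraction = multimap_fraction,
    mrna_sdlog = mrna_sdlog,
    utr5 = as.integer(utr5), utr3 = as.integer(utr3),
    seed = as.integer(seed)
  )
  validate_ribo_sim_config(cfg)
  class(cfg) <- "ribo_sim_config"
  cfg
}

validate_ribo_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L)
  if (length(cfg$cds_length_range) != 2L ||
      cfg$cds_length_range[1] > cfg$cds_length_range[2] ||
      cfg$cds_length_range[1] < 6L) {
    stop("infeasible cds_length_range (need min <= max, min >= 6 codons)")
  }
  probs <- c(cfg$fraction_sp_genes, cfg$fraction_tm_genes,
             cfg$offlen_fraction, cfg$frame_fidelity, cfg$multimap_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$depth < 0) stop("depth must be non-negative")
  if (cfg$n_planted_down > cfg$n_genes) stop("more planted genes than genes")
  if (cfg$planted_te_ratio > 0.5 || cfg$planted_te_ratio <= 0) {
    stop("planted_te_ratio must lie in (0, 0.5]")
  }
  if (cfg$stall_strength < 1) stop("stall_strength must be >= 1")
  if (abs(sum(cfg$read_length_probs) - 1) > 1e-8 ||
      !setequal(names(cfg$read_length_probs), c("28", "29", "30", "31"))) {
    stop("read_length_probs must be a distribution over lengths 28-31")
  }
  if (cfg$utr5 < 16L) stop("utr5 must be >= 16 nt to place start-codon footprints")
  invisible(cfg)
}

# Run code under a temporary RNG state so generators are pure in (config, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

SENSE_CODONS <- {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

random_cds <- function(n_codons) {
  # ATG + random sense codons + TAA; no internal stops by construction
  paste0("ATG",
         paste0(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                collapse = ""),
         "TAA")
}

#' Generate a synthetic transcriptome with known ground truth
#'
#' @param config A [ribo_sim_config()].
#' @return List with `transcripts` (a `transcript_table`) and `truth`
#'   (data.frame: `transcript_id`, `mrna_weight` — relative mRNA
#'   abundance shared by both conditions —, `te_ctrl`, `te_ratio`
#'   (true KO/CTRL TE ratio), `is_planted_down`, `is_stalled`).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "ribo_sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    ids <- sprintf("g%05d", seq_len(n))
    len_choices <- seq.int(config$cds_length_range[1], config$cds_length_range[2])
    n_codons <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
    seqs <- vapply(n_codons, function(k) {
      paste0(random_seq(config$utr5), random_cds(k), random_seq(config$utr3))
    }, character(1))
    n_sp <- round(config$fraction_sp_genes * n)
    sp <- logical(n); sp[sample.int(n, n_sp)] <- TRUE
    n_tm <- round(config$fraction_tm_genes * n)
    tm <- logical(n); tm[sample.int(n, n_tm)] <- TRUE
    transcripts <- transcript_table(
      transcript_id = ids, sequence = seqs,
      cds_start = config$utr5, cds_end = config$utr5 + 3L * n_codons,
      has_signal_peptide = sp, has_transmembrane = tm
    )
    w <- rep(1, n)
    w[sp] <- config$planted_sp_weight
    planted <- sample.int(n, config$n_planted_down, prob = w)
    te_ratio <- exp(stats::rnorm(n, 0, config$te_sdlog))
    te_ratio[planted] <- config$planted_te_ratio
    truth <- data.frame(
      transcript_id = ids,
      mrna_weight = exp(stats::rnorm(n, 0, config$mrna_sdlog)),
      te_ctrl = exp(stats::rnorm(n, 0, 0.3)),
      te_ratio = te_ratio,
      is_planted_down = seq_len(n) %in% planted,
      is_stalled = sp,  # stall applies to SP genes in the knockout
      stringsAsFactors = FALSE
    )
    list(transcripts = transcripts, truth = truth)
  })
}

random_seq <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate one ribosome-footprint library
#'
#' Reads are drawn per gene with abundance proportional to
#' `mrna_weight * TE(condition)`; within a gene, A-site codon positions
#' are uniform except over the stall window of stalled genes in the
#' knockout, where density is multiplied by `stall_strength` (and
#' renormalized, leaving gene totals untouched). The 5' end sits 15 nt
#' upstream of the A site, jittered off-frame with probability
#' `1 - frame_fidelity`.
#'
#' @param transcripts,truth Output of [generate_transcriptome()].
#' @param config The [ribo_sim_config()] used to generate them.
#' @param condition `"CTRL"` or `"KO"`.
#' @param library_id Prefix for read ids.
#' @param seed Integer seed for this library.
#' @param depth Reads to draw (defaults to `config$depth`).
#' @return Alignment data.frame (`read_id`, `transcript_id`,
#'   `five_prime_pos`, `read_length`, `is_unique`).
#' @export
simulate_rpf_library <- function(transcripts, truth, config,
                                 condition = c("CTRL", "KO"),
                                 library_id = condition, seed = config$seed,
                                 depth = config$depth) {
  condition <- match.arg(condition)
  stopifnot(identical(transcripts$transcript_id, truth$transcript_id))
  with_seed(seed, {
    te <- truth$te_ctrl * if (condition == "KO") truth$te_ratio else 1
    w <- truth$mrna_weight * te
    n_reads <- as.vector(stats::rmultinom(1, size = depth, prob = w))
    ncod <- cds_codons(transcripts)
    stall_here <- condition == "KO" & truth$is_stalled
    codon_idx <- vector("list", nrow(transcripts))
    for (g in which(n_reads > 0L)) {
      k <- unname(ncod[g])
      wpos <- rep(1, k)
      if (stall_here[g]) {
        j <- seq_len(min(config$stall_codons, k))
        wpos[j] <- wpos[j] * config$stall_strength
      }
      codon_idx[[g]] <- sample.int(k, n_reads[g], replace = TRUE, prob = wpos) - 1L
    }
    gene_of <- rep.int(seq_len(nrow(transcripts)), n_reads)
    codon <- unlist(codon_idx, use.names = FALSE)
    total <- length(gene_of)
    fp <- transcripts$cds_start[gene_of] + 3L * codon - 15L
    off <- stats::runif(total) > config$frame_fidelity
    fp[off] <- fp[off] + sample(c(-1L, 1L), sum(off), replace = TRUE)
    len <- integer(total)
    offlen <- stats::runif(total) < config$offlen_fraction
    len[offlen] <- sample(c(26L, 27L, 32L, 33L), sum(offlen), replace = TRUE)
    len[!offlen] <- sample(as.integer(names(config$read_length_probs)),
                           sum(!offlen), replace = TRUE,
                           prob = config$read_length_probs)
    out <- data.frame(
      read_id = paste0(library_id, "_r", seq_len(total)),
      transcript_id = transcripts$transcript_id[gene_of],
      five_prime_pos = fp,
      read_length = len,
      is_unique = stats::runif(total) >= config$multimap_fraction,
      stringsAsFactors = FALSE
    )
    # permute so within-file order carries no gene structure
    out <- out[sample.int(total), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate an mRNA-seq count column
#'
#' A multinomial draw from the per-gene mRNA abundances, which are shared
#' by both conditions (knockout of the exoribonuclease does not change
#' steady-state mRNA levels in this model).
#'
#' @inheritParams simulate_rpf_library
#' @return Named integer vector of counts over transcripts.
#' @export
simulate_mrna_counts <- function(transcripts, truth, config,
                                 condition = c("CTRL", "KO"),
                                 seed = config$seed, depth = config$depth) {
  condition <- match.arg(condition)
  stopifnot(identical(transcripts$transcript_id, truth$transcript_id))
  with_seed(seed, {
    if (depth == 0) {
      return(stats::setNames(integer(nrow(truth)), truth$transcript_id))
    }
    cnt <- as.vector(stats::rmultinom(1, size = depth, prob = truth$mrna_weight))
    stats::setNames(cnt, truth$transcript_id)
  })
}

#' Simulate the full two-condition, two-replicate ribosome-profiling study
#'
#' Convenience wrapper producing everything the TE pipeline consumes:
#' the transcriptome with truth table, one footprint alignment set per
#' RPF library, and the assembled RPF + mRNA [count_table()] (RPF counts
#' are taken after [filter_rpfs()], i.e. the same filtering real data
#' receives).
#'
#' @param config A [ribo_sim_config()].
#' @param n_replicates Replicates per condition.
#' @return List: `transcripts`, `truth`, `rpf_alignments` (named list of
#'   alignment data.frames), `counts` (a `count_table`).
#' @export
simulate_ribo_study <- function(config, n_replicates = 2L) {
  tx <- generate_transcriptome(config)
  conditions <- c("CTRL", "KO")
  rpf <- list()
  cols <- list()
  libs <- list()
  i <- 0L
  for (cond in conditions) {
    for (rep_i in seq_len(n_replicates)) {
      i <- i + 1L
      lib <- sprintf("RPF_%s_%d", cond, rep_i)
      aln <- simulate_rpf_library(tx$transcripts, tx$truth, config, cond,
                                  library_id = lib,
                                  seed = config$seed + 1000L + i)
      rpf[[lib]] <- aln
      kept <- filter_rpfs(aln, tx$transcripts)
      cols[[lib]] <- count_per_transcript(kept, tx$transcripts$transcript_id)
      libs[[lib]] <- data.frame(library_id = lib, assay = "RPF",
                                condition = cond, replicate = rep_i,
                                stringsAsFactors = FALSE)
      mlib <- sprintf("mRNA_%s_%d", cond, rep_i)
      cols[[mlib]] <- simulate_mrna_counts(tx$transcripts, tx$truth, config,
                                           cond, seed = config$seed + 2000L + i)
      libs[[mlib]] <- data.frame(library_id = mlib, assay = "mRNA",
                                 condition = cond, replicate = rep_i,
                                 stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- tx$transcripts$transcript_id
  list(transcripts = tx$transcripts, truth = tx$truth,
       rpf_alignments = rpf,
       counts = count_table(counts, do.call(rbind, libs)))
}
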