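#' Filter ribosome-protected fragments for A-site analysis
#'
#' Keeps footprints that are uniquely mapped, 28-31 nt long, and whose
#' A site — inferred at a fixed offset of 15 nt from the fragment 5'
#' end — lies inside the CDS in the zero reading frame. Alignments to
#' unknown transcripts are skipped and counted. The filter is idempotent.
#'
#' @param alignments Alignment data.frame (see [read_alignments()]).
#' @param transcripts A `transcript_table`.
#' @param min_length,max_length Retained fragment-length window (nt).
#' @param offset A-site offset from the 5' end (nt).
#' @return The retained alignments, with attribute `filter_report`: a
#'   named integer vector of rejection counts
#'   (`unknown_transcript`, `not_unique`, `length`, `outside_cds`,
#'   `frame`) plus `input` and `retained`.
#' @export
filter_rpfs <- function(alignments, transcripts,
                        min_length = 28L, max_length = 31L, offset = 15L) {
  idx <- match(alignments$transcript_id, transcripts$transcript_id)
  known <- !is.na(idx)
  unique_ok <- known & alignments$is_unique
  len_ok <- unique_ok & alignments$read_length >= min_length &
    alignments$read_length <= max_length
  a_site <- alignments$five_prime_pos + offset
  cds_start <- transcripts$cds_start[idx]
  cds_end <- transcripts$cds_end[idx]
  in_cds <- len_ok & !is.na(cds_start) & a_site >= cds_start & a_site < cds_end
  in_cds[is.na(in_cds)] <- FALSE
  frame_ok <- in_cds & ((a_site - cds_start) %% 3L == 0L)
  frame_ok[is.na(frame_ok)] <- FALSE
  report <- c(
    input = nrow(alignments),
    unknown_transcript = sum(!known),
    not_unique = sum(known & !unique_ok),
    length = sum(unique_ok & !len_ok),
    outside_cds = sum(len_ok & !in_cds),
    frame = sum(in_cds & !frame_ok),
    retained = sum(frame_ok)
  )
  out <- alignments[frame_ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}

#' Assign A-site codons to filtered footprints
#'
#' For each retained fragment the decoded (A-site) codon index within the
#' CDS is `(five_prime_pos + offset - cds_start) / 3`, and the codon
#' 3-mer is read off the transcript sequence. Events whose A site falls
#' on one of the last three CDS codons are flagged `near_stop`: they are
#' valid for metagene and TE counting but have fewer than three
#' downstream codons, so they are excluded from basal occupancy
#' normalization.
#'
#' @param alignments Output of [filter_rpfs()].
#' @param transcripts A `transcript_table`.
#' @param offset A-site offset from the 5' end (nt); must match the
#'   offset used in filtering.
#' @return data.frame: `transcript_id`, `codon_index` (0-based within
#'   CDS), `codon`, `near_stop`.
#' @export
assign_a_sites <- function(alignments, transcripts, offset = 15L) {
  idx <- match(alignments$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) stop("assign_a_sites: unknown transcript_id; run filter_rpfs first")
  a_site <- alignments$five_prime_pos + offset
  cds_start <- transcripts$cds_start[idx]
  rel <- a_site - cds_start
  if (any(rel < 0L) || any(rel %% 3L != 0L) ||
      any(a_site >= transcripts$cds_end[idx])) {
    stop("assign_a_sites: alignment outside CDS or off-frame; run filter_rpfs first")
  }
  codon_index <- rel %/% 3L
  ncod <- (transcripts$cds_end[idx] - cds_start) %/% 3L
  codon <- substr(transcripts$sequence[idx], cds_start + 3L * codon_index + 1L,
                  cds_start + 3L * codon_index + 3L)
  data.frame(
    transcript_id = alignments$transcript_id,
    codon_index = codon_index,
    codon = codon,
    near_stop = codon_index >= ncod - 3L,
    stringsAsFactors = FALSE
  )
}

#' Codon occupancy with basal normalization
#'
#' For every A-site event the raw positional count at its codon is
#' divided by the basal occupancy of that position — the mean of the raw
#' counts at the +1, +2 and +3 codons downstream on the same gene. The
#' normalized occupancy of a codon species is the mean of these
#' per-event ratios over all events decoding that codon. Under globally
#' uniform coverage every codon's occupancy is exactly 1
#' (self-normalization identity). Events with fewer than three
#' downstream CDS codons or a zero basal are excluded and counted, never
#' divided.
#'
#' @param assignments Output of [assign_a_sites()].
#' @param transcripts A `transcript_table`.
#' @return data.frame over the 61 sense codons: `codon`, `n_events`
#'   (events contributing), `occupancy` (NA for codons never observed),
#'   with attribute `excluded` = c(near_stop = ..., zero_basal = ...).
#' @export
codon_occupancy <- function(assignments, transcripts) {
  empty <- data.frame(codon = SENSE_CODONS, n_events = 0L,
                      occupancy = NA_real_, stringsAsFactors = FALSE)
  if (nrow(assignments) == 0L) {
    warning("codon_occupancy: no A-site events")
    attr(empty, "excluded") <- c(near_stop = 0L, zero_basal = 0L)
    return(empty)
  }
  ncod <- cds_codons(transcripts)
  # raw positional profile per gene: count of A-site events per codon index
  key <- paste(assignments$transcript_id, assignments$codon_index)
  pos_count_tab <- table(key)
  pos_count <- as.integer(pos_count_tab)[match(key, names(pos_count_tab))]
  down <- function(k) {
    dk <- paste(assignments$transcript_id, assignments$codon_index + k)
    cnt <- as.integer(pos_count_tab)[match(dk, names(pos_count_tab))]
    ifelse(is.na(cnt), 0L, cnt)
  }
  eligible <- assignments$codon_index + 3L < ncod[assignments$transcript_id]
  basal <- (down(1L) + down(2L) + down(3L)) / 3
  zero_basal <- eligible & basal == 0
  use <- eligible & basal > 0
  ratio <- pos_count[use] / basal[use]
  codon_f <- factor(assignments$codon[use], levels = SENSE_CODONS)
  occ <- tapply(ratio, codon_f, mean)
  n_events <- as.integer(table(codon_f))
  out <- data.frame(codon = SENSE_CODONS, n_events = n_events,
                    occupancy = as.numeric(occ), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- c(near_stop = sum(!eligible),
                             zero_basal = sum(zero_basal))
  out
}

#' Metagene profile over length-normalized CDS bins
#'
#' Each gene's CDS is divided into `n_bins` equal bins; A-site events at
#' codon index `i` of an `L`-codon CDS fall in bin
#' `floor(n_bins * i / L)`. Per-gene binned counts are normalized by the
#' gene's total footprint count (each per-gene profile sums to 1), then
#' averaged across genes with equal weight. Genes with fewer than
#' `min_rpf` events are excluded; genes shorter than `n_bins` codons are
#' allowed (bins may receive several or zero codons) but flagged.
#'
#' @param assignments Output of [assign_a_sites()].
#' @param transcripts A `transcript_table`.
#' @param gene_set Character vector of transcript ids to profile.
#' @param n_bins Number of bins.
#' @param min_rpf Minimum footprints per gene.
#' @return data.frame: `bin` (0-based), `mean_density`, `n_genes`; with
#'   attributes `genes_used`, `genes_dropped_low_count`,
#'   `genes_shorter_than_bins`.
#' @export
metagene_profile <- function(assignments, transcripts, gene_set,
                             n_bins = 50L, min_rpf = 32L) {
  stopifnot(length(gene_set) > 0L)
  asg <- assignments[assignments$transcript_id %in% gene_set, , drop = FALSE]
  counts_per_gene <- table(factor(asg$transcript_id, levels = gene_set))
  usable <- names(counts_per_gene)[counts_per_gene >= min_rpf]
  if (length(usable) == 0L) {
    stop("metagene_profile: no gene in gene_set has >= ", min_rpf, " footprints")
  }
  asg <- asg[asg$transcript_id %in% usable, , drop = FALSE]
  ncod <- cds_codons(transcripts)
  L <- ncod[asg$transcript_id]
  bin <- as.integer(floor(n_bins * asg$codon_index / L))
  gene_f <- factor(asg$transcript_id, levels = usable)
  bin_f <- factor(bin, levels = 0:(n_bins - 1L))
  m <- table(gene_f, bin_f)                 # genes x bins counts
  prof <- sweep(m, 1, rowSums(m), "/")      # per-gene profiles sum to 1
  mean_density <- colMeans(prof)
  out <- data.frame(bin = 0:(n_bins - 1L),
                    mean_density = as.numeric(mean_density),
                    n_genes = length(usable))
  attr(out, "genes_used") <- usable
  attr(out, "genes_dropped_low_count") <-
    setdiff(gene_set, c(usable, setdiff(gene_set, names(counts_per_gene))))
  attr(out, "genes_shorter_than_bins") <-
    names(ncod)[ncod < n_bins][names(ncod)[ncod < n_bins] %in% usable]
  out
}

#' Translation efficiency per gene and condition
#'
#' TE is footprint abundance on the CDS divided by mRNA abundance.
#' Counts are scaled to counts-per-million within each library (library
#' totals taken over testable genes), a pseudocount stabilizes ratios at
#' low counts, replicate TEs are combined by geometric mean per
#' condition, and the KO-vs-CTRL contrast is reported as
#' `log2_te_ratio`. A gene is testable iff its mRNA count is at least
#' `min_mrna` in every mRNA library and its RPF count at least `min_rpf`
#' in at least one library. Replicates are paired by replicate index
#' (RPF replicate i over mRNA replicate i of the same condition).
#'
#' @param counts A [count_table()] with RPF and mRNA libraries for
#'   conditions `"CTRL"` and `"KO"`.
#' @param pseudocount Added to both CPM values.
#' @param min_mrna,min_rpf Testability thresholds on raw counts.
#' @return data.frame (class `te_table`): `gene`, one `rpf_cpm_*` and
#'   `mrna_cpm_*` column per library, `te_CTRL`, `te_KO`,
#'   `log2_te_ratio`, `testable`.
#' @export
compute_te <- function(counts, pseudocount = 0.5, min_mrna = 10L,
                       min_rpf = 10L) {
  stopifnot(inherits(counts, "count_table"))
  libs <- counts$libraries
  m <- counts$counts
  for (cond in c("CTRL", "KO")) {
    for (assay in c("RPF", "mRNA")) {
      if (!any(libs$condition == cond & libs$assay == assay)) {
        stop("compute_te: no ", assay, " library for condition ", cond)
      }
    }
  }
  mrna_cols <- libs$library_id[libs$assay == "mRNA"]
  rpf_cols <- libs$library_id[libs$assay == "RPF"]
  testable <- rowSums(m[, mrna_cols, drop = FALSE] >= min_mrna) ==
    length(mrna_cols) &
    rowSums(m[, rpf_cols, drop = FALSE] >= min_rpf) >= 1L
  cpm <- m
  storage.mode(cpm) <- "double"
  totals <- colSums(m[testable, , drop = FALSE])
  if (any(totals == 0)) stop("compute_te: a library has zero testable counts")
  cpm <- sweep(cpm, 2, totals, "/") * 1e6
  te_cond <- function(cond) {
    rpf_i <- libs$library_id[libs$assay == "RPF" & libs$condition == cond]
    rpf_i <- rpf_i[order(libs$replicate[match(rpf_i, libs$library_id)])]
    mrna_i <- libs$library_id[libs$assay == "mRNA" & libs$condition == cond]
    mrna_i <- mrna_i[order(libs$replicate[match(mrna_i, libs$library_id)])]
    if (length(rpf_i) != length(mrna_i)) {
      stop("compute_te: unpaired RPF/mRNA replicates in condition ", cond)
    }
    lte <- 0
    for (r in seq_along(rpf_i)) {
      lte <- lte + log2((cpm[, rpf_i[r]] + pseudocount) /
                          (cpm[, mrna_i[r]] + pseudocount))
    }
    2^(lte / length(rpf_i))  # geometric mean over replicates
  }
  te_ctrl <- te_cond("CTRL")
  te_ko <- te_cond("KO")
  out <- data.frame(gene = rownames(m), stringsAsFactors = FALSE)
  for (lib in libs$library_id) {
    prefix <- if (libs$assay[libs$library_id == lib] == "RPF") "rpf_cpm_" else "mrna_cpm_"
    out[[paste0(prefix, sub("^(RPF|mRNA)_", "", lib))]] <- unname(cpm[, lib])
  }
  out$te_CTRL <- unname(te_ctrl)
  out$te_KO <- unname(te_ko)
  out$log2_te_ratio <- unname(log2(te_ko / te_ctrl))
  out$testable <- unname(testable)
  class(out) <- c("te_table", "data.frame")
  out
}

#' Call differential translation at a fold-change threshold
#'
#' A testable gene is called `down` when its TE ratio drops at least
#' `threshold`-fold (`log2_te_ratio <= -log2(threshold)`), `up` when it
#' rises at least `threshold`-fold, otherwise `unchanged`; non-testable
#' genes are `not_testable`.
#'
#' @param te_records Output of [compute_te()].
#' @param threshold Fold-change threshold (> 1); default 2.
#' @return `te_records` with a `call` column added.
#' @export
call_differential_te <- function(te_records, threshold = 2) {
  if (threshold <= 1) stop("threshold must be > 1")
  lt <- log2(threshold)
  call <- rep("unchanged", nrow(te_records))
  call[te_records$log2_te_ratio <= -lt] <- "down"
  call[te_records$log2_te_ratio >= lt] <- "up"
  call[!te_records$testable] <- "not_testable"
  te_records$call <- call
  te_records
}
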