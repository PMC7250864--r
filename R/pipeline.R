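#' Simulate a full synthetic study to disk
#'
#' Writes a complete synthetic dataset — transcriptome FASTA +
#' annotation, per-library footprint alignment TSVs, mRNA/RPF count
#' table, cRACE reads FASTA, truth tables and a run manifest — in the
#' same on-disk formats real ingested data uses, so downstream stages
#' cannot tell the difference.
#'
#' @param out_dir Output directory (created).
#' @param ribo_config A [ribo_sim_config()] (NULL to skip the Ribo-seq
#'   half).
#' @param crace_config A [crace_sim_config()] (NULL to skip the cRACE
#'   half).
#' @param crace_reference A [crace_reference()]; defaults to
#'   [synthetic_crace_reference()] seeded from `crace_config`.
#' @param n_replicates Replicates per condition for the Ribo-seq half.
#' @return Invisibly, the list of files written.
#' @export
run_simulation <- function(out_dir, ribo_config = ribo_sim_config(),
                           crace_config = crace_sim_config(),
                           crace_reference = NULL, n_replicates = 2L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)   # relative names, so manifests are location-independent
  w <- function(p) { files <<- c(files, basename(p)); p }
  if (!is.null(ribo_config)) {
    study <- simulate_ribo_study(ribo_config, n_replicates = n_replicates)
    write_fasta(stats::setNames(study$transcripts$sequence,
                                study$transcripts$transcript_id),
                w(file.path(out_dir, "transcripts.fa")))
    write_annotation(study$transcripts, w(file.path(out_dir, "annotation.tsv")))
    write_tsv(study$truth, w(file.path(out_dir, "ribo_truth.tsv")))
    for (lib in names(study$rpf_alignments)) {
      write_alignments(study$rpf_alignments[[lib]],
                       w(file.path(out_dir, paste0(lib, ".alignments.tsv"))))
    }
    write_count_table(study$counts,
                      w(file.path(out_dir, "counts.tsv")),
                      w(file.path(out_dir, "libraries.tsv")))
  }
  if (!is.null(crace_config)) {
    if (is.null(crace_reference)) {
      crace_reference <- synthetic_crace_reference(seed = crace_config$seed)
    }
    sim <- simulate_crace_reads(crace_reference, crace_config)
    write_fasta(sim$reads, w(file.path(out_dir, "crace_reads.fa")))
    write_tsv(sim$truth, w(file.path(out_dir, "crace_truth.tsv")))
    yaml::write_yaml(list(mature_seq = crace_reference$mature_seq,
                          genomic_extension = crace_reference$genomic_extension,
                          five_prime_anchor_len = crace_reference$five_prime_anchor_len,
                          min_anchor = crace_reference$min_anchor),
                     w(file.path(out_dir, "crace_reference.yaml")))
  }
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = list(ribo = unclass(ribo_config),
                               crace = unclass(crace_config),
                               n_replicates = n_replicates),
                 seed = if (!is.null(ribo_config)) ribo_config$seed
                        else crace_config$seed,
                 outputs = files)
  invisible(file.path(out_dir, c(files, "manifest.json")))
}

#' Run the ribosome-profiling analysis stage on on-disk inputs
#'
#' Filter footprints, assign A sites, compute codon occupancy, metagene
#' profiles of called gene sets, translation efficiency with 2-fold
#' differential calls, annotation enrichment and codon-usage comparison;
#' writes `te.tsv`, `occupancy.tsv`, `metagene.tsv`, `enrichment.tsv`,
#' `codon_usage.tsv`, `filter_report.json` and a manifest.
#'
#' @param fasta,annotation Transcriptome inputs (see [read_fasta()],
#'   [read_annotation()]).
#' @param alignment_files Named character vector: RPF library id ->
#'   alignment TSV path. Ids must match the RPF columns of the counts.
#' @param counts_file,libraries_file Count table as written by
#'   [write_count_table()]; RPF columns are recomputed from the
#'   alignments when `recount_rpf = TRUE`.
#' @param out_dir Output directory.
#' @param occupancy_library Library id whose A sites feed the codon
#'   occupancy table (first alignment file by default).
#' @param threshold Fold-change threshold for differential TE.
#' @param pseudocount,min_mrna,min_rpf See [compute_te()].
#' @param n_bins,metagene_min_rpf See [metagene_profile()].
#' @param recount_rpf Recompute RPF count columns from the filtered
#'   alignments (TRUE) or trust the stored counts (FALSE).
#' @return Invisibly, a list with the in-memory results
#'   (`te`, `occupancy`, `metagene`, `enrichment`, `codon_usage`).
#' @export
run_ribo_pipeline <- function(fasta, annotation, alignment_files,
                              counts_file, libraries_file, out_dir,
                              occupancy_library = names(alignment_files)[1],
                              threshold = 2, pseudocount = 0.5,
                              min_mrna = 10L, min_rpf = 10L,
                              n_bins = 50L, metagene_min_rpf = 32L,
                              recount_rpf = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_fasta(fasta)
  transcripts <- read_annotation(annotation, seqs)
  ct <- read_count_table(counts_file, libraries_file)
  asites <- list()
  reports <- list()
  for (lib in names(alignment_files)) {
    aln <- read_alignments(alignment_files[[lib]], "tsv", transcripts)
    kept <- filter_rpfs(aln, transcripts)
    reports[[lib]] <- as.list(attr(kept, "filter_report"))
    asites[[lib]] <- assign_a_sites(kept, transcripts)
    if (recount_rpf) {
      ct$counts[, lib] <- count_per_transcript(kept,
                                               rownames(ct$counts))
    }
  }
  te <- call_differential_te(compute_te(ct, pseudocount = pseudocount,
                                        min_mrna = min_mrna,
                                        min_rpf = min_rpf),
                             threshold = threshold)
  occupancy <- codon_occupancy(asites[[occupancy_library]], transcripts)
  enrichment <- annotation_enrichment(te, transcripts)
  down <- te$gene[te$call == "down"]
  unchanged <- te$gene[te$call == "unchanged"]
  metagene <- NULL
  all_asites <- do.call(rbind, asites)
  for (set_name in c("down", "unchanged")) {
    genes <- if (set_name == "down") down else unchanged
    prof <- tryCatch(
      metagene_profile(all_asites, transcripts, genes, n_bins = n_bins,
                       min_rpf = metagene_min_rpf),
      error = function(e) NULL)
    if (!is.null(prof)) {
      prof$gene_set <- set_name
      metagene <- rbind(metagene, prof)
    }
  }
  codon_usage <- if (length(down) > 0 && length(unchanged) > 0) {
    codon_usage_compare(transcripts, down, unchanged)
  } else NULL
  write_tsv(as.data.frame(te), file.path(out_dir, "te.tsv"))
  write_tsv(occupancy, file.path(out_dir, "occupancy.tsv"))
  if (!is.null(metagene)) write_tsv(metagene, file.path(out_dir, "metagene.tsv"))
  write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  if (!is.null(codon_usage)) {
    write_tsv(codon_usage, file.path(out_dir, "codon_usage.tsv"))
  }
  jsonlite::write_json(reports, file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = list(threshold = threshold, pseudocount = pseudocount,
                               min_mrna = min_mrna, min_rpf = min_rpf,
                               n_bins = n_bins,
                               metagene_min_rpf = metagene_min_rpf,
                               occupancy_library = occupancy_library,
                               inputs = list(fasta = fasta,
                                             annotation = annotation,
                                             alignments = as.list(alignment_files),
                                             counts = counts_file)),
                 outputs = list.files(out_dir, full.names = FALSE))
  invisible(list(te = te, occupancy = occupancy, metagene = metagene,
                 enrichment = enrichment, codon_usage = codon_usage,
                 filter_reports = reports))
}

#' Run the cRACE 3'-end stage on on-disk inputs
#'
#' Junction detection, tail calling, offset spectrum and the logistic
#' uridylation-vs-truncation fit; writes `tails.tsv`, `spectrum.tsv`,
#' `logistic.json` and a manifest.
#'
#' @param reads_file FASTA or FASTQ of cRACE reads.
#' @param reference_yaml YAML with `mature_seq`, `genomic_extension` and
#'   optional `five_prime_anchor_len`, `min_anchor`.
#' @param out_dir Output directory.
#' @param truncation_only Restrict the logistic fit to non-extended
#'   reads.
#' @return Invisibly, list(`tails`, `spectrum`, `model`).
#' @export
run_crace_pipeline <- function(reads_file, reference_yaml, out_dir,
                               truncation_only = FALSE) {
  if (!file.exists(reference_yaml)) {
    stop("cRACE reference file not found: ", reference_yaml)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref_spec <- yaml::read_yaml(reference_yaml)
  reference <- crace_reference(
    ref_spec$mature_seq, ref_spec$genomic_extension,
    five_prime_anchor_len = ref_spec$five_prime_anchor_len %||% 20L,
    min_anchor = ref_spec$min_anchor %||% 12L)
  is_fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", reads_file, ignore.case = TRUE)
  reads <- if (is_fastq) read_fastq(reads_file) else read_fasta(reads_file)
  if (length(reads) == 0L) stop("no cRACE reads in ", reads_file)
  tails <- call_tails(reads, reference)
  spectrum <- tail_spectrum(tails)
  model <- fit_uridylation_logistic(tails, truncation_only = truncation_only)
  write_tsv(tails, file.path(out_dir, "tails.tsv"))
  write_tsv(spectrum, file.path(out_dir, "spectrum.tsv"))
  jsonlite::write_json(unclass(model), file.path(out_dir, "logistic.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = list(reads = reads_file,
                               reference = reference_yaml,
                               truncation_only = truncation_only,
                               five_prime_anchor_len = reference$five_prime_anchor_len,
                               min_anchor = reference$min_anchor),
                 outputs = c("tails.tsv", "spectrum.tsv", "logistic.json"))
  invisible(list(tails = tails, spectrum = spectrum, model = model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
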