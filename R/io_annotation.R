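#' Build a validated transcript table from sequences and a CDS annotation
#'
#' Joins a TSV annotation (columns `transcript_id`, `cds_start`, `cds_end`,
#' `has_signal_peptide`, `has_transmembrane`) with sequences read from
#' FASTA. Coordinates are 0-based, half-open in transcript space: the CDS
#' covers `sequence[cds_start + 1 .. cds_end]` in R's 1-based terms.
#' Signal-peptide / transmembrane flags are produced externally (e.g. by
#' Phobius, SignalP or TMHMM) and consumed as plain booleans.
#'
#' Every record must satisfy: `0 <= cds_start < cds_end <= nchar(sequence)`,
#' CDS length divisible by 3, and CDS at least 6 codons. All violations are
#' collected and reported together, naming each offending transcript.
#'
#' @param path Path to the annotation TSV (with header).
#' @param sequences Named character vector as returned by [read_fasta()].
#' @return A `data.frame` (class `transcript_table`) with columns
#'   `transcript_id`, `sequence`, `cds_start`, `cds_end`,
#'   `has_signal_peptide`, `has_transmembrane`.
#' @export
read_annotation <- function(path, sequences) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "cds_start", "cds_end",
            "has_signal_peptide", "has_transmembrane")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  transcript_table(
    transcript_id = as.character(tab$transcript_id),
    sequence = sequences[as.character(tab$transcript_id)],
    cds_start = as.integer(tab$cds_start),
    cds_end = as.integer(tab$cds_end),
    has_signal_peptide = parse_flag(tab$has_signal_peptide),
    has_transmembrane = parse_flag(tab$has_transmembrane)
  )
}

#' Construct and validate a transcript table
#'
#' @inheritParams read_annotation
#' @param transcript_id,sequence,cds_start,cds_end Parallel vectors; see
#'   [read_annotation()] for the coordinate conventions.
#' @param has_signal_peptide,has_transmembrane Logical annotation flags.
#' @return Validated `transcript_table` data.frame.
#' @export
transcript_table <- function(transcript_id, sequence, cds_start, cds_end,
                             has_signal_peptide = FALSE,
                             has_transmembrane = FALSE) {
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    sequence = normalize_nt(as.character(sequence)),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    has_signal_peptide = rep_len(as.logical(has_signal_peptide),
                                 length(transcript_id)),
    has_transmembrane = rep_len(as.logical(has_transmembrane),
                                length(transcript_id)),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  problems <- character(0)
  flag <- function(bad, why) {
    if (any(bad, na.rm = TRUE)) {
      ids <- df$transcript_id[which(bad)]
      problems <<- c(problems, paste0(why, ": ", paste(ids, collapse = ", ")))
    }
  }
  flag(is.na(df$sequence), "no sequence for transcript")
  ok_seq <- !is.na(df$sequence)
  len <- ifelse(ok_seq, nchar(df$sequence), NA_integer_)
  flag(ok_seq & (df$cds_start < 0L), "cds_start negative")
  flag(ok_seq & (df$cds_start >= df$cds_end), "cds_start not before cds_end")
  flag(ok_seq & (df$cds_end > len), "cds_end beyond sequence length")
  cds_len <- df$cds_end - df$cds_start
  flag(ok_seq & (cds_len %% 3L != 0L), "CDS length not divisible by 3")
  flag(ok_seq & (cds_len %% 3L == 0L) & (cds_len < 18L), "CDS shorter than 6 codons")
  if (anyDuplicated(df$transcript_id)) {
    problems <- c(problems, paste0("duplicated transcript_id: ",
                                   df$transcript_id[duplicated(df$transcript_id)][1]))
  }
  if (length(problems)) {
    stop("transcript validation failed (", length(problems), " problem group(s)):\n  ",
         paste(problems, collapse = "\n  "))
  }
  class(df) <- c("transcript_table", "data.frame")
  df
}

#' Number of CDS codons per transcript
#' @param transcripts A `transcript_table`.
#' @return Named integer vector of codon counts.
#' @export
cds_codons <- function(transcripts) {
  stats::setNames(
    as.integer((transcripts$cds_end - transcripts$cds_start) %/% 3L),
    transcripts$transcript_id
  )
}

#' Write a transcript annotation TSV (sequence omitted; see [write_fasta()])
#' @param transcripts A `transcript_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(transcripts, path) {
  out <- transcripts[, c("transcript_id", "cds_start", "cds_end",
                         "has_signal_peptide", "has_transmembrane")]
  write_tsv(out, path)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes")
  bad <- !(x %in% c("true", "t", "1", "yes", "false", "f", "0", "no"))
  if (any(bad)) stop("cannot parse boolean flag value: '", x[bad][1], "'")
  out
}
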