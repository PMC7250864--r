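#' Read a FASTA file of transcript (or read) sequences
#'
#' Sequences are uppercased and U is normalized to T, so downstream code
#' works in a single DNA alphabet; U reappears only in human-readable tail
#' reports. Record order is preserved.
#'
#' The reader is deliberately strict: a sequence line before the first
#' header, an empty header, or a record with no sequence is a parse error
#' that names the offending line, because silently tolerating malformed
#' records upstream of coordinate arithmetic corrupts every later stage.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header_idx <- grep("^>", lines)
  if (length(header_idx) == 0L) {
    stop("FASTA parse error at line 1: no '>' header found in ", path)
  }
  pre <- lines[seq_len(header_idx[1] - 1L)]
  if (any(nzchar(trimws(pre)))) {
    bad <- which(nzchar(trimws(pre)))[1]
    stop("FASTA parse error at line ", bad, ": sequence before first header")
  }
  ids <- sub("^>\\s*", "", lines[header_idx])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    bad <- header_idx[!nzchar(ids)][1]
    stop("FASTA parse error at line ", bad, ": empty header")
  }
  bounds <- c(header_idx, length(lines) + 1L)
  seqs <- character(length(header_idx))
  for (i in seq_along(header_idx)) {
    n_body <- bounds[i + 1L] - bounds[i] - 1L
    body <- if (n_body > 0L) lines[bounds[i] + seq_len(n_body)] else character(0)
    seqs[i] <- paste0(gsub("\\s", "", body), collapse = "")
    if (!nzchar(seqs[i])) {
      stop("FASTA parse error at line ", header_idx[i],
           ": record '", ids[i], "' has empty sequence")
    }
  }
  seqs <- normalize_nt(seqs)
  bad_chr <- grepl("[^ACGTN]", seqs)
  if (any(bad_chr)) {
    stop("FASTA parse error at line ", header_idx[bad_chr][1],
         ": record '", ids[bad_chr][1], "' contains non-nucleotide characters")
  }
  if (anyDuplicated(ids)) {
    stop("FASTA parse error: duplicated record id '", ids[duplicated(ids)][1], "'")
  }
  stats::setNames(seqs, ids)
}

#' Read a FASTQ file of read sequences
#'
#' Minimal strict 4-line-record FASTQ reader; qualities are discarded
#' (tail calling is sequence-only). U is normalized to T as in
#' [read_fasta()].
#'
#' @param path Path to a FASTQ file.
#' @return Named character vector of sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error at line ", length(lines),
         ": truncated record (line count not a multiple of 4)")
  }
  n <- length(lines) %/% 4L
  at <- seq_len(n) * 4L - 3L
  heads <- lines[at]
  bad <- !startsWith(heads, "@")
  if (any(bad)) {
    stop("FASTQ parse error at line ", at[bad][1], ": header must start with '@'")
  }
  ids <- sub("\\s.*$", "", sub("^@", "", heads))
  seqs <- normalize_nt(lines[at + 1L])
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTQ parse error at line ", at[empty][1] + 1L, ": empty sequence")
  }
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Uppercase and fold U onto T (T canonical internally).
normalize_nt <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# RNA alphabet for human-readable tail reports.
as_rna <- function(x) chartr("T", "U", x)
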