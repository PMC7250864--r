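#' Read transcript-space read alignments
#'
#' Two dialects are accepted. The native TSV has columns `read_id`,
#' `transcript_id`, `five_prime_pos` (0-based transcript coordinate of the
#' read's 5' end), `read_length` and `is_unique`. Text SAM is also
#' accepted for transcript-space alignments: `POS - 1` becomes
#' `five_prime_pos` for forward-strand records; unmapped and secondary
#' records are skipped; uniqueness is taken from the `NH` tag when present
#' (NH:i:1), otherwise assumed unique.
#'
#' Records whose coordinates fall outside the transcript (when
#' `transcripts` is supplied) or that reference an unknown transcript are
#' dropped, not fatal: their counts are attached as the `rejected`
#' attribute so pipelines can report them. No length or frame filtering
#' happens here — that is [filter_rpfs()]'s job, so the filters are
#' testable in isolation.
#'
#' @param path Path to the alignment file.
#' @param format `"tsv"` or `"sam"`.
#' @param transcripts Optional `transcript_table` used to bounds-check
#'   coordinates.
#' @return A `data.frame` with columns `read_id`, `transcript_id`,
#'   `five_prime_pos`, `read_length`, `is_unique`, with attribute
#'   `rejected` (named integer vector of per-reason skip counts).
#' @export
read_alignments <- function(path, format = c("tsv", "sam"), transcripts = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  aln <- switch(format,
    tsv = read_alignments_tsv(path),
    sam = read_alignments_sam(path)
  )
  rejected <- attr(aln, "rejected")
  if (is.null(rejected)) rejected <- c(unmapped = 0L, secondary = 0L)
  bad_neg <- aln$five_prime_pos < 0L | aln$read_length <= 0L
  rejected["negative_coordinate"] <- sum(bad_neg)
  keep <- !bad_neg
  if (!is.null(transcripts)) {
    tlen <- stats::setNames(nchar(transcripts$sequence), transcripts$transcript_id)
    known <- aln$transcript_id %in% names(tlen)
    rejected["unknown_transcript"] <- sum(!known)
    over <- known & (aln$five_prime_pos + aln$read_length >
                       unname(tlen[aln$transcript_id]))
    over[is.na(over)] <- FALSE
    rejected["out_of_bounds"] <- sum(over, na.rm = TRUE)
    keep <- keep & known & !over
  }
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

read_alignments_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "transcript_id", "five_prime_pos", "read_length",
            "is_unique")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("alignment TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data.frame(
    read_id = as.character(tab$read_id),
    transcript_id = as.character(tab$transcript_id),
    five_prime_pos = as.integer(tab$five_prime_pos),
    read_length = as.integer(tab$read_length),
    is_unique = parse_flag(tab$is_unique),
    stringsAsFactors = FALSE
  )
}

read_alignments_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    out <- data.frame(read_id = character(0), transcript_id = character(0),
                      five_prime_pos = integer(0), read_length = integer(0),
                      is_unique = logical(0), stringsAsFactors = FALSE)
    attr(out, "rejected") <- c(unmapped = 0L, secondary = 0L, reverse_strand = 0L)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("SAM parse error: record with fewer than 11 fields at alignment line ",
         which(nf < 11L)[1])
  }
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  reverse <- bitwAnd(flag, 16L) != 0L
  keep <- !unmapped & !secondary & !reverse
  nh <- vapply(fields, function(f) {
    hit <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub("^NH:i:", "", hit[1])) else 1L
  }, integer(1))
  out <- data.frame(
    read_id = vapply(fields, `[[`, "", 1L)[keep],
    transcript_id = vapply(fields, `[[`, "", 3L)[keep],
    five_prime_pos = as.integer(vapply(fields, `[[`, "", 4L))[keep] - 1L,
    read_length = nchar(vapply(fields, `[[`, "", 10L))[keep],
    is_unique = nh[keep] == 1L,
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- c(unmapped = sum(unmapped),
                             secondary = sum(secondary & !unmapped),
                             reverse_strand = sum(reverse & !secondary & !unmapped))
  out
}

#' Write alignments in the native TSV dialect
#' @param alignments Alignment `data.frame` (see [read_alignments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  write_tsv(alignments[, c("read_id", "transcript_id", "five_prime_pos",
                           "read_length", "is_unique")], path)
}
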