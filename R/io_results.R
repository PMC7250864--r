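#' Write a results table as TSV with deterministic formatting
#'
#' Column order is taken from the data.frame as given; doubles are
#' formatted at a fixed precision so repeated runs on identical inputs
#' produce byte-identical files.
#'
#' @param df A data.frame.
#' @param path Output path (parent directories are created).
#' @param digits Significant digits for doubles.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, digits = 10L) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
    } else if (is.logical(out[[j]])) {
      out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_tsv()]
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Assemble a count table from per-library counts
#'
#' The count table is the hand-off between read-level processing and the
#' translation-efficiency math: a genes-by-libraries integer matrix plus a
#' library sheet describing each column.
#'
#' @param counts Integer matrix, rows = transcripts (rownames required),
#'   columns = libraries (colnames required).
#' @param libraries data.frame with columns `library_id`, `assay`
#'   (`"RPF"` or `"mRNA"`), `condition`, `replicate`; one row per column
#'   of `counts`, matched by `library_id`.
#' @return List of class `count_table` with elements `counts`,
#'   `libraries`.
#' @export
count_table <- function(counts, libraries) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs row (transcript) and column (library) names")
  }
  need <- c("library_id", "assay", "condition", "replicate")
  if (!all(need %in% names(libraries))) {
    stop("library sheet needs columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(libraries$library_id, colnames(counts)) ||
      anyDuplicated(libraries$library_id)) {
    stop("library sheet must describe each count column exactly once")
  }
  if (any(counts < 0L, na.rm = TRUE)) stop("counts must be non-negative")
  if (!all(libraries$assay %in% c("RPF", "mRNA"))) {
    stop("assay must be 'RPF' or 'mRNA'")
  }
  libraries <- libraries[match(colnames(counts), libraries$library_id), ,
                         drop = FALSE]
  rownames(libraries) <- NULL
  structure(list(counts = counts, libraries = libraries),
            class = "count_table")
}

#' Count filtered alignments per transcript into one library column
#' @param alignments Alignment data.frame (typically [filter_rpfs()] output).
#' @param transcript_ids Character vector fixing row order.
#' @return Named integer vector over `transcript_ids`.
#' @export
count_per_transcript <- function(alignments, transcript_ids) {
  tab <- table(factor(alignments$transcript_id, levels = transcript_ids))
  stats::setNames(as.integer(tab), transcript_ids)
}

#' Write a count table as TSV (+ library sheet)
#' @param ct A `count_table`.
#' @param counts_path,libraries_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_count_table <- function(ct, counts_path, libraries_path) {
  df <- data.frame(transcript_id = rownames(ct$counts),
                   as.data.frame(ct$counts, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(ct$libraries, libraries_path)
  invisible(counts_path)
}

#' Read a count table written by [write_count_table()]
#' @param counts_path,libraries_path Paths written by [write_count_table()].
#' @return A `count_table`.
#' @export
read_count_table <- function(counts_path, libraries_path) {
  df <- read_tsv(counts_path)
  libs <- read_tsv(libraries_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_id
  count_table(m, libs)
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed and package version of a run so any
#' output can be regenerated byte-for-byte.
#'
#' @param path Output path.
#' @param config Named list of run parameters.
#' @param seed Integer seed used for the run (NA if none).
#' @param outputs Character vector of files the run wrote.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed = NA_integer_,
                           outputs = character(0)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "riboTails",
    version = as.character(utils::packageVersion("riboTails")),
    seed = seed,
    config = config,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
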