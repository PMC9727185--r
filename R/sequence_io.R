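# FASTA input, sequence cleaning, and feature-table I/O.

#' The 20 standard amino-acid one-letter codes
#'
#' Fixed alphabetical residue order used throughout the package: the amino-acid
#' composition features f1..f20 follow this order.
#'
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Clean a raw amino-acid sequence
#'
#' Uppercases the sequence, strips whitespace and `*` (stop) characters, and
#' deletes any residue outside the 20-letter standard alphabet (ambiguity and
#' non-standard codes such as B, J, O, U, X, Z, and gap characters). Each class
#' of removed character is reported via [message()]. Non-standard residues are
#' deleted rather than remapped, so the sequence length used by the descriptors
#' is the cleaned length.
#'
#' @param raw single non-empty character string.
#' @return The cleaned sequence string.
#' @examples
#' clean_sequence("acd e")  # "ACDE"
#' @export
clean_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("'raw' must be a single non-empty string")
  }
  s <- gsub("[[:space:]*]+", "", toupper(raw))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  keep <- chars %in% AA_ALPHABET
  if (any(!keep)) {
    dropped <- table(chars[!keep])
    message(
      "clean_sequence: removed ", sum(!keep), " non-standard residue(s): ",
      paste0(names(dropped), " (", as.integer(dropped), ")", collapse = ", ")
    )
  }
  out <- paste0(chars[keep], collapse = "")
  if (!nzchar(out)) stop("sequence is empty after cleaning")
  out
}

#' Read and validate protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file, cleans each sequence with
#' [clean_sequence()], and drops records whose cleaned length falls below
#' `min_length` (with a warning). The record id is the first
#' whitespace-delimited token of the FASTA header.
#'
#' @param path path to a FASTA file.
#' @param min_length minimum cleaned sequence length to keep (default 2, the
#'   shortest length for which transition features are defined).
#' @return A `data.frame` with columns `id`, `sequence`, and `length`, one row
#'   per retained record, in file order.
#' @export
read_fasta <- function(path, min_length = 2L) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read FASTA file: ", path)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("no sequences found in '", path, "'")
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  cleaned <- vapply(as.character(set), function(s) {
    if (!nzchar(s)) return("")
    tryCatch(clean_sequence(s), error = function(e) "")
  }, character(1), USE.NAMES = FALSE)
  short <- nchar(cleaned) < min_length
  if (any(short)) {
    warning("dropped ", sum(short), " record(s) shorter than ", min_length,
            " after cleaning: ", paste(ids[short], collapse = ", "))
  }
  if (all(short)) stop("no records of length >= ", min_length, " in '", path, "'")
  data.frame(
    id = ids[!short],
    sequence = cleaned[!short],
    length = nchar(cleaned[!short]),
    stringsAsFactors = FALSE
  )
}

#' Write protein records to a FASTA file
#'
#' @param records data.frame with columns `id` and `sequence`.
#' @param path output path.
#' @param width line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a labeled feature table
#'
#' Writes a delimited text table with header `id`, `label`, `f1`..`fD`.
#' Numeric values are written with 15 significant digits so that a
#' write/read round trip preserves features to at least 12 significant digits.
#'
#' @param records data.frame with an `id` column (or a character vector of ids).
#' @param vectors numeric matrix, one row per record.
#' @param labels vector of class labels, one per record.
#' @param path output path.
#' @param sep field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, vectors, labels, path, sep = "\t") {
  ids <- if (is.data.frame(records)) records$id else as.character(records)
  vectors <- as.matrix(vectors)
  if (length(ids) != nrow(vectors) || length(labels) != nrow(vectors)) {
    stop("records, vectors and labels must have equal counts")
  }
  df <- data.frame(id = ids, label = as.character(labels),
                   stringsAsFactors = FALSE)
  feat <- as.data.frame(vectors)
  names(feat) <- paste0("f", seq_len(ncol(vectors)))
  df <- cbind(df, feat)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled feature table written by [write_feature_table()]
#'
#' @param path input path.
#' @param sep field delimiter, default tab.
#' @return A list with `ids` (character), `labels` (character), and `X`
#'   (numeric matrix with columns `f1`..`fD`).
#' @export
read_feature_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("cannot read feature table: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "label") %in% names(df))) {
    stop("feature table must have 'id' and 'label' columns: ", path)
  }
  fcols <- setdiff(names(df), c("id", "label"))
  X <- as.matrix(df[, fcols, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df$id
  list(ids = as.character(df$id), labels = as.character(df$label), X = X)
}
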