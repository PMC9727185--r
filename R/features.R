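# The 188-dimensional descriptor: amino-acid composition (20 features) plus,
# for each of 8 physicochemical properties, 3 composition + 15 distribution +
# 3 transition features. Layout: [f1..f20 AAC | per property: C(3) D(15) T(3)].

seq_chars <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) < 2L || !all(chars %in% AA_ALPHABET)) {
    stop("sequence must be a cleaned amino-acid string of length >= 2")
  }
  chars
}

group_index <- function(chars, table) {
  gi <- integer(length(chars))
  for (g in 1:3) gi[chars %in% table$groups[[g]]] <- g
  gi
}

#' Amino-acid composition (AAC) features
#'
#' Frequency of each of the 20 standard residues, `n_i / L`, in fixed
#' alphabetical order `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @param seq cleaned amino-acid sequence string (length >= 2).
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
aac_features <- function(seq) {
  chars <- seq_chars(seq)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  out <- as.numeric(counts) / length(chars)
  names(out) <- AA_ALPHABET
  out
}

#' CTD composition features for one property
#'
#' Fraction of residues falling in each of the property's three groups;
#' the triple sums to 1.
#'
#' @param seq cleaned amino-acid sequence string.
#' @param table a property table from [load_property_groups()].
#' @return Numeric vector of 3 group fractions.
#' @export
ctd_composition <- function(seq, table) {
  chars <- seq_chars(seq)
  gi <- group_index(chars, table)
  as.numeric(tabulate(gi, nbins = 3L)) / length(chars)
}

#' CTD distribution features for one property
#'
#' For each group, the 1-based sequence positions of the 1st,
#' `ceiling(0.25 n)`-th, `ceiling(0.50 n)`-th, `ceiling(0.75 n)`-th, and
#' `n`-th occurrence of a group residue, divided by the sequence length L
#' (`n` = occurrence count of the group; quantile index is
#' `max(1, ceiling(q n))`). A group with no occurrences contributes five
#' zeros.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of 15 values (5 per group), each in `[0, 1]`.
#' @export
ctd_distribution <- function(seq, table) {
  chars <- seq_chars(seq)
  L <- length(chars)
  gi <- group_index(chars, table)
  out <- numeric(15)
  for (g in 1:3) {
    pos <- which(gi == g)
    n <- length(pos)
    if (n > 0L) {
      idx <- pmax(1L, ceiling(c(0, 0.25, 0.5, 0.75, 1) * n))
      out[(g - 1L) * 5L + 1:5] <- pos[idx] / L
    }
  }
  out
}

#' CTD transition features for one property
#'
#' Counts of adjacent residue pairs whose two members lie in different groups
#' — pairs (group1, group2), (group1, group3), (group2, group3) in either
#' order — each divided by `L - 1`, the number of adjacent pairs.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of 3 normalized cross-group transition counts.
#' @export
ctd_transition <- function(seq, table) {
  chars <- seq_chars(seq)
  L <- length(chars)
  gi <- group_index(chars, table)
  a <- gi[-L]
  b <- gi[-1L]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  c(sum(lo == 1L & hi == 2L),
    sum(lo == 1L & hi == 3L),
    sum(lo == 2L & hi == 3L)) / (L - 1L)
}

#' Extract the full 188-dimensional descriptor
#'
#' Concatenates the 20 AAC features with, for each of the 8 property tables in
#' order, 3 composition, 15 distribution and 3 transition features
#' (21 per property, 168 in total).
#'
#' @param seq cleaned amino-acid sequence string (length >= 2).
#' @param tables list of exactly 8 property tables in canonical order;
#'   default [load_property_groups()].
#' @return Named numeric vector of length 188 (`f1`..`f188`).
#' @export
extract_188d <- function(seq, tables = default_property_groups()) {
  if (length(tables) != 8L) {
    stop("extract_188d requires exactly 8 property tables, got ", length(tables))
  }
  blocks <- lapply(tables, function(tab) {
    c(ctd_composition(seq, tab), ctd_distribution(seq, tab),
      ctd_transition(seq, tab))
  })
  out <- c(aac_features(seq), unlist(blocks, use.names = FALSE))
  names(out) <- paste0("f", seq_along(out))
  out
}

#' Amino-acid-composition-only descriptor
#'
#' Alias of [aac_features()] exposed for descriptor comparisons; identical to
#' the first 20 entries of [extract_188d()].
#'
#' @inheritParams aac_features
#' @return Named numeric vector of 20 frequencies.
#' @export
extract_aac_only <- function(seq) {
  out <- aac_features(seq)
  names(out) <- paste0("f", 1:20)
  out
}

#' Extract a feature matrix for a set of protein records
#'
#' @param records data.frame with columns `id` and `sequence`
#'   (as from [read_fasta()]).
#' @param descriptor `"188d"` (default) or `"aac"`.
#' @param tables property tables for the 188-D descriptor.
#' @return Numeric matrix, one row per record (rownames = ids), columns
#'   `f1..f188` or `f1..f20`.
#' @export
extract_features <- function(records, descriptor = c("188d", "aac"),
                             tables = default_property_groups()) {
  descriptor <- match.arg(descriptor)
  fun <- switch(descriptor,
                "188d" = function(s) extract_188d(s, tables),
                "aac" = extract_aac_only)
  X <- t(vapply(records$sequence, fun,
                numeric(if (descriptor == "188d") 188L else 20L),
                USE.NAMES = FALSE))
  rownames(X) <- records$id
  X
}
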