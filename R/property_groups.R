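# The eight physicochemical property groupings behind the CTD features.

#' Load physicochemical property group tables
#'
#' Each of the eight properties (hydrophobicity, normalized van der Waals
#' volume, polarity, polarizability, charge, secondary structure, solvent
#' accessibility, surface tension) partitions the 20 standard residues into
#' three disjoint groups. The partitions shipped with the package are the
#' standard groupings of the CTD descriptor literature; the surface-tension
#' table's first group is GQDNAHR. The file format (one row per property:
#' `property`, `group1`, `group2`, `group3` as residue strings) is part of the
#' public interface so that alternative groupings can be substituted.
#'
#' The row order of the file fixes the feature layout: feature indices 21..188
#' are the 8 per-property blocks of 21 features (3 composition, 15
#' distribution, 3 transition) in file order.
#'
#' @param path path to a group-table TSV; default is the table shipped in
#'   `inst/extdata/ctd_property_groups.tsv`.
#' @return A named list of property tables; each element is a list with
#'   `property` (name) and `groups` (list of three character vectors of
#'   residues).
#' @export
load_property_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ctd_property_groups.tsv",
                        package = "snareid", mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("property", "group1", "group2", "group3")
  if (!all(req %in% names(df))) {
    stop("property-group table must have columns: ", paste(req, collapse = ", "))
  }
  tables <- lapply(seq_len(nrow(df)), function(i) {
    groups <- lapply(df[i, c("group1", "group2", "group3")], function(g) {
      strsplit(toupper(g), "", fixed = TRUE)[[1]]
    })
    names(groups) <- NULL
    tab <- list(property = df$property[i], groups = groups)
    validate_property_table(tab)
    tab
  })
  names(tables) <- df$property
  tables
}

validate_property_table <- function(tab) {
  all_res <- unlist(tab$groups)
  if (length(tab$groups) != 3L) {
    stop("property '", tab$property, "': need exactly 3 groups")
  }
  if (anyDuplicated(all_res)) {
    stop("property '", tab$property, "': groups are not disjoint")
  }
  if (!setequal(all_res, AA_ALPHABET) || length(all_res) != 20L) {
    stop("property '", tab$property,
         "': groups must partition the 20 standard residues")
  }
  invisible(tab)
}

# Cache the default tables per session; loading re-reads ~1 KB otherwise.
.snareid_cache <- new.env(parent = emptyenv())

default_property_groups <- function() {
  if (is.null(.snareid_cache$groups)) {
    .snareid_cache$groups <- load_property_groups()
  }
  .snareid_cache$groups
}
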