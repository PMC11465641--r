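# Loaders for the auxiliary delimited-text tables the pipeline consumes.

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "#", quote = "\"")
}

#' Shipped compound synonym table
#'
#' A small static synonym table (the role of a PubChem synonyms snapshot)
#' mapping published spellings to canonical compound identifiers. Extensible:
#' pass your own table to [canonicalize_compound()] to extend coverage.
#'
#' @param path Optional path to a user synonym CSV with columns `synonym`,
#'   `compound_id`; defaults to the table shipped in `inst/extdata`.
#' @return Data.frame with columns `synonym`, `compound_id`.
#' @export
ot_synonym_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compound_synonyms.csv",
                        package = "ovotransfer", mustWork = TRUE)
  out <- read_delim_auto(path)
  stopifnot(all(c("synonym", "compound_id") %in% names(out)))
  out
}

#' Read a lipid-content lookup table
#'
#' Columns: `species`, `tissue`, `lipid_fraction` in `(0, 1]`, optional
#' `source` and `reference`. Fractions outside `(0, 1]` are rejected.
#'
#' @param path Path to a CSV/TSV file.
#' @return Validated data.frame.
#' @export
read_lipid_table <- function(path) {
  out <- read_delim_auto(path)
  stopifnot(all(c("species", "tissue", "lipid_fraction") %in% names(out)))
  if (any(out$lipid_fraction <= 0 | out$lipid_fraction > 1))
    stop("lipid_fraction must lie in (0, 1]")
  out
}

#' Read a tissue water-content table
#'
#' Columns: `species`, `tissue`, `water_fraction` in `[0, 1)`, optional
#' `reference`.
#'
#' @param path Path to a CSV/TSV file.
#' @return Validated data.frame.
#' @export
read_water_table <- function(path) {
  out <- read_delim_auto(path)
  stopifnot(all(c("species", "tissue", "water_fraction") %in% names(out)))
  if (any(out$water_fraction < 0 | out$water_fraction >= 1))
    stop("water_fraction must lie in [0, 1)")
  out
}

#' Read a molecular property table
#'
#' Columns: `compound_id`, `log_kow_experimental`, `log_kow_estimated`, plus
#' the descriptor columns `molecular_weight`, `complexity`,
#' `heavy_atom_count`, `h_bond_donors`, `h_bond_acceptors`, `tpsa`,
#' `formal_charge`, `rotatable_bonds`. Missing values are `NA`.
#'
#' @param path Path to a CSV/TSV file.
#' @return Validated data.frame.
#' @export
read_property_table <- function(path) {
  out <- read_delim_auto(path)
  stopifnot("compound_id" %in% names(out))
  for (col in c("log_kow_experimental", "log_kow_estimated", .DESCRIPTORS)) {
    if (col == "log_kow") next
    if (!col %in% names(out)) out[[col]] <- NA_real_
    out[[col]] <- as.numeric(out[[col]])
  }
  out
}

#' Read a descriptor override table
#'
#' Columns: `key` (a compound id, or the "+"-joined sorted member ids of a
#' coelution), `descriptor`, `value`, `reference`.
#'
#' @param path Path to a CSV/TSV file.
#' @return Validated data.frame.
#' @export
read_override_table <- function(path) {
  out <- read_delim_auto(path)
  stopifnot(all(c("key", "descriptor", "value") %in% names(out)))
  out$value <- as.numeric(out$value)
  out
}

#' Read a species-relatedness map
#'
#' Columns: `species`, `related_species`. Rows are consulted in order when
#' the lipid-fraction fallback chain reaches the related-species level.
#'
#' @param path Path to a CSV/TSV file.
#' @return Validated data.frame.
#' @export
read_relatedness <- function(path) {
  out <- read_delim_auto(path)
  stopifnot(all(c("species", "related_species") %in% names(out)))
  out
}
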