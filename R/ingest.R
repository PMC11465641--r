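# Ingest: per-study delimited tables -> canonical study records.

#' Read a per-study table of concentration records
#'
#' Reads one observation per row from a delimited text file (comma- or
#' tab-separated, chosen by extension) and maps its columns onto the canonical
#' study-record layout. Rows whose mandatory fields cannot be parsed (unknown
#' tissue token, unsupported unit, negative value, inconsistent censoring
#' flags) are excluded from the returned records but reported row by row in
#' the attached diagnostics table — never silently dropped.
#'
#' Censoring is derived from the file's censoring column: an empty token or
#' `"uncensored"`/`"none"` means a measured value; any below-LOD token
#' (`"<LOD"`, `"<LOQ"`, `"nd"`, `"below_lod"`, `"censored"`) marks a censored
#' observation, quantitatively censored when the LOD column carries a value
#' and qualitatively censored when it is empty.
#'
#' @param path Path to a CSV (or TSV, by `.tsv`/`.txt` extension) file.
#' @param column_map Named character vector mapping canonical column names
#'   (see Details) to the file's column names. Unmapped canonical columns are
#'   looked up under their own names; absent optional columns are filled with
#'   defaults.
#' @param tissue_aliases Optional named character vector mapping study-specific
#'   tissue spellings to the controlled vocabulary of [ot_tissues()].
#'
#' @details Mandatory columns: `study_id`, `species`, `subject_role`,
#' `subject_id`, `tissue`, `compound_raw`, `unit`, `basis`, and `value`
#' (`value` may be empty on censored rows). Optional: `mother_id`,
#' `compound_class`, `censoring`, `lod`, `n_pooled`, `aggregation`, `is_sum`,
#' `is_coelution`, `members` ("|"-separated), `lipid_fraction_reported`,
#' `out_of_calibration`.
#'
#' @return A data.frame of canonical study records with attribute
#'   `"diagnostics"`, a data.frame with columns `row`, `field`, `message`
#'   (retrievable with [ingest_diagnostics()]).
#' @seealso [canonicalize_records()], [apply_exclusion_rules()]
#' @export
read_study_table <- function(path, column_map = NULL, tissue_aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE, quote = "\"",
                           colClasses = "character")
  as_study_records(raw, column_map = column_map, tissue_aliases = tissue_aliases)
}

#' Coerce a raw data.frame to canonical study records
#'
#' The in-memory counterpart of [read_study_table()]: applies the same column
#' mapping, field parsing and row-level validation to an already-loaded
#' data.frame.
#'
#' @inheritParams read_study_table
#' @param x A data.frame with one observation per row, all columns character
#'   or coercible.
#' @return See [read_study_table()].
#' @export
as_study_records <- function(x, column_map = NULL, tissue_aliases = NULL) {
  x[] <- lapply(x, as.character)
  pick <- function(canon) {
    src <- if (!is.null(column_map) && canon %in% names(column_map)) column_map[[canon]] else canon
    if (src %in% names(x)) x[[src]] else NULL
  }

  mandatory <- c("study_id", "species", "subject_role", "subject_id",
                 "tissue", "compound_raw", "unit", "basis")
  for (m in c(mandatory, "value")) {
    if (is.null(pick(m))) stop("missing mandatory column: ", m)
  }

  n <- nrow(x)
  get_or <- function(canon, default) {
    v <- pick(canon)
    if (is.null(v)) rep(default, n) else v
  }
  blank_na <- function(v) ifelse(is.na(v) | !nzchar(trimws(v)), NA_character_, trimws(v))
  num_or_na <- function(v) suppressWarnings(as.numeric(blank_na(v)))
  bool_or <- function(v, default = FALSE) {
    v <- tolower(blank_na(v))
    out <- v %in% c("true", "t", "1", "yes")
    out[is.na(v)] <- default
    out
  }

  rec <- data.frame(
    study_id = blank_na(pick("study_id")),
    species = blank_na(pick("species")),
    subject_role = tolower(blank_na(pick("subject_role"))),
    subject_id = blank_na(pick("subject_id")),
    mother_id = blank_na(get_or("mother_id", NA_character_)),
    tissue = blank_na(pick("tissue")),
    compound_raw = blank_na(pick("compound_raw")),
    compound_id = blank_na(get_or("compound_id", NA_character_)),
    compound_class = blank_na(get_or("compound_class", "other")),
    value = num_or_na(pick("value")),
    unit = blank_na(pick("unit")),
    basis = tolower(blank_na(pick("basis"))),
    censoring = rep(NA_character_, n),
    lod = num_or_na(get_or("lod", NA_character_)),
    n_pooled = suppressWarnings(as.integer(blank_na(get_or("n_pooled", "1")))),
    aggregation = blank_na(get_or("aggregation", "individual")),
    is_sum = bool_or(get_or("is_sum", NA_character_)),
    is_coelution = bool_or(get_or("is_coelution", NA_character_)),
    members = blank_na(get_or("members", NA_character_)),
    lipid_fraction_reported = num_or_na(get_or("lipid_fraction_reported", NA_character_)),
    out_of_calibration = bool_or(get_or("out_of_calibration", NA_character_)),
    stringsAsFactors = FALSE
  )
  rec$n_pooled[is.na(rec$n_pooled)] <- 1L
  rec$aggregation[is.na(rec$aggregation)] <- "individual"
  rec$compound_class[!(rec$compound_class %in% ot_compound_classes())] <- "other"

  if (!is.null(tissue_aliases)) {
    hit <- rec$tissue %in% names(tissue_aliases)
    rec$tissue[hit] <- unname(tissue_aliases[rec$tissue[hit]])
  }

  cens_tok <- tolower(blank_na(get_or("censoring", NA_character_)))
  below <- !is.na(cens_tok) &
    cens_tok %in% c("<lod", "<loq", "nd", "n.d.", "below_lod", "below lod",
                    "censored", "quant_censored", "qual_censored")

  diag <- list()
  bad <- rep(FALSE, n)
  flag <- function(rows, field, message) {
    if (any(rows)) {
      diag[[length(diag) + 1L]] <<- data.frame(
        row = which(rows), field = field, message = message,
        stringsAsFactors = FALSE)
      bad[rows] <<- TRUE
    }
  }

  for (m in mandatory) flag(is.na(rec[[m]]), m, "missing mandatory field")
  flag(!is.na(rec$tissue) & !(rec$tissue %in% ot_tissues()),
       "tissue", "unknown tissue token")
  known_unit <- !is.na(rec$unit) & vapply(rec$unit, function(u)
    !is.na(unit_factor_or_na(u)), logical(1))
  flag(!is.na(rec$unit) & !known_unit, "unit", "unsupported unit token")
  flag(!is.na(rec$basis) & !(rec$basis %in% ot_bases()),
       "basis", "unknown basis token")
  flag(!is.na(rec$value) & rec$value < 0, "value", "negative concentration")
  flag(!below & is.na(rec$value), "value", "no value and no censoring flag")
  flag(below & !is.na(rec$value), "censoring",
       "measured value present on a below-LOD row")
  flag(!is.na(rec$lod) & rec$lod < 0, "lod", "negative LOD")

  ok_cls <- !bad
  rec$censoring[ok_cls] <- classify_censoring(
    value_present = !is.na(rec$value[ok_cls]),
    below_lod = below[ok_cls],
    lod_present = !is.na(rec$lod[ok_cls]))
  # censored rows carry no point value; LOD is dropped on qualitative rows
  rec$value[!is.na(rec$censoring) & rec$censoring != "uncensored"] <- NA_real_
  rec$lod[!is.na(rec$censoring) & rec$censoring == "qual_censored"] <- NA_real_

  out <- rec[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- if (length(diag)) do.call(rbind, diag) else
    data.frame(row = integer(0), field = character(0), message = character(0),
               stringsAsFactors = FALSE)
  out
}

#' Row-level diagnostics from ingestion
#'
#' @param records A record table returned by [read_study_table()] or
#'   [as_study_records()].
#' @return Data.frame with columns `row`, `field`, `message`.
#' @export
ingest_diagnostics <- function(records) {
  d <- attr(records, "diagnostics")
  if (is.null(d)) data.frame(row = integer(0), field = character(0),
                             message = character(0), stringsAsFactors = FALSE) else d
}

# Normalization key used for synonym lookup: case- and punctuation-insensitive.
compound_key <- function(x) {
  toupper(gsub("[^A-Za-z0-9]", "", x))
}

#' Resolve compound names against a synonym table
#'
#' Case- and punctuation-insensitive lookup of raw compound names against a
#' synonym table (the role of a PubChem synonyms snapshot). Names matched in
#' the table map to their canonical identifier; unmatched names are returned
#' in normalized form and flagged unresolved — never guessed. The mapping is
#' idempotent: canonical identifiers resolve to themselves.
#'
#' @param compound_raw Character vector of compound names as published.
#' @param synonym_table Data.frame with columns `synonym` and `compound_id`;
#'   defaults to the synonym table shipped with the package
#'   ([ot_synonym_table()]).
#' @return Character vector of compound identifiers with a logical attribute
#'   `"unresolved"` marking entries not found in the table.
#' @examples
#' canonicalize_compound(c("p,p'-DDE", "4,4'-DDE", "PCB-153"))
#' @export
canonicalize_compound <- function(compound_raw, synonym_table = ot_synonym_table()) {
  if (any(is.na(compound_raw) | !nzchar(compound_raw)))
    stop("empty compound name")
  keys <- compound_key(compound_raw)
  lut <- stats::setNames(synonym_table$compound_id,
                         compound_key(synonym_table$synonym))
  # canonical ids always resolve to themselves
  lut <- c(lut, stats::setNames(synonym_table$compound_id,
                                compound_key(synonym_table$compound_id)))
  lut <- lut[!duplicated(names(lut))]
  hit <- keys %in% names(lut)
  out <- ifelse(hit, unname(lut[keys]), keys)
  attr(out, "unresolved") <- !hit
  out
}

#' Fill canonical compound identifiers on a record table
#'
#' Applies [canonicalize_compound()] to `compound_raw` wherever `compound_id`
#' is not already set, and canonicalizes the member lists of sums and
#' coelutions. Adds a logical `unresolved` column.
#'
#' @param records Canonical record table.
#' @inheritParams canonicalize_compound
#' @return The record table with `compound_id`, `members` and `unresolved`
#'   filled in.
#' @export
canonicalize_records <- function(records, synonym_table = ot_synonym_table()) {
  need <- is.na(records$compound_id)
  if (any(need)) {
    ids <- canonicalize_compound(records$compound_raw[need], synonym_table)
    records$compound_id[need] <- ids
    records$unresolved <- FALSE
    records$unresolved[need] <- attr(ids, "unresolved")
  } else {
    records$unresolved <- rep(FALSE, nrow(records))
  }
  has_members <- !is.na(records$members) & nzchar(records$members)
  if (any(has_members)) {
    records$members[has_members] <- vapply(
      split_members(records$members[has_members]),
      function(m) paste(unname(canonicalize_compound(m, synonym_table)),
                        collapse = "|"),
      character(1))
  }
  records
}

#' Apply database inclusion/exclusion rules
#'
#' Partitions canonical records into kept and excluded sets with a reason code
#' attached to every exclusion:
#' \describe{
#'   \item{`bile`}{bile concentrations are excluded — bile is a liver product
#'     of highly variable composition, not a body compartment comparable
#'     across studies.}
#'   \item{`duplicate_sum`}{a sum of compounds all of whose members are
#'     already reported individually within the same study duplicates
#'     information and is excluded; sums contributing at least one compound
#'     not reported individually are kept.}
#'   \item{`calibration`}{records flagged as measured outside the analytical
#'     calibration range (driven by the explicit `out_of_calibration` input
#'     column).}
#' }
#'
#' @param records Canonicalized record table.
#' @return List with elements `kept` (record table) and `excluded` (record
#'   table with an extra `reason` column). The two partition the input.
#' @export
apply_exclusion_rules <- function(records) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  reason[is.na(reason) & records$tissue == "bile"] <- "bile"
  reason[is.na(reason) & records$out_of_calibration] <- "calibration"

  is_sum <- records$is_sum & !is.na(records$members) & nzchar(records$members)
  if (any(is_sum)) {
    mem <- split_members(records$members)
    for (i in which(is_sum & is.na(reason))) {
      sid <- records$study_id[i]
      individual <- records$compound_id[records$study_id == sid &
                                          !records$is_sum]
      if (length(mem[[i]]) && all(mem[[i]] %in% individual))
        reason[i] <- "duplicate_sum"
    }
  }

  excl <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excl)) excl$reason <- reason[!is.na(reason)]
  else excl$reason <- character(0)
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- rownames(excl) <- NULL
  list(kept = kept, excluded = excl)
}

#' Aggregate group-reported concentrations
#'
#' When a study reports only group-level data, the geometric mean is used,
#' falling back to the arithmetic mean when the geometric mean is not
#' derivable (any zero or negative member). Individually reported data are
#' passed through untouched — individual data always take priority over
#' group summaries.
#'
#' @param values Numeric vector of concentrations for one reporting group.
#' @param reported `"individual"` if the study reports individuals (no
#'   aggregation is performed), otherwise `"group"`.
#' @return For `reported = "individual"`, a list with `value = values`,
#'   `aggregation = "individual"`, `n_pooled = 1`. Otherwise a list with the
#'   aggregated `value`, the `aggregation` actually used
#'   (`"geometric_mean"` or `"arithmetic_mean"`), `n_pooled = length(values)`,
#'   and `diagnostic` (message or `NA`).
#' @examples
#' select_aggregation(c(10, 1000), reported = "group")  # geometric mean 100
#' @export
select_aggregation <- function(values, reported = c("group", "individual")) {
  reported <- match.arg(reported)
  if (reported == "individual") {
    return(list(value = values, aggregation = "individual", n_pooled = 1L,
                diagnostic = NA_character_))
  }
  stopifnot(length(values) >= 1)
  if (all(values > 0)) {
    list(value = exp(mean(log(values))), aggregation = "geometric_mean",
         n_pooled = length(values), diagnostic = NA_character_)
  } else {
    list(value = mean(values), aggregation = "arithmetic_mean",
         n_pooled = length(values),
         diagnostic = "geometric mean undefined for non-positive values; arithmetic mean used")
  }
}
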