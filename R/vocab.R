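# Controlled vocabularies shared across the pipeline.

#' Controlled vocabulary of tissues
#'
#' Tissue tokens accepted in study records. Offspring matrices are the subset
#' measured in eggs, follicles or hatchlings; everything else is a maternal
#' tissue. Unknown tissue tokens are quarantined at ingest rather than coerced.
#'
#' @return Character vector of accepted tissue tokens.
#' @export
ot_tissues <- function() {
  c("whole_egg", "yolk", "albumen", "follicle", "hatchling_blood",
    "fat", "liver", "whole_blood", "plasma", "muscle", "kidney", "skin",
    "intestine", "stomach", "spleen", "heart", "lung", "bile", "other")
}

#' Offspring matrices
#'
#' The subset of the tissue vocabulary that counts as an offspring matrix when
#' pairing mothers with their offspring.
#'
#' @return Character vector.
#' @export
ot_offspring_matrices <- function() {
  c("whole_egg", "yolk", "albumen", "follicle", "hatchling_blood")
}

#' Compound classes
#'
#' Compound-class labels used for grouping: PCBs, organochlorine pesticides
#' (OCP), brominated and phosphorylated halogenated flame retardants
#' (HFR_BFR, HFR_PFR), PAHs, phthalates, alternative plasticizers,
#' chlorinated paraffins (CP), PFAS, and other.
#'
#' @return Character vector.
#' @export
ot_compound_classes <- function() {
  c("PCB", "OCP", "HFR_BFR", "HFR_PFR", "PAH", "phthalate",
    "alt_plasticizer", "CP", "PFAS", "other")
}

#' Censoring states
#'
#' @return Character vector: `uncensored`, `quant_censored` (value below a
#'   known LOD) and `qual_censored` (below an unknown LOD).
#' @export
ot_censoring_states <- function() {
  c("uncensored", "quant_censored", "qual_censored")
}

#' Measurement bases
#'
#' @return Character vector: `wet`, `dry`, `lipid`.
#' @export
ot_bases <- function() {
  c("wet", "dry", "lipid")
}

# Column set of a canonical study-record table. `members` holds "|"-separated
# compound ids for sums/coelutions so the table stays CSV-serializable.
ot_record_columns <- function() {
  c("study_id", "species", "subject_role", "subject_id", "mother_id",
    "tissue", "compound_raw", "compound_id", "compound_class",
    "value", "unit", "basis", "censoring", "lod", "n_pooled",
    "aggregation", "is_sum", "is_coelution", "members",
    "lipid_fraction_reported", "out_of_calibration")
}

split_members <- function(members) {
  lapply(members, function(m) {
    if (is.na(m) || !nzchar(m)) character(0) else strsplit(m, "|", fixed = TRUE)[[1]]
  })
}

join_members <- function(members) {
  vapply(members, function(m) paste(m, collapse = "|"), character(1))
}

# Empty canonical record table with correct column types.
empty_records <- function() {
  data.frame(
    study_id = character(0), species = character(0),
    subject_role = character(0), subject_id = character(0),
    mother_id = character(0), tissue = character(0),
    compound_raw = character(0), compound_id = character(0),
    compound_class = character(0), value = numeric(0), unit = character(0),
    basis = character(0), censoring = character(0), lod = numeric(0),
    n_pooled = integer(0), aggregation = character(0),
    is_sum = logical(0), is_coelution = logical(0), members = character(0),
    lipid_fraction_reported = numeric(0), out_of_calibration = logical(0),
    stringsAsFactors = FALSE
  )
}
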