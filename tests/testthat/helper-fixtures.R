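# Fixture builders shared across test files. Everything is generated in code;
# no stored binary fixtures.

# One-row canonical study record with overridable fields.
make_record <- function(...) {
  rec <- data.frame(
    study_id = "S1", species = "Malaclemys terrapin",
    subject_role = "mother", subject_id = "m01", mother_id = "m01",
    tissue = "liver", compound_raw = "PCB-153", compound_id = "PCB153",
    compound_class = "PCB", value = 1, unit = "ng/g", basis = "wet",
    censoring = "uncensored", lod = NA_real_, n_pooled = 1L,
    aggregation = "individual", is_sum = FALSE, is_coelution = FALSE,
    members = NA_character_, lipid_fraction_reported = NA_real_,
    out_of_calibration = FALSE, stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) rec[[nm]] <- args[[nm]]
  rec
}

make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Minimal harmonized-style row for transfer-statistics tests.
make_harmonized <- function(subject_role, subject_id, tissue, compound_id,
                            conc_lw, conc_ww = conc_lw * 0.05,
                            mother_id = NA_character_,
                            censoring = "uncensored", study_id = "S1",
                            species = "Malaclemys terrapin",
                            compound_class = "PCB") {
  data.frame(study_id = study_id, species = species,
             subject_role = subject_role, subject_id = subject_id,
             mother_id = mother_id, tissue = tissue,
             compound_id = compound_id, compound_class = compound_class,
             censoring = censoring, conc_ng_g_lw = conc_lw,
             conc_ng_g_ww = conc_ww, stringsAsFactors = FALSE)
}

# Write records to a raw study-table CSV the way a study file would look.
write_raw_fixture <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Small descriptor table used by the chemprops tests.
chemprops_fixture_table <- function() {
  data.frame(
    compound_id = c("A", "B", "C", "PCB82", "PCB151", "CPX"),
    log_kow_experimental = c(6.1, NA, NA, NA, NA, NA),
    log_kow_estimated = c(6.4, 6.8, 6.1, 6.1, 6.8, NA),
    molecular_weight = c(360.88, 360.88, 300.5, 360.88, 360.88, 420),
    complexity = c(321, 321, 250, 321, 321, 190),
    heavy_atom_count = c(18, 18, 16, 18, 18, 20),
    h_bond_donors = c(0, 0, 0, 0, 0, 0),
    h_bond_acceptors = c(0, 0, 1, 0, 0, 0),
    tpsa = c(0, 0, 9.2, 0, 0, 0),
    formal_charge = c(0, 0, 0, 0, 0, 0),
    rotatable_bonds = c(1, 1, 2, 1, 1, 8),
    stringsAsFactors = FALSE)
}

chemprops_fixture_overrides <- function() {
  data.frame(
    key = c("CPY", "PCB151+PCB82"),
    descriptor = c("log_kow", "log_kow"),
    value = c(6.2, 6.45),
    reference = c("test", "test"),
    stringsAsFactors = FALSE)
}

# Independent brute-force type-7 quantile from first principles: sort, then
# linear interpolation at h = (n-1)p + 1.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Independent unit-conversion oracle: derive the factor from SI prefix
# exponents instead of a lookup table. value [x/y] = value * 10^(ex - ey + 9)
# ng/g, with ppm/ppb/ppt read as ug/g, ng/g, pg/g.
oracle_to_ng_g <- function(value, unit) {
  map <- list("ppm" = c("ug", "g"), "ppb" = c("ng", "g"), "ppt" = c("pg", "g"))
  if (unit %in% names(map)) {
    parts <- map[[unit]]
  } else {
    parts <- strsplit(unit, "/", fixed = TRUE)[[1]]
  }
  pref <- c(pg = -12, ng = -9, ug = -6, mg = -3)
  denom <- c(g = 0, kg = 3)
  value * 10^(pref[[parts[1]]] - denom[[parts[2]]] + 9 + 0)
}
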