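# Harmonize: unit conversion, dry->wet conversion, lipid normalization.

# Exact rational scale factors to ng/g. ppm/ppb/ppt read as mass ratios
# (ppm = µg/g, ppb = ng/g, ppt = pg/g).
.UNIT_FACTORS <- c(
  "ng/g"  = 1,
  "ug/g"  = 1000,
  "ug/kg" = 1,
  "mg/kg" = 1000,
  "ng/kg" = 0.001,
  "pg/g"  = 0.001,
  "ppm"   = 1000,
  "ppb"   = 1,
  "ppt"   = 0.001
)

normalize_unit_token <- function(unit) {
  u <- tolower(trimws(unit))
  u <- gsub("µ|μ", "u", u)  # micro sign / Greek mu -> "u"
  gsub("\\s", "", u)
}

unit_factor_or_na <- function(unit) {
  u <- normalize_unit_token(unit)
  out <- unname(.UNIT_FACTORS[u])
  out
}

#' Convert a concentration to ng/g
#'
#' Supported unit dialect: `ng/g`, `µg/g` (or `ug/g`), `µg/kg`, `mg/kg`,
#' `ng/kg`, `pg/g`, and the mass-ratio readings `ppm` (= µg/g), `ppb`
#' (= ng/g), `ppt` (= pg/g). All factors are exact rational scalings.
#'
#' @param value Numeric concentration(s).
#' @param unit Unit token(s), recycled against `value`.
#' @return Concentration(s) in ng/g.
#' @examples
#' convert_unit(0.5, "mg/kg")  # 500 ng/g
#' @export
convert_unit <- function(value, unit) {
  f <- unit_factor_or_na(unit)
  if (any(is.na(f) & !is.na(unit)))
    stop("unsupported unit token: ",
         paste(unique(unit[is.na(f)]), collapse = ", "))
  value * f
}

#' Convert a dry-weight concentration to wet weight
#'
#' `conc_wet = conc_dry * (1 - water_fraction)`: the analyte mass is
#' unchanged while the reference mass gains the tissue's water.
#'
#' @param conc_dry Concentration in ng/g dry weight.
#' @param water_fraction Tissue water content as a fraction in `[0, 1)`.
#' @return Concentration in ng/g wet weight.
#' @examples
#' dry_to_wet(100, 0.667)  # 33.3 ng/g ww
#' @export
dry_to_wet <- function(conc_dry, water_fraction) {
  if (any(water_fraction < 0 | water_fraction >= 1))
    stop("water_fraction must lie in [0, 1)")
  conc_dry * (1 - water_fraction)
}

#' Lipid-normalize a wet-weight concentration
#'
#' `conc_lw = conc_wet / lipid_fraction`, expressing the burden per gram of
#' tissue lipid so lipophilic compounds are comparable across tissues.
#'
#' @param conc_wet Concentration in ng/g wet weight.
#' @param lipid_fraction Tissue lipid content as a fraction in `(0, 1]`, on
#'   the same (wet) basis as the concentration.
#' @return Concentration in ng/g lipid weight.
#' @examples
#' lipid_normalize(50, 0.05)  # 1000 ng/g lw
#' @export
lipid_normalize <- function(conc_wet, lipid_fraction) {
  if (any(lipid_fraction <= 0 | lipid_fraction > 1))
    stop("lipid_fraction must lie in (0, 1]")
  conc_wet / lipid_fraction
}

#' Look up the lipid fraction for one record
#'
#' Strictly ordered fallback chain: the lipid content reported in the study
#' itself, then a literature value for the same species and tissue, then a
#' literature value for a closely related species (via an explicit
#' species-relatedness map) and the same tissue. The chosen source is always
#' recorded.
#'
#' @param species,tissue Character scalars.
#' @param lipid_fraction_reported The study-reported lipid fraction, or `NA`.
#' @param lipid_table Data.frame with columns `species`, `tissue`,
#'   `lipid_fraction`, and optionally `reference`.
#' @param relatedness Optional data.frame with columns `species` and
#'   `related_species`, consulted in row order.
#' @return List with `lipid_fraction` (`NA` if no source applies) and
#'   `source` (`"study_reported"`, `"same_species_literature"`,
#'   `"related_species_literature"`, or `"none"`).
#' @export
lookup_lipid_fraction <- function(species, tissue,
                                  lipid_fraction_reported = NA_real_,
                                  lipid_table = NULL, relatedness = NULL) {
  if (!is.na(lipid_fraction_reported)) {
    if (lipid_fraction_reported <= 0 || lipid_fraction_reported > 1)
      stop("reported lipid fraction outside (0, 1]")
    return(list(lipid_fraction = lipid_fraction_reported,
                source = "study_reported"))
  }
  if (!is.null(lipid_table)) {
    hit <- lipid_table$species == species & lipid_table$tissue == tissue
    if (any(hit)) {
      return(list(lipid_fraction = lipid_table$lipid_fraction[which(hit)[1]],
                  source = "same_species_literature"))
    }
    if (!is.null(relatedness)) {
      rel <- relatedness$related_species[relatedness$species == species]
      for (r in rel) {
        hit <- lipid_table$species == r & lipid_table$tissue == tissue
        if (any(hit)) {
          return(list(lipid_fraction = lipid_table$lipid_fraction[which(hit)[1]],
                      source = "related_species_literature"))
        }
      }
    }
  }
  list(lipid_fraction = NA_real_, source = "none")
}

lookup_water_fraction <- function(species, tissue, water_table) {
  if (is.null(water_table)) return(NA_real_)
  hit <- water_table$species == species & water_table$tissue == tissue
  if (any(hit)) water_table$water_fraction[which(hit)[1]] else NA_real_
}

#' Harmonize study records to ng/g wet-weight and lipid-normalized bases
#'
#' Composes unit conversion, dry-to-wet conversion (where the record is on a
#' dry basis) and lipid normalization, applying the identical composed map to
#' the measured value and to the LOD, so censoring intervals survive
#' harmonization intact. The censoring status is never altered. Each record
#' carries a `conversion_trace` listing every applied step with its factor.
#'
#' Records whose basis is `lipid` yield the lipid-normalized concentration
#' directly; their wet-weight value is reconstructed from the lipid fraction
#' when one is available. Records lacking a lipid fraction at every level of
#' the fallback chain are kept un-normalized (wet-weight only) with a
#' diagnostic; dry-basis records lacking a water fraction cannot be
#' harmonized and are flagged.
#'
#' @param records Canonical record table (post-ingest).
#' @param lipid_table,relatedness See [lookup_lipid_fraction()].
#' @param water_table Data.frame with columns `species`, `tissue`,
#'   `water_fraction`.
#' @return The record table with added columns `conc_ng_g_ww`,
#'   `conc_ng_g_lw`, `lod_ng_g_ww`, `lod_ng_g_lw`, `lipid_fraction_used`,
#'   `lipid_source`, `conversion_trace`, plus a `"diagnostics"` attribute
#'   (data.frame `row`, `message`).
#' @export
harmonize_records <- function(records, lipid_table = NULL, water_table = NULL,
                              relatedness = NULL) {
  n <- nrow(records)
  ww <- lw <- lod_ww <- lod_lw <- rep(NA_real_, n)
  lf_used <- rep(NA_real_, n)
  lf_source <- rep(NA_character_, n)
  trace <- rep("", n)
  diag <- list()

  for (i in seq_len(n)) {
    r <- records[i, ]
    steps <- character(0)

    lf <- lookup_lipid_fraction(r$species, r$tissue,
                                r$lipid_fraction_reported,
                                lipid_table, relatedness)
    lf_used[i] <- lf$lipid_fraction
    lf_source[i] <- lf$source

    if (r$censoring == "qual_censored") {
      # below an unknown LOD: nothing numeric to transform
      trace[i] <- "qual_censored:none"
      next
    }

    uf <- unit_factor_or_na(r$unit)
    if (is.na(uf)) {
      diag[[length(diag) + 1L]] <- data.frame(
        row = i, message = paste0("unsupported unit: ", r$unit),
        stringsAsFactors = FALSE)
      next
    }
    steps <- c(steps, sprintf("unit[%s]:x%g", r$unit, uf))
    v_ng <- if (!is.na(r$value)) r$value * uf else NA_real_
    l_ng <- if (!is.na(r$lod)) r$lod * uf else NA_real_

    if (r$basis == "lipid") {
      lw[i] <- v_ng
      lod_lw[i] <- l_ng
      steps <- c(steps, "basis:lipid")
      if (!is.na(lf$lipid_fraction)) {
        ww[i] <- v_ng * lf$lipid_fraction
        lod_ww[i] <- l_ng * lf$lipid_fraction
        steps <- c(steps, sprintf("to_wet:x%g", lf$lipid_fraction))
      }
    } else {
      v_ww <- v_ng
      l_ww <- l_ng
      if (r$basis == "dry") {
        wf <- lookup_water_fraction(r$species, r$tissue, water_table)
        if (is.na(wf)) {
          diag[[length(diag) + 1L]] <- data.frame(
            row = i, message = "dry basis without a known water fraction",
            stringsAsFactors = FALSE)
          trace[i] <- paste(steps, collapse = ";")
          next
        }
        v_ww <- dry_to_wet(v_ww, wf)
        l_ww <- dry_to_wet(l_ww, wf)
        steps <- c(steps, sprintf("dry_to_wet:x%g", 1 - wf))
      }
      ww[i] <- v_ww
      lod_ww[i] <- l_ww
      if (!is.na(lf$lipid_fraction)) {
        lw[i] <- lipid_normalize(v_ww, lf$lipid_fraction)
        lod_lw[i] <- lipid_normalize(l_ww, lf$lipid_fraction)
        steps <- c(steps, sprintf("lipid_norm:/%g", lf$lipid_fraction))
      } else {
        diag[[length(diag) + 1L]] <- data.frame(
          row = i, message = "no lipid fraction at any fallback level; kept wet-weight only",
          stringsAsFactors = FALSE)
      }
    }
    trace[i] <- paste(steps, collapse = ";")
  }

  out <- records
  out$conc_ng_g_ww <- ww
  out$conc_ng_g_lw <- lw
  out$lod_ng_g_ww <- lod_ww
  out$lod_ng_g_lw <- lod_lw
  out$lipid_fraction_used <- lf_used
  out$lipid_source <- lf_source
  out$conversion_trace <- trace
  attr(out, "diagnostics") <- if (length(diag)) do.call(rbind, diag) else
    data.frame(row = integer(0), message = character(0), stringsAsFactors = FALSE)
  out
}

#' Harmonize a single record
#'
#' Convenience wrapper around [harmonize_records()] for one record.
#'
#' @inheritParams harmonize_records
#' @param record One-row canonical record table.
#' @return One-row harmonized record table.
#' @export
harmonize_record <- function(record, lipid_table = NULL, water_table = NULL,
                             relatedness = NULL) {
  stopifnot(nrow(record) == 1)
  harmonize_records(record, lipid_table, water_table, relatedness)
}
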