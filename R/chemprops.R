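# Molecular descriptors with provenance; coelution and sum rules.

.DESCRIPTORS <- c("log_kow", "molecular_weight", "complexity",
                  "heavy_atom_count", "h_bond_donors", "h_bond_acceptors",
                  "tpsa", "formal_charge", "rotatable_bonds")
.INT_DESCRIPTORS <- c("heavy_atom_count", "h_bond_donors", "h_bond_acceptors",
                      "formal_charge", "rotatable_bonds")

empty_property <- function(compound_id) {
  out <- data.frame(compound_id = compound_id, stringsAsFactors = FALSE)
  for (d in .DESCRIPTORS) out[[d]] <- NA_real_
  out$kow_provenance <- "unassigned"
  out
}

override_key <- function(ids) paste(sort(ids), collapse = "+")

lookup_override <- function(key, descriptor, override_table) {
  if (is.null(override_table)) return(NA_real_)
  hit <- override_table$key == key & override_table$descriptor == descriptor
  if (any(hit)) override_table$value[which(hit)[1]] else NA_real_
}

#' Attach molecular descriptors to a compound
#'
#' Fills a compound's descriptor record from a local property table (the role
#' of a PubChem/KOWWIN export). For log Kow the policy is: experimental value
#' when available, otherwise the model-estimated value, otherwise an explicit
#' override entry (the route used for chlorinated paraffins, whose Kow values
#' are taken from dedicated literature); the provenance of the chosen value is
#' recorded. A compound absent from every table yields an all-unassigned
#' record — absence is a recorded state, not an error.
#'
#' @param compound_id Canonical compound identifier (scalar).
#' @param property_table Data.frame keyed by `compound_id` with columns
#'   `log_kow_experimental`, `log_kow_estimated` and the descriptor columns
#'   `molecular_weight`, `complexity`, `heavy_atom_count`, `h_bond_donors`,
#'   `h_bond_acceptors`, `tpsa`, `formal_charge`, `rotatable_bonds`.
#' @param override_table Optional data.frame with columns `key` (compound id
#'   or "+"-joined sorted member ids), `descriptor`, `value`, `reference`.
#' @return One-row data.frame with the descriptor columns and
#'   `kow_provenance` in `{"experimental", "estimated", "override",
#'   "unassigned"}`.
#' @export
attach_properties <- function(compound_id, property_table,
                              override_table = NULL) {
  stopifnot(length(compound_id) == 1)
  out <- empty_property(compound_id)
  row <- property_table[property_table$compound_id == compound_id, , drop = FALSE]
  if (nrow(row)) {
    row <- row[1, ]
    for (d in setdiff(.DESCRIPTORS, "log_kow"))
      if (d %in% names(row)) out[[d]] <- as.numeric(row[[d]])
    if (!is.na(row$log_kow_experimental)) {
      out$log_kow <- row$log_kow_experimental
      out$kow_provenance <- "experimental"
    } else if (!is.na(row$log_kow_estimated)) {
      out$log_kow <- row$log_kow_estimated
      out$kow_provenance <- "estimated"
    }
  }
  if (is.na(out$log_kow)) {
    ov <- lookup_override(compound_id, "log_kow", override_table)
    if (!is.na(ov)) {
      out$log_kow <- ov
      out$kow_provenance <- "override"
    }
  }
  out
}

#' Resolve descriptors for a coelution
#'
#' Compounds not separable by the analytical method are reported as one
#' combined measurement. A descriptor is assigned to the coelution only if
#' every contributing compound yields the same value (exactly for integer
#' descriptors, within 1e-6 absolute for real-valued ones); otherwise that
#' descriptor stays unassigned. Explicit override entries — such as an
#' experimentally derived log Kow for a specific congener pair — take
#' precedence over the equality rule and are marked with provenance
#' `"override"`. A member missing from the tables leaves the affected
#' descriptors unassigned.
#'
#' @param members Character vector of at least two member compound ids;
#'   order-insensitive.
#' @inheritParams attach_properties
#' @return One-row data.frame as in [attach_properties()], with
#'   `compound_id` set to the "+"-joined sorted member ids.
#' @export
resolve_coelution <- function(members, property_table, override_table = NULL) {
  stopifnot(length(members) >= 2)
  key <- override_key(members)
  out <- empty_property(key)
  props <- lapply(members, attach_properties, property_table = property_table,
                  override_table = NULL)
  for (d in .DESCRIPTORS) {
    vals <- vapply(props, function(p) p[[d]], numeric(1))
    if (any(is.na(vals))) next
    agree <- if (d %in% .INT_DESCRIPTORS) length(unique(vals)) == 1 else
      max(vals) - min(vals) <= 1e-6
    if (agree) {
      out[[d]] <- vals[1]
      if (d == "log_kow") {
        prov <- vapply(props, function(p) p$kow_provenance, character(1))
        out$kow_provenance <- if (all(prov == "experimental")) "experimental" else "estimated"
      }
    }
  }
  for (d in .DESCRIPTORS) {
    ov <- lookup_override(key, d, override_table)
    if (!is.na(ov)) {
      out[[d]] <- ov
      if (d == "log_kow") out$kow_provenance <- "override"
    }
  }
  out
}

#' Descriptor rule for sums of compounds
#'
#' Data available only as sums of individual compounds receive no molecular
#' descriptors: unlike coelutions, a sum aggregates measurements of distinct
#' analytes, so no single structure underlies the value — even when all
#' members happen to share identical descriptor values.
#'
#' @param record One-row canonical record table with `is_sum = TRUE`.
#' @return One-row all-unassigned descriptor record.
#' @export
sum_property_rule <- function(record) {
  stopifnot(nrow(record) == 1)
  if (!isTRUE(record$is_sum)) stop("sum_property_rule applies only to sum records")
  empty_property(record$compound_id)
}

#' Attach descriptors to every unique compound in a record table
#'
#' Routes each unique analyte through the applicable rule: sums get no
#' descriptors, coelutions go through the equality rule, plain compounds
#' through the provenance policy.
#'
#' @param records Canonicalized record table.
#' @inheritParams attach_properties
#' @return Data.frame with one row per unique analyte (`compound_id`),
#'   descriptor columns, `kow_provenance` and `compound_class`.
#' @export
attach_properties_db <- function(records, property_table, override_table = NULL) {
  keys <- !duplicated(records$compound_id)
  idx <- which(keys)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (isTRUE(records$is_sum[i])) {
      p <- sum_property_rule(records[i, ])
    } else if (isTRUE(records$is_coelution[i])) {
      mem <- split_members(records$members[i])[[1]]
      p <- if (length(mem) >= 2)
        resolve_coelution(mem, property_table, override_table)
      else attach_properties(records$compound_id[i], property_table, override_table)
      p$compound_id <- records$compound_id[i]
    } else {
      p <- attach_properties(records$compound_id[i], property_table, override_table)
    }
    p$compound_class <- records$compound_class[i]
    rows[[k]] <- p
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize the chemical space covered per compound class
#'
#' Per compound class: mean, min and max of every descriptor over the
#' compounds with an assigned value, the number of unique compounds, and the
#' fraction of compounds with zero formal charge, zero H-bond donors, zero
#' H-bond acceptors and zero topological polar surface area. Input is
#' deduplicated by `compound_id`, so summaries are invariant to repeated
#' records of the same compound. Empty classes are omitted.
#'
#' @param properties Data.frame as from [attach_properties_db()] (must carry
#'   `compound_class`).
#' @return Data.frame with one row per class: `compound_class`,
#'   `n_compounds`, `<descriptor>_mean/_min/_max` for each descriptor, and
#'   the four `fraction_zero_*` columns.
#' @export
chemical_space_summary <- function(properties) {
  properties <- properties[!duplicated(properties$compound_id), , drop = FALSE]
  classes <- unique(properties$compound_class)
  rows <- lapply(classes, function(cl) {
    p <- properties[properties$compound_class == cl, , drop = FALSE]
    row <- data.frame(compound_class = cl, n_compounds = nrow(p),
                      stringsAsFactors = FALSE)
    for (d in .DESCRIPTORS) {
      v <- p[[d]][!is.na(p[[d]])]
      row[[paste0(d, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(d, "_min")]]  <- if (length(v)) min(v) else NA_real_
      row[[paste0(d, "_max")]]  <- if (length(v)) max(v) else NA_real_
    }
    fz <- function(d) {
      v <- p[[d]][!is.na(p[[d]])]
      if (length(v)) mean(v == 0) else NA_real_
    }
    row$fraction_zero_charge <- fz("formal_charge")
    row$fraction_zero_donors <- fz("h_bond_donors")
    row$fraction_zero_acceptors <- fz("h_bond_acceptors")
    row$fraction_zero_tpsa <- fz("tpsa")
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
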