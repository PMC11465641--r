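# Censoring audit: three-state classification and data-amount accounting.

#' Classify the censoring state of observations
#'
#' Deterministic mapping from the three flags an extracted row can carry:
#' a measured value with no below-LOD flag is `uncensored`; a below-LOD flag
#' with a known limit is `quant_censored` (the observation is the interval
#' `[0, LOD]`); a below-LOD flag without a limit is `qual_censored` (no
#' quantitative information at all). A measured value together with a
#' below-LOD flag is inconsistent and raises an error.
#'
#' @param value_present Logical vector: a point value is present.
#' @param below_lod Logical vector: the row is flagged below the LOD/LOQ.
#' @param lod_present Logical vector: the LOD's value is known.
#' @return Character vector over [ot_censoring_states()].
#' @export
classify_censoring <- function(value_present, below_lod, lod_present) {
  if (any(value_present & below_lod))
    stop("inconsistent flags: measured value present on a below-LOD row")
  if (any(!value_present & !below_lod))
    stop("row carries neither a value nor a below-LOD flag")
  ifelse(!below_lod, "uncensored",
         ifelse(lod_present, "quant_censored", "qual_censored"))
}

#' Count censoring states per group
#'
#' @param db Record table with a `censoring` column.
#' @param group_by Character vector of grouping columns (e.g.
#'   `c("study_id", "species")`); `NULL` for one global row.
#' @return Data.frame with the grouping keys plus `n_total`, `n_uncensored`,
#'   `n_quant_censored`, `n_qual_censored`, `n_quantitative`
#'   (`= n_total - n_qual_censored`) and the three `prop_*` proportions.
#'   Empty groups are omitted.
#' @export
censoring_summary <- function(db, group_by = NULL) {
  if (is.null(group_by)) {
    db$.all <- "all"
    group_by <- ".all"
  }
  key <- interaction(db[group_by], drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(db)), key), function(idx) {
    g <- db[idx, , drop = FALSE]
    out <- g[1, group_by, drop = FALSE]
    out$n_total <- nrow(g)
    out$n_uncensored <- sum(g$censoring == "uncensored")
    out$n_quant_censored <- sum(g$censoring == "quant_censored")
    out$n_qual_censored <- sum(g$censoring == "qual_censored")
    out$n_quantitative <- out$n_total - out$n_qual_censored
    out$prop_uncensored <- out$n_uncensored / out$n_total
    out$prop_quant_censored <- out$n_quant_censored / out$n_total
    out$prop_qual_censored <- out$n_qual_censored / out$n_total
    out
  })
  out <- do.call(rbind, rows)
  if (".all" %in% names(out)) out$.all <- NULL
  rownames(out) <- NULL
  out
}

#' Count quantitatively informative data points per key
#'
#' "Data point" means one compound in one individual (or pooled group) in one
#' tissue. Only points carrying quantitative information count: measured
#' values and censored values with a known LOD; qualitatively censored points
#' are excluded. Because the field sometimes counts sums of compounds as
#' single points and sometimes not, the count is reported both ways.
#'
#' @param db Record table with `censoring` and `is_sum` columns.
#' @param keys Character vector of grouping columns, e.g.
#'   `c("species", "compound_class")`.
#' @return Data.frame with the keys plus `n` (quantitative points) and
#'   `n_excluding_sums` (the same, not counting sum-of-compound rows).
#' @export
data_amount_summary <- function(db, keys) {
  quant <- db[db$censoring != "qual_censored", , drop = FALSE]
  if (!nrow(quant)) {
    out <- db[0, keys, drop = FALSE]
    out$n <- integer(0)
    out$n_excluding_sums <- integer(0)
    return(out)
  }
  key <- interaction(quant[keys], drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(quant)), key), function(idx) {
    g <- quant[idx, , drop = FALSE]
    out <- g[1, keys, drop = FALSE]
    out$n <- nrow(g)
    out$n_excluding_sums <- sum(!g$is_sum)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a harmonized database the way the deposited database is described
#'
#' Computes the headline accounting quantities of a compiled maternal-transfer
#' database: total data points, percentage of uncensored values, percentages
#' of quantitatively and qualitatively censored values (overall and as shares
#' of the censored subset), the percentage of records that are sums of
#' compounds, the percentage that are coelutions, and the share of unique
#' compounds lacking any assigned molecular descriptor.
#'
#' @param db Record table with `censoring`, `is_sum`, `is_coelution` columns.
#' @param properties Optional descriptor table from [attach_properties_db()];
#'   when supplied, descriptor coverage is computed over unique compounds.
#' @return Named list of counts and percentages (percentages on 0–100 scale).
#' @export
deposit_summary <- function(db, properties = NULL) {
  n <- nrow(db)
  n_unc <- sum(db$censoring == "uncensored")
  n_quant_c <- sum(db$censoring == "quant_censored")
  n_qual_c <- sum(db$censoring == "qual_censored")
  out <- list(
    n_data_points = n,
    pct_uncensored = 100 * n_unc / n,
    pct_censored = 100 * (n_quant_c + n_qual_c) / n,
    pct_quant_censored_of_censored =
      if (n_quant_c + n_qual_c > 0) 100 * n_quant_c / (n_quant_c + n_qual_c) else NA_real_,
    pct_qual_censored_of_censored =
      if (n_quant_c + n_qual_c > 0) 100 * n_qual_c / (n_quant_c + n_qual_c) else NA_real_,
    pct_sums = 100 * mean(db$is_sum),
    pct_coelutions = 100 * mean(db$is_coelution)
  )
  if (!is.null(properties)) {
    u <- properties[!duplicated(properties$compound_id), , drop = FALSE]
    no_desc <- apply(u[, .DESCRIPTORS, drop = FALSE], 1,
                     function(v) all(is.na(v)))
    out$pct_compounds_missing_descriptors <- 100 * mean(no_desc)
  }
  out
}
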