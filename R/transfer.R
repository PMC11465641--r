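# Transfer statistics: pairing, partition ratios, banding, correlations,
# ratio-vs-Kow trends.

geometric_mean <- function(x) exp(mean(log(x)))

#' Pair mother and offspring observations
#'
#' Builds one mother-offspring pair per (study, mother, compound, mother
#' tissue, offspring matrix) combination from a harmonized database, linking
#' offspring rows to their mother through `mother_id`. Under
#' `policy = "per_egg"` each offspring unit yields its own pair; under
#' `policy = "clutch_mean"` replicate eggs of one clutch are first collapsed
#' to the geometric mean of their uncensored values. Offspring without a
#' linked mother are reported in the `"diagnostics"` attribute and yield no
#' pair.
#'
#' @param db Harmonized record table ([harmonize_records()]).
#' @param policy `"per_egg"` or `"clutch_mean"`.
#' @param basis `"lipid"` (default; concentrations `conc_ng_g_lw`) or
#'   `"wet"` (`conc_ng_g_ww`, the basis used for PFAS).
#' @return Data.frame of pairs: `study_id`, `species`, `mother_id`,
#'   `mother_tissue`, `offspring_matrix`, `offspring_id`, `compound_id`,
#'   `compound_class`, `basis`, `c_mother`, `c_offspring`,
#'   `censoring_mother`, `censoring_offspring`.
#' @export
pair_mother_offspring <- function(db, policy = c("per_egg", "clutch_mean"),
                                  basis = c("lipid", "wet")) {
  policy <- match.arg(policy)
  basis <- match.arg(basis)
  conc_col <- if (basis == "lipid") "conc_ng_g_lw" else "conc_ng_g_ww"

  mothers <- db[db$subject_role == "mother", , drop = FALSE]
  offspring <- db[db$subject_role == "offspring", , drop = FALSE]

  orphan <- is.na(offspring$mother_id) |
    !(paste(offspring$study_id, offspring$mother_id) %in%
        paste(mothers$study_id, mothers$subject_id))
  diag <- if (any(orphan)) data.frame(
    study_id = offspring$study_id[orphan],
    subject_id = offspring$subject_id[orphan],
    message = "offspring without linked mother",
    stringsAsFactors = FALSE) else
      data.frame(study_id = character(0), subject_id = character(0),
                 message = character(0), stringsAsFactors = FALSE)
  offspring <- offspring[!orphan, , drop = FALSE]

  out <- NULL
  if (nrow(mothers) && nrow(offspring)) {
    off <- data.frame(
      study_id = offspring$study_id, mother_id = offspring$mother_id,
      compound_id = offspring$compound_id,
      offspring_matrix = offspring$tissue,
      offspring_id = offspring$subject_id,
      c_offspring = offspring[[conc_col]],
      censoring_offspring = offspring$censoring,
      stringsAsFactors = FALSE)
    if (policy == "clutch_mean") {
      key <- interaction(off$study_id, off$mother_id, off$compound_id,
                         off$offspring_matrix, drop = TRUE, sep = "\r")
      off <- do.call(rbind, lapply(split(seq_len(nrow(off)), key), function(idx) {
        o <- off[idx, , drop = FALSE]
        unc <- o$censoring_offspring == "uncensored" &
          !is.na(o$c_offspring) & o$c_offspring > 0
        data.frame(
          study_id = o$study_id[1], mother_id = o$mother_id[1],
          compound_id = o$compound_id[1],
          offspring_matrix = o$offspring_matrix[1],
          offspring_id = paste0(o$mother_id[1], "_clutch"),
          c_offspring = if (any(unc)) geometric_mean(o$c_offspring[unc]) else NA_real_,
          censoring_offspring = if (any(unc)) "uncensored" else
            o$censoring_offspring[1],
          stringsAsFactors = FALSE)
      }))
    }
    mom <- data.frame(
      study_id = mothers$study_id, species = mothers$species,
      mother_id = mothers$subject_id, mother_tissue = mothers$tissue,
      compound_id = mothers$compound_id,
      compound_class = mothers$compound_class,
      c_mother = mothers[[conc_col]],
      censoring_mother = mothers$censoring,
      stringsAsFactors = FALSE)
    out <- merge(mom, off, by = c("study_id", "mother_id", "compound_id"))
    if (nrow(out)) {
      out$basis <- basis
      out <- out[, c("study_id", "species", "mother_id", "mother_tissue",
                     "offspring_matrix", "offspring_id", "compound_id",
                     "compound_class", "basis", "c_mother", "c_offspring",
                     "censoring_mother", "censoring_offspring")]
    } else out <- NULL
  }
  if (is.null(out)) out <- data.frame(
    study_id = character(0), species = character(0), mother_id = character(0),
    mother_tissue = character(0), offspring_matrix = character(0),
    offspring_id = character(0), compound_id = character(0),
    compound_class = character(0), basis = character(0),
    c_mother = numeric(0), c_offspring = numeric(0),
    censoring_mother = character(0), censoring_offspring = character(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag
  out
}

#' Compute log10 offspring:mother partition ratios
#'
#' `R = log10(c_offspring / c_mother)`; 0 marks the lipid-normalized
#' equilibrium, +1/-1 a ten-fold higher or lower burden in the offspring.
#' Only pairs with both sides uncensored and strictly positive yield a
#' ratio; other pairs are skipped with a reason recorded in the
#' `"skipped"` attribute.
#'
#' @param pairs Data.frame from [pair_mother_offspring()].
#' @return The qualifying pairs with an added column `R`, plus attribute
#'   `"skipped"` (the excluded pairs with a `reason` column:
#'   `censored_mother`, `censored_offspring`, `nonpositive_concentration`,
#'   `missing_concentration`).
#' @export
transfer_ratios <- function(pairs) {
  reason <- rep(NA_character_, nrow(pairs))
  reason[is.na(reason) & pairs$censoring_mother != "uncensored"] <- "censored_mother"
  reason[is.na(reason) & pairs$censoring_offspring != "uncensored"] <- "censored_offspring"
  reason[is.na(reason) & (is.na(pairs$c_mother) | is.na(pairs$c_offspring))] <-
    "missing_concentration"
  reason[is.na(reason) & (pairs$c_mother <= 0 | pairs$c_offspring <= 0)] <-
    "nonpositive_concentration"
  keep <- is.na(reason)
  out <- pairs[keep, , drop = FALSE]
  out$R <- log10(out$c_offspring / out$c_mother)
  skipped <- pairs[!keep, , drop = FALSE]
  if (nrow(skipped)) skipped$reason <- reason[!keep] else skipped$reason <- character(0)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Classify a partition ratio against the ten-fold equilibrium band
#'
#' `within_10fold` iff `|R| <= 1` (the band is closed: a ratio exactly on the
#' ten-fold line counts as within), `above` for `R > 1`, `below` for
#' `R < -1`.
#'
#' @param R Numeric vector of finite log10 partition ratios.
#' @return Character vector in `{"within_10fold", "above", "below"}`.
#' @export
equilibrium_band <- function(R) {
  stopifnot(all(is.finite(R)))
  ifelse(abs(R) <= 1, "within_10fold", ifelse(R > 1, "above", "below"))
}

#' Boxplot-style summary of partition ratios per group
#'
#' For each group: n, median, quartiles (type-7 linear interpolation, so the
#' convention is explicit and reproducible across languages), whisker bounds
#' at `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR` clamped to the most extreme observed
#' values inside the fences, and the count of observations beyond the
#' whiskers. Empty groups are omitted.
#'
#' @param ratios Data.frame from [transfer_ratios()].
#' @param by Character vector of grouping columns; default
#'   `c("species", "mother_tissue", "compound_class")`.
#' @return Data.frame with the grouping keys plus `n`, `median`, `q1`, `q3`,
#'   `iqr`, `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
ratio_summary <- function(ratios,
                          by = c("species", "mother_tissue", "compound_class")) {
  if (!nrow(ratios)) {
    out <- ratios[0, by, drop = FALSE]
    for (col in c("n", "median", "q1", "q3", "iqr", "whisker_lo",
                  "whisker_hi", "n_outliers")) out[[col]] <- numeric(0)
    return(out)
  }
  key <- interaction(ratios[by], drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(ratios)), key), function(idx) {
    g <- ratios[idx, , drop = FALSE]
    q <- stats::quantile(g$R, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- g$R[g$R >= lo_fence & g$R <= hi_fence]
    out <- g[1, by, drop = FALSE]
    out$n <- nrow(g)
    out$median <- q[2]
    out$q1 <- q[1]
    out$q3 <- q[3]
    out$iqr <- iqr
    out$whisker_lo <- min(inside)
    out$whisker_hi <- max(inside)
    out$n_outliers <- sum(g$R < lo_fence | g$R > hi_fence)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlations of pollutant concentrations among maternal tissues
#'
#' For each pair of maternal tissues, correlates log10 lipid-normalized
#' concentrations over co-measured observations (same study, same mother,
#' same compound, both uncensored). Pearson is reported as the primary
#' coefficient with Spearman alongside, since published tissue-correlation
#' summaries rarely name their method. Tissue pairs with fewer than
#' `min_pairs` co-measurements are absent from the output.
#'
#' @param db Harmonized record table; only `subject_role == "mother"` rows
#'   are used.
#' @param min_pairs Minimum number of co-measured observations per tissue
#'   pair (default 10).
#' @param conc_col Concentration column to correlate (default lipid basis).
#' @return List with `pairs` (data.frame `tissue_a`, `tissue_b`, `n`,
#'   `pearson`, `spearman`) and `summary` (median, min, max of the Pearson
#'   entries; `NA` when no pair qualifies).
#' @export
tissue_correlations <- function(db, min_pairs = 10, conc_col = "conc_ng_g_lw") {
  m <- db[db$subject_role == "mother" & db$censoring == "uncensored" &
            !is.na(db[[conc_col]]) & db[[conc_col]] > 0, , drop = FALSE]
  m$obs_key <- paste(m$study_id, m$subject_id, m$compound_id, sep = "\r")
  tissues <- sort(unique(m$tissue))
  rows <- list()
  if (length(tissues) >= 2) {
    for (a in seq_along(tissues)) {
      for (b in seq_along(tissues)) {
        if (b <= a) next
        xa <- m[m$tissue == tissues[a], c("obs_key", conc_col)]
        xb <- m[m$tissue == tissues[b], c("obs_key", conc_col)]
        xa <- xa[!duplicated(xa$obs_key), ]
        xb <- xb[!duplicated(xb$obs_key), ]
        j <- merge(xa, xb, by = "obs_key")
        if (nrow(j) < min_pairs) next
        la <- log10(j[[2]])
        lb <- log10(j[[3]])
        rows[[length(rows) + 1L]] <- data.frame(
          tissue_a = tissues[a], tissue_b = tissues[b], n = nrow(j),
          pearson = stats::cor(la, lb),
          spearman = stats::cor(la, lb, method = "spearman"),
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else data.frame(
    tissue_a = character(0), tissue_b = character(0), n = integer(0),
    pearson = numeric(0), spearman = numeric(0), stringsAsFactors = FALSE)
  summary <- if (nrow(pairs)) list(median = stats::median(pairs$pearson),
                                   min = min(pairs$pearson),
                                   max = max(pairs$pearson))
  else list(median = NA_real_, min = NA_real_, max = NA_real_)
  list(pairs = pairs, summary = summary)
}

#' Relate partition ratios to log Kow
#'
#' Per group: the ordinary least-squares slope and intercept of the partition
#' ratio on log10 Kow, the slope's standard error, the Spearman rank
#' correlation, and n. Groups with fewer than five ratios are flagged
#' `low_n`; groups with no variation in log Kow get an undefined slope
#' (`NA`) with `undefined_slope = TRUE`.
#'
#' @param ratios Data.frame from [transfer_ratios()] with an added `log_kow`
#'   column (e.g. merged from [attach_properties_db()]).
#' @param by Grouping columns; default
#'   `c("species", "mother_tissue", "compound_class")`. `NULL` pools
#'   everything into one group.
#' @return Data.frame with the keys plus `n`, `slope`, `slope_se`,
#'   `intercept`, `spearman`, `low_n`, `undefined_slope`.
#' @export
ratio_vs_kow <- function(ratios,
                         by = c("species", "mother_tissue", "compound_class")) {
  r <- ratios[!is.na(ratios$log_kow) & is.finite(ratios$R), , drop = FALSE]
  if (is.null(by)) {
    r$.all <- "all"
    by <- ".all"
  }
  if (!nrow(r)) {
    out <- r[0, setdiff(by, ".all"), drop = FALSE]
    for (col in c("n", "slope", "slope_se", "intercept", "spearman"))
      out[[col]] <- numeric(0)
    out$low_n <- logical(0)
    out$undefined_slope <- logical(0)
    return(out)
  }
  key <- interaction(r[by], drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(r)), key), function(idx) {
    g <- r[idx, , drop = FALSE]
    out <- g[1, by, drop = FALSE]
    out$n <- nrow(g)
    if (stats::var(g$log_kow) == 0 || nrow(g) < 2) {
      out$slope <- NA_real_
      out$slope_se <- NA_real_
      out$intercept <- NA_real_
      out$spearman <- NA_real_
      out$undefined_slope <- TRUE
    } else {
      fit <- stats::lm(R ~ log_kow, data = g)
      cf <- suppressWarnings(summary(fit))$coefficients
      out$slope <- cf["log_kow", "Estimate"]
      out$slope_se <- cf["log_kow", "Std. Error"]
      out$intercept <- cf["(Intercept)", "Estimate"]
      out$spearman <- suppressWarnings(
        stats::cor(g$R, g$log_kow, method = "spearman"))
      out$undefined_slope <- FALSE
    }
    out$low_n <- out$n < 5
    out
  })
  out <- do.call(rbind, rows)
  if (".all" %in% names(out)) out$.all <- NULL
  rownames(out) <- NULL
  out
}
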