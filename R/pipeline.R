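# Pipeline orchestration: simulate | build | analyze, with table export.

#' Assemble a pipeline configuration
#'
#' Collects the file paths and switches that drive [run_build()] and
#' [run_analyze()]. Referenced input paths are checked at run time, before
#' any output is written.
#'
#' @param study_tables Character vector of per-study table paths.
#' @param lipid_table,water_table,property_table,override_table,synonym_table,relatedness
#'   Paths to the auxiliary tables (each optional except `lipid_table` for
#'   lipid-normalized analyses).
#' @param out_dir Output directory; created if absent.
#' @param pairing_policy `"per_egg"` or `"clutch_mean"`.
#' @param min_pairs Minimum co-measurements per tissue pair for
#'   [tissue_correlations()].
#' @param pfas_wet Also analyze PFAS on a wet-weight basis (default `TRUE`).
#' @param seed Integer seed recorded in every output header.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(study_tables, lipid_table = NULL,
                            water_table = NULL, property_table = NULL,
                            override_table = NULL, synonym_table = NULL,
                            relatedness = NULL, out_dir = ".",
                            pairing_policy = "per_egg", min_pairs = 10,
                            pfas_wet = TRUE, seed = 1L) {
  cfg <- list(study_tables = study_tables, lipid_table = lipid_table,
              water_table = water_table, property_table = property_table,
              override_table = override_table, synonym_table = synonym_table,
              relatedness = relatedness, out_dir = out_dir,
              pairing_policy = pairing_policy, min_pairs = min_pairs,
              pfas_wet = isTRUE(pfas_wet), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the 'yaml' package")
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

# Every exported table carries the configuration hash and seed in a header
# comment so any output can be traced to the run that produced it.
write_output_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ovotransfer config_hash=%s seed=%d",
                     config_hash(config), config$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Serialize canonical records to the raw study-table format that
# read_study_table() parses (censoring as a "<LOD" token).
write_raw_study_table <- function(records, path) {
  out <- records
  out$censoring <- ifelse(records$censoring == "uncensored", "",
                          "<LOD")
  utils::write.csv(out[, setdiff(names(out), "compound_id")], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Simulate study files on disk
#'
#' Generates a synthetic dataset ([generate_studies()]) and writes one raw
#' study table per simulated study (in that study's declared unit and basis,
#' with censoring encoded as the tokens a publication would print), the
#' ground-truth table, and the auxiliary lipid/water/property/relatedness
#' tables consistent with the generator's truth.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the generated data and a `paths` element
#'   naming every file written.
#' @export
run_simulate <- function(config = synthetic_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_studies(config)
  paths <- list()
  for (sid in unique(sim$records$study_id)) {
    p <- file.path(out_dir, paste0("study_", sid, ".csv"))
    write_raw_study_table(sim$records[sim$records$study_id == sid, ], p)
    paths$study_tables <- c(paths$study_tables, p)
  }
  hdr_cfg <- list(seed = config$seed)
  class(hdr_cfg) <- "pipeline_config"
  for (nm in c("truth", "lipid", "water", "property", "relatedness")) {
    df <- switch(nm,
                 truth = sim$truth,
                 lipid = synthetic_lipid_table(config),
                 water = synthetic_water_table(config),
                 property = synthetic_property_table(config),
                 relatedness = synthetic_relatedness(config))
    p <- file.path(out_dir, paste0(nm, if (nm == "truth") ".csv" else "_table.csv"))
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths[[nm]] <- p
  }
  invisible(c(sim, list(paths = paths)))
}

#' Build the harmonized database
#'
#' Orchestrates ingest, canonicalization, exclusion rules, harmonization and
#' descriptor annotation, and exports the harmonized database plus every
#' report: excluded records with reason codes, row-level ingest diagnostics,
#' harmonization diagnostics, and the per-compound descriptor table. Every
#' dropped record appears in exactly one report. Missing input paths raise an
#' error before any output is written.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `harmonized`, `excluded`, `properties`,
#'   `ingest_diagnostics`, `harmonize_diagnostics`.
#' @export
run_build <- function(config) {
  paths <- c(config$study_tables, config$lipid_table, config$water_table,
             config$property_table, config$override_table,
             config$synonym_table, config$relatedness)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  syn <- if (!is.null(config$synonym_table)) ot_synonym_table(config$synonym_table)
  else ot_synonym_table()
  lipid <- if (!is.null(config$lipid_table)) read_lipid_table(config$lipid_table)
  water <- if (!is.null(config$water_table)) read_water_table(config$water_table)
  rel <- if (!is.null(config$relatedness)) read_relatedness(config$relatedness)

  recs <- list()
  diags <- list()
  for (p in config$study_tables) {
    r <- read_study_table(p)
    d <- ingest_diagnostics(r)
    if (nrow(d)) d$file <- p
    recs[[p]] <- r
    diags[[p]] <- d
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  ingest_diag <- do.call(rbind, diags)
  rownames(ingest_diag) <- NULL

  records <- canonicalize_records(records, syn)
  split <- apply_exclusion_rules(records)
  harmonized <- harmonize_records(split$kept, lipid_table = lipid,
                                  water_table = water, relatedness = rel)
  harm_diag <- attr(harmonized, "diagnostics")

  properties <- NULL
  if (!is.null(config$property_table)) {
    prop <- read_property_table(config$property_table)
    over <- if (!is.null(config$override_table))
      read_override_table(config$override_table)
    properties <- attach_properties_db(harmonized, prop, over)
  }

  write_output_table(harmonized, file.path(config$out_dir, "harmonized.csv"),
                     config)
  write_output_table(split$excluded, file.path(config$out_dir, "excluded.csv"),
                     config)
  write_output_table(ingest_diag,
                     file.path(config$out_dir, "ingest_diagnostics.csv"),
                     config)
  write_output_table(harm_diag,
                     file.path(config$out_dir, "harmonize_diagnostics.csv"),
                     config)
  if (!is.null(properties))
    write_output_table(properties,
                       file.path(config$out_dir, "properties.csv"), config)

  invisible(list(harmonized = harmonized, excluded = split$excluded,
                 properties = properties, ingest_diagnostics = ingest_diag,
                 harmonize_diagnostics = harm_diag))
}

#' Analyze a harmonized database
#'
#' Computes and exports the full set of summary tables: censoring audit and
#' data-amount counts, mother-offspring pairs and partition ratios,
#' equilibrium band counts, boxplot-style group summaries, maternal tissue
#' correlations, and ratio-vs-log Kow trends. When `pfas_wet` is on, PFAS
#' pairs and ratios are additionally computed on the wet-weight basis; all
#' other outputs are untouched by the switch. An empty database yields empty
#' tables with headers.
#'
#' @param config A [pipeline_config()].
#' @param build Optional result of [run_build()]; when omitted, [run_build()]
#'   is executed first.
#' @return Invisibly, a list of all computed tables.
#' @export
run_analyze <- function(config, build = NULL) {
  if (is.null(build)) build <- run_build(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- build$harmonized

  audit <- censoring_summary(db, group_by = c("study_id", "species"))
  amounts <- data_amount_summary(db, keys = c("species", "compound_class",
                                              "tissue"))

  pairs <- pair_mother_offspring(db, policy = config$pairing_policy,
                                 basis = "lipid")
  ratios <- transfer_ratios(pairs)
  if (!is.null(build$properties) && nrow(ratios)) {
    ratios <- merge(ratios,
                    build$properties[, c("compound_id", "log_kow")],
                    by = "compound_id", all.x = TRUE, sort = FALSE)
  } else ratios$log_kow <- numeric(nrow(ratios)) * NA_real_
  bands <- if (nrow(ratios)) {
    b <- table(equilibrium_band(ratios$R))
    data.frame(band = names(b), n = as.integer(b), stringsAsFactors = FALSE)
  } else data.frame(band = character(0), n = integer(0))
  summaries <- ratio_summary(ratios)
  correlations <- tissue_correlations(db, min_pairs = config$min_pairs)
  kow_trends <- ratio_vs_kow(ratios)

  out <- list(censoring_audit = audit, data_amounts = amounts, pairs = pairs,
              ratios = ratios, band_counts = bands,
              ratio_summaries = summaries,
              tissue_correlations = correlations$pairs,
              tissue_correlation_summary = correlations$summary,
              kow_trends = kow_trends)

  if (config$pfas_wet) {
    pfas <- db[db$compound_class == "PFAS", , drop = FALSE]
    pfas_pairs <- pair_mother_offspring(pfas, policy = config$pairing_policy,
                                        basis = "wet")
    pfas_ratios <- transfer_ratios(pfas_pairs)
    out$pfas_wet_pairs <- pfas_pairs
    out$pfas_wet_ratios <- pfas_ratios
    out$pfas_wet_summaries <- ratio_summary(pfas_ratios)
  }

  for (nm in setdiff(names(out), "tissue_correlation_summary")) {
    write_output_table(out[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")), config)
  }
  write_output_table(
    data.frame(statistic = c("median", "min", "max"),
               pearson = unlist(correlations$summary)),
    file.path(config$out_dir, "tissue_correlation_summary.csv"), config)

  invisible(out)
}
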