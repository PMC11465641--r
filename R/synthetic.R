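# Seeded generator of multi-study mother-offspring datasets with known truth.

# Ground-truth tissue lipid fractions (wet basis) and water fractions used by
# the generator; chosen as typical reptile values so the fixture looks like
# field data (lipid-rich fat and yolk, lipid-poor blood and plasma).
.TRUE_LIPID <- c(fat = 0.60, liver = 0.05, whole_blood = 0.005,
                 plasma = 0.006, muscle = 0.02, kidney = 0.04,
                 whole_egg = 0.08, yolk = 0.22)
.TRUE_WATER <- c(whole_egg = 0.667, yolk = 0.50, plasma = 0.92,
                 whole_blood = 0.80, liver = 0.70, muscle = 0.75,
                 kidney = 0.78, fat = 0.10)

default_synthetic_compounds <- function() {
  data.frame(
    compound_id = c("PCB28", "PCB52", "PCB101", "PCB118", "PCB138",
                    "PCB153", "PCB180", "DDEPP", "DDTPP", "HCB",
                    "BDE47", "PFOS"),
    compound_class = c(rep("PCB", 7), rep("OCP", 3), "HFR_BFR", "PFAS"),
    log_kow = c(5.67, 5.84, 6.38, 6.74, 6.83, 6.92, 7.36,
                6.51, 6.91, 5.73, 6.81, 4.49),
    stringsAsFactors = FALSE
  )
}

default_synthetic_studies <- function() {
  list(
    list(study_id = "S1", species = "Malaclemys terrapin", n_mothers = 12L,
         eggs_per_mother = 3L,
         mother_tissues = c("fat", "liver", "whole_blood", "muscle"),
         offspring_matrix = "whole_egg", unit = "µg/g", basis = "wet",
         reports_lipid = TRUE),
    list(study_id = "S2", species = "Enhydris chinensis", n_mothers = 10L,
         eggs_per_mother = 2L,
         mother_tissues = c("liver", "whole_blood", "plasma", "muscle",
                            "kidney", "fat"),
         offspring_matrix = "whole_egg", unit = "ng/g", basis = "wet",
         reports_lipid = FALSE),
    list(study_id = "S3", species = "Chelonia mydas", n_mothers = 15L,
         eggs_per_mother = 3L, mother_tissues = "plasma",
         offspring_matrix = "whole_egg", unit = "ng/g", basis = "dry",
         reports_lipid = TRUE),
    list(study_id = "S4", species = "Caretta caretta", n_mothers = 8L,
         eggs_per_mother = 2L, mother_tissues = "whole_blood",
         offspring_matrix = "yolk", unit = "mg/kg", basis = "wet",
         reports_lipid = FALSE),
    list(study_id = "S5", species = "Alligator mississippiensis",
         n_mothers = 8L, eggs_per_mother = 2L, mother_tissues = "liver",
         offspring_matrix = "yolk", unit = "ppb", basis = "wet",
         reports_lipid = FALSE),
    list(study_id = "S6", species = "Dermochelys coriacea", n_mothers = 6L,
         eggs_per_mother = 2L, mother_tissues = "whole_blood",
         offspring_matrix = "whole_egg", unit = "ng/g", basis = "lipid",
         reports_lipid = FALSE)
  )
}

#' Configuration of the synthetic-data generator
#'
#' Defines a multi-study mother-offspring dataset with known ground truth.
#' Mother concentrations are lognormal on the lipid-normalized scale
#' (`log10 c_mother ~ Normal(mu_m, sigma_m)`, one latent draw per mother and
#' compound, plus a small tissue-level deviation `sigma_t` shared structure
#' that keeps maternal tissues strongly correlated). Offspring follow the
#' transfer model `log10 c_offspring = log10 c_mother + alpha +
#' beta * log_kow + Normal(0, sigma_e)`. Each study declares its own unit and
#' measurement basis, which the generator encodes into the emitted records so
#' that harmonization has to undo them. Censoring places each compound's LOD
#' at the `q_lod` quantile of the record's own concentration distribution, so
#' the expected censored fraction equals `q_lod`; a censored record's LOD is
#' withheld (qualitative censoring) with probability `p_qual`. A clutch is
#' reported as a pooled geometric mean with probability `p_pool` (only when
#' all its eggs are uncensored, mirroring how studies report pooled means of
#' measured values).
#'
#' The default fixture mirrors the shape of the compiled reptile literature:
#' two data-rich flagship studies with many maternal tissues, several
#' whole-egg-only species, heterogeneous units and bases across studies, and
#' roughly 70% censoring split evenly between quantitative and qualitative.
#'
#' @param seed Integer seed; all sampling flows through one stream.
#' @param studies List of per-study descriptors (see
#'   `default_synthetic_studies()` for the shape).
#' @param compounds Data.frame with `compound_id`, `compound_class`,
#'   `log_kow`.
#' @param mu_m,sigma_m Mean and SD of log10 mother concentration (ng/g lipid).
#' @param sigma_t SD of the tissue-level deviation around the mother latent.
#' @param alpha,beta,sigma_e Transfer-model offset, log Kow slope, and
#'   residual SD.
#' @param q_lod LOD quantile in `[0, 1)`; 0 disables censoring.
#' @param p_qual Probability a censored record's LOD is withheld.
#' @param p_pool Probability a fully uncensored clutch is reported pooled.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L,
                             studies = default_synthetic_studies(),
                             compounds = default_synthetic_compounds(),
                             mu_m = 1.5, sigma_m = 0.6, sigma_t = 0.1,
                             alpha = -0.1, beta = 0, sigma_e = 0.3,
                             q_lod = 0.7, p_qual = 0.5, p_pool = 0.2) {
  cfg <- list(seed = as.integer(seed), studies = studies,
              compounds = compounds, mu_m = mu_m, sigma_m = sigma_m,
              sigma_t = sigma_t, alpha = alpha, beta = beta,
              sigma_e = sigma_e, q_lod = q_lod, p_qual = p_qual,
              p_pool = p_pool)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$seed), length(cfg$seed) == 1,
    cfg$sigma_m >= 0, cfg$sigma_t >= 0, cfg$sigma_e >= 0,
    cfg$q_lod >= 0, cfg$q_lod < 1,
    cfg$p_qual >= 0, cfg$p_qual <= 1,
    cfg$p_pool >= 0, cfg$p_pool <= 1,
    nrow(cfg$compounds) >= 1,
    all(c("compound_id", "compound_class", "log_kow") %in% names(cfg$compounds)),
    length(cfg$studies) >= 1
  )
  for (s in cfg$studies) {
    stopifnot(s$n_mothers >= 1, s$eggs_per_mother >= 1,
              s$basis %in% ot_bases(),
              all(s$mother_tissues %in% names(.TRUE_LIPID)),
              s$offspring_matrix %in% names(.TRUE_LIPID),
              !is.na(unit_factor_or_na(s$unit)))
  }
  invisible(cfg)
}

# Encode a true lipid-normalized concentration (ng/g lw) into a study's
# declared unit and basis. Returns NA for NA input.
encode_concentration <- function(lw, tissue, unit, basis) {
  lf <- .TRUE_LIPID[[tissue]]
  x <- switch(basis,
              lipid = lw,
              wet = lw * lf,
              dry = lw * lf / (1 - .TRUE_WATER[[tissue]]))
  x / unit_factor_or_na(unit)
}

#' Generate a synthetic multi-study dataset
#'
#' Draws records under the model of [synthetic_config()] and returns both the
#' observable record table (in each study's declared unit and basis, with
#' censored values blanked exactly as a study would report them) and a truth
#' table holding every latent value. Output is deterministic given
#' `config$seed`; the caller's RNG state is left untouched.
#'
#' @param config A `synthetic_config`.
#' @return List with `records` (canonical study-record table as produced by
#'   ingest), `truth` (data.frame with one row per emitted record:
#'   `study_id`, `subject_id`, `tissue`, `compound_id`, `true_lw`, `lod_lw`,
#'   `censoring`), and `config`.
#' @export
generate_studies <- function(config) {
  validate_synthetic_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  cmp <- config$compounds
  n_max <- sum(vapply(config$studies, function(s)
    s$n_mothers * nrow(cmp) * (length(s$mother_tissues) + s$eggs_per_mother),
    numeric(1)))
  acc <- new.env(parent = emptyenv())
  acc$k <- 0L
  for (f in c("study", "species", "role", "subject", "mother", "tissue",
              "compound", "class", "aggregation", "censoring"))
    assign(f, character(n_max), envir = acc)
  for (f in c("value", "lod", "lf_reported", "true_lw", "lod_lw"))
    assign(f, rep(NA_real_, n_max), envir = acc)
  acc$n_pooled <- integer(n_max)
  emit <- function(study, species, role, subject, mother, tissue, j,
                   true_lw, lod_lw, censoring, value_declared, lod_declared,
                   n_pooled, aggregation, lf_reported) {
    k <- acc$k + 1L
    acc$k <- k
    acc$study[k] <- study; acc$species[k] <- species; acc$role[k] <- role
    acc$subject[k] <- subject; acc$mother[k] <- mother; acc$tissue[k] <- tissue
    acc$compound[k] <- cmp$compound_id[j]; acc$class[k] <- cmp$compound_class[j]
    acc$value[k] <- value_declared; acc$lod[k] <- lod_declared
    acc$n_pooled[k] <- n_pooled; acc$aggregation[k] <- aggregation
    acc$lf_reported[k] <- lf_reported; acc$censoring[k] <- censoring
    acc$true_lw[k] <- true_lw; acc$lod_lw[k] <- lod_lw
  }

  for (s in config$studies) {
    n_m <- s$n_mothers
    n_c <- nrow(cmp)
    latent <- matrix(stats::rnorm(n_m * n_c, config$mu_m, config$sigma_m),
                     n_m, n_c)
    # analytic per-record log10 distributions, used to place LODs
    sd_mother <- sqrt(config$sigma_m^2 + config$sigma_t^2)
    sd_off <- sqrt(config$sigma_m^2 + config$sigma_e^2)
    mu_off <- config$mu_m + config$alpha + config$beta * cmp$log_kow
    lod_mother <- if (config$q_lod > 0)
      10^stats::qnorm(config$q_lod, config$mu_m, sd_mother) else 0
    lod_off <- if (config$q_lod > 0)
      10^stats::qnorm(config$q_lod, mu_off, sd_off) else rep(0, n_c)

    for (m in seq_len(n_m)) {
      mid <- sprintf("%s_m%02d", s$study_id, m)
      for (tis in s$mother_tissues) {
        lw <- 10^(latent[m, ] + stats::rnorm(n_c, 0, config$sigma_t))
        for (j in seq_len(n_c)) {
          censored <- config$q_lod > 0 && lw[j] < lod_mother
          qual <- censored && stats::runif(1) < config$p_qual
          cens <- if (!censored) "uncensored" else
            if (qual) "qual_censored" else "quant_censored"
          emit(s$study_id, s$species, "mother", mid, mid, tis, j,
               true_lw = lw[j], lod_lw = lod_mother, censoring = cens,
               value_declared = if (censored) NA_real_ else
                 encode_concentration(lw[j], tis, s$unit, s$basis),
               lod_declared = if (cens == "quant_censored")
                 encode_concentration(lod_mother, tis, s$unit, s$basis) else NA_real_,
               n_pooled = 1L, aggregation = "individual",
               lf_reported = if (isTRUE(s$reports_lipid))
                 .TRUE_LIPID[[tis]] else NA_real_)
        }
      }
      # eggs
      tis_o <- s$offspring_matrix
      egg_lw <- matrix(NA_real_, s$eggs_per_mother, n_c)
      for (e in seq_len(s$eggs_per_mother)) {
        egg_lw[e, ] <- 10^(latent[m, ] + config$alpha +
                             config$beta * cmp$log_kow +
                             stats::rnorm(n_c, 0, config$sigma_e))
      }
      for (j in seq_len(n_c)) {
        vals <- egg_lw[, j]
        censored <- config$q_lod > 0 & vals < lod_off[j]
        pool <- !any(censored) && s$eggs_per_mother > 1 &&
          stats::runif(1) < config$p_pool
        if (pool) {
          gm <- geometric_mean(vals)
          emit(s$study_id, s$species, "offspring",
               paste0(mid, "_clutch"), mid, tis_o, j,
               true_lw = gm, lod_lw = lod_off[j], censoring = "uncensored",
               value_declared = encode_concentration(gm, tis_o, s$unit, s$basis),
               lod_declared = NA_real_,
               n_pooled = s$eggs_per_mother, aggregation = "geometric_mean",
               lf_reported = if (isTRUE(s$reports_lipid))
                 .TRUE_LIPID[[tis_o]] else NA_real_)
        } else {
          for (e in seq_len(s$eggs_per_mother)) {
            qual <- censored[e] && stats::runif(1) < config$p_qual
            cens <- if (!censored[e]) "uncensored" else
              if (qual) "qual_censored" else "quant_censored"
            emit(s$study_id, s$species, "offspring",
                 sprintf("%s_egg%d", mid, e), mid, tis_o, j,
                 true_lw = vals[e], lod_lw = lod_off[j], censoring = cens,
                 value_declared = if (censored[e]) NA_real_ else
                   encode_concentration(vals[e], tis_o, s$unit, s$basis),
                 lod_declared = if (cens == "quant_censored")
                   encode_concentration(lod_off[j], tis_o, s$unit, s$basis) else NA_real_,
                 n_pooled = 1L, aggregation = "individual",
                 lf_reported = if (isTRUE(s$reports_lipid))
                   .TRUE_LIPID[[tis_o]] else NA_real_)
          }
        }
      }
    }
  }

  k <- acc$k
  records <- data.frame(
    study_id = acc$study[seq_len(k)], species = acc$species[seq_len(k)],
    subject_role = acc$role[seq_len(k)], subject_id = acc$subject[seq_len(k)],
    mother_id = acc$mother[seq_len(k)], tissue = acc$tissue[seq_len(k)],
    compound_raw = acc$compound[seq_len(k)],
    compound_id = acc$compound[seq_len(k)],
    compound_class = acc$class[seq_len(k)],
    value = acc$value[seq_len(k)], unit = NA_character_,
    basis = NA_character_, censoring = acc$censoring[seq_len(k)],
    lod = acc$lod[seq_len(k)], n_pooled = acc$n_pooled[seq_len(k)],
    aggregation = acc$aggregation[seq_len(k)],
    is_sum = FALSE, is_coelution = FALSE, members = NA_character_,
    lipid_fraction_reported = acc$lf_reported[seq_len(k)],
    out_of_calibration = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(
    study_id = acc$study[seq_len(k)], subject_id = acc$subject[seq_len(k)],
    tissue = acc$tissue[seq_len(k)], compound_id = acc$compound[seq_len(k)],
    true_lw = acc$true_lw[seq_len(k)], lod_lw = acc$lod_lw[seq_len(k)],
    censoring = acc$censoring[seq_len(k)], stringsAsFactors = FALSE)
  # fill per-study unit/basis columns
  for (s in config$studies) {
    sel <- records$study_id == s$study_id
    records$unit[sel] <- s$unit
    records$basis[sel] <- s$basis
  }
  rownames(records) <- rownames(truth) <- NULL
  attr(truth, "alpha") <- config$alpha
  attr(truth, "beta") <- config$beta
  list(records = records, truth = truth, config = config)
}

#' Analytic expectations for a synthetic configuration
#'
#' Closed-form expectations against which recovered statistics can be
#' checked: the expected median partition ratio
#' `alpha + beta * mean(log_kow)`, the expected censored fraction (the LOD is
#' placed at the `q_lod` quantile of each record's own lognormal
#' distribution, so the expected fraction is `q_lod` itself), and the
#' expected qualitatively censored share (`q_lod * p_qual`).
#'
#' @param config A `synthetic_config`.
#' @return List with `median_ratio`, `censored_fraction`, `qual_share`,
#'   `quant_share`.
#' @export
expected_statistics <- function(config) {
  validate_synthetic_config(config)
  list(
    median_ratio = config$alpha + config$beta * mean(config$compounds$log_kow),
    censored_fraction = config$q_lod,
    qual_share = config$q_lod * config$p_qual,
    quant_share = config$q_lod * (1 - config$p_qual)
  )
}

#' Ground-truth auxiliary tables for a synthetic configuration
#'
#' `synthetic_lipid_table()` returns literature-style lipid-content entries
#' consistent with the generator's ground truth, with the leatherback
#' (*Dermochelys coriacea*) deliberately absent so the related-species
#' fallback is exercised; `synthetic_relatedness()` maps it to the loggerhead.
#' `synthetic_water_table()` returns tissue water contents for the dry-basis
#' studies, and `synthetic_property_table()` the compound descriptor table
#' (log Kow carried as the estimated value).
#'
#' @param config A `synthetic_config`.
#' @return A data.frame (see each description).
#' @export
synthetic_lipid_table <- function(config) {
  rows <- list()
  for (s in config$studies) {
    if (s$species == "Dermochelys coriacea") next
    # literature tables cover more tissues than any one study reports
    for (t in unique(c(s$mother_tissues, s$offspring_matrix, "whole_egg"))) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = s$species, tissue = t,
        lipid_fraction = .TRUE_LIPID[[t]],
        source = "same_species_literature",
        reference = "synthetic", stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' @rdname synthetic_lipid_table
#' @export
synthetic_water_table <- function(config) {
  rows <- list()
  for (s in config$studies) {
    if (s$basis != "dry") next
    for (t in unique(c(s$mother_tissues, s$offspring_matrix))) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = s$species, tissue = t,
        water_fraction = .TRUE_WATER[[t]],
        reference = "synthetic", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(species = character(0), tissue = character(0),
                      water_fraction = numeric(0), reference = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' @rdname synthetic_lipid_table
#' @export
synthetic_relatedness <- function(config) {
  data.frame(species = "Dermochelys coriacea",
             related_species = "Caretta caretta",
             stringsAsFactors = FALSE)
}

#' @rdname synthetic_lipid_table
#' @export
synthetic_property_table <- function(config) {
  cmp <- config$compounds
  data.frame(
    compound_id = cmp$compound_id,
    log_kow_experimental = NA_real_,
    log_kow_estimated = cmp$log_kow,
    molecular_weight = NA_real_, complexity = NA_real_,
    heavy_atom_count = NA_real_, h_bond_donors = NA_real_,
    h_bond_acceptors = NA_real_, tpsa = NA_real_,
    formal_charge = NA_real_, rotatable_bonds = NA_real_,
    stringsAsFactors = FALSE
  )
}
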