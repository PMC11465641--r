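test_that("unit conversion applies exact rational factors", {
  expect_equal(convert_unit(1, "µg/g"), 1000)
  expect_equal(convert_unit(0.5, "mg/kg"), 500)
  expect_equal(convert_unit(2, "ppb"), 2)
  expect_equal(convert_unit(3, "ug/kg"), 3)
  expect_equal(convert_unit(4, "pg/g"), 0.004)
  expect_error(convert_unit(1, "oz"), "oz")
})

test_that("unit conversion matches an SI-prefix oracle on random values", {
  set.seed(3)
  units <- c("ng/g", "ug/g", "ug/kg", "mg/kg", "ng/kg", "pg/g",
             "ppm", "ppb", "ppt")
  values <- rlnorm(1000, 0, 3)
  us <- sample(units, 1000, replace = TRUE)
  got <- mapply(convert_unit, values, us)
  want <- mapply(oracle_to_ng_g, values, us)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("dry-to-wet conversion scales by the solid mass fraction", {
  expect_equal(dry_to_wet(100, 0.667), 33.3)
  expect_equal(dry_to_wet(42, 0), 42)
  expect_equal(dry_to_wet(0, 0.5), 0)
  expect_error(dry_to_wet(1, 1), "water_fraction")
})

test_that("lipid normalization divides by the lipid fraction", {
  expect_equal(lipid_normalize(50, 0.05), 1000)
  expect_equal(lipid_normalize(7, 1), 7)
  expect_equal(lipid_normalize(0, 0.3), 0)
  expect_error(lipid_normalize(1, 0), "lipid_fraction")
  expect_error(lipid_normalize(1, 1.2), "lipid_fraction")
})

test_that("lipid normalization round-trips within 1e-9 relative tolerance", {
  set.seed(5)
  conc <- rlnorm(200, 2, 2)
  lf <- runif(200, 0.001, 1)
  back <- lipid_normalize(conc, lf) * lf
  expect_true(all(abs(back - conc) / conc < 1e-9))
})

test_that("lipid fraction lookup follows the strict fallback chain", {
  tab <- data.frame(species = c("Chelonia mydas", "Caretta caretta"),
                    tissue = c("whole_egg", "whole_egg"),
                    lipid_fraction = c(0.06, 0.07),
                    stringsAsFactors = FALSE)
  rel <- data.frame(species = "Dermochelys coriacea",
                    related_species = "Caretta caretta",
                    stringsAsFactors = FALSE)

  r <- lookup_lipid_fraction("Chelonia mydas", "whole_egg",
                             lipid_fraction_reported = 0.04, lipid_table = tab)
  expect_equal(r, list(lipid_fraction = 0.04, source = "study_reported"))

  r <- lookup_lipid_fraction("Chelonia mydas", "whole_egg", NA, tab)
  expect_equal(r, list(lipid_fraction = 0.06, source = "same_species_literature"))

  r <- lookup_lipid_fraction("Dermochelys coriacea", "whole_egg", NA, tab, rel)
  expect_equal(r, list(lipid_fraction = 0.07,
                       source = "related_species_literature"))

  r <- lookup_lipid_fraction("Nerodia sipedon", "liver", NA, tab, rel)
  expect_equal(r$source, "none")
  expect_true(is.na(r$lipid_fraction))
})

test_that("a dry-weight egg record harmonizes through the composed map", {
  rec <- make_record(species = "Chelonia mydas", tissue = "whole_egg",
                     value = 0.2, unit = "µg/g", basis = "dry",
                     lipid_fraction_reported = 0.08)
  wt <- data.frame(species = "Chelonia mydas", tissue = "whole_egg",
                   water_fraction = 0.667, stringsAsFactors = FALSE)
  h <- harmonize_record(rec, water_table = wt)
  expect_equal(h$conc_ng_g_ww, 66.6)
  expect_equal(h$conc_ng_g_lw, 832.5)
  expect_equal(h$lipid_source, "study_reported")
  # trace shows dry->wet strictly before lipid normalization
  steps <- strsplit(h$conversion_trace, ";")[[1]]
  expect_lt(grep("dry_to_wet", steps), grep("lipid_norm", steps))
})

test_that("the LOD is transformed by the identical map and censoring survives", {
  rec <- make_record(value = NA_real_, lod = 1, unit = "ng/g", basis = "wet",
                     censoring = "quant_censored",
                     lipid_fraction_reported = 0.05)
  h <- harmonize_record(rec)
  expect_equal(h$lod_ng_g_lw, 20)
  expect_equal(h$censoring, "quant_censored")
  expect_true(is.na(h$conc_ng_g_lw))

  qual <- make_record(value = NA_real_, lod = NA_real_,
                      censoring = "qual_censored")
  hq <- harmonize_record(qual)
  expect_equal(hq$censoring, "qual_censored")
  expect_true(all(is.na(c(hq$conc_ng_g_ww, hq$conc_ng_g_lw,
                          hq$lod_ng_g_ww, hq$lod_ng_g_lw))))
})

test_that("harmonized concentration is strictly increasing in the input value", {
  vals <- sort(rlnorm(50, 0, 2))
  recs <- do.call(rbind, lapply(vals, function(v)
    make_record(value = v, unit = "µg/kg", basis = "wet",
                lipid_fraction_reported = 0.07)))
  h <- harmonize_records(recs)
  expect_true(all(diff(h$conc_ng_g_ww) > 0))
  expect_true(all(diff(h$conc_ng_g_lw) > 0))
})

test_that("censoring statuses are conserved as a multiset through harmonization", {
  cfg <- synthetic_config(seed = 202)
  sim <- generate_studies(cfg)
  h <- harmonize_records(sim$records,
                         lipid_table = synthetic_lipid_table(cfg),
                         water_table = synthetic_water_table(cfg),
                         relatedness = synthetic_relatedness(cfg))
  expect_equal(table(h$censoring), table(sim$records$censoring))
})

test_that("records without any lipid source stay wet-weight only with a diagnostic", {
  rec <- make_record(species = "Nerodia sipedon", tissue = "liver",
                     value = 10, unit = "ng/g", basis = "wet")
  h <- harmonize_record(rec)
  expect_equal(h$conc_ng_g_ww, 10)
  expect_true(is.na(h$conc_ng_g_lw))
  expect_match(attr(h, "diagnostics")$message, "lipid fraction")
})
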