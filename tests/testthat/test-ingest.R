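test_that("study tables are read row-per-record with parse diagnostics, not silent drops", {
  df <- data.frame(
    study_id = "S1", species = "Chelonia mydas", subject_role = "mother",
    subject_id = c("m1", "m2", "m3"), tissue = "plasma",
    compound_raw = c("PCB-153", "p,p'-DDE", "HCB"),
    value = c(1.2, 0.4, 7), unit = "ng/g", basis = "wet",
    stringsAsFactors = FALSE)
  p <- write_raw_fixture(df, withr::local_tempfile(fileext = ".csv"))
  rec <- read_study_table(p)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$censoring, rep("uncensored", 3))
  expect_equal(nrow(ingest_diagnostics(rec)), 0)

  # censoring flag with empty LOD column -> qualitatively censored
  df$censoring <- c("", "<LOD", "")
  df$value <- c("1.2", "", "7")
  df$lod <- c("", "", "")
  p2 <- write_raw_fixture(df, withr::local_tempfile(fileext = ".csv"))
  rec2 <- read_study_table(p2)
  expect_equal(rec2$censoring[2], "qual_censored")
  expect_true(is.na(rec2$value[2]))

  # unsupported unit -> row-level diagnostic, record excluded
  df$unit <- c("ng/g", "ng/g", "oz")
  p3 <- write_raw_fixture(df, withr::local_tempfile(fileext = ".csv"))
  rec3 <- read_study_table(p3)
  expect_equal(nrow(rec3), 2)
  d <- ingest_diagnostics(rec3)
  expect_equal(d$field, "unit")
  expect_equal(d$row, 3L)

  # missing mandatory column -> hard error
  expect_error(as_study_records(df[, setdiff(names(df), "tissue")]),
               "mandatory")
})

test_that("column maps and tissue aliases resolve study-specific layouts", {
  df <- data.frame(pub = "S9", sp = "Caretta caretta", who = "offspring",
                   id = "e1", mum = "m1", organ = "egg (no shell)",
                   chem = "HCB", conc = 2, u = "ppm", b = "wet",
                   stringsAsFactors = FALSE)
  rec <- as_study_records(df, column_map = c(
    study_id = "pub", species = "sp", subject_role = "who", subject_id = "id",
    mother_id = "mum", tissue = "organ", compound_raw = "chem",
    value = "conc", unit = "u", basis = "b"),
    tissue_aliases = c("egg (no shell)" = "whole_egg"))
  expect_equal(rec$tissue, "whole_egg")
  expect_equal(rec$mother_id, "m1")
})

test_that("compound names resolve case- and punctuation-insensitively and idempotently", {
  ids <- canonicalize_compound(c("p,p'-DDE", "4,4'-DDE"))
  expect_equal(ids[1], ids[2])
  expect_false(any(attr(ids, "unresolved")))

  expect_equal(as.vector(canonicalize_compound("PCB-153")), "PCB153")

  unk <- canonicalize_compound("unknowncompoundX")
  expect_true(attr(unk, "unresolved"))

  expect_error(canonicalize_compound(""), "empty")

  # idempotence: canonical ids resolve to themselves, resolved or not
  raw <- c("PCB-153", "p,p'-DDE", "unknowncompoundX", "BDE 47")
  once <- as.vector(canonicalize_compound(raw))
  twice <- as.vector(canonicalize_compound(once))
  expect_equal(twice, once)
})

test_that("exclusion rules partition records with reason codes", {
  recs <- make_records(
    make_record(subject_id = "m1", tissue = "bile", compound_id = "PCB153"),
    make_record(subject_id = "m1", tissue = "liver", compound_id = "DDTPP",
                compound_raw = "DDT"),
    make_record(subject_id = "m1", tissue = "liver", compound_id = "DDEPP",
                compound_raw = "DDE"),
    make_record(subject_id = "m1", tissue = "liver", compound_id = "DDDPP",
                compound_raw = "DDD"),
    make_record(subject_id = "m1", tissue = "liver", compound_id = "sumDDT",
                is_sum = TRUE, members = "DDTPP|DDEPP|DDDPP"),
    make_record(subject_id = "m1", tissue = "liver", compound_id = "sumPCB",
                is_sum = TRUE, members = "PCB999|DDEPP"),
    make_record(subject_id = "m2", tissue = "liver", compound_id = "TCDD",
                out_of_calibration = TRUE))
  out <- apply_exclusion_rules(recs)
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(recs))
  expect_setequal(out$excluded$reason, c("bile", "duplicate_sum", "calibration"))
  expect_equal(out$excluded$compound_id[out$excluded$reason == "duplicate_sum"],
               "sumDDT")
  # a sum contributing an otherwise-unreported compound is kept
  expect_true("sumPCB" %in% out$kept$compound_id)
})

test_that("exclusion is a conservation-preserving partition on random fixtures", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    recs <- do.call(rbind, lapply(seq_len(n), function(k)
      make_record(subject_id = paste0("m", k),
                  tissue = sample(ot_tissues(), 1),
                  compound_id = sample(c("A", "B", "C"), 1),
                  out_of_calibration = runif(1) < 0.1)))
    out <- apply_exclusion_rules(recs)
    expect_equal(nrow(out$kept) + nrow(out$excluded), n)
    key <- function(d) paste(d$subject_id, d$tissue, d$compound_id)
    expect_setequal(c(key(out$kept), key(out$excluded)), key(recs))
    expect_length(intersect(rownames(out$kept), character(0)), 0)
  }
})

test_that("group aggregation prefers the geometric mean with arithmetic fallback", {
  ind <- select_aggregation(c(10, 1000), reported = "individual")
  expect_equal(ind$value, c(10, 1000))
  expect_equal(ind$aggregation, "individual")

  gm <- select_aggregation(c(10, 1000), reported = "group")
  expect_equal(gm$value, 100)
  expect_equal(gm$aggregation, "geometric_mean")
  expect_equal(gm$n_pooled, 2L)

  am <- select_aggregation(c(0, 10), reported = "group")
  expect_equal(am$value, 5)
  expect_equal(am$aggregation, "arithmetic_mean")
  expect_false(is.na(am$diagnostic))
})

test_that("geometric mean never exceeds arithmetic mean on positive inputs", {
  set.seed(7)
  for (i in 1:50) {
    x <- rlnorm(sample(2:12, 1), meanlog = runif(1, -2, 4), sdlog = runif(1, 0, 2))
    gm <- select_aggregation(x, reported = "group")
    expect_equal(gm$aggregation, "geometric_mean")
    expect_lte(gm$value, mean(x) + 1e-12)
  }
})
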