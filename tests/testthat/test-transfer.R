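test_that("pairing links offspring to mothers under both policies", {
  db <- rbind(
    make_harmonized("mother", "m1", "liver", "PCB153", conc_lw = 100,
                    mother_id = "m1"),
    make_harmonized("offspring", "e1", "whole_egg", "PCB153", conc_lw = 10,
                    mother_id = "m1"),
    make_harmonized("offspring", "e2", "whole_egg", "PCB153", conc_lw = 100,
                    mother_id = "m1"),
    make_harmonized("offspring", "e3", "whole_egg", "PCB153", conc_lw = 1000,
                    mother_id = "m1"))

  per_egg <- pair_mother_offspring(db, policy = "per_egg")
  expect_equal(nrow(per_egg), 3)
  expect_setequal(per_egg$offspring_id, c("e1", "e2", "e3"))

  clutch <- pair_mother_offspring(db, policy = "clutch_mean")
  expect_equal(nrow(clutch), 1)
  expect_equal(clutch$c_offspring, (10 * 100 * 1000)^(1 / 3))

  # compound measured only in eggs yields no pair
  only_eggs <- db[db$subject_role == "offspring", ]
  only_eggs$compound_id <- "HCB"
  expect_equal(nrow(pair_mother_offspring(rbind(db[1, ], only_eggs))), 0)

  # orphan offspring reported, not paired
  orphan <- make_harmonized("offspring", "e9", "whole_egg", "PCB153",
                            conc_lw = 5, mother_id = "m99")
  p <- pair_mother_offspring(rbind(db, orphan))
  expect_equal(nrow(p), 3)
  expect_equal(attr(p, "diagnostics")$subject_id, "e9")
})

test_that("partition ratios are log10 offspring over mother for uncensored pairs", {
  db <- rbind(
    make_harmonized("mother", "m1", "liver", c("A", "B", "C"),
                    conc_lw = c(100, 100, 500), mother_id = "m1"),
    make_harmonized("offspring", "e1", "whole_egg", c("A", "B", "C"),
                    conc_lw = c(100, 1000, 50), mother_id = "m1"))
  r <- transfer_ratios(pair_mother_offspring(db))
  r <- r[order(r$compound_id), ]
  expect_equal(r$R, c(0, 1, -1))

  # censored side -> skipped with reason
  dbc <- db
  dbc$censoring[dbc$subject_role == "offspring" & dbc$compound_id == "A"] <-
    "quant_censored"
  rc <- transfer_ratios(pair_mother_offspring(dbc))
  expect_equal(nrow(rc), 2)
  expect_equal(attr(rc, "skipped")$reason, "censored_offspring")

  # zero concentration -> skipped
  dbz <- db
  dbz$conc_ng_g_lw[dbz$compound_id == "A" & dbz$subject_role == "mother"] <- 0
  rz <- transfer_ratios(pair_mother_offspring(dbz))
  expect_true("nonpositive_concentration" %in% attr(rz, "skipped")$reason)
})

test_that("ratios are antisymmetric and invariant to common scale factors", {
  set.seed(13)
  cm <- rlnorm(40, 2, 1)
  co <- rlnorm(40, 2, 1)
  mk <- function(m, o) {
    db <- rbind(
      make_harmonized("mother", sprintf("m%d", seq_along(m)), "liver",
                      "PCB153", conc_lw = m,
                      mother_id = sprintf("m%d", seq_along(m))),
      make_harmonized("offspring", sprintf("e%d", seq_along(o)), "whole_egg",
                      "PCB153", conc_lw = o,
                      mother_id = sprintf("m%d", seq_along(o))))
    transfer_ratios(pair_mother_offspring(db))$R
  }
  expect_equal(mk(cm, co), -mk(co, cm))
  expect_equal(mk(cm, co), mk(cm * 1000, co * 1000))
})

test_that("the ten-fold equilibrium band is closed at its boundary", {
  expect_equal(equilibrium_band(c(0.3, 1.0, -1.0, 1.0000001, -1.7)),
               c("within_10fold", "within_10fold", "within_10fold",
                 "above", "below"))
  expect_error(equilibrium_band(NA_real_))
})

test_that("ratio group summaries follow the 1.5 IQR whisker convention", {
  r <- data.frame(species = "s", mother_tissue = "liver",
                  compound_class = "PCB", R = c(-1, 0, 1),
                  stringsAsFactors = FALSE)
  s <- ratio_summary(r)
  expect_equal(s$median, 0)
  expect_equal(s$iqr, 1)  # type-7 quartiles of {-1,0,1} are -0.5 and 0.5
  expect_equal(s$n_outliers, 0)

  single <- ratio_summary(r[2, , drop = FALSE])
  expect_equal(c(single$median, single$q1, single$q3), c(0, 0, 0))
})

test_that("ratio summaries equal brute-force order statistics on random groups", {
  set.seed(31)
  for (i in 1:100) {
    x <- rnorm(sample(3:40, 1))
    r <- data.frame(species = "s", mother_tissue = "t", compound_class = "c",
                    R = x, stringsAsFactors = FALSE)
    s <- ratio_summary(r)
    q1 <- oracle_quantile7(x, 0.25)
    q3 <- oracle_quantile7(x, 0.75)
    expect_equal(s$median, oracle_quantile7(x, 0.5))
    expect_equal(s$q1, q1)
    expect_equal(s$q3, q3)
    iqr <- q3 - q1
    inside <- x[x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr]
    expect_equal(s$whisker_lo, min(inside))
    expect_equal(s$whisker_hi, max(inside))
    expect_equal(s$n_outliers, sum(x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr))
  }
})

test_that("tissue correlations use co-measured uncensored observations", {
  # tissue B exactly 2x tissue A -> perfect correlation on the log scale
  n <- 30
  ca <- rlnorm(n, 2, 1)
  db <- rbind(
    make_harmonized("mother", sprintf("m%d", 1:n), "liver", "PCB153",
                    conc_lw = ca, mother_id = sprintf("m%d", 1:n)),
    make_harmonized("mother", sprintf("m%d", 1:n), "muscle", "PCB153",
                    conc_lw = 2 * ca, mother_id = sprintf("m%d", 1:n)))
  tc <- tissue_correlations(db, min_pairs = 10)
  expect_equal(tc$pairs$pearson, 1)
  expect_equal(tc$pairs$spearman, 1)
  expect_equal(tc$summary$median, 1)

  # independent tissues: correlation near zero
  set.seed(41)
  n <- 500
  db2 <- rbind(
    make_harmonized("mother", sprintf("m%d", 1:n), "liver", "PCB153",
                    conc_lw = rlnorm(n, 2, 1), mother_id = sprintf("m%d", 1:n)),
    make_harmonized("mother", sprintf("m%d", 1:n), "muscle", "PCB153",
                    conc_lw = rlnorm(n, 2, 1), mother_id = sprintf("m%d", 1:n)))
  tc2 <- tissue_correlations(db2, min_pairs = 10)
  expect_lt(abs(tc2$pairs$pearson), 0.1)

  # too few shared observations -> entry absent
  tc3 <- tissue_correlations(db, min_pairs = 31)
  expect_equal(nrow(tc3$pairs), 0)
  expect_true(is.na(tc3$summary$median))
})

test_that("ratio-vs-Kow trends recover noiseless and null relations", {
  kow <- seq(5, 8, length.out = 30)
  r <- data.frame(species = "s", mother_tissue = "liver",
                  compound_class = "PCB", R = -0.2 * kow + 1, log_kow = kow,
                  stringsAsFactors = FALSE)
  fit <- ratio_vs_kow(r)
  expect_equal(fit$slope, -0.2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$spearman, -1)
  expect_false(fit$low_n)

  set.seed(51)
  r2 <- r
  r2$R <- rnorm(30, 0, 0.3)
  r2 <- r2[rep(1:30, length.out = 200), ]
  r2$R <- rnorm(200, 0, 0.3)
  fit2 <- ratio_vs_kow(r2)
  expect_lt(abs(fit2$slope), 2 * fit2$slope_se + 1e-12)

  r3 <- r
  r3$log_kow <- 6.5
  fit3 <- ratio_vs_kow(r3)
  expect_true(fit3$undefined_slope)
  expect_true(is.na(fit3$slope))

  r4 <- r[1:3, ]
  expect_true(ratio_vs_kow(r4)$low_n)
})
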