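test_that("drift correction is the identity on a constant QC trend", {
  s <- tiny_samples()
  m <- matrix(rep(c(100, 200), each = 16), nrow = 2, byrow = TRUE)
  m[, 6] <- m[, 9] <- m[, 12] <- c(50, 80)  # constant across the 3 QC columns
  ft <- tiny_table(m, s)
  corr <- correct_drift(ft, s, window = 8)
  expect_equal(unclass(corr), unclass(ft), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(corr, "scale_tag"), "corrected")
})

test_that("noise-free linear drift is removed exactly on QC injections", {
  cfg <- sim_config(n_features = 10, residual_sd = 0, subject_sd = 0,
                    technical_sd_qc = 0, rhythm_amplitude_range = c(0, 0),
                    drift_slope_range = c(0.3, 0.3), lod_quantile = 0,
                    class_mix = c(null = 1), seed = 12)
  ds <- generate_dataset(cfg)
  corr <- correct_drift(ds$table, ds$samples, window = 8)
  iq <- which(ds$samples$sample_type == "qc_pool")
  qc <- unclass(corr)[, iq, drop = FALSE]
  rel_spread <- apply(qc, 1, function(x) (max(x) - min(x)) / median(x))
  expect_true(all(rel_spread < 1e-6))
})

test_that("features without QC support pass through flagged; no QC errors", {
  s <- tiny_samples()
  m <- matrix(runif(2 * 16, 50, 150), nrow = 2)
  ft0 <- tiny_table(m, s)
  m[1, c(6, 9, 12)] <- NA  # feature F01 missing in every QC injection
  ft <- tiny_table(m, s)
  corr <- correct_drift(ft, s)
  expect_identical(attr(corr, "passthrough"), "F01")
  expect_equal(unclass(corr)[1, ], unclass(ft)[1, ])

  s2 <- s[s$sample_type != "qc_pool", ]
  ft2 <- tiny_table(matrix(1, 1, nrow(s2)), s2)
  expect_error(correct_drift(ft2, s2), "no QC pool injections")
})

test_that("QC metrics match their closed forms on handcrafted data", {
  s <- tiny_samples()
  m <- matrix(NA_real_, nrow = 1, ncol = 16)
  m[, c(6, 9, 12)] <- c(90, 100, 110)                # QC pool
  m[, c(7, 8, 10, 11)] <- c(60, 100, 140, 100)       # study, sd = 33.0
  m[, 1:4]   <- c(1.0, 0.5, 0.2, 0.1) * 1000         # dilution, proportional
  m[, 13:16] <- c(1.0, 0.5, 0.2, 0.1) * 1000
  m[, 5] <- 0                                        # blank
  ft <- tiny_table(m, s, scale = "corrected")
  rep_df <- compute_feature_qc(ft, s)
  expect_equal(rep_df$rsd_qc_pct, 10.0)              # sd 10, mean 100
  expect_equal(rep_df$dilution_r2, 1.0)
  expect_equal(rep_df$d_ratio_pct, 100 * 10 / sd(c(60, 100, 140, 100)))
  expect_false(rep_df$blank_detected)
  expect_equal(rep_df$missing_fraction, 0)
  expect_true(rep_df$keep)

  # direct d-ratio example: sd(QC) = 10, sd(study) = 40 -> 25%
  m2 <- m
  m2[, c(7, 8, 10, 11)] <- 100 + 40 * scale(c(1, 2, 3, 4))[, 1]  # sd = 40
  ft2 <- tiny_table(m2, s, scale = "corrected")
  rep2 <- compute_feature_qc(ft2, s)
  expect_equal(rep2$d_ratio_pct, 25.0)
})

test_that("undefined metrics degrade to NA and obey the policy", {
  s <- tiny_samples()
  m <- matrix(NA_real_, nrow = 2, ncol = 16)
  m[, c(6, 9, 12)] <- 100        # constant QC, no missing
  m[, c(7, 8, 10, 11)] <- 100    # constant study -> sd 0 -> d-ratio undefined
  m[1, 1:4] <- NA                # dilution fully missing for F01
  m[1, 13:16] <- NA
  m[2, c(1:4, 13:16)] <- c(1, .5, .2, .1, 1, .5, .2, .1) * 500
  m[, 5] <- 0
  ft <- tiny_table(m, s, scale = "corrected")
  rep_df <- compute_feature_qc(ft, s)
  expect_true(is.na(rep_df$dilution_r2[1]))
  expect_true(all(is.na(rep_df$d_ratio_pct)))
  expect_identical(filter_features(rep_df), character(0))  # drop policy
  kept <- filter_features(rep_df, policy_undefined = "keep")
  expect_identical(kept, c("F01", "F02"))
})

test_that("the four-criterion filter keeps exactly the clean feature", {
  # fixture: six violators (one per criterion incl. both missingness-ish
  # paths) plus one clean feature
  s <- tiny_samples()
  base <- matrix(NA_real_, nrow = 7, ncol = 16,
                 dimnames = list(c("clean", "in_blank", "high_rsd", "bad_r2",
                                   "high_d", "too_missing", "all_zero"), NULL))
  qc_cols <- c(6, 9, 12); st_cols <- c(7, 8, 10, 11)
  dil_cols <- c(1:4, 13:16); frac <- c(1, .5, .2, .1)
  for (f in 1:7) {
    base[f, qc_cols] <- c(95, 100, 105)
    base[f, st_cols] <- c(40, 90, 150, 120)
    base[f, dil_cols] <- rep(frac, 2) * 800
    base[f, 5] <- 0
  }
  base["in_blank", 5] <- 50                       # > 5% of QC mean
  base["high_rsd", qc_cols] <- c(60, 100, 140)    # RSD 40%
  base["bad_r2", dil_cols] <- c(500, 500, 500, 500, 500, 500, 500, 500)
  base["high_d", st_cols] <- c(98, 100, 102, 100) # tight study spread
  base["too_missing", st_cols] <- c(NA, NA, 150, 120)  # 50% missing
  base["all_zero", st_cols] <- 0                  # 100% zero
  ft <- tiny_table(base, s, scale = "corrected")
  ft <- feature_table(`rownames<-`(unclass(ft), rownames(base)), "corrected")
  rep_df <- compute_feature_qc(ft, s)
  expect_identical(filter_features(rep_df), "clean")
  expect_identical(rep_df$feature_id[rep_df$keep], "clean")

  # vacuous thresholds keep everything (blank detection is part of the
  # report, so the loose report must be recomputed with the loose ratio)
  loose <- filter_thresholds(rsd_max_pct = Inf, r2_min = 0,
                             d_ratio_max_pct = Inf, missing_max_fraction = 1,
                             blank_ratio_max = Inf)
  rep_loose <- compute_feature_qc(ft, s, loose)
  expect_length(filter_features(rep_loose, loose, policy_undefined = "keep"), 7)
})

test_that("boundary values survive the strict greater-than wording", {
  s <- tiny_samples()
  m <- matrix(NA_real_, nrow = 1, ncol = 16)
  # QC values with RSD exactly 25%: mean 100, sd 25; study spread wide
  # enough that the D-ratio criterion is comfortably met
  m[, c(6, 9, 12)] <- 100 + 25 * scale(c(1, 2, 3))[, 1]
  m[, c(7, 8, 10, 11)] <- c(10, 60, 150, 250)
  m[, c(1:4, 13:16)] <- rep(c(1, .5, .2, .1), 2) * 800
  m[, 5] <- 0
  ft <- tiny_table(m, s, scale = "corrected")
  rep_df <- compute_feature_qc(ft, s)
  expect_equal(rep_df$rsd_qc_pct, 25.0)
  expect_identical(filter_features(rep_df), "F01")
})

test_that("subject filter applies the strict 30% missing-or-zero rule", {
  ds <- generate_dataset(sim_config(n_features = 10, n_subjects = 4,
                                    lod_quantile = 0, seed = 6))
  s <- ds$samples
  vals <- unclass(ds$table)
  i_s1 <- which(s$sample_type == "study" & s$subject_id == "S01")
  i_s2 <- which(s$sample_type == "study" & s$subject_id == "S02")
  # S01: exactly 30% of its cells zeroed -> kept (strictly more is excluded)
  n1 <- length(i_s1) * 10
  cells <- arrayInd(seq_len(round(0.3 * n1)), c(10, length(i_s1)))
  vals[cbind(cells[, 1], i_s1[cells[, 2]])] <- 0
  # S02: half of its cells missing -> dropped
  cells2 <- arrayInd(seq_len(round(0.5 * length(i_s2) * 10)), c(10, length(i_s2)))
  vals[cbind(cells2[, 1], i_s2[cells2[, 2]])] <- NA
  ft <- feature_table(vals, "raw")
  kept <- filter_subjects(ft, s)
  expect_true("S01" %in% kept)
  expect_false("S02" %in% kept)
  expect_true(all(c("S03", "S04") %in% kept))
  # fewer than 3 kept subjects errors
  vals[, c(i_s1, i_s2)] <- NA
  expect_error(filter_subjects(feature_table(vals, "raw"), s), "fewer than 3")
})

test_that("one-fifth LOD imputation fills missing and zero study values", {
  s <- tiny_samples()
  m <- matrix(NA_real_, nrow = 2, ncol = 16)
  m[1, c(7, 8, 10, 11)] <- c(10, NA, 50, 0)
  m[2, c(7, 8, 10, 11)] <- c(5, 6, 7, 8)
  m[, c(6, 9, 12)] <- 100; m[, c(1:4, 13:16)] <- 100; m[, 5] <- 0
  ft <- tiny_table(m, s)
  imp <- impute_lod(ft, s)
  expect_equal(unclass(imp)[1, c(7, 8, 10, 11)],
               c(s1 = 10, s2 = 2, s3 = 50, s4 = 2))
  expect_equal(unclass(imp)[2, c(7, 8, 10, 11)], c(s1 = 5, s2 = 6, s3 = 7, s4 = 8))
  expect_equal(attr(imp, "n_replaced"), 2L)
  # QC/blank/dilution untouched
  expect_equal(unclass(imp)[, 5], unclass(ft)[, 5])

  m[1, c(7, 8, 10, 11)] <- c(0, 0, NA, 0)
  expect_error(impute_lod(tiny_table(m, s), s), "F01.*no positive study value")
})

test_that("imputed fraction tracks the LOD quantile across seeds", {
  fr <- vapply(1:10, function(sd_) {
    d <- generate_dataset(sim_config(n_features = 40, seed = sd_))
    imp <- impute_lod(d$table, d$samples)
    n_study <- sum(d$samples$sample_type == "study")
    attr(imp, "n_replaced") / (nrow(d$table) * n_study)
  }, numeric(1))
  expect_true(all(fr >= 0.03 & fr <= 0.09))
})

test_that("log transform hits study/QC/dilution and excludes blanks", {
  s <- tiny_samples()
  m <- matrix(100, nrow = 1, ncol = 16)
  m[, c(7, 8)] <- c(100, 1)
  m[, 5] <- 7  # blank: excluded, not an error even though it would log fine
  ft <- tiny_table(m, s)
  lg <- log_transform(ft, s)
  expect_equal(unclass(lg)[1, "s1"], 2)
  expect_equal(unclass(lg)[1, "s2"], 0)
  expect_true(is.na(unclass(lg)[1, "b1"]))
  expect_equal(10^unclass(lg)[1, "q1"], 100, tolerance = 1e-12)

  m[, 7] <- 0
  expect_error(log_transform(tiny_table(m, s), s), "non-positive value.*s1")
})

test_that("drift correction improves QC precision and preserves structure", {
  ds <- generate_dataset(sim_config(n_features = 120,
                                    drift_slope_range = c(0.25, 0.35),
                                    seed = 17))
  corr <- correct_drift(ds$table, ds$samples)
  iq <- which(ds$samples$sample_type == "qc_pool")
  rsd <- function(tab) apply(unclass(tab)[, iq, drop = FALSE], 1, function(x)
    sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE))
  expect_gte(mean(rsd(corr) <= rsd(ds$table)), 0.95)
  # sign/zero pattern unchanged
  expect_identical(is.na(unclass(corr)), is.na(unclass(ds$table)))
  expect_identical(unclass(corr) == 0, unclass(ds$table) == 0)
  # invariant to feature relabeling
  shuffled <- unclass(ds$table)[rev(seq_len(nrow(ds$table))), , drop = FALSE]
  corr2 <- correct_drift(feature_table(shuffled, "raw"), ds$samples)
  expect_equal(unclass(corr2)[rev(seq_len(nrow(corr2))), ], unclass(corr),
               ignore_attr = TRUE)
})
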