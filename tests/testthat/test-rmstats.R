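make_log_table <- function(n_features = 4, seed = 1, ...) {
  ds <- generate_dataset(sim_config(n_features = n_features, seed = seed, ...))
  imp <- impute_lod(ds$table, ds$samples)
  list(table = log_transform(imp, ds$samples), samples = ds$samples,
       truth = ds$truth)
}

test_that("z-normalization satisfies its defining identities", {
  d <- make_log_table(n_features = 6, seed = 3)
  z <- z_normalize(d$table, d$samples)
  expect_equal(attr(z, "scale_tag"), "zscore")
  st <- d$samples$sample_type == "study"
  subj <- d$samples$subject_id[st]
  zz <- unclass(z)[, st, drop = FALSE]
  for (sb in unique(subj)) {
    blk <- zz[, subj == sb, drop = FALSE]
    expect_true(all(abs(rowMeans(blk)) < 1e-12))
    expect_true(all(abs(apply(blk, 1, sd) - 1) < 1e-12))
  }
  # non-study injections carry no z-scale
  expect_true(all(is.na(unclass(z)[, !st])))

  # {1, 2, 3} -> {-1, 0, 1}: check on a tiny handcrafted subject
  s <- tiny_samples()
  s$timepoint[c(7, 8, 10)] <- c("t1", "t2", "t3")
  s$condition[c(7, 8, 10)] <- "control"
  s$subject_id[10] <- "A"
  m <- matrix(NA_real_, 1, 16); m[, c(7, 8, 10)] <- log10(c(10, 100, 1000))
  m[, c(1:6, 9, 11:16)] <- 1
  lt <- tiny_table(m, s, scale = "raw")
  lt <- feature_table(unclass(lt), "log10")
  zt <- suppressWarnings(z_normalize(lt, s))
  expect_equal(unname(unclass(zt)[1, c(7, 8, 10)]), c(-1, 0, 1))
})

test_that("constant subject values yield missing z-scores with a warning", {
  d <- make_log_table(n_features = 2, seed = 5)
  vals <- unclass(d$table)
  st <- d$samples$sample_type == "study"
  i_a <- which(st & d$samples$subject_id == "S01")
  vals[1, i_a] <- 3  # zero spread for (S01, feature 1)
  lt <- feature_table(vals, "log10")
  expect_warning(z <- z_normalize(lt, d$samples), "zero spread")
  expect_true(all(is.na(unclass(z)[1, i_a])))
  expect_false(anyNA(unclass(z)[2, i_a]))
})

test_that("ANOVA handles degenerate blocks per convention", {
  y <- array(5, dim = c(4, 4, 2))
  av <- rm_anova_2way(y)
  expect_true(all(av$ss == 0))
  expect_equal(unname(av$pct_total_variation), c(0, 0, 0))
  expect_equal(unname(av$p_gg), c(1, 1, 1))

  # pure time main effect: y depends on the time level only
  y2 <- array(0, dim = c(4, 4, 2))
  for (a in 1:4) y2[, a, ] <- a
  av2 <- rm_anova_2way(y2)
  expect_equal(av2$ss[["time"]], av2$ss_total, tolerance = 1e-12)
  expect_equal(av2$pct_total_variation[["time"]], 100)
  expect_equal(av2$pct_total_variation[["sleep"]], 0)

  expect_error(rm_anova_2way(array(1, dim = c(2, 4, 2))), "at least 3")
  y3 <- array(rnorm(24), dim = c(3, 4, 2)); y3[1, 1, 1] <- NA
  expect_error(rm_anova_2way(y3), "unbalanced")
})

test_that("sums of squares and F match the aov error-strata oracle", {
  set.seed(202)
  for (r in 1:10) {
    y <- array(rnorm(6 * 4 * 2, sd = runif(1, 0.5, 2)), dim = c(6, 4, 2))
    av <- rm_anova_2way(y)
    orc <- aov_oracle(y)
    expect_equal(av$ss[names(orc$ss)], orc$ss, tolerance = 1e-10)
    expect_equal(av$F, orc$F, tolerance = 1e-10)
    expect_equal(sum(av$ss), av$ss_total, tolerance = 1e-8 * av$ss_total)
    expect_true(all(av$pct_total_variation >= 0 &
                      av$pct_total_variation <= 100))
  }
})

test_that("epsilon matches the eigenvalue oracle and its exact cases", {
  expect_equal(gg_epsilon(matrix(rnorm(20), ncol = 2)), 1)

  # compound symmetry: equal variances and covariances -> epsilon 1
  set.seed(7)
  n <- 200; k <- 4
  u <- rnorm(n)
  cs <- matrix(rep(u, k), ncol = k) + matrix(rnorm(n * k, sd = 1), ncol = k)
  eps_cs <- gg_epsilon(cs)
  expect_gt(eps_cs, 0.95)  # estimate; exactly 1 only for the population S

  S_cs <- diag(4) * 2 + 1
  C <- stats::contr.helmert(4); C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  M <- t(C) %*% S_cs %*% C
  expect_equal(sum(diag(M))^2 / (3 * sum(M * M)), 1)

  set.seed(31)
  for (r in 1:10) {
    scores <- matrix(rnorm(10 * 4), ncol = 4) %*% matrix(runif(16), 4, 4)
    expect_equal(gg_epsilon(scores), eigen_epsilon_oracle(scores),
                 tolerance = 1e-12)
    expect_gte(gg_epsilon(scores), 1 / 3)
    expect_lte(gg_epsilon(scores), 1)
  }
})

test_that("GG correction is conservative throughout the rejection region", {
  # scaling both dfs by epsilon <= 1 inflates p wherever the uncorrected
  # test would come near rejection; deep inside the acceptance region the
  # ordering can flip, which is immaterial to the calls reported
  set.seed(44)
  for (r in 1:40) {
    y <- array(rnorm(8 * 4 * 2, sd = 0.7), dim = c(8, 4, 2))
    y[, , 2] <- y[, , 2] + rnorm(1, 0, 0.3)  # sprinkle some real effects
    av <- rm_anova_2way(y)
    sel <- !is.na(av$F) & av$p_uncorrected <= 0.05
    expect_true(all(av$p_gg[sel] >= av$p_uncorrected[sel] - 1e-15))
  }
})

test_that("anova_table rows are deterministic functions of the data", {
  d <- make_log_table(n_features = 2, seed = 9)
  vals <- unclass(d$table)
  vals[2, ] <- vals[1, ]  # two identical features
  lt <- feature_table(vals, "log10")
  at <- anova_table(lt, d$samples)
  expect_equal(nrow(at), 2)
  cols <- setdiff(names(at), "feature_id")
  expect_equal(at[1, cols], at[2, cols], ignore_attr = TRUE)
  expect_s3_class(attr(at, "summary"), "data.frame")
})

test_that("z-scoring shifts variance from subject to time", {
  # rhythm-only world: no sleep effect anywhere
  diffs <- t(vapply(1:8, function(sd_) {
    d <- make_log_table(n_features = 15, seed = 300 + sd_,
                        class_mix = c(null = 1),
                        rhythm_amplitude_range = c(0.15, 0.3))
    z <- suppressWarnings(z_normalize(d$table, d$samples))
    a_l <- anova_table(d$table, d$samples)
    a_z <- anova_table(z, d$samples)
    c(subj = median(a_z$pct_subject) - median(a_l$pct_subject),
      time_gt_sleep = median(a_z$pct_time) - median(a_z$pct_sleep))
  }, numeric(2)))
  expect_true(all(diffs[, "subj"] < 0))
  expect_true(all(diffs[, "time_gt_sleep"] > 0))
})
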