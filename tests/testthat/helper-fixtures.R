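# Shared fixtures and independent oracles for the test suite. Everything is
# built in code; no binary fixtures.

# minimal hand-written injection metadata: n_study study samples of one
# subject pair, plus QC / blank / dilution injections
tiny_samples <- function() {
  data.frame(
    sample_id = c("d1", "d2", "d3", "d4", "b1",
                  "q1", "s1", "s2", "q2", "s3", "s4", "q3",
                  "d5", "d6", "d7", "d8"),
    sample_type = c(rep("dilution", 4), "blank",
                    "qc_pool", "study", "study", "qc_pool", "study", "study",
                    "qc_pool", rep("dilution", 4)),
    subject_id = c(rep(NA, 6), "A", "A", NA, "B", "B", rep(NA, 5)),
    condition = c(rep(NA, 6), "control", "sleep_deprivation", NA,
                  "control", "sleep_deprivation", rep(NA, 5)),
    timepoint = c(rep(NA, 6), "t1", "t1", NA, "t1", "t1", rep(NA, 5)),
    run_order = 1:16,
    batch = 1L,
    dilution_fraction = c(1, 0.5, 0.2, 0.1, rep(NA, 8), 1, 0.5, 0.2, 0.1),
    clock_hour = NA_real_,
    stringsAsFactors = FALSE
  )
}

tiny_table <- function(values, samples = tiny_samples(), scale = "raw") {
  stopifnot(ncol(values) == nrow(samples))
  colnames(values) <- samples$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("F%02d", seq_len(nrow(values)))
  }
  feature_table(values, scale)
}

# independent repeated-measures ANOVA oracle via stats::aov error strata
aov_oracle <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  df <- expand.grid(subject = factor(seq_len(n)),
                    time = factor(seq_len(a)),
                    sleep = factor(seq_len(b)))
  df$y <- as.vector(y)
  fit <- stats::aov(y ~ time * sleep + Error(subject / (time * sleep)),
                    data = df)
  sm <- summary(fit)
  pick <- function(stratum, row) {
    tab <- sm[[stratum]][[1]]
    i <- grep(row, trimws(rownames(tab)), fixed = TRUE)
    tab[i, c("Sum Sq", "F value"), drop = FALSE]
  }
  list(
    ss = c(
      subject = sm[["Error: subject"]][[1]]["Sum Sq"][1, 1],
      time = pick("Error: subject:time", "time")[1, 1],
      `time:subject` = pick("Error: subject:time", "Residuals")[1, 1],
      sleep = pick("Error: subject:sleep", "sleep")[1, 1],
      `sleep:subject` = pick("Error: subject:sleep", "Residuals")[1, 1],
      `time:sleep` = pick("Error: subject:time:sleep", "time:sleep")[1, 1],
      `time:sleep:subject` = pick("Error: subject:time:sleep", "Residuals")[1, 1]
    ),
    F = c(time = pick("Error: subject:time", "time")[1, 2],
          sleep = pick("Error: subject:sleep", "sleep")[1, 2],
          `time:sleep` = pick("Error: subject:time:sleep", "time:sleep")[1, 2])
  )
}

# eigenvalue form of the Box epsilon: lambda of C S C'
eigen_epsilon_oracle <- function(scores) {
  k <- ncol(scores)
  S <- stats::cov(scores)
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  lam <- eigen(t(C) %*% S %*% C, symmetric = TRUE, only.values = TRUE)$values
  min(1, max(1 / (k - 1), sum(lam)^2 / ((k - 1) * sum(lam^2))))
}

# two-sided paired-t p-value by numeric integration of the t density,
# written from the closed-form density (independent of stats::pt)
quadrature_paired_p <- function(d) {
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  v <- n - 1
  dens <- function(x) {
    exp(lgamma((v + 1) / 2) - lgamma(v / 2)) / sqrt(v * pi) *
      (1 + x^2 / v)^(-(v + 1) / 2)
  }
  tail <- stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
  list(t = tstat, p = 2 * tail)
}
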