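# ---------------------------------------------------------------------------
# Subject-wise normalization and repeated-measures two-way ANOVA -------------

#' Subject-wise z-score normalization (auto-scaling)
#'
#' For each (subject, feature), subtracts the subject's mean and divides by
#' the subject's sample standard deviation, pooling both conditions and all
#' time points of that subject's study injections. The resulting values
#' have per-subject-feature mean 0 and sd 1, making rhythmic profiles
#' comparable irrespective of each individual's absolute abundance scale.
#' Non-study injections have no defined z-scale and are set to missing.
#'
#' @param table Log10-scale [feature_table()].
#' @param samples Matching sample metadata.
#' @return A zscore-scale `feature_table`. (subject, feature) pairs with
#'   zero spread or fewer than 2 values are set to missing, with one
#'   warning summarizing the count.
#' @export
z_normalize <- function(table, samples) {
  stopifnot_scale(table, "log10")
  samples <- align_samples(table, samples)
  vals <- unclass(table)
  i_st <- study_idx(samples)
  out <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
                dimnames = dimnames(vals))
  n_degenerate <- 0L
  for (ix in split(i_st, samples$subject_id[i_st])) {
    block <- vals[, ix, drop = FALSE]
    m <- rowMeans(block, na.rm = TRUE)
    s <- apply(block, 1, sample_sd)
    degen <- is.na(s) | s == 0
    n_degenerate <- n_degenerate + sum(degen)
    s[degen] <- NA_real_
    out[, ix] <- (block - m) / s
  }
  if (n_degenerate > 0) {
    warning(n_degenerate, " (subject, feature) pair(s) with zero spread; ",
            "their z-scores are set to missing")
  }
  feature_table(out, "zscore")
}

#' Assemble a complete-case cell block for one feature
#'
#' Extracts a subjects x time x condition array over the deprivation-effect
#' window (t3--t6 by default) from a feature table, dropping subjects with
#' any missing cell.
#'
#' @param table Log10- or zscore-scale [feature_table()].
#' @param samples Matching sample metadata.
#' @param feature_id Feature to extract.
#' @param timepoints Time levels of the block (default t3--t6).
#' @return A list of class `cell_block`: `y` (n x a x b array), `subjects`,
#'   `n_dropped` (incomplete subjects removed).
#' @export
cell_block <- function(table, samples, feature_id,
                       timepoints = SLEEP_TIMEPOINTS) {
  stopifnot_scale(table, c("log10", "zscore"))
  samples <- align_samples(table, samples)
  if (!feature_id %in% rownames(table)) stop("unknown feature: ", feature_id)
  i_st <- study_idx(samples)
  st <- samples[i_st, ]
  x <- unclass(table)[feature_id, i_st]
  keep <- st$timepoint %in% timepoints
  st <- st[keep, ]; x <- x[keep]
  subjects <- sort(unique(st$subject_id))
  a <- length(timepoints); b <- length(CONDITION_LEVELS)
  y <- array(NA_real_, dim = c(length(subjects), a, b),
             dimnames = list(subjects, timepoints, CONDITION_LEVELS))
  y[cbind(match(st$subject_id, subjects),
          match(st$timepoint, timepoints),
          match(st$condition, CONDITION_LEVELS))] <- x
  complete <- apply(y, 1, function(m) !anyNA(m))
  res <- list(y = y[complete, , , drop = FALSE],
              subjects = subjects[complete],
              n_dropped = sum(!complete))
  class(res) <- "cell_block"
  res
}

#' Box/Greenhouse-Geisser epsilon estimate
#'
#' Epsilon-hat from the sample covariance `S` of within-subject scores:
#' with `C` an orthonormal (k-1) x k contrast basis and `M = C S C'`,
#' `epsilon = tr(M)^2 / ((k-1) tr(M^2))`, clamped to `[1/(k-1), 1]`. Equals
#' 1 exactly under compound symmetry (sphericity) and for k = 2.
#'
#' @param scores n x k matrix of within-subject scores (n subjects, k
#'   levels): subject-level means over the other factor for a main effect,
#'   per-subject condition differences for the interaction.
#' @return Epsilon in `[1/(k-1), 1]`; 1 by convention if the contrast
#'   covariance has no dispersion at all.
#' @export
gg_epsilon <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 levels")
  S <- stats::cov(scores)
  C <- stats::contr.helmert(k)          # k x (k-1)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  M <- t(C) %*% S %*% C
  tr2 <- sum(M * M)
  if (tr2 <= .Machine$double.eps * max(1, sum(diag(M))^2)) return(1)
  eps <- sum(diag(M))^2 / ((k - 1) * tr2)
  min(1, max(1 / (k - 1), eps))
}

#' Repeated-measures two-way ANOVA (both factors within-subject)
#'
#' Classical balanced decomposition for one feature's complete block over
#' time (a levels) x sleep condition (b levels) x subject (n): sums of
#' squares for the seven terms (time, sleep, time x sleep, subject, and the
#' subject interactions), F tests of each fixed effect against its own
#' subject-interaction mean square, Greenhouse-Geisser corrected p-values
#' (degrees of freedom multiplied by the effect's epsilon; the sleep factor
#' has 2 levels so its epsilon is 1), and percent-of-total-variation for
#' time, sleep, and subject.
#'
#' @param block A [cell_block()] (or n x a x b array) with n >= 3.
#' @return A list of class `rm_anova`: `ss`, `df`, `ms`, `epsilon`, `F`,
#'   `p_gg`, `p_uncorrected`, `pct_total_variation`, `n`.
#' @export
rm_anova_2way <- function(block) {
  y <- if (inherits(block, "cell_block")) block$y else block
  if (length(dim(y)) != 3) stop("block must be a subjects x time x condition array")
  if (anyNA(y)) stop("unbalanced block: missing cells must be dropped upstream")
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (n < 3) stop("need at least 3 complete subjects")

  gm <- mean(y)
  m_s  <- apply(y, 1, mean)            # subject means
  m_a  <- apply(y, 2, mean)            # time means
  m_b  <- apply(y, 3, mean)            # sleep means
  m_ab <- apply(y, c(2, 3), mean)
  m_as <- apply(y, c(1, 2), mean)      # n x a
  m_bs <- apply(y, c(1, 3), mean)      # n x b

  ss <- c(
    time  = n * b * sum((m_a - gm)^2),
    sleep = n * a * sum((m_b - gm)^2),
    `time:sleep` = n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2),
    subject = a * b * sum((m_s - gm)^2),
    `time:subject`  = b * sum((sweep(sweep(m_as, 2, m_a), 1, m_s) + gm)^2),
    `sleep:subject` = a * sum((sweep(sweep(m_bs, 2, m_b), 1, m_s) + gm)^2)
  )
  ss_total <- sum((y - gm)^2)
  ss <- c(ss, `time:sleep:subject` = max(0, ss_total - sum(ss)))

  df <- c(time = a - 1, sleep = b - 1, `time:sleep` = (a - 1) * (b - 1),
          subject = n - 1, `time:subject` = (a - 1) * (n - 1),
          `sleep:subject` = (b - 1) * (n - 1),
          `time:sleep:subject` = (a - 1) * (b - 1) * (n - 1))
  ms <- ss / df

  eps <- c(
    time = if (a > 1) gg_epsilon(m_as) else 1,
    sleep = 1,  # two levels: a single contrast is always spherical
    `time:sleep` = if (a > 1 && b == 2) {
      gg_epsilon(y[, , 2] - y[, , 1])
    } else 1
  )

  f_of <- function(effect, err) {
    if (ms[err] <= 0) return(c(f = NA_real_, p = 1, p0 = 1))
    f <- ms[effect] / ms[err]
    p0 <- stats::pf(f, df[effect], df[err], lower.tail = FALSE)
    pg <- stats::pf(f, eps[effect] * df[effect], eps[effect] * df[err],
                    lower.tail = FALSE)
    c(f = unname(f), p = unname(pg), p0 = unname(p0))
  }
  ft <- f_of("time", "time:subject")
  fs <- f_of("sleep", "sleep:subject")
  fi <- f_of("time:sleep", "time:sleep:subject")

  pct <- if (ss_total > 0) {
    100 * c(time = unname(ss["time"]), sleep = unname(ss["sleep"]),
            subject = unname(ss["subject"])) / ss_total
  } else c(time = 0, sleep = 0, subject = 0)

  structure(list(
    ss = ss, ss_total = ss_total, df = df, ms = ms, epsilon = eps,
    F = c(time = ft[["f"]], sleep = fs[["f"]], `time:sleep` = fi[["f"]]),
    p_gg = c(time = ft[["p"]], sleep = fs[["p"]], `time:sleep` = fi[["p"]]),
    p_uncorrected = c(time = ft[["p0"]], sleep = fs[["p0"]],
                      `time:sleep` = fi[["p0"]]),
    pct_total_variation = pct,
    n = n
  ), class = "rm_anova")
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 1e-4, "****",
                ifelse(p < 1e-3, "***",
                       ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*", "")))))
}

#' Per-feature repeated-measures ANOVA table
#'
#' Runs [rm_anova_2way()] on every feature's complete t3--t6 block and
#' tabulates percent-of-total-variation, epsilons, F statistics and
#' Greenhouse-Geisser p-values with significance stars (p < 0.05 *,
#' < 0.01 **, < 0.001 ***, < 0.0001 ****). A summary attribute holds the
#' median/min/max percent variation per factor.
#'
#' @param table Log10- or zscore-scale [feature_table()].
#' @param samples Matching sample metadata.
#' @param mode Label recorded in the output ("log10" or "zscore"); defaults
#'   to the table's scale tag.
#' @return A data.frame with one row per analysable feature; attribute
#'   `summary` (median/min/max of each percent column) and `skipped`
#'   (features without >= 3 complete subjects).
#' @export
anova_table <- function(table, samples, mode = scale_tag(table)) {
  stopifnot_scale(table, c("log10", "zscore"))
  samples <- align_samples(table, samples)
  rows <- vector("list", nrow(table))
  skipped <- character(0)
  for (f in rownames(table)) {
    blk <- cell_block(table, samples, f)
    if (length(blk$subjects) < 3) {
      skipped <- c(skipped, f)
      next
    }
    av <- rm_anova_2way(blk)
    rows[[f]] <- data.frame(
      feature_id = f, mode = mode, n_subjects = av$n,
      pct_time = av$pct_total_variation[["time"]],
      pct_sleep = av$pct_total_variation[["sleep"]],
      pct_subject = av$pct_total_variation[["subject"]],
      eps_time = av$epsilon[["time"]],
      eps_interaction = av$epsilon[["time:sleep"]],
      F_time = av$F[["time"]], p_time = av$p_gg[["time"]],
      F_sleep = av$F[["sleep"]], p_sleep = av$p_gg[["sleep"]],
      F_interaction = av$F[["time:sleep"]],
      p_interaction = av$p_gg[["time:sleep"]],
      stars_time = p_stars(av$p_gg[["time"]]),
      stars_sleep = p_stars(av$p_gg[["sleep"]]),
      stars_interaction = p_stars(av$p_gg[["time:sleep"]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  if (nrow(out)) {
    pct_cols <- c("pct_time", "pct_sleep", "pct_subject")
    attr(out, "summary") <- data.frame(
      factor = c("time", "sleep", "subject"),
      median = vapply(pct_cols, function(cn) stats::median(out[[cn]]), 0),
      min = vapply(pct_cols, function(cn) min(out[[cn]]), 0),
      max = vapply(pct_cols, function(cn) max(out[[cn]]), 0),
      row.names = NULL)
  }
  attr(out, "skipped") <- skipped
  out
}
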