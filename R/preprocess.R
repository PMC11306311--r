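# ---------------------------------------------------------------------------
# QC-anchored preprocessing ---------------------------------------------------
#
# Fixed stage order: correct_drift -> compute_feature_qc / filter_features ->
# filter_subjects -> impute_lod -> log_transform. QC metrics are computed on
# drift-corrected, pre-log abundances.

#' Feature-filter thresholds
#'
#' Defaults restate the published quality criteria: a feature is removed if
#' it is present in the process blank, its QC-pool relative standard
#' deviation exceeds 25%, its dilution-series linearity r^2 falls below 0.7,
#' its dispersion ratio (D-ratio) exceeds 50%, or more than 30% of its study
#' values are missing or zero. "Present in blank" is operationalized as mean
#' blank abundance above `blank_ratio_max` (5%) of the mean QC abundance.
#'
#' @param rsd_max_pct Maximum QC RSD, percent.
#' @param r2_min Minimum dilution-series r-squared.
#' @param d_ratio_max_pct Maximum D-ratio, percent.
#' @param missing_max_fraction Maximum fraction of missing-or-zero study
#'   values (strictly more than this fraction is removed).
#' @param blank_ratio_max Blank-to-QC mean abundance ratio above which a
#'   feature counts as blank-detected.
#' @return A validated list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(rsd_max_pct = 25, r2_min = 0.7,
                              d_ratio_max_pct = 50,
                              missing_max_fraction = 0.30,
                              blank_ratio_max = 0.05) {
  th <- list(rsd_max_pct = rsd_max_pct, r2_min = r2_min,
             d_ratio_max_pct = d_ratio_max_pct,
             missing_max_fraction = missing_max_fraction,
             blank_ratio_max = blank_ratio_max)
  if (th$rsd_max_pct < 0 || th$d_ratio_max_pct < 0 || th$blank_ratio_max < 0) {
    stop("config error: percent/ratio thresholds must be >= 0")
  }
  if (th$r2_min < 0 || th$r2_min > 1) {
    stop("config error: r2_min must lie in [0, 1]")
  }
  if (th$missing_max_fraction < 0 || th$missing_max_fraction > 1) {
    stop("config error: missing_max_fraction must lie in [0, 1]")
  }
  class(th) <- "filter_thresholds"
  th
}

#' QC-pool-anchored LOWESS run-order drift correction
#'
#' Per feature and batch, fits a locally weighted regression (tricube local
#' linear, plain least squares within the window) of QC-pool abundances
#' against run order; the span is chosen so that about `window` QC points
#' carry weight. The fitted trend is evaluated at every injection's run
#' order by linear interpolation, clamped to the edge fitted values beyond
#' the first/last QC injection, and each value is rescaled by
#' `median(QC) / trend(run_order)`. QC, blank, and dilution injections are
#' corrected with the same factors. Features with fewer than 2 non-missing
#' QC values in a batch pass through unchanged and are flagged.
#'
#' @param table Raw-scale [feature_table()].
#' @param samples Matching sample metadata.
#' @param window Number of QC points the smoother effectively uses
#'   (default 8).
#' @return A corrected-scale `feature_table`; attribute `passthrough` names
#'   features (per batch) left uncorrected for lack of QC support.
#' @export
correct_drift <- function(table, samples, window = 8) {
  stopifnot_scale(table, "raw")
  samples <- align_samples(table, samples)
  if (window < 2) stop("config error: window must be >= 2")
  i_qc_all <- qc_idx(samples)
  if (!length(i_qc_all)) {
    stop("no QC pool injections present; drift correction cannot be anchored ",
         "- skip the correction stage explicitly if this is intended")
  }
  out <- unclass(table)
  passthrough <- character(0)
  for (b in sort(unique(samples$batch))) {
    in_batch <- samples$batch == b
    i_qc <- which(in_batch & samples$sample_type == "qc_pool")
    i_all <- which(in_batch)
    r_qc <- samples$run_order[i_qc]
    r_all <- samples$run_order[i_all]
    for (f in seq_len(nrow(out))) {
      yq <- out[f, i_qc]
      ok <- !is.na(yq)
      if (sum(ok) < 2) {
        passthrough <- c(passthrough, rownames(table)[f])
        next
      }
      x <- r_qc[ok]
      y <- yq[ok]
      span <- min(1, window / length(y))
      fit <- stats::lowess(x, y, f = span, iter = 0)
      trend <- stats::approx(fit$x, fit$y, xout = r_all, rule = 2,
                             ties = "ordered")$y
      med <- stats::median(y)
      # trend must stay positive: cap the correction factor at 100x
      trend <- pmax(trend, 0.01 * abs(med))
      if (med <= 0 || all(trend <= 0)) {
        passthrough <- c(passthrough, rownames(table)[f])
        next
      }
      out[f, i_all] <- out[f, i_all] * (med / trend)
    }
  }
  res <- feature_table(out, "corrected")
  attr(res, "passthrough") <- unique(passthrough)
  res
}

sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}

#' Per-feature quality-control metrics
#'
#' Computes, per feature on the drift-corrected scale: blank presence (mean
#' blank abundance, missing counted as 0, above `blank_ratio_max` times the
#' mean QC abundance); QC relative standard deviation (100 * sd/mean over
#' non-missing QC values, sample sd); dilution-series linearity (squared
#' Pearson correlation of abundance against dilution fraction over all
#' non-missing dilution injections); D-ratio (100 * sd(QC)/sd(study));
#' and the fraction of missing-or-zero study values. Metrics with fewer
#' than 3 usable points or a zero-variance denominator are recorded as
#' `NA` (undefined) rather than erroring.
#'
#' @param table Corrected-scale [feature_table()].
#' @param samples Matching sample metadata.
#' @param thresholds [filter_thresholds()] used for the blank ratio and the
#'   pass flags.
#' @param policy_undefined How an undefined metric counts in the pass
#'   flags: "drop" (fails the criterion, default) or "keep".
#' @return A data.frame (class `feature_qc_report`) with one row per
#'   feature: the metrics, per-criterion `pass_*` flags, and `keep`.
#' @export
compute_feature_qc <- function(table, samples,
                               thresholds = filter_thresholds(),
                               policy_undefined = c("drop", "keep")) {
  stopifnot_scale(table, c("corrected", "raw"))
  policy_undefined <- match.arg(policy_undefined)
  samples <- align_samples(table, samples)
  vals <- unclass(table)
  i_st <- study_idx(samples)
  i_qc <- qc_idx(samples)
  i_bl <- blank_idx(samples)
  i_dl <- dil_idx(samples)

  qc_mean <- if (length(i_qc)) {
    rowMeans(vals[, i_qc, drop = FALSE], na.rm = TRUE)
  } else rep(NaN, nrow(vals))
  qc_mean[!is.finite(qc_mean)] <- NA_real_

  blank_vals <- vals[, i_bl, drop = FALSE]
  blank_vals[is.na(blank_vals)] <- 0
  blank_mean <- if (length(i_bl)) rowMeans(blank_vals) else rep(NA_real_, nrow(vals))
  blank_detected <- ifelse(is.na(blank_mean) | is.na(qc_mean), NA,
                           blank_mean > thresholds$blank_ratio_max * qc_mean)

  rsd <- d_ratio <- r2 <- rep(NA_real_, nrow(vals))
  for (f in seq_len(nrow(vals))) {
    q <- vals[f, i_qc]; q <- q[!is.na(q)]
    if (length(q) >= 3 && mean(q) > 0) rsd[f] <- 100 * stats::sd(q) / mean(q)
    s <- vals[f, i_st]; s <- s[!is.na(s)]
    if (length(q) >= 3 && length(s) >= 3) {
      sds <- stats::sd(s)
      if (sds > 0) d_ratio[f] <- 100 * stats::sd(q) / sds
    }
    d <- vals[f, i_dl]
    frac <- samples$dilution_fraction[i_dl]
    ok <- !is.na(d)
    if (sum(ok) >= 3 && stats::sd(d[ok]) > 0 && stats::sd(frac[ok]) > 0) {
      r2[f] <- stats::cor(d[ok], frac[ok])^2
    }
  }

  # NA | (NA == 0) is TRUE, so missing cells always count
  miss_frac <- rowMeans(is.na(vals[, i_st, drop = FALSE]) |
                          vals[, i_st, drop = FALSE] == 0)

  und <- policy_undefined == "keep"
  pass_blank <- ifelse(is.na(blank_detected), und, !blank_detected)
  pass_rsd <- ifelse(is.na(rsd), und, rsd <= thresholds$rsd_max_pct)
  pass_r2 <- ifelse(is.na(r2), und, r2 >= thresholds$r2_min)
  pass_d <- ifelse(is.na(d_ratio), und, d_ratio <= thresholds$d_ratio_max_pct)
  pass_missing <- miss_frac <= thresholds$missing_max_fraction

  rep_df <- data.frame(feature_id = rownames(vals),
                       blank_detected = blank_detected,
                       rsd_qc_pct = rsd,
                       dilution_r2 = r2,
                       d_ratio_pct = d_ratio,
                       missing_fraction = miss_frac,
                       pass_blank = pass_blank,
                       pass_rsd = pass_rsd,
                       pass_r2 = pass_r2,
                       pass_d_ratio = pass_d,
                       pass_missing = pass_missing,
                       keep = pass_blank & pass_rsd & pass_r2 & pass_d &
                         pass_missing,
                       stringsAsFactors = FALSE)
  class(rep_df) <- c("feature_qc_report", "data.frame")
  rep_df
}

#' Apply the feature quality filter
#'
#' A feature is kept iff it is not blank-detected, QC RSD <= `rsd_max_pct`,
#' dilution r^2 >= `r2_min`, D-ratio <= `d_ratio_max_pct`, and
#' missing-or-zero fraction <= `missing_max_fraction` (thresholds are
#' exclusive on the removal side, so boundary values survive). Undefined
#' metrics are resolved by `policy_undefined`.
#'
#' @param report A [compute_feature_qc()] report.
#' @param thresholds [filter_thresholds()].
#' @param policy_undefined "drop" (default) or "keep" for undefined metrics.
#' @return Character vector of kept feature ids.
#' @export
filter_features <- function(report, thresholds = filter_thresholds(),
                            policy_undefined = c("drop", "keep")) {
  policy_undefined <- match.arg(policy_undefined)
  und <- policy_undefined == "keep"
  keep <- ifelse(is.na(report$blank_detected), und, !report$blank_detected) &
    ifelse(is.na(report$rsd_qc_pct), und,
           report$rsd_qc_pct <= thresholds$rsd_max_pct) &
    ifelse(is.na(report$dilution_r2), und,
           report$dilution_r2 >= thresholds$r2_min) &
    ifelse(is.na(report$d_ratio_pct), und,
           report$d_ratio_pct <= thresholds$d_ratio_max_pct) &
    report$missing_fraction <= thresholds$missing_max_fraction
  report$feature_id[keep]
}

#' Filter subjects by missing-or-zero fraction
#'
#' A subject is kept iff the fraction of missing-or-zero cells over (all
#' features x that subject's study injections) is at most
#' `missing_max_fraction`; strictly more is excluded.
#'
#' @param table A [feature_table()] (typically already feature-filtered).
#' @param samples Matching sample metadata.
#' @param missing_max_fraction Threshold (default 0.30).
#' @return Character vector of kept subject ids.
#' @export
filter_subjects <- function(table, samples, missing_max_fraction = 0.30) {
  samples <- align_samples(table, samples)
  i_st <- study_idx(samples)
  subj <- samples$subject_id[i_st]
  vals <- unclass(table)[, i_st, drop = FALSE]
  bad <- is.na(vals) | vals == 0
  frac <- vapply(split(seq_along(subj), subj),
                 function(ix) mean(bad[, ix, drop = FALSE]), numeric(1))
  kept <- names(frac)[frac <= missing_max_fraction]
  if (length(kept) < 3) {
    stop("fewer than 3 subjects pass the missingness filter (",
         length(kept), " kept); downstream tests need more degrees of freedom")
  }
  kept
}

#' One-fifth limit-of-detection imputation
#'
#' Replaces every missing or zero study value of a feature by one fifth of
#' the lowest positive value detected for that feature across study
#' injections. QC, blank, and dilution injections are left untouched.
#'
#' @param table Raw- or corrected-scale [feature_table()].
#' @param samples Matching sample metadata.
#' @return The table with study-sample missings imputed; attribute
#'   `n_replaced` counts replacements.
#' @export
impute_lod <- function(table, samples) {
  stopifnot_scale(table, c("raw", "corrected"))
  samples <- align_samples(table, samples)
  i_st <- study_idx(samples)
  vals <- unclass(table)
  n_replaced <- 0L
  for (f in seq_len(nrow(vals))) {
    x <- vals[f, i_st]
    pos <- x[!is.na(x) & x > 0]
    if (!length(pos)) {
      stop("feature '", rownames(vals)[f],
           "' has no positive study value; it should have been filtered out")
    }
    need <- is.na(x) | x == 0
    if (any(need)) {
      x[need] <- min(pos) / 5
      vals[f, i_st] <- x
      n_replaced <- n_replaced + sum(need)
    }
  }
  res <- feature_table(vals, scale_tag(table))
  attr(res, "passthrough") <- attr(table, "passthrough")
  attr(res, "n_replaced") <- n_replaced
  res
}

#' Log10 transformation
#'
#' Elementwise base-10 logarithm of study, QC, and dilution injections;
#' process blanks are excluded (set to missing). Non-missing values must be
#' strictly positive.
#'
#' @param table Raw- or corrected-scale [feature_table()] (post-imputation).
#' @param samples Matching sample metadata.
#' @return A log10-scale `feature_table`.
#' @export
log_transform <- function(table, samples) {
  stopifnot_scale(table, c("raw", "corrected"))
  samples <- align_samples(table, samples)
  vals <- unclass(table)
  i_bl <- blank_idx(samples)
  keep_cols <- setdiff(seq_len(ncol(vals)), i_bl)
  sub <- vals[, keep_cols, drop = FALSE]
  bad <- which(!is.na(sub) & sub <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive value at feature '", rownames(sub)[bad[1, 1]],
         "', sample '", colnames(sub)[bad[1, 2]],
         "'; impute before log-transforming")
  }
  vals[, keep_cols] <- log10(sub)
  if (length(i_bl)) vals[, i_bl] <- NA_real_
  feature_table(vals, "log10")
}
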