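# ---------------------------------------------------------------------------
# Per-timepoint paired testing and time-course profile classification -------

PROFILE_CATEGORIES <- c("non_robust", "non_adaptive", "sleep_linear",
                        "sleep_rhythmic", "unaffected")

#' Paired t-tests per sampling time point
#'
#' For every feature and time point t1..t7, a classical two-sided paired
#' t-test of sleep deprivation against control across subjects. Subjects
#' lacking either condition's value at a time point are dropped pairwise;
#' cells with fewer than 3 complete pairs are reported undefined. A cell
#' with zero-variance differences is a degenerate limit: p = 1 if the
#' differences are all zero, otherwise p = 0 with a `degenerate` flag.
#'
#' @param table Log10- or zscore-scale [feature_table()].
#' @param samples Matching sample metadata.
#' @param alpha Significance level (0.01 for untargeted analysis, 0.05 for
#'   targeted).
#' @return A list of class `timepoint_tests` with features x 7 matrices
#'   `p`, `t`, `mean_diff` (deprivation minus control), `n_pairs`, `df`,
#'   logical `significant` (p < alpha) and `degenerate`, plus `alpha`.
#' @export
paired_tests <- function(table, samples, alpha = 0.01) {
  stopifnot_scale(table, c("log10", "zscore"))
  if (alpha < 0 || alpha > 1) stop("config error: alpha must lie in [0, 1]")
  samples <- align_samples(table, samples)
  vals <- unclass(table)
  i_st <- study_idx(samples)
  st <- samples[i_st, ]
  subjects <- sort(unique(st$subject_id))
  p_feat <- nrow(vals)
  tps <- TIMEPOINT_LEVELS
  mk <- function(init) matrix(init, nrow = p_feat, ncol = length(tps),
                              dimnames = list(rownames(vals), tps))
  P <- mk(NA_real_); Tm <- mk(NA_real_); D <- mk(NA_real_)
  N <- mk(NA_integer_); DEG <- mk(FALSE)
  warned <- 0L
  for (j in seq_along(tps)) {
    sel <- function(cond) {
      ix <- i_st[st$timepoint == tps[j] & st$condition == cond]
      m <- matrix(NA_real_, nrow = p_feat, ncol = length(subjects))
      sid <- samples$subject_id[ix]
      m[, match(sid, subjects)] <- vals[, ix, drop = FALSE]
      m
    }
    d <- sel("sleep_deprivation") - sel("control")
    ok <- !is.na(d)
    n <- rowSums(ok)
    dbar <- rowMeans(d, na.rm = TRUE)
    sd_d <- sqrt(pmax(0, rowSums((d - dbar)^2, na.rm = TRUE) / pmax(1, n - 1)))
    enough <- n >= 3
    warned <- warned + sum(!enough)
    N[, j] <- as.integer(n)
    D[enough, j] <- dbar[enough]
    zero_sd <- enough & sd_d == 0
    DEG[, j] <- zero_sd & dbar != 0
    tt <- dbar / (sd_d / sqrt(n))
    P[, j] <- ifelse(!enough, NA_real_,
                     ifelse(zero_sd, ifelse(dbar == 0, 1, 0),
                            2 * stats::pt(-abs(tt), n - 1)))
    Tm[enough, j] <- ifelse(zero_sd[enough],
                            ifelse(dbar[enough] == 0, 0, Inf * sign(dbar[enough])),
                            tt[enough])
  }
  if (warned > 0) {
    warning(warned, " (feature, timepoint) cell(s) with < 3 complete pairs ",
            "reported undefined")
  }
  structure(list(p = P, t = Tm, mean_diff = D, n_pairs = N,
                 df = N - 1L, significant = !is.na(P) & P < alpha,
                 degenerate = DEG, alpha = alpha),
            class = "timepoint_tests")
}

#' Classify one feature's time-course profile
#'
#' Applies the profile taxonomy in strict rule order on the seven
#' per-timepoint p-values: (1) significant at t1 or t2 (before the
#' experimental night) -> `non_robust`; (2) else significant at t7 (after
#' the recovery night, the proof-of-concept control) -> `non_adaptive`;
#' (3) else significant at all of t3--t6 -> `sleep_linear`; (4) else
#' significant at at least one of t3--t6 -> `sleep_rhythmic`; (5) else
#' `unaffected`. Undefined p-values count as non-significant and set a
#' quality flag.
#'
#' @param pvals Named (t1..t7) numeric vector of p-values.
#' @param alpha Significance level.
#' @param mean_diff Optional named vector of mean differences (deprivation
#'   minus control) used for the direction at the first significant time
#'   point.
#' @return A list of class `profile_classification`: `category`,
#'   `significant_timepoints`, `direction_at_first_hit` ("up"/"down"/
#'   "none"), `has_undefined`.
#' @export
classify_profile <- function(pvals, alpha = 0.01, mean_diff = NULL) {
  if (is.null(names(pvals))) names(pvals) <- TIMEPOINT_LEVELS
  if (!setequal(names(pvals), TIMEPOINT_LEVELS)) {
    stop("pvals must cover exactly t1..t7")
  }
  pvals <- pvals[TIMEPOINT_LEVELS]
  has_undefined <- anyNA(pvals)
  sig <- !is.na(pvals) & pvals < alpha
  hits <- TIMEPOINT_LEVELS[sig]
  category <- if (sig[["t1"]] || sig[["t2"]]) {
    "non_robust"
  } else if (sig[["t7"]]) {
    "non_adaptive"
  } else if (all(sig[SLEEP_TIMEPOINTS])) {
    "sleep_linear"
  } else if (any(sig[SLEEP_TIMEPOINTS])) {
    "sleep_rhythmic"
  } else "unaffected"
  direction <- "none"
  if (length(hits) && !is.null(mean_diff)) {
    d1 <- mean_diff[[hits[1]]]
    if (!is.na(d1) && d1 != 0) direction <- if (d1 > 0) "up" else "down"
  }
  structure(list(category = category,
                 significant_timepoints = hits,
                 direction_at_first_hit = direction,
                 has_undefined = has_undefined),
            class = "profile_classification")
}

#' Classify every feature from a paired-test matrix
#'
#' @param tests A [paired_tests()] result.
#' @param alpha Significance level; defaults to the one the tests used.
#' @return A data.frame with one row per feature: `category`,
#'   `significant_timepoints` (comma-separated), `n_significant`,
#'   `direction_at_first_hit`, `has_undefined`.
#' @export
classify_features <- function(tests, alpha = tests$alpha) {
  rows <- lapply(rownames(tests$p), function(f) {
    cl <- classify_profile(tests$p[f, ], alpha, tests$mean_diff[f, ])
    data.frame(feature_id = f,
               category = cl$category,
               significant_timepoints = paste(cl$significant_timepoints,
                                              collapse = ","),
               n_significant = length(cl$significant_timepoints),
               direction_at_first_hit = cl$direction_at_first_hit,
               has_undefined = cl$has_undefined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), category = character(),
                      significant_timepoints = character(),
                      n_significant = integer(),
                      direction_at_first_hit = character(),
                      has_undefined = logical(), stringsAsFactors = FALSE)
  }
  out
}

#' Compound false-positive rate of the gated classification
#'
#' Probability that a truly null feature is significant at one given time
#' point within the deprivation window while remaining non-significant at
#' the `n_gate` control time points (t1, t2, t7):
#' `alpha * (1 - alpha)^n_gate`. At alpha = 0.01 this is 0.009703, i.e.
#' 0.97%.
#'
#' @param alpha Per-test significance level in `[0, 1]`.
#' @param n_gate Number of gate time points (default 3).
#' @return The compound false-positive probability.
#' @export
#' @examples
#' compound_fp_rate(0.01)  # 0.009703
compound_fp_rate <- function(alpha, n_gate = 3) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  alpha * (1 - alpha)^n_gate
}

#' Summarize a profile classification
#'
#' @param classification A [classify_features()] data.frame.
#' @param tests The matching [paired_tests()] result (for per-timepoint
#'   significance counts).
#' @return A list: `n_features`, `category_counts`, `category_fractions`,
#'   `sleep_related_fraction` (sleep_linear + sleep_rhythmic),
#'   `per_timepoint_significant` (counts among t3--t6),
#'   `multi_timepoint_features` (significant at >= 2 time points),
#'   `direction_counts`.
#' @export
summarize_classification <- function(classification, tests = NULL) {
  n <- nrow(classification)
  cnt <- table(factor(classification$category, levels = PROFILE_CATEGORIES))
  cnt <- stats::setNames(as.integer(cnt), names(cnt))
  frac <- if (n > 0) cnt / n else stats::setNames(rep(0, length(cnt)), names(cnt))
  per_tp <- stats::setNames(rep(0L, length(SLEEP_TIMEPOINTS)), SLEEP_TIMEPOINTS)
  if (!is.null(tests) && nrow(tests$p)) {
    per_tp <- colSums(tests$significant[, SLEEP_TIMEPOINTS, drop = FALSE])
  }
  multi <- classification$feature_id[classification$n_significant >= 2]
  dirs <- table(factor(classification$direction_at_first_hit,
                       levels = c("up", "down", "none")))
  list(n_features = n,
       category_counts = cnt,
       category_fractions = frac,
       sleep_related_fraction =
         unname(frac[["sleep_linear"]] + frac[["sleep_rhythmic"]]),
       per_timepoint_significant = per_tp,
       multi_timepoint_features = multi,
       direction_counts = stats::setNames(as.integer(dirs), names(dirs)))
}
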