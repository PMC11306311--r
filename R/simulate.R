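# ---------------------------------------------------------------------------
# Synthetic crossover sleep-study generator ---------------------------------

FEATURE_CLASSES <- c("null", "sleep_linear", "sleep_rhythmic",
                     "non_adaptive", "non_robust", "contaminant")

#' Configuration for the synthetic study generator
#'
#' All abundance-scale parameters are in log10 units. The defaults restate
#' the study design being emulated: 13 subjects in a crossover with 7
#' sampling time points per condition, QC pool reinjected every 5 study
#' samples, a dilution series (100/50/20/10%) at the start and end of the
#' run, one process blank, and limit-of-detection censoring of roughly 5%
#' of study values. Between-subject spread (0.35 log10 units) dominates
#' residual within-subject noise (0.08), matching the observation that the
#' subject effect is the largest variance component before normalization.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param n_features Number of molecular features.
#' @param class_mix Named proportions over the feature classes `null`,
#'   `sleep_linear`, `sleep_rhythmic`, `non_adaptive`, `non_robust`,
#'   `contaminant`; must sum to 1.
#' @param subject_sd SD of subject-level offsets (log10 units).
#' @param residual_sd SD of residual noise on study injections (log10).
#' @param technical_sd_qc SD of technical noise on QC/dilution/blank
#'   injections (log10).
#' @param rhythm_amplitude_range Range of cosine rhythm amplitudes (log10).
#' @param effect_size_range Range of sleep-deprivation effect sizes (log10).
#' @param drift_slope_range Range of linear multiplicative run-order drift
#'   slopes (fractional change over the whole run).
#' @param baseline_mu_range Range of feature baseline abundances (log10).
#' @param lod_quantile Per-feature quantile of study values below which
#'   measurements are censored to missing; 0 disables censoring.
#' @param qc_every Insert a QC pool injection after this many study samples.
#' @param dilution_fractions Dilution series fractions in (0, 1].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 13,
                       n_features = 200,
                       class_mix = c(null = 0.70, sleep_linear = 0.05,
                                     sleep_rhythmic = 0.05, non_adaptive = 0.05,
                                     non_robust = 0.05, contaminant = 0.10),
                       subject_sd = 0.35,
                       residual_sd = 0.08,
                       technical_sd_qc = 0.04,
                       rhythm_amplitude_range = c(0.05, 0.25),
                       effect_size_range = c(0.15, 0.45),
                       drift_slope_range = c(-0.2, 0.2),
                       baseline_mu_range = c(3.5, 5.5),
                       lod_quantile = 0.05,
                       qc_every = 5,
                       dilution_fractions = c(1, 0.5, 0.2, 0.1),
                       seed = NULL) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_features = as.integer(n_features),
              class_mix = class_mix,
              subject_sd = subject_sd, residual_sd = residual_sd,
              technical_sd_qc = technical_sd_qc,
              rhythm_amplitude_range = rhythm_amplitude_range,
              effect_size_range = effect_size_range,
              drift_slope_range = drift_slope_range,
              baseline_mu_range = baseline_mu_range,
              lod_quantile = lod_quantile,
              qc_every = as.integer(qc_every),
              dilution_fractions = dilution_fractions,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$n_subjects < 3) stop("config error: n_subjects must be >= 3")
  if (cfg$n_features < 1) stop("config error: n_features must be >= 1")
  if (is.null(names(cfg$class_mix)) ||
      !all(names(cfg$class_mix) %in% FEATURE_CLASSES)) {
    stop("config error: class_mix must be named with classes among: ",
         paste(FEATURE_CLASSES, collapse = ", "))
  }
  if (any(cfg$class_mix < 0) || abs(sum(cfg$class_mix) - 1) > 1e-9) {
    stop("config error: class_mix proportions must be >= 0 and sum to 1")
  }
  for (nm in c("rhythm_amplitude_range", "effect_size_range",
               "drift_slope_range", "baseline_mu_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop("config error: ", nm, " must be an increasing length-2 range")
    }
  }
  if (any(c(cfg$subject_sd, cfg$residual_sd, cfg$technical_sd_qc) < 0)) {
    stop("config error: standard deviations must be >= 0")
  }
  if (cfg$lod_quantile < 0 || cfg$lod_quantile >= 1) {
    stop("config error: lod_quantile must lie in [0, 1)")
  }
  if (cfg$qc_every < 1) stop("config error: qc_every must be >= 1")
  if (any(cfg$dilution_fractions <= 0 | cfg$dilution_fractions > 1)) {
    stop("config error: dilution_fractions must lie in (0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

# deterministic class counts: floor + largest remainders, so the mix is met
# as closely as an integer split allows
class_counts <- function(mix, n) {
  mix <- mix[mix > 0]
  raw <- mix * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[extra] <- cnt[extra] + 1
  }
  cnt
}

# injection sequence: dilution series, blank, then QC-bracketed randomized
# study blocks (QC every `qc_every` study samples), closing QC, and the
# dilution series again at the end of the run
build_injection_sequence <- function(n_study, qc_every, n_dilution) {
  seq_types <- c(rep("dilution", n_dilution), "blank", "qc_pool")
  done <- 0
  while (done < n_study) {
    k <- min(qc_every, n_study - done)
    seq_types <- c(seq_types, rep("study", k), "qc_pool")
    done <- done + k
  }
  c(seq_types, rep("dilution", n_dilution))
}

#' Generate a synthetic crossover sleep-deprivation dataset
#'
#' Draws per-feature generative parameters (baseline, cosine diurnal rhythm,
#' subject offsets, sleep-deprivation effect, run-order drift slope, limit
#' of detection) and emits a raw abundance table, the matching injection
#' metadata, and the ground truth.
#'
#' The log10 abundance of feature *f* in a study sample of subject *s* at
#' time point *t* is
#' `mu_f + u_fs + A_f cos(2 pi (h(t) - phi_f) / 24) + effect + noise`,
#' where `h(t)` is clock time of day. The sleep-deprivation effect term is 0
#' in the control condition and, in the deprivation arm, depends on the
#' feature class: `sleep_linear` scales with hours awake,
#' `delta * (hours_awake - 15) / 25`, at t3--t6 and is 0 at t1/t2/t7;
#' `sleep_rhythmic` adds `delta` at t3 only (suppressed morning trough);
#' `non_adaptive` adds `delta` at t3--t7 (no recovery); `non_robust` adds
#' `delta` at all seven time points (a pre-existing group difference);
#' `null` and `contaminant` have no effect. The raw value is `10^y` times a
#' linear multiplicative drift in run order (clipped at 0.1). QC pools sit
#' at the feature's rhythm-averaged baseline with technical noise, dilution
#' injections scale the QC level by their fraction, and process blanks are
#' zero except for contaminant features. Study values below the feature's
#' LOD threshold (the `lod_quantile` quantile of its study values) are
#' censored to missing.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `table` (raw [feature_table()]), `samples`
#'   (metadata data.frame) and `truth` (per-feature data.frame carrying
#'   class and generative parameters; subject offsets as `offset_*`
#'   columns).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  sched <- timepoint_schedule()
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  design <- expand.grid(timepoint = sched$timepoint,
                        condition = CONDITION_LEVELS,
                        subject_id = subjects,
                        stringsAsFactors = FALSE)
  n_study <- nrow(design)
  design <- design[sample.int(n_study), , drop = FALSE]  # randomized order

  n_dil <- length(cfg$dilution_fractions)
  types <- build_injection_sequence(n_study, cfg$qc_every, n_dil)
  n_inj <- length(types)

  samples <- data.frame(sample_id = character(n_inj),
                        sample_type = types,
                        subject_id = NA_character_,
                        condition = NA_character_,
                        timepoint = NA_character_,
                        run_order = seq_len(n_inj),
                        batch = 1L,
                        dilution_fraction = NA_real_,
                        clock_hour = NA_real_,
                        stringsAsFactors = FALSE)
  i_study <- which(types == "study")
  samples$subject_id[i_study] <- design$subject_id
  samples$condition[i_study]  <- design$condition
  samples$timepoint[i_study]  <- design$timepoint
  samples$clock_hour[i_study] <-
    sched$clock_hour[match(design$timepoint, sched$timepoint)]
  i_dil <- which(types == "dilution")
  samples$dilution_fraction[i_dil] <- rep(cfg$dilution_fractions, 2)
  samples$sample_id <- paste0(
    c(study = "STY", qc_pool = "QC", blank = "BLK", dilution = "DIL")[types],
    "_", sprintf("%03d", samples$run_order))
  validate_samples(samples)

  # per-feature generative parameters
  p <- cfg$n_features
  cnt <- class_counts(cfg$class_mix, p)
  true_class <- sample(rep(names(cnt), cnt))
  runif_range <- function(r) stats::runif(p, r[1], r[2])
  baseline_mu <- runif_range(cfg$baseline_mu_range)
  amplitude <- runif_range(cfg$rhythm_amplitude_range)
  acrophase <- stats::runif(p, 0, 24)
  effect_delta <- runif_range(cfg$effect_size_range)
  effect_delta[true_class %in% c("null", "contaminant")] <- 0
  drift_slope <- runif_range(cfg$drift_slope_range)
  offsets <- matrix(stats::rnorm(p * cfg$n_subjects, 0, cfg$subject_sd),
                    nrow = p, dimnames = list(NULL, subjects))

  # drift factor per injection, shared functional form across features
  mid <- (1 + n_inj) / 2
  span <- max(n_inj - 1, 1)
  drift <- pmax(1 + outer(drift_slope, (samples$run_order - mid) / span), 0.1)

  values <- matrix(NA_real_, nrow = p, ncol = n_inj,
                   dimnames = list(sprintf("MF%04d", seq_len(p)),
                                   samples$sample_id))

  # study samples
  tp <- samples$timepoint[i_study]
  cond <- samples$condition[i_study]
  hod <- samples$clock_hour[i_study] %% 24
  rhythm <- amplitude %o% rep(1, length(i_study)) *
    cos(outer(acrophase, hod, function(a, h) 2 * pi * (h - a) / 24))
  subj_col <- match(samples$subject_id[i_study], subjects)
  eff <- effect_matrix(true_class, effect_delta, tp, cond)
  y <- baseline_mu + offsets[, subj_col, drop = FALSE] + rhythm + eff +
    matrix(stats::rnorm(p * length(i_study), 0, cfg$residual_sd),
           nrow = p)
  values[, i_study] <- 10^y * drift[, i_study, drop = FALSE]

  # QC pool level: baseline plus the rhythm averaged over the 7 time points
  # (pooling averages subjects and times; subject offsets average to ~0)
  mean_rhythm <- rowMeans(
    amplitude %o% rep(1, 7) *
      cos(outer(acrophase, sched$clock_hour %% 24, function(a, h) 2 * pi * (h - a) / 24)))
  qc_base <- 10^(baseline_mu + mean_rhythm)
  tech_noise <- function(k) {
    matrix(10^stats::rnorm(p * k, 0, cfg$technical_sd_qc), nrow = p)
  }
  i_qc <- qc_idx(samples)
  values[, i_qc] <- qc_base * drift[, i_qc, drop = FALSE] * tech_noise(length(i_qc))
  values[, i_dil] <- qc_base *
    rep(samples$dilution_fraction[i_dil], each = p) *
    drift[, i_dil, drop = FALSE] * tech_noise(length(i_dil))
  i_blk <- blank_idx(samples)
  values[, i_blk] <- 0
  contam <- true_class == "contaminant"
  if (any(contam)) {
    values[contam, i_blk] <- 10^baseline_mu[contam] *
      drift[contam, i_blk, drop = FALSE] *
      matrix(10^stats::rnorm(sum(contam) * length(i_blk), 0, cfg$technical_sd_qc),
             nrow = sum(contam))
  }

  # LOD censoring on study injections
  lod <- rep(0, p)
  if (cfg$lod_quantile > 0) {
    lod <- apply(values[, i_study, drop = FALSE], 1, stats::quantile,
                 probs = cfg$lod_quantile, names = FALSE)
    censor <- values[, i_study, drop = FALSE] < lod
    sv <- values[, i_study, drop = FALSE]
    sv[censor] <- NA_real_
    values[, i_study] <- sv
  }

  truth <- data.frame(feature_id = rownames(values),
                      true_class = true_class,
                      baseline_mu = baseline_mu,
                      amplitude = amplitude,
                      acrophase_hour = acrophase,
                      effect_delta = effect_delta,
                      drift_slope = drift_slope,
                      lod_threshold = lod,
                      stringsAsFactors = FALSE)
  off_df <- as.data.frame(offsets)
  names(off_df) <- paste0("offset_", subjects)
  truth <- cbind(truth, off_df)

  list(table = feature_table(values, "raw"),
       samples = samples,
       truth = truth)
}

# per-feature x per-study-sample effect term on the log10 scale
effect_matrix <- function(true_class, effect_delta, tp, cond) {
  p <- length(true_class)
  eff <- matrix(0, nrow = p, ncol = length(tp))
  dep <- cond == "sleep_deprivation"
  in_window <- tp %in% SLEEP_TIMEPOINTS

  cls <- true_class == "sleep_linear"
  if (any(cls)) {
    ha <- hours_awake(tp, cond)
    w <- ifelse(dep & in_window, (ha - 15) / 25, 0)
    eff[cls, ] <- eff[cls, , drop = FALSE] + effect_delta[cls] %o% w
  }
  cls <- true_class == "sleep_rhythmic"
  if (any(cls)) {
    w <- as.numeric(dep & tp == "t3")
    eff[cls, ] <- eff[cls, , drop = FALSE] + effect_delta[cls] %o% w
  }
  cls <- true_class == "non_adaptive"
  if (any(cls)) {
    w <- as.numeric(dep & tp %in% c(SLEEP_TIMEPOINTS, "t7"))
    eff[cls, ] <- eff[cls, , drop = FALSE] + effect_delta[cls] %o% w
  }
  cls <- true_class == "non_robust"
  if (any(cls)) {
    eff[cls, ] <- eff[cls, , drop = FALSE] + effect_delta[cls] %o% as.numeric(dep)
  }
  eff
}

#' Write a simulated dataset to CSV files
#'
#' Emits `<stem>_features.csv`, `<stem>_samples.csv`, `<stem>_truth.csv`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param stem Path stem for the three files.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, stem) {
  paths <- c(features = paste0(stem, "_features.csv"),
             samples  = paste0(stem, "_samples.csv"),
             truth    = paste0(stem, "_truth.csv"))
  write_table(dataset$table, paths[["features"]])
  write_sample_metadata(dataset$samples, paths[["samples"]])
  write_table(dataset$truth, paths[["truth"]])
  invisible(paths)
}
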