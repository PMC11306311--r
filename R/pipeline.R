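# ---------------------------------------------------------------------------
# End-to-end orchestration and command-line interface ------------------------

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Either `input_stem` points
#' at an existing `<stem>_features.csv` / `<stem>_samples.csv` pair, or a
#' dataset is simulated from `sim` first.
#'
#' @param out_dir Artifact directory (created if absent).
#' @param input_stem Optional path stem of an existing dataset; `NULL`
#'   simulates one.
#' @param sim A [sim_config()] used when simulating.
#' @param thresholds A [filter_thresholds()].
#' @param window LOWESS batch-correction window (default 8 QC points).
#' @param alpha_untargeted Significance level of the untargeted paired
#'   tests (default 0.01).
#' @param alpha_targeted Significance level for targeted mode (default
#'   0.05).
#' @param test_scale Scale the paired tests run on: "log10" (default) or
#'   "zscore".
#' @param seed Seed driving all randomness of the run.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "sleepmetab_run",
                            input_stem = NULL,
                            sim = sim_config(),
                            thresholds = filter_thresholds(),
                            window = 8,
                            alpha_untargeted = 0.01,
                            alpha_targeted = 0.05,
                            test_scale = c("log10", "zscore"),
                            seed = 1L) {
  test_scale <- match.arg(test_scale)
  if (alpha_untargeted <= 0 || alpha_untargeted > 1 ||
      alpha_targeted <= 0 || alpha_targeted > 1) {
    stop("config error: alpha levels must lie in (0, 1]")
  }
  if (window < 2) stop("config error: window must be >= 2")
  if (!inherits(thresholds, "filter_thresholds")) {
    thresholds <- do.call(filter_thresholds, thresholds)
  }
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  structure(list(out_dir = out_dir, input_stem = input_stem, sim = sim,
                 thresholds = thresholds, window = window,
                 alpha_untargeted = alpha_untargeted,
                 alpha_targeted = alpha_targeted,
                 test_scale = test_scale, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (or input loading), QC-anchored drift
#' correction, feature QC metrics and filtering, subject filtering,
#' one-fifth-LOD imputation, log10 transformation, subject-wise z-scoring,
#' repeated-measures ANOVA tables in both modes, per-timepoint paired
#' tests, profile classification and its summary. All artifacts are written
#' as CSV under `config$out_dir`, together with a JSON run manifest
#' recording the seed, thresholds, per-stage counts and artifact names.
#' Identical config and seed reproduce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`samples`,
#'   `qc_report`, `kept_features`, `kept_subjects`, `log_table`,
#'   `z_table`, `anova_log10`, `anova_zscore`, `tests`, `classification`,
#'   `summary`, `manifest`).
#' @export
run_all <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("config error: not a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$out_dir, name)
  manifest <- list(package_version = as.character(utils::packageVersion("sleepmetab")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   window = config$window,
                   alpha_untargeted = config$alpha_untargeted,
                   test_scale = config$test_scale,
                   thresholds = unclass(config$thresholds),
                   artifacts = character(0))

  if (is.null(config$input_stem)) {
    sim <- config$sim
    sim$seed <- config$seed
    ds <- generate_dataset(sim)
    write_dataset(ds, file.path(config$out_dir, "simulated"))
    manifest$artifacts <- c(manifest$artifacts, "simulated_features.csv",
                            "simulated_samples.csv", "simulated_truth.csv")
  } else {
    samples <- read_sample_metadata(paste0(config$input_stem, "_samples.csv"))
    tab <- read_feature_table(paste0(config$input_stem, "_features.csv"), samples)
    ds <- list(table = tab, samples = samples, truth = NULL)
  }
  samples <- ds$samples

  corrected <- correct_drift(ds$table, samples, window = config$window)
  write_table(corrected, art("corrected_features.csv"))
  manifest$n_passthrough_features <- length(attr(corrected, "passthrough"))

  qc_report <- compute_feature_qc(corrected, samples, config$thresholds)
  write_table(as.data.frame(qc_report), art("feature_qc_report.csv"))

  kept_features <- filter_features(qc_report, config$thresholds)
  manifest$n_features_in <- nrow(ds$table)
  manifest$n_features_kept <- length(kept_features)
  if (!length(kept_features)) stop("data error: no features pass the QC filter")
  filtered <- feature_table(unclass(corrected)[kept_features, , drop = FALSE],
                            "corrected")

  kept_subjects <- filter_subjects(filtered, samples,
                                   config$thresholds$missing_max_fraction)
  manifest$n_subjects_kept <- length(kept_subjects)
  drop_cols <- samples$sample_type == "study" &
    !(samples$subject_id %in% kept_subjects)
  if (any(drop_cols)) {
    keep_ids <- samples$sample_id[!drop_cols]
    filtered <- feature_table(
      unclass(filtered)[, keep_ids, drop = FALSE], "corrected")
    samples <- samples[!drop_cols, , drop = FALSE]
  }

  imputed <- impute_lod(filtered, samples)
  manifest$n_values_imputed <- attr(imputed, "n_replaced")
  log_table <- log_transform(imputed, samples)
  write_table(log_table, art("log10_features.csv"))

  z_table <- z_normalize(log_table, samples)
  write_table(z_table, art("zscore_features.csv"))

  anova_log10 <- anova_table(log_table, samples, mode = "log10")
  anova_zscore <- anova_table(z_table, samples, mode = "zscore")
  write_table(rbind(anova_log10, anova_zscore), art("anova_table.csv"))

  test_tab <- if (config$test_scale == "zscore") z_table else log_table
  tests <- paired_tests(test_tab, samples, alpha = config$alpha_untargeted)
  pmat <- as.data.frame(tests$p)
  pmat <- cbind(feature_id = rownames(tests$p), pmat)
  rownames(pmat) <- NULL
  write_table(pmat, art("pvalue_matrix.csv"))

  classification <- classify_features(tests)
  write_table(classification, art("classification.csv"))
  summ <- summarize_classification(classification, tests)
  cat_df <- data.frame(category = names(summ$category_counts),
                       count = as.integer(summ$category_counts),
                       fraction = as.numeric(summ$category_fractions))
  write_table(cat_df, art("classification_summary.csv"))

  manifest$artifacts <- c(manifest$artifacts, "corrected_features.csv",
                          "feature_qc_report.csv", "log10_features.csv",
                          "zscore_features.csv", "anova_table.csv",
                          "pvalue_matrix.csv", "classification.csv",
                          "classification_summary.csv")
  manifest$sleep_related_fraction <- summ$sleep_related_fraction
  jsonlite::write_json(manifest, art("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(samples = samples, qc_report = qc_report,
                 kept_features = kept_features,
                 kept_subjects = kept_subjects,
                 log_table = log_table, z_table = z_table,
                 anova_log10 = anova_log10, anova_zscore = anova_zscore,
                 tests = tests, classification = classification,
                 summary = summ, manifest = manifest))
}

# --- minimal subcommand CLI -------------------------------------------------

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("config error: unexpected argument '", a, "'")
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1
    } else {
      flags[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  flags
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}
flag_chr <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.character(flags[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `correct`, `qc`, `filter`, `analyze`,
#' `classify`, `run-all`, `report`. Shared flags: `--stem` (input path
#' stem), `--out` (output path or directory), `--seed`, `--alpha`,
#' `--scale {log10,zscore}`, `--window`, `--n-features`, `--n-subjects`.
#' Designed to be called from `Rscript -e
#' 'sleepmetab::sleepmetab_cli()'`.
#'
#' @param args Character vector of command-line arguments; defaults to the
#'   process's trailing arguments.
#' @return Integer exit status, invisibly: 0 ok, 2 config error, 3 data
#'   error, 4 stage failure.
#' @export
sleepmetab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: sleepmetab <simulate|correct|qc|filter|analyze|classify|run-all|report> [--flags]\n")
    return(invisible(2L))
  }
  cmd <- args[1]
  status <- tryCatch({
    flags <- parse_flags(args[-1])
    switch(cmd,
      "simulate" = {
        cfg <- sim_config(
          n_subjects = flag_num(flags, "n-subjects", 13),
          n_features = flag_num(flags, "n-features", 200),
          seed = flag_num(flags, "seed", 1))
        write_dataset(generate_dataset(cfg), flag_chr(flags, "out", "simulated"))
        0L
      },
      "correct" = {
        stem <- flag_chr(flags, "stem", stop("config error: --stem required"))
        samples <- read_sample_metadata(paste0(stem, "_samples.csv"))
        tab <- read_feature_table(paste0(stem, "_features.csv"), samples)
        corr <- correct_drift(tab, samples, window = flag_num(flags, "window", 8))
        write_table(corr, flag_chr(flags, "out", paste0(stem, "_corrected.csv")))
        0L
      },
      "qc" = {
        stem <- flag_chr(flags, "stem", stop("config error: --stem required"))
        samples <- read_sample_metadata(paste0(stem, "_samples.csv"))
        tab <- read_feature_table(paste0(stem, "_corrected.csv"), samples,
                                  scale_tag = "corrected")
        rep_df <- compute_feature_qc(tab, samples)
        write_table(as.data.frame(rep_df),
                    flag_chr(flags, "out", paste0(stem, "_qc_report.csv")))
        0L
      },
      "run-all" = ,
      "filter" = ,
      "analyze" = ,
      "classify" = ,
      "report" = {
        cfg <- pipeline_config(
          out_dir = flag_chr(flags, "out", "sleepmetab_run"),
          input_stem = flags[["stem"]],
          seed = flag_num(flags, "seed", 1),
          window = flag_num(flags, "window", 8),
          alpha_untargeted = flag_num(flags, "alpha", 0.01),
          test_scale = flag_chr(flags, "scale", "log10"),
          sim = sim_config(
            n_subjects = flag_num(flags, "n-subjects", 13),
            n_features = flag_num(flags, "n-features", 200)))
        run_all(cfg)
        0L
      },
      stop("config error: unknown subcommand '", cmd, "'")
    )
  }, error = function(e) {
    message("sleepmetab ", cmd, ": ", conditionMessage(e))
    if (grepl("config error", conditionMessage(e))) 2L
    else if (grepl("data error|validation|unknown sample|duplicate",
                   conditionMessage(e))) 3L
    else 4L
  })
  invisible(status)
}
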