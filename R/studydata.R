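# ---------------------------------------------------------------------------
# Sample metadata -----------------------------------------------------------

SAMPLE_COLUMNS <- c("sample_id", "sample_type", "subject_id", "condition",
                    "timepoint", "run_order", "batch", "dilution_fraction",
                    "clock_hour")

#' Validate a sample-metadata table
#'
#' Checks the invariants of the injection metadata: unique `sample_id` and
#' `run_order`; study samples carry `subject_id`, `condition`, `timepoint`
#' and each (subject, condition, timepoint) triple occurs at most once;
#' `dilution_fraction` in (0, 1] is present exactly for dilution-series
#' injections; non-study samples carry no subject/condition/timepoint.
#'
#' @param samples A data.frame with the columns of [read_sample_metadata()].
#' @return The validated data.frame, invisibly, with enum columns
#'   canonicalized to lower case.
#' @export
validate_samples <- function(samples) {
  if (!is.data.frame(samples)) stop("samples must be a data.frame")
  missing_cols <- setdiff(setdiff(SAMPLE_COLUMNS, "clock_hour"), names(samples))
  if (length(missing_cols)) {
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"clock_hour" %in% names(samples)) samples$clock_hour <- NA_real_

  samples$sample_id <- as.character(samples$sample_id)
  # enums parse case-insensitively; subject_id is an identifier, case kept
  for (col in c("sample_type", "subject_id", "condition", "timepoint")) {
    x <- trimws(as.character(samples[[col]]))
    if (col != "subject_id") x <- tolower(x)
    x[x %in% c("", "na", "nan", "NA", "NaN")] <- NA_character_
    samples[[col]] <- x
  }
  samples$run_order <- as.integer(samples$run_order)
  samples$batch <- as.integer(samples$batch)
  samples$dilution_fraction <- as.numeric(samples$dilution_fraction)
  samples$clock_hour <- as.numeric(samples$clock_hour)

  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  dup_ro <- unique(samples$run_order[duplicated(samples$run_order)])
  if (length(dup_ro)) {
    offenders <- samples$sample_id[samples$run_order %in% dup_ro]
    stop("duplicate run_order (", paste(dup_ro, collapse = ", "),
         ") for samples: ", paste(offenders, collapse = ", "))
  }
  if (anyNA(samples$run_order) || any(samples$run_order < 1)) {
    stop("run_order must be a positive integer for every sample")
  }
  if (anyNA(samples$batch) || any(samples$batch < 1)) {
    stop("batch must be a positive integer for every sample")
  }
  bad_type <- setdiff(unique(samples$sample_type), SAMPLE_TYPE_LEVELS)
  if (length(bad_type) || anyNA(samples$sample_type)) {
    stop("sample_type must be one of: ", paste(SAMPLE_TYPE_LEVELS, collapse = ", "))
  }

  is_study <- samples$sample_type == "study"
  need <- c("subject_id", "condition", "timepoint")
  for (col in need) {
    lacking <- is_study & is.na(samples[[col]])
    if (any(lacking)) {
      stop("study sample(s) lacking ", col, ": ",
           paste(samples$sample_id[lacking], collapse = ", "))
    }
    stray <- !is_study & !is.na(samples[[col]])
    if (any(stray)) {
      stop("non-study sample(s) must not carry ", col, ": ",
           paste(samples$sample_id[stray], collapse = ", "))
    }
  }
  bad_cond <- is_study & !samples$condition %in% CONDITION_LEVELS
  if (any(bad_cond)) {
    stop("invalid condition for: ", paste(samples$sample_id[bad_cond], collapse = ", "))
  }
  bad_tp <- is_study & !samples$timepoint %in% TIMEPOINT_LEVELS
  if (any(bad_tp)) {
    stop("invalid timepoint for: ", paste(samples$sample_id[bad_tp], collapse = ", "))
  }
  key <- paste(samples$subject_id, samples$condition, samples$timepoint)[is_study]
  if (anyDuplicated(key)) {
    stop("duplicated (subject, condition, timepoint) triple(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }

  is_dil <- samples$sample_type == "dilution"
  if (any(is_dil & is.na(samples$dilution_fraction))) {
    stop("dilution sample(s) lacking dilution_fraction: ",
         paste(samples$sample_id[is_dil & is.na(samples$dilution_fraction)],
               collapse = ", "))
  }
  if (any(!is_dil & !is.na(samples$dilution_fraction))) {
    stop("dilution_fraction present on non-dilution sample(s): ",
         paste(samples$sample_id[!is_dil & !is.na(samples$dilution_fraction)],
               collapse = ", "))
  }
  df <- samples$dilution_fraction[is_dil]
  if (any(df <= 0 | df > 1)) stop("dilution_fraction must lie in (0, 1]")

  invisible(samples)
}

#' Read injection (sample) metadata from CSV
#'
#' One row per injection; comma-separated, UTF-8, header mandatory. Enum
#' fields are parsed case-insensitively; empty cells, "NA" and "NaN" denote
#' absent values.
#'
#' @param path Path to a CSV file with columns `sample_id`, `sample_type`,
#'   `subject_id`, `condition`, `timepoint`, `run_order`, `batch`,
#'   `dilution_fraction` and optionally `clock_hour`.
#' @return A validated data.frame of sample records, ordered as on file.
#' @export
read_sample_metadata <- function(path) {
  samples <- utils::read.csv(path, colClasses = "character",
                             check.names = FALSE, na.strings = character())
  validate_samples(samples)
}

#' Write sample metadata to CSV
#'
#' @param samples Validated sample metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(samples, path) {
  samples <- validate_samples(samples)
  write_table(samples[SAMPLE_COLUMNS], path)
}

# ---------------------------------------------------------------------------
# Feature table --------------------------------------------------------------

SCALE_TAGS <- c("raw", "corrected", "log10", "zscore")

#' Construct a feature abundance table
#'
#' A features x injections matrix with explicit missingness and a scale tag.
#' Raw and drift-corrected tables must be non-negative; log10 and z-score
#' tables may contain any real value.
#'
#' @param values Numeric matrix, rows = features, columns = samples; both
#'   dimnames required and unique. `NA` encodes a missing measurement.
#' @param scale_tag One of "raw", "corrected", "log10", "zscore".
#' @return An object of class `feature_table` (a matrix with attributes).
#' @export
feature_table <- function(values, scale_tag = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  scale_tag <- match.arg(scale_tag, SCALE_TAGS)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("values must carry feature ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (scale_tag %in% c("raw", "corrected")) {
    neg <- which(values < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      stop("negative value on ", scale_tag, " scale at feature '",
           rownames(values)[neg[1, 1]], "', sample '",
           colnames(values)[neg[1, 2]], "'")
    }
  }
  structure(values, scale_tag = scale_tag, class = c("feature_table", "matrix"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples, scale = %s, %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "scale_tag"),
              100 * mean(is.na(x))))
  invisible(x)
}

scale_tag <- function(table) attr(table, "scale_tag")

stopifnot_scale <- function(table, allowed) {
  if (!inherits(table, "feature_table")) stop("expected a feature_table")
  tag <- scale_tag(table)
  if (!tag %in% allowed) {
    stop("table is on '", tag, "' scale; expected ",
         paste(allowed, collapse = " or "))
  }
  invisible(table)
}

#' Read a feature abundance table from CSV
#'
#' Rows are features, columns are injections; the first column must be
#' `feature_id`. Empty cells, "NA" and "NaN" (case-insensitive) are missing.
#'
#' @param path CSV path.
#' @param samples Sample metadata the columns must match (every abundance
#'   column must name a known sample).
#' @param scale_tag Scale of the stored values (default "raw").
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, samples, scale_tag = "raw") {
  samples <- validate_samples(samples)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  if (!ncol(raw) || names(raw)[1] != "feature_id") {
    stop("first column of a feature table must be 'feature_id'")
  }
  ids <- raw$feature_id
  sample_ids <- names(raw)[-1]
  unknown <- setdiff(sample_ids, samples$sample_id)
  if (length(unknown)) {
    stop("unknown sample column(s): ", paste(unknown, collapse = ", "))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[vals %in% c("", "NA", "na", "Na", "NaN", "nan")] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric value '", vals[bad[1, , drop = FALSE]],
         "' at feature '", ids[bad[1, 1]], "', sample '",
         sample_ids[bad[1, 2]], "'")
  }
  dimnames(num) <- list(ids, sample_ids)
  if (scale_tag %in% c("raw", "corrected")) {
    neg <- which(num < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      stop("negative value at feature '", ids[neg[1, 1]],
           "', sample '", sample_ids[neg[1, 2]], "'")
    }
  }
  feature_table(num, scale_tag = scale_tag)
}

#' Write a table to CSV
#'
#' Deterministic column order, missing values written as empty strings,
#' comma-separated, UTF-8. Reading the output back reproduces the object up
#' to floating-point formatting (15 significant digits).
#'
#' @param obj A `feature_table` or any data.frame (QC reports, result
#'   tables).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) {
  UseMethod("write_table")
}

#' @export
write_table.feature_table <- function(obj, path) {
  df <- as.data.frame(format_numeric(unclass(obj)), stringsAsFactors = FALSE,
                      check.names = FALSE, optional = TRUE)
  df <- cbind(feature_id = rownames(obj), df)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
write_table.data.frame <- function(obj, path) {
  out <- obj
  for (i in seq_along(out)) {
    if (is.numeric(out[[i]]) && !is.integer(out[[i]])) {
      out[[i]] <- format_numeric(out[[i]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# 15 significant digits keeps write -> read -> write byte-stable
format_numeric <- function(x) {
  out <- ifelse(is.na(x), NA_character_,
                formatC(x, digits = 15, format = "g"))
  if (is.matrix(x)) dim(out) <- dim(x)
  if (!is.null(dimnames(x))) dimnames(out) <- dimnames(x)
  out
}

study_idx <- function(samples) which(samples$sample_type == "study")
qc_idx    <- function(samples) which(samples$sample_type == "qc_pool")
blank_idx <- function(samples) which(samples$sample_type == "blank")
dil_idx   <- function(samples) which(samples$sample_type == "dilution")

# align metadata rows to the table's column order; errors on mismatch
align_samples <- function(table, samples) {
  samples <- validate_samples(samples)
  i <- match(colnames(table), samples$sample_id)
  if (anyNA(i)) {
    stop("table columns missing from metadata: ",
         paste(colnames(table)[is.na(i)], collapse = ", "))
  }
  samples[i, , drop = FALSE]
}
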