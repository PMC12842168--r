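MANIFEST_MANDATORY <- c("file", "patient_id", "access_type", "site", "group")
MANIFEST_OPTIONAL <- c("phase", "stenosis_pct", "age", "sex")

#' Read a recording manifest
#'
#' Reads a comma-separated manifest with one row per recording. Mandatory
#' columns: `file`, `patient_id`, `access_type`, `site`, `group`; optional:
#' `phase`, `stenosis_pct`, `age`, `sex`. Columns whose names start with
#' `gt_` carry simulator ground truth and are passed through untouched.
#' Empty cells denote missing values; numeric missing data are never
#' encoded as 0.
#'
#' Each row is validated against the metadata invariants (e.g. an
#' anastomosis row must be AVF). Invalid rows are reported together, by
#' row number, as a fatal error.
#'
#' @param path Path to a CSV manifest.
#' @return A data frame of validated metadata rows (plus any `gt_`
#'   ground-truth columns), one per recording.
#' @seealso [write_features()], [generate_cohort()]
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest_unreadable: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop(sprintf(
      "manifest_unreadable: %s (%s)", path, conditionMessage(e)),
      call. = FALSE)
  )
  if (nrow(df) == 0 && ncol(df) == 0) {
    stop("manifest_empty: no header or rows", call. = FALSE)
  }
  missing_cols <- setdiff(MANIFEST_MANDATORY, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("manifest_missing_column: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("stenosis_pct", "age")) {
    if (col %in% names(df)) {
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    } else {
      df[[col]] <- NA_real_
    }
  }
  if (!"phase" %in% names(df)) df$phase <- "none"
  df$phase[is.na(df$phase) | df$phase == ""] <- "none"
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  df$sex[!is.na(df$sex) & df$sex == ""] <- NA_character_

  errors <- character(0)
  for (i in seq_len(nrow(df))) {
    res <- tryCatch({
      metadata_from_row(df[i, ])
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      errors <- c(errors, sprintf("row %d: %s", i, res))
    }
  }
  if (length(errors) > 0) {
    stop(sprintf("manifest_invalid_rows:\n%s",
                 paste(errors, collapse = "\n")), call. = FALSE)
  }
  df
}

FEATURE_COLUMNS <- c("mean_peak", "mean_valley", "peak_valley_ratio",
                     "low_frequency_pct", "n_peaks", "n_valleys",
                     "n_rejected_peaks", "n_rejected_valleys", "flags")

#' Write extracted features to CSV
#'
#' One row per recording: the four acoustic features (mean peak, mean
#' valley, peak-to-valley ratio, low-frequency percentage), peak/valley
#' counts and QC flags, plus the acquisition metadata. Undefined features
#' (e.g. a ratio with no valleys) are written as empty cells, never as a
#' sentinel number. The file round-trips losslessly through
#' [read_features()].
#'
#' @param features A list of `acoustic_features` objects (from
#'   [extract_features()]) or a feature data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  df <- features_as_table(features)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) {
    stop(sprintf("features_unwritable: directory does not exist: %s",
                 dirname(path)), call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return A data frame with one row per recording.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("features_unreadable: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num_cols <- intersect(
    c("mean_peak", "mean_valley", "peak_valley_ratio", "low_frequency_pct",
      "stenosis_pct", "age"), names(df))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  int_cols <- intersect(c("n_peaks", "n_valleys", "n_rejected_peaks",
                          "n_rejected_valleys"), names(df))
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  if ("flags" %in% names(df)) {
    df$flags <- as.character(df$flags)
    df$flags[is.na(df$flags)] <- ""
  }
  chr_cols <- intersect(c("patient_id", "access_type", "site", "group",
                          "phase", "sex"), names(df))
  for (col in chr_cols) df[[col]] <- as.character(df[[col]])
  df
}

features_as_table <- function(features) {
  if (is.data.frame(features)) return(features)
  if (inherits(features, "acoustic_features")) features <- list(features)
  if (length(features) == 0) {
    cols <- c("patient_id", "access_type", "site", "group", "phase",
              "stenosis_pct", "age", "sex", FEATURE_COLUMNS)
    df <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(cols)), cols),
      stringsAsFactors = FALSE)
    return(df)
  }
  rows <- lapply(features, function(f) {
    stopifnot(inherits(f, "acoustic_features"))
    cbind(metadata_as_row(f$metadata), as.data.frame.acoustic_features(f))
  })
  do.call(rbind, rows)
}
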