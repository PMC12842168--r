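#' Extract features for every recording in a manifest
#'
#' Reads each WAV file listed in a manifest, runs the full feature
#' pipeline, and returns the combined feature table. Recordings that fail
#' (e.g. silent files) are reported and returned with `NA` features and a
#' flag rather than aborting the batch.
#'
#' @param manifest A manifest data frame (see [read_manifest()]) or path
#'   to a manifest CSV.
#' @param dir Directory the manifest's `file` column is relative to;
#'   defaults to the manifest's own directory when `manifest` is a path,
#'   otherwise the working directory.
#' @param config A [pipeline_config()].
#' @return A feature data frame, one row per manifest row, including any
#'   `gt_` ground-truth columns from the manifest.
#' @export
extract_manifest <- function(manifest, dir = NULL,
                             config = pipeline_config()) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(dir)) dir <- "."
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    md <- metadata_from_row(manifest[i, ])
    path <- file.path(dir, manifest$file[i])
    feats <- tryCatch(
      extract_features(read_recording(path, md, config), config),
      error = function(e) {
        message(sprintf("row %d (%s): %s", i, manifest$file[i],
                        conditionMessage(e)))
        structure(
          list(mean_peak = NA_real_, mean_valley = NA_real_,
               peak_valley_ratio = NA_real_, low_frequency_pct = NA_real_,
               n_peaks = 0L, n_valleys = 0L, n_rejected_peaks = 0L,
               n_rejected_valleys = 0L,
               flags = sub(":.*$", "", conditionMessage(e)),
               metadata = md),
          class = "acoustic_features")
      })
    row <- cbind(metadata_as_row(md), as.data.frame(feats))
    gt_cols <- grep("^gt_", names(manifest), value = TRUE)
    if (length(gt_cols) > 0) row <- cbind(row, manifest[i, gt_cols,
                                                        drop = FALSE])
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract features for an in-memory cohort
#'
#' Convenience wrapper over [extract_features()] for the output of
#' [generate_cohort()]: extracts every recording and joins the features
#' onto the cohort manifest (including its ground-truth columns).
#'
#' @param cohort A list with `recordings` and `manifest`, as returned by
#'   [generate_cohort()].
#' @param config A [pipeline_config()].
#' @return A feature data frame, one row per recording.
#' @export
extract_cohort <- function(cohort, config = pipeline_config()) {
  feats <- lapply(cohort$recordings, extract_features, config = config)
  df <- do.call(rbind, lapply(feats, as.data.frame))
  rownames(df) <- NULL
  cbind(cohort$manifest, df)
}
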