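FEATURES_REPORTED <- c("mean_peak", "mean_valley", "peak_valley_ratio",
                       "low_frequency_pct")
SITE_ORDER <- c("anastomosis", "arterial_puncture", "venous_puncture")

#' Build a cohort report of acoustic features
#'
#' Produces the standard cohort table: per access type, recording site and
#' feature, a summary for every group plus a p-value against the
#' designated reference group, and -- when pre/post-angioplasty phases are
#' present -- a paired pre-vs-post comparison per dysfunction group.
#' Summaries and test choices follow [summarize_feature()],
#' [compare_unpaired()] and [compare_paired()]. Undefined feature values
#' are excluded from summaries and tests and tallied in the QC table.
#' No multiple-testing correction is applied across cells: each
#' comparison stands alone at `alpha` (a faithful-reproduction choice,
#' not a statistical endorsement; see the package vignette).
#'
#' Group comparisons use the pre-angioplasty (or phase-free) recordings.
#' For AVG cohorts the anastomosis rows are reported as `"N/A"`: grafts
#' have no auscultable anastomosis site.
#'
#' @param features A feature data frame (from [read_features()],
#'   [features_as_table()], or [extract_features()] rows bound together).
#' @param reference_group Group label others are compared against.
#' @param alpha Significance level.
#' @return An object of class `cohort_report` with `group_table`,
#'   `paired_table` and `qc` data frames.
#' @export
build_report <- function(features, reference_group = "normal",
                         alpha = 0.05) {
  df <- features_as_table(features)
  needed <- c("site", "group", "access_type", FEATURES_REPORTED)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("report_missing_columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!"phase" %in% names(df)) df$phase <- "none"

  pre <- df[df$phase != "post_PTA", , drop = FALSE]
  group_rows <- list()
  qc_rows <- list()
  for (acc in unique(df$access_type)) {
    sub_acc <- pre[pre$access_type == acc, , drop = FALSE]
    groups <- unique(sub_acc$group)
    multi <- length(groups) > 1
    if (multi && !reference_group %in% groups) {
      stop(sprintf("report_reference_missing: no '%s' group among %s for %s",
                   reference_group, paste(groups, collapse = ", "), acc),
           call. = FALSE)
    }
    sites <- intersect(SITE_ORDER, unique(sub_acc$site))
    if (acc == "AVG") sites <- union(sites, "anastomosis")
    for (site in intersect(SITE_ORDER, sites)) {
      sub <- sub_acc[sub_acc$site == site, , drop = FALSE]
      for (feat in FEATURES_REPORTED) {
        for (grp in groups) {
          x <- sub[[feat]][sub$group == grp]
          na_here <- acc == "AVG" && site == "anastomosis"
          summ <- if (na_here) NULL else summarize_feature(x, alpha)
          pval <- NA_real_
          test <- ""
          if (!na_here && multi && grp != reference_group) {
            ref <- sub[[feat]][sub$group == reference_group]
            cmp <- tryCatch(
              compare_unpaired(ref, x, alpha, feature = feat,
                               labels = c(reference_group, grp)),
              error = function(e) NULL)
            if (!is.null(cmp)) {
              pval <- cmp$p_value
              test <- cmp$test_used
            }
          }
          group_rows[[length(group_rows) + 1L]] <- data.frame(
            access_type = acc, site = site, feature = feat, group = grp,
            n = if (na_here) NA_integer_ else summ$n,
            summary = if (na_here) "N/A" else summ$label,
            p_value = pval, test = test,
            significant = !is.na(pval) && pval < alpha,
            stringsAsFactors = FALSE)
          qc_rows[[length(qc_rows) + 1L]] <- data.frame(
            access_type = acc, site = site, feature = feat, group = grp,
            n_undefined = if (na_here) NA_integer_ else sum(is.na(x)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  group_table <- do.call(rbind, group_rows)

  paired_table <- NULL
  has_phases <- all(c("pre_PTA", "post_PTA") %in% df$phase) &&
    "patient_id" %in% names(df)
  if (has_phases) {
    paired_rows <- list()
    both <- df[df$phase %in% c("pre_PTA", "post_PTA"), , drop = FALSE]
    for (acc in unique(both$access_type)) {
      for (grp in setdiff(unique(both$group[both$access_type == acc]),
                          reference_group)) {
        for (site in intersect(SITE_ORDER, unique(both$site))) {
          sub <- both[both$access_type == acc & both$group == grp &
                        both$site == site, , drop = FALSE]
          pre_sub <- sub[sub$phase == "pre_PTA", , drop = FALSE]
          post_sub <- sub[sub$phase == "post_PTA", , drop = FALSE]
          common <- intersect(pre_sub$patient_id, post_sub$patient_id)
          if (length(common) < 3) next
          pre_sub <- pre_sub[match(common, pre_sub$patient_id), ]
          post_sub <- post_sub[match(common, post_sub$patient_id), ]
          for (feat in FEATURES_REPORTED) {
            cmp <- tryCatch(
              compare_paired(pre_sub[[feat]], post_sub[[feat]], alpha,
                             feature = feat),
              error = function(e) NULL)
            if (is.null(cmp)) next
            paired_rows[[length(paired_rows) + 1L]] <- data.frame(
              access_type = acc, site = site, feature = feat, group = grp,
              n_pairs = length(common) - cmp$n_excluded,
              pre_summary = cmp$summaries[[1]]$label,
              post_summary = cmp$summaries[[2]]$label,
              p_value = cmp$p_value, test = cmp$test_used,
              significant = cmp$significant, stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(paired_rows) > 0) paired_table <- do.call(rbind, paired_rows)
  }

  structure(
    list(group_table = group_table, paired_table = paired_table,
         qc = do.call(rbind, qc_rows), alpha = alpha,
         reference_group = reference_group),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> reference group:", x$reference_group,
      "| alpha:", x$alpha, "\n\n")
  gt <- x$group_table
  gt$p <- ifelse(is.na(gt$p_value), "",
                 sprintf("%s%.3g", ifelse(gt$significant, "* ", ""),
                         gt$p_value))
  print(gt[, c("access_type", "site", "feature", "group", "n", "summary",
               "p")], row.names = FALSE)
  if (!is.null(x$paired_table)) {
    cat("\nPaired pre/post-angioplasty comparisons:\n")
    pt <- x$paired_table
    pt$p <- sprintf("%s%.3g", ifelse(pt$significant, "* ", ""), pt$p_value)
    print(pt[, c("access_type", "site", "feature", "group", "n_pairs",
                 "pre_summary", "post_summary", "p")], row.names = FALSE)
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Writes the group table (and paired table, when present) as CSV and the
#' full report as JSON.
#'
#' @param report A `cohort_report` from [build_report()].
#' @param path Output path stem; `.csv` / `_paired.csv` / `.json` are
#'   appended.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  utils::write.csv(report$group_table, paste0(path, ".csv"),
                   row.names = FALSE, na = "")
  if (!is.null(report$paired_table)) {
    utils::write.csv(report$paired_table, paste0(path, "_paired.csv"),
                     row.names = FALSE, na = "")
  }
  jsonlite::write_json(
    list(group_table = report$group_table,
         paired_table = report$paired_table, qc = report$qc,
         alpha = report$alpha, reference_group = report$reference_group),
    paste0(path, ".json"), dataframe = "rows", na = "null",
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
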