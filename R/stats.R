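# Cohort statistics: per-subgroup accuracy summaries, splits of the
# derotation group by planned amount and staging, normality and paired
# testing, and overall efficacy.
#
# Unit convention, stated prominently because it is easy to trip over:
# mean/highest/lowest accuracies are percentages, while the standard
# deviation is reported as a dimensionless fraction of the efficacy ratio
# (sd = 0.2 means 20 percentage points). This mirrors how clinical
# aligner-efficacy tables print "mean accuracy 37.5 / SD 0.3".

#' Statistics configuration
#'
#' @param alpha Significance threshold (default 0.05).
#' @param amount_threshold_deg Planned-amount split point for the
#'   derotation group, degrees (default 15).
#' @param staging_threshold_deg_per_aligner Staging split point, degrees
#'   per aligner (default 1.5).
#' @return List of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, amount_threshold_deg = 15,
                         staging_threshold_deg_per_aligner = 1.5) {
  cm_assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)", "config_error")
  structure(list(alpha = alpha,
                 amount_threshold_deg = amount_threshold_deg,
                 staging_threshold_deg_per_aligner =
                   staging_threshold_deg_per_aligner),
            class = "stats_config")
}

#' Summarize the efficacy of a set of movements
#'
#' Computes n, mean/highest/lowest accuracy (percent), the sample standard
#' deviation of the efficacy ratio (as a fraction; undefined and reported
#' as `NA` for n = 1), and the two-sided paired t-test p-value of achieved
#' versus predicted movement (`NA` when fewer than two records).
#'
#' @param records Efficacy-record data frame (see [measure_patient()]);
#'   must be non-empty.
#' @param label Row label.
#' @return One-row data frame: `label`, `n`, `mean_accuracy`, `highest`,
#'   `lowest`, `sd`, `p_value`.
#' @export
summarize_group <- function(records, label = "") {
  cm_assert(is.data.frame(records), "records must be a data frame",
            "config_error")
  if (nrow(records) == 0L)
    cm_stop("cannot summarize an empty record set", "config_error")
  eff <- records$efficacy_percent
  cm_assert(is.numeric(eff) && all(is.finite(eff)),
            "records must carry finite efficacy_percent values",
            "config_error")
  n <- length(eff)
  sd_frac <- if (n >= 2L) sd(eff / 100) else NA_real_
  p <- NA_real_
  if (n >= 2L && !is.null(records$achieved) && !is.null(records$predicted)) {
    p <- tryCatch(paired_t(records$achieved, records$predicted)$p,
                  castmove_degenerate_test_error = function(e) NA_real_)
  }
  data.frame(label = label, n = n, mean_accuracy = mean(eff),
             highest = max(eff), lowest = min(eff), sd = sd_frac,
             p_value = p, stringsAsFactors = FALSE)
}

#' Overall efficacy across subgroups
#'
#' The unweighted arithmetic mean of the subgroup mean accuracies. The
#' unweighted mean is used deliberately: pooling subgroups of unequal size
#' by simple averaging is how the overall figure is quoted in the clinical
#' literature this package mirrors (a movement-count-weighted mean gives a
#' different value; see the methods vignette).
#'
#' @param subgroup_rows Data frame of [summarize_group()] rows (>= 1).
#' @return Percent.
#' @export
overall_efficacy <- function(subgroup_rows) {
  cm_assert(is.data.frame(subgroup_rows) && nrow(subgroup_rows) >= 1L &&
              "mean_accuracy" %in% names(subgroup_rows),
            "subgroup_rows must be a non-empty summary data frame",
            "config_error")
  mean(subgroup_rows$mean_accuracy)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Shapiro-Wilk W statistic, with the
#' degenerate zero-variance case reported as an explicit error.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  cm_assert(all(is.finite(values)), "values must be finite", "config_error")
  if (length(values) < 3L || length(values) > 5000L)
    cm_stop("Shapiro-Wilk requires 3 <= n <= 5000", "config_error")
  if (sd(values) == 0)
    cm_stop("Shapiro-Wilk is degenerate for a constant sample (zero variance)",
            "degenerate_test_error")
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p = unname(st$p.value))
}

#' Paired t-test of achieved versus predicted movement
#'
#' Two-sided paired Student t-test on the differences
#' `achieved - predicted`. Under-achievement (achieved smaller than
#' predicted on average) gives a negative t. Identical vectors return
#' `t = 0, p = 1`; nonzero constant differences are a degenerate test and
#' raise an error.
#'
#' @param achieved,predicted Equal-length numeric vectors, n >= 2.
#' @return List with `t` and `p`.
#' @export
paired_t <- function(achieved, predicted) {
  achieved <- as.numeric(achieved)
  predicted <- as.numeric(predicted)
  cm_assert(length(achieved) == length(predicted) && length(achieved) >= 2L,
            "paired t-test needs equal-length vectors with n >= 2",
            "config_error")
  cm_assert(all(is.finite(achieved)) && all(is.finite(predicted)),
            "paired t-test inputs must be finite", "config_error")
  d <- achieved - predicted
  if (all(d == 0)) return(list(t = 0, p = 1))
  if (sd(d) == 0)
    cm_stop("paired t-test is degenerate: differences have zero variance",
            "degenerate_test_error")
  tt <- t.test(achieved, predicted, paired = TRUE)
  list(t = unname(tt$statistic), p = unname(tt$p.value))
}

#' Split the derotation records by planned amount and staging
#'
#' Partitions derotation records at the configured thresholds (planned
#' total vs `amount_threshold_deg`; staging vs
#' `staging_threshold_deg_per_aligner`). Records exactly at a threshold go
#' to the lower bin (a fixed, documented boundary rule). Empty partitions
#' produce a row with n = 0 and missing statistics.
#'
#' @param records Efficacy records, all from the derotation group.
#' @param config A [stats_config()].
#' @return List with data frames `by_amount` and `by_staging`.
#' @export
split_tables <- function(records, config = stats_config()) {
  cm_assert(is.data.frame(records) && nrow(records) >= 1L,
            "records must be a non-empty data frame", "config_error")
  cm_assert(all(records$group == "derotation"),
            "split tables are defined for the derotation group only",
            "config_error")
  empty_row <- function(label) data.frame(
    label = label, n = 0L, mean_accuracy = NA_real_, highest = NA_real_,
    lowest = NA_real_, sd = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE)
  side <- function(sel, label) {
    if (any(sel)) summarize_group(records[sel, , drop = FALSE], label)
    else empty_row(label)
  }
  a <- config$amount_threshold_deg
  s <- config$staging_threshold_deg_per_aligner
  low_amount <- records$planned_total <= a
  low_staging <- records$staging_per_aligner <= s
  list(
    by_amount = rbind(
      side(low_amount, sprintf("derotation <= %g deg", a)),
      side(!low_amount, sprintf("derotation > %g deg", a))),
    by_staging = rbind(
      side(low_staging, sprintf("derotation <= %g deg/aligner", s)),
      side(!low_staging, sprintf("derotation > %g deg/aligner", s))))
}

#' Cohort report
#'
#' Summarizes a cohort of efficacy records into the standard tables: one
#' accuracy row per (group, subgroup), derotation splits by planned amount
#' and staging, and the overall (unweighted) efficacy. Optionally written
#' to CSV plus a human-readable text summary; deterministic given inputs.
#'
#' @param records Efficacy-record data frame (non-empty).
#' @param config A [stats_config()].
#' @param out_dir Output directory for CSV/text files, or `NULL` to skip
#'   writing.
#' @return List with `by_subgroup`, `by_amount`, `by_staging` (or `NULL`),
#'   `overall_efficacy_percent`, and `files` (written paths), invisibly
#'   when writing.
#' @export
efficacy_report <- function(records, config = stats_config(), out_dir = NULL) {
  cm_assert(is.data.frame(records), "records must be a data frame",
            "config_error")
  if (nrow(records) == 0L)
    cm_stop("cannot report on an empty cohort", "config_error")
  combos <- unique(records[, c("group", "subgroup")])
  combos <- combos[order(combos$group, combos$subgroup), , drop = FALSE]
  by_subgroup <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- records$group == combos$group[i] &
      records$subgroup == combos$subgroup[i]
    summarize_group(records[sel, , drop = FALSE],
                    sprintf("%s/%s", combos$group[i], combos$subgroup[i]))
  }))
  dero <- records[records$group == "derotation", , drop = FALSE]
  splits <- if (nrow(dero) > 0L) split_tables(dero, config) else NULL
  overall <- overall_efficacy(by_subgroup)
  out <- list(by_subgroup = by_subgroup,
              by_amount = splits$by_amount,
              by_staging = splits$by_staging,
              overall_efficacy_percent = overall)
  if (is.null(out_dir)) return(out)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(file.path(out_dir, "accuracy_by_subgroup.csv"),
             file.path(out_dir, "report.txt"))
  write.csv(by_subgroup, files[1], row.names = FALSE)
  if (!is.null(splits)) {
    f3 <- file.path(out_dir, "derotation_by_amount.csv")
    f4 <- file.path(out_dir, "derotation_by_staging.csv")
    write.csv(splits$by_amount, f3, row.names = FALSE)
    write.csv(splits$by_staging, f4, row.names = FALSE)
    files <- c(files, f3, f4)
  }
  txt <- c("castmove cohort report",
           sprintf("records: %d", nrow(records)),
           sprintf("overall efficacy (unweighted mean of subgroup means): %.1f%%",
                   overall),
           "",
           "accuracy by subgroup (mean/highest/lowest in %, sd as fraction):",
           sprintf("  %-28s n=%2d mean=%6.1f high=%6.1f low=%6.1f sd=%s p=%s",
                   by_subgroup$label, by_subgroup$n, by_subgroup$mean_accuracy,
                   by_subgroup$highest, by_subgroup$lowest,
                   ifelse(is.na(by_subgroup$sd), "NA",
                          sprintf("%.2f", by_subgroup$sd)),
                   ifelse(is.na(by_subgroup$p_value), "NA",
                          sprintf("%.3f", by_subgroup$p_value))))
  writeLines(txt, files[2])
  out$files <- files
  invisible(out)
}
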