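# Published summary tables from the clinical split-mouth aligner study
# whose measurement methodology this package implements. The study's raw
# per-patient casts are not publicly available; these printed summaries
# are what the synthetic cohort generator is calibrated against and what
# the arithmetic cross-checks (overall efficacy, pooled accuracies,
# dropout accounting) are computed from.

#' Published per-subgroup accuracy summary
#'
#' Accuracy of the three studied movements by subgroup, as printed in the
#' source study's results: mean/highest/lowest accuracy in percent, the
#' standard deviation as a fraction of the efficacy ratio, the paired
#' t-test p-value, and the number of analyzed movements.
#'
#' @return Data frame with columns `group`, `subgroup`, `n`,
#'   `mean_accuracy`, `highest`, `lowest`, `sd`, `p_value`.
#' @export
reference_efficacy_table <- function() {
  data.frame(
    group = c("derotation", "derotation", "distalization", "distalization",
              "torque", "torque"),
    subgroup = c("attachment", "none", "attachment", "none",
                 "attachment", "power_ridge"),
    n = c(10L, 10L, 7L, 8L, 7L, 7L),
    mean_accuracy = c(37.5, 42.4, 88.4, 86.9, 49.1, 51.5),
    highest = c(80.6, 79.8, 108.7, 104.2, 71.6, 75.1),
    lowest = c(-2.9, 23.6, 56.4, 61.0, 29.9, 27.4),
    sd = c(0.3, 0.3, 0.2, 0.16, 0.2, 0.2),
    p_value = c(0.00, 0.02, 0.38, 0.46, 0.00, 0.00),
    stringsAsFactors = FALSE)
}

#' Published planned-movement table
#'
#' Staging caps, maximal and mean planned movements, and mean staging per
#' aligner for each subgroup of the source study (degrees for rotations,
#' mm for distalization).
#'
#' @return Data frame with columns `group`, `subgroup`, `possible_staging`,
#'   `max_amount`, `mean_amount`, `mean_staging`.
#' @export
reference_planning_table <- function() {
  data.frame(
    group = c("derotation", "derotation", "distalization", "distalization",
              "torque", "torque"),
    subgroup = c("attachment", "none", "attachment", "none",
                 "attachment", "power_ridge"),
    possible_staging = c(2.0, 2.0, 0.25, 0.25, 1.0, 1.0),
    max_amount = c(30.0, 35.0, 3.2, 3.2, 28.0, 30.0),
    mean_amount = c(17.8, 20.1, 2.7, 2.6, 16.1, 15.9),
    mean_staging = c(1.1, 1.2, 0.2, 0.2, 1.2, 1.1),
    stringsAsFactors = FALSE)
}

#' Published cohort accounting
#'
#' Enrollment and dropout counts of the source study: 30 patients were
#' enrolled for 60 designed split-mouth movements (20 per movement group,
#' 10 per subgroup); 4 patients dropped out, leaving 49 analyzed
#' movements (14 torque, 20 derotation, 15 distalization).
#'
#' @return List with `patients_enrolled`, `dropouts`, `movements_designed`,
#'   `movements_per_group_designed`, `movements_per_subgroup_designed`,
#'   `movements_analyzed_by_group`.
#' @export
reference_cohort_counts <- function() {
  list(patients_enrolled = 30L,
       dropouts = 4L,
       movements_designed = 60L,
       movements_per_group_designed = 20L,
       movements_per_subgroup_designed = 10L,
       movements_analyzed_by_group = c(torque = 14L, derotation = 20L,
                                       distalization = 15L))
}
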