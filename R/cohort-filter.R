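#' Partition a manifest by the clinical inclusion criteria
#'
#' Applies the study's inclusion rules to every session:
#' \itemize{
#'   \item symptomatic dementia: MMSE <= 23 and GDS <= 5;
#'   \item symptomatic depression: HAMD17 >= 8;
#'   \item recording at least `min_duration_s` seconds long;
#'   \item \strong{age-matched set}: age between 57 and 84 (inclusive);
#'   \item \strong{transfer test set}: same symptomatic rules but age >= 85
#'     (dementia) or age <= 56 (depression).
#' }
#' Sessions failing a rule are excluded with a reason code; the three sets
#' are disjoint and exhaustive. Sessions are treated as independent
#' datasets; set `group_by_subject = TRUE` to additionally return subject
#' ids for leakage-aware (subject-grouped) evaluation downstream.
#'
#' @param manifest manifest data frame (see [generate_cohort()]), requiring
#'   columns `session_id`, `group`, `age`, `duration` and the group's score
#'   columns (`mmse`, `gds` for dementia; `hamd17` for depression).
#' @param min_duration_s minimum session length in seconds (the clinical
#'   criterion is 600; shorter synthetic sessions can lower it).
#' @param age_band inclusive age range of the age-matched analysis set.
#' @param group_by_subject attach subject ids to the partition for grouped
#'   evaluation.
#' @return list of class `cohort_partition` with data frames `age_matched`,
#'   `transfer_test` and `excluded` (with `reason`), plus a `counts`
#'   summary.
#' @export
filter_cohort <- function(manifest, min_duration_s = 600,
                          age_band = c(57, 84), group_by_subject = FALSE) {
  needed <- c("session_id", "group", "age", "duration")
  if (!all(needed %in% names(manifest)))
    stop("manifest lacks columns: ",
         paste(setdiff(needed, names(manifest)), collapse = ", "))
  n <- nrow(manifest)
  reason <- character(n)
  for (i in seq_len(n)) {
    row <- manifest[i, ]
    if (is.na(row$age)) { reason[i] <- "missing_age"; next }
    if (is.na(row$duration) || row$duration < min_duration_s) {
      reason[i] <- "too_short"; next
    }
    if (row$group == "dementia") {
      if (is.na(row$mmse) || is.na(row$gds)) {
        reason[i] <- "missing_score"; next
      }
      if (row$mmse > 23) { reason[i] <- "mmse_above_23"; next }
      if (row$gds > 5) { reason[i] <- "gds_above_5"; next }
      reason[i] <- if (row$age >= age_band[1] && row$age <= age_band[2])
        "age_matched" else if (row$age >= 85) "transfer" else "age_below_band"
    } else if (row$group == "depression") {
      if (is.na(row$hamd17)) { reason[i] <- "missing_score"; next }
      if (row$hamd17 < 8) { reason[i] <- "hamd_below_8"; next }
      reason[i] <- if (row$age >= age_band[1] && row$age <= age_band[2])
        "age_matched" else if (row$age <= 56) "transfer" else "age_above_band"
    } else {
      reason[i] <- "unknown_group"
    }
  }
  sel_cols <- names(manifest)
  out <- list(
    age_matched = manifest[reason == "age_matched", sel_cols, drop = FALSE],
    transfer_test = manifest[reason == "transfer", sel_cols, drop = FALSE],
    excluded = cbind(
      manifest[!reason %in% c("age_matched", "transfer"), , drop = FALSE],
      data.frame(reason = reason[!reason %in% c("age_matched", "transfer")],
                 stringsAsFactors = FALSE)))
  rownames(out$age_matched) <- rownames(out$transfer_test) <-
    rownames(out$excluded) <- NULL
  out$counts <- c(input = n,
                  age_matched = nrow(out$age_matched),
                  transfer_test = nrow(out$transfer_test),
                  excluded = nrow(out$excluded))
  out$group_by_subject <- group_by_subject
  class(out) <- "cohort_partition"
  out
}

#' Sessions passing the age-matched inclusion criteria
#' @inheritParams filter_cohort
#' @return data frame of included sessions.
#' @export
filter_age_matched <- function(manifest, min_duration_s = 600,
                               age_band = c(57, 84)) {
  filter_cohort(manifest, min_duration_s, age_band)$age_matched
}

#' Sessions forming the non-age-matched transfer test set
#' @inheritParams filter_cohort
#' @return data frame of transfer-phase sessions (old dementia, young
#'   depression).
#' @export
filter_transfer_test <- function(manifest, min_duration_s = 600,
                                 age_band = c(57, 84)) {
  filter_cohort(manifest, min_duration_s, age_band)$transfer_test
}
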