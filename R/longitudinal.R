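#' Six longitudinal trend descriptors of a short trajectory
#'
#' Summarises one feature measured at three occasions (months 0, 4, 8 by
#' default) with six descriptors: `MF` mean level; `SDF` sample SD; `RF`
#' range (max - min); `AF` trapezoidal area under the trajectory between the
#' first and last occasion; `MVF`/`SDVF` mean and sample SD of the
#' consecutive-interval slopes (`Velocity_t = (X(t+1) - X(t)) / dt`, units
#' per month). With `include_span_slope = TRUE` the first-to-last slope is
#' appended as a third velocity before averaging.
#'
#' @param values numeric vector of length 3 (the feature at occasions 1-3).
#' @param times measurement times in months, strictly increasing.
#' @param include_span_slope add the time1 -> time3 slope as an extra
#'   velocity (off by default; see the methods vignette).
#' @return Named numeric vector `c(MF, SDF, RF, AF, MVF, SDVF)`.
#' @export
#' @examples
#' longitudinal_stats(c(1, 2, 4))  # MF 2.33, SDF 1.53, RF 3, AF 18, ...
longitudinal_stats <- function(values, times = c(0, 4, 8),
                               include_span_slope = FALSE) {
  if (length(values) != 3L || length(times) != 3L) {
    stop_invalid_input("exactly three measurement occasions are required")
  }
  if (any(!is.finite(values)) || any(!is.finite(times))) {
    stop_invalid_input("values and times must be finite")
  }
  if (any(diff(times) <= 0)) {
    stop_invalid_input("measurement times must be strictly increasing")
  }
  vel <- diff(values) / diff(times)
  if (include_span_slope) {
    vel <- c(vel, (values[3L] - values[1L]) / (times[3L] - times[1L]))
  }
  c(MF = mean(values),
    SDF = sd(values),
    RF = max(values) - min(values),
    AF = trapz(times, values),
    MVF = mean(vel),
    SDVF = sd(vel))
}

longitudinal_descriptors <- function() c("MF", "SDF", "RF", "AF", "MVF", "SDVF")

#' Assemble the subject-level longitudinal feature table
#'
#' Expands every cross-sectional feature into its six trend descriptors over
#' timepoints 1-3 and returns one row per subject. Subjects missing any of
#' the three required timepoints are dropped with a warning (complete-case
#' analysis). Column names are `{feature}__{descriptor}`; with the full
#' 328-feature bank this yields 6 x 328 = 1,968 feature columns.
#'
#' @param features data.frame of per-recording cross-sectional features with
#'   columns `subject_id`, `group`, `timepoint` and one column per feature
#'   (as produced by [extract_cohort_features()]).
#' @param times measurement times in months for timepoints 1-3.
#' @param include_span_slope see [longitudinal_stats()].
#' @return data.frame with `subject_id`, `label` (SMCI = 0, PMCI = 1) and
#'   the descriptor columns, of class `longitudinal_table`.
#' @export
build_feature_table <- function(features, times = c(0, 4, 8),
                                include_span_slope = FALSE) {
  required <- c("subject_id", "group", "timepoint")
  if (!all(required %in% names(features))) {
    stop_invalid_input("features must have subject_id, group and timepoint columns")
  }
  feat_cols <- setdiff(names(features), required)
  if (length(feat_cols) == 0L) stop_invalid_input("no feature columns present")

  subjects <- unique(features$subject_id)
  keep <- vapply(subjects, function(s) {
    tps <- features$timepoint[features$subject_id == s]
    all(1:3 %in% tps)
  }, logical(1))
  if (any(!keep)) {
    warning(sprintf("excluding %d subject(s) without complete timepoints 1-3: %s",
                    sum(!keep), paste(subjects[!keep], collapse = ", ")))
  }
  subjects <- subjects[keep]
  if (length(subjects) == 0L) stop_insufficient_data("no complete subjects")

  desc <- longitudinal_descriptors()
  col_names <- as.vector(t(outer(feat_cols, desc, paste, sep = "__")))
  out <- matrix(NA_real_, length(subjects), length(col_names),
                dimnames = list(NULL, col_names))
  label <- integer(length(subjects))
  for (si in seq_along(subjects)) {
    rows <- features[features$subject_id == subjects[si] &
                       features$timepoint %in% 1:3, ]
    rows <- rows[order(rows$timepoint), ]
    label[si] <- as.integer(rows$group[1L] == "PMCI")
    vals <- as.matrix(rows[, feat_cols, drop = FALSE])  # 3 x P
    stats <- apply(vals, 2L, longitudinal_stats, times = times,
                   include_span_slope = include_span_slope)  # 6 x P
    out[si, ] <- as.vector(stats)  # P-major blocks of 6, matching col_names
  }
  res <- data.frame(subject_id = subjects, label = label, out,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(res) <- c("longitudinal_table", "data.frame")
  res
}

#' Feature columns of a longitudinal table
#'
#' @param table a `longitudinal_table` from [build_feature_table()].
#' @return Character vector of descriptor column names.
#' @export
table_feature_cols <- function(table) {
  setdiff(names(table), c("subject_id", "label"))
}
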