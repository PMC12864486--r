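#' Feature-extraction configuration
#'
#' @param spectral,nonlinear,connectivity logical toggles for the three
#'   feature sets.
#' @param welch_segment_seconds,welch_overlap Welch PSD parameters.
#' @param pe_m,pe_tau permutation entropy embedding.
#' @param se_window_s optional sample-entropy windowing (seconds).
#' @param delay_rule M-DCPSR delay selection rule.
#' @param pli_band connectivity band in Hz.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(spectral = TRUE, nonlinear = TRUE,
                           connectivity = TRUE,
                           welch_segment_seconds = 2, welch_overlap = 0.5,
                           pe_m = 3, pe_tau = 1, se_window_s = NULL,
                           delay_rule = "as_printed", pli_band = c(8, 13)) {
  structure(list(spectral = spectral, nonlinear = nonlinear,
                 connectivity = connectivity,
                 welch_segment_seconds = welch_segment_seconds,
                 welch_overlap = welch_overlap, pe_m = pe_m, pe_tau = pe_tau,
                 se_window_s = se_window_s, delay_rule = delay_rule,
                 pli_band = pli_band),
            class = "feature_config")
}

#' Extract all cross-sectional features from one recording
#'
#' With all three sets enabled, returns the 328 named features: 80 PSD
#' ratios, 80 within-band PSD entropies, 48 nonlinear features and 120
#' alpha-band PLI values, in the canonical order of [feature_names()].
#'
#' @param epoch a preprocessed [eeg_epoch()].
#' @param config a [feature_config()].
#' @return Named numeric vector.
#' @export
extract_features <- function(epoch, config = feature_config()) {
  assert_epoch(epoch)
  out <- numeric(0)
  if (config$spectral) {
    out <- c(out, spectral_features(epoch, config$welch_segment_seconds,
                                    config$welch_overlap))
  }
  if (config$nonlinear) {
    out <- c(out, nonlinear_features(epoch, pe_m = config$pe_m,
                                     pe_tau = config$pe_tau,
                                     se_window_s = config$se_window_s,
                                     delay_rule = config$delay_rule))
  }
  if (config$connectivity) {
    out <- c(out, connectivity_features(epoch, config$pli_band))
  }
  out
}

#' Extract features for a whole cohort
#'
#' Runs [extract_features()] (optionally after [preprocess_epoch()]) on every
#' subject and requested timepoint and returns a long per-recording table.
#'
#' @param cohort a [cohort_dataset()].
#' @param timepoints which timepoints to process (default 1-3, the
#'   predictor visits).
#' @param config a [feature_config()].
#' @param preprocess optional [preprocess_config()]; `NULL` (default) when
#'   epochs are already preprocessed (the generator emits analysis-ready
#'   250 Hz segments).
#' @return data.frame: `subject_id`, `group`, `timepoint`, then one column
#'   per feature.
#' @export
extract_cohort_features <- function(cohort, timepoints = 1:3,
                                    config = feature_config(),
                                    preprocess = NULL) {
  rows <- list()
  for (s in cohort$subjects) {
    for (tp in timepoints) {
      ep <- s$epochs[[as.character(tp)]]
      if (is.null(ep)) next
      if (!is.null(preprocess)) ep <- preprocess_epoch(ep, preprocess)
      f <- extract_features(ep, config)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, group = s$group, timepoint = tp,
        t(f), check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
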