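#' Construct an EEG epoch
#'
#' An `eeg_epoch` is one subject-by-timepoint recording: a channels x samples
#' voltage matrix (microvolts) with its sampling rate and montage. The montage
#' is fixed to the 16-channel 10-20 set returned by [eeg_channels()].
#'
#' @param data numeric matrix, channels x samples (muV). Row names, if set,
#'   must equal `channels`.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id subject identifier.
#' @param timepoint integer measurement occasion, 1-4.
#' @param channels ordered channel names; defaults to [eeg_channels()].
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, fs, subject_id = NA_character_,
                      timepoint = NA_integer_, channels = eeg_channels()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_invalid_input("`data` must be a numeric channels x samples matrix")
  }
  if (nrow(data) != length(channels)) {
    stop_invalid_input(sprintf(
      "data has %d rows but %d channels were declared",
      nrow(data), length(channels)))
  }
  if (!is.finite(fs) || fs <= 0) stop_invalid_config("`fs` must be > 0")
  if (any(!is.finite(data))) {
    stop_invalid_input("epoch data contains non-finite values")
  }
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels,
         subject_id = as.character(subject_id),
         timepoint = as.integer(timepoint)),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> subject %s, timepoint %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$timepoint, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_epoch <- function(x) dim(x$data)

epoch_duration <- function(epoch) ncol(epoch$data) / epoch$fs

assert_epoch <- function(epoch) {
  if (!inherits(epoch, "eeg_epoch")) {
    stop_invalid_input("expected an `eeg_epoch` object")
  }
  invisible(epoch)
}

#' Construct a subject record
#'
#' Bundles one subject's group label and their per-timepoint epochs. The
#' feature pipeline requires timepoints 1-3; timepoint 4 (the 12-month visit)
#' only defines the outcome and is never used as a predictor.
#'
#' @param subject_id identifier, unique within a cohort.
#' @param group `"SMCI"` (stable) or `"PMCI"` (progressed to AD at one year).
#' @param epochs named list of [eeg_epoch()] objects; names are timepoint
#'   indices (`"1"`..`"4"`).
#' @param metadata optional named list of scalar covariates.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group, epochs, metadata = list()) {
  group <- match.arg(group, c("SMCI", "PMCI"))
  if (is.null(names(epochs)) || any(!nzchar(names(epochs)))) {
    stop_invalid_input("`epochs` must be named by timepoint index")
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         epochs = epochs, metadata = metadata),
    class = "subject_record"
  )
}

#' Construct a cohort dataset
#'
#' @param subjects list of [subject_record()] objects with unique ids.
#' @param generation_config the full parameter set (including seed) used to
#'   generate the cohort, when synthetic; `NULL` for imported data.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(subjects, generation_config = NULL) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop_invalid_input("subject ids must be unique")
  structure(
    list(subjects = subjects, generation_config = generation_config),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$group, character(1))
  cat(sprintf("<cohort_dataset> %d subjects (%d SMCI, %d PMCI)\n",
              length(x$subjects), sum(groups == "SMCI"), sum(groups == "PMCI")))
  invisible(x)
}

#' @export
length.cohort_dataset <- function(x) length(x$subjects)

cohort_groups <- function(cohort) {
  vapply(cohort$subjects, function(s) s$group, character(1))
}
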