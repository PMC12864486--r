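#' Standard 16-channel 10-20 montage
#'
#' The fixed, ordered channel set used throughout the pipeline. All epochs
#' must carry exactly these channels in exactly this order; the registry is
#' the single source of truth for feature column order.
#'
#' @return Character vector of 16 channel names.
#' @export
#' @examples
#' eeg_channels()
eeg_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")
}

#' Canonical channel-pair order for connectivity features
#'
#' All 120 unordered channel pairs, lexicographic by channel index (i < j),
#' matching the upper triangle of the 16 x 16 connectivity matrix.
#'
#' @return data.frame with columns `i`, `j` (channel indices), `a`, `b`
#'   (channel names) and `name` (the feature label `PLI__a-b`).
#' @export
eeg_channel_pairs <- function() {
  ch <- eeg_channels()
  idx <- which(upper.tri(matrix(0, 16, 16)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(
    i = idx[, "row"], j = idx[, "col"],
    a = ch[idx[, "row"]], b = ch[idx[, "col"]],
    name = paste0("PLI__", ch[idx[, "row"]], "-", ch[idx[, "col"]]),
    stringsAsFactors = FALSE
  )
}

#' Frequency band definitions
#'
#' The five conventional EEG sub-bands used for spectral features:
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz.
#'
#' @return data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(0.5, 4, 8, 13, 30),
    hi = c(4, 8, 13, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Canonical cross-sectional feature names
#'
#' The 328 per-recording feature labels in their fixed order: 80 PSD ratios
#' (`Ratio1..5__<ch>`), 80 within-band PSD entropies (`PSDE_<band>__<ch>`),
#' 48 nonlinear features (`PE__<ch>`, `SE__<ch>`, `MDCPSR__<ch>`) and 120
#' alpha-band phase lag indices (`PLI__<a>-<b>`).
#'
#' @param sets character subset of `c("spectral", "nonlinear",
#'   "connectivity")`; defaults to all three.
#' @return Character vector of feature names.
#' @export
feature_names <- function(sets = c("spectral", "nonlinear", "connectivity")) {
  sets <- match.arg(sets, several.ok = TRUE)
  ch <- eeg_channels()
  out <- character(0)
  if ("spectral" %in% sets) {
    ratios <- as.vector(vapply(paste0("Ratio", 1:5),
                               function(r) paste0(r, "__", ch), character(16)))
    psde <- as.vector(vapply(eeg_bands()$band,
                             function(b) paste0("PSDE_", b, "__", ch),
                             character(16)))
    out <- c(out, ratios, psde)
  }
  if ("nonlinear" %in% sets) {
    out <- c(out, paste0("PE__", ch), paste0("SE__", ch),
             paste0("MDCPSR__", ch))
  }
  if ("connectivity" %in% sets) {
    out <- c(out, eeg_channel_pairs()$name)
  }
  out
}
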