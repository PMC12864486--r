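## Analytic signal via the frequency-domain Hilbert transform.
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

## Zero-phase FIR band-pass on a bare numeric vector.
bandpass_vector <- function(x, fs, lo, hi) {
  n <- fir_taps(fs, lo / 5, length(x))
  h <- signal::fir1(n, c(lo, hi) / (fs / 2), type = "pass")
  y <- apply_fir_zerophase(x, h)
  as.numeric(y)
}

#' Instantaneous phase of a band-limited signal
#'
#' Band-pass filters (unless `prefiltered`), forms the analytic signal via
#' the Hilbert transform and returns the instantaneous phase
#' `atan2(imag, real)` in `(-pi, pi]`. The first and last second are
#' discarded to suppress filter and Hilbert edge transients.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param band `c(lo, hi)` in Hz; default alpha (8-13 Hz).
#' @param prefiltered set `TRUE` if `x` is already band-limited.
#' @param edge_trim_s seconds trimmed from each end after the transform.
#' @return List with `phase` (radians), `amplitude` (instantaneous envelope)
#'   and `fs`.
#' @export
analytic_phase <- function(x, fs, band = c(8, 13), prefiltered = FALSE,
                           edge_trim_s = 1) {
  if (length(x) < 4 * fs) {
    stop_insufficient_data("need at least 4 s of signal for phase estimation")
  }
  if (var(x) == 0) {
    stop_degenerate_input("constant/zero signal: instantaneous phase undefined")
  }
  if (!prefiltered) x <- bandpass_vector(x, fs, band[1L], band[2L])
  an <- hilbert_analytic(x)
  trim <- round(edge_trim_s * fs)
  keep <- seq(trim + 1L, length(x) - trim)
  list(phase = Arg(an[keep]), amplitude = Mod(an[keep]), fs = fs)
}

#' Phase lag index between two signals
#'
#' `PLI = |mean(sign(sin(phi_x - phi_y)))|` over the trimmed interior of the
#' band-limited analytic phases: 0 when the phase difference is absent or
#' centred on 0 or pi, 1 for perfect locking at any other lag. Insensitive to
#' amplitude and, by construction, to zero-lag (volume-conduction-like)
#' coupling. `variant = "as_printed"` instead folds the absolute phase
#' difference into `[0, 2*pi)` before taking the sign; that variant is
#' retained only for auditability since it saturates near 1 for any input.
#'
#' @param x,y equal-length numeric series at the same sampling rate.
#' @param fs sampling rate (Hz).
#' @param band frequency band `c(lo, hi)` in Hz; default alpha.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @param prefiltered set `TRUE` if inputs are already band-limited.
#' @return PLI in `[0, 1]`.
#' @export
pli_pair <- function(x, y, fs, band = c(8, 13),
                     variant = c("standard", "as_printed"),
                     prefiltered = FALSE) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) {
    stop_invalid_input("signals must have equal length")
  }
  px <- analytic_phase(x, fs, band, prefiltered)$phase
  py <- analytic_phase(y, fs, band, prefiltered)$phase
  pli_from_phases(px, py, variant)
}

pli_from_phases <- function(px, py, variant = "standard") {
  if (variant == "standard") {
    abs(mean(sign(sin(px - py))))
  } else {
    dphi <- abs(px - py) %% (2 * pi)
    abs(mean(sign(dphi)))
  }
}

#' Alpha-band phase lag index over all channel pairs
#'
#' Band-filters each channel once, extracts analytic phases and evaluates the
#' PLI for all 120 unordered channel pairs in the canonical order of
#' [eeg_channel_pairs()].
#'
#' @param epoch a preprocessed [eeg_epoch()].
#' @param band frequency band in Hz; default alpha (8-13).
#' @param variant see [pli_pair()].
#' @return Object of class `pli_matrix`: list with `matrix` (symmetric
#'   16 x 16, zero diagonal) and `features` (named length-120 vector).
#' @export
pli_matrix <- function(epoch, band = c(8, 13),
                       variant = c("standard", "as_printed")) {
  assert_epoch(epoch)
  variant <- match.arg(variant)
  nch <- nrow(epoch$data)
  phases <- lapply(seq_len(nch), function(ch) {
    analytic_phase(epoch$data[ch, ], epoch$fs, band)$phase
  })
  pairs <- eeg_channel_pairs()
  M <- matrix(0, nch, nch, dimnames = list(epoch$channels, epoch$channels))
  feats <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    v <- pli_from_phases(phases[[pairs$i[p]]], phases[[pairs$j[p]]], variant)
    M[pairs$i[p], pairs$j[p]] <- v
    M[pairs$j[p], pairs$i[p]] <- v
    feats[p] <- v
  }
  names(feats) <- pairs$name
  structure(list(matrix = M, features = feats, band = band,
                 variant = variant),
            class = "pli_matrix")
}

#' Connectivity features for one recording
#'
#' @param epoch a preprocessed [eeg_epoch()].
#' @param band frequency band in Hz; default alpha.
#' @return Named numeric vector of 120 `PLI__{a}-{b}` features.
#' @export
connectivity_features <- function(epoch, band = c(8, 13)) {
  pli_matrix(epoch, band)$features
}
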