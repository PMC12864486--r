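#' Welch power spectral density estimate
#'
#' Mean of tapered-segment periodograms per channel. Defaults: 2 s Hann
#' segments with 50% overlap, giving 0.5 Hz resolution at 250 Hz. One-sided
#' density in muV^2/Hz, scaled so that the integral over frequency equals the
#' signal variance (for zero-mean input).
#'
#' @param epoch an [eeg_epoch()].
#' @param segment_seconds taper segment length (s).
#' @param overlap fractional overlap between consecutive segments, in `[0,1)`.
#' @return A list of class `spectral_decomposition` with `freq` (Hz) and
#'   `psd` (channels x frequencies matrix), plus the Welch parameters.
#' @export
welch_psd <- function(epoch, segment_seconds = 2, overlap = 0.5) {
  assert_epoch(epoch)
  nper <- round(segment_seconds * epoch$fs)
  n <- ncol(epoch$data)
  if (n < nper) {
    stop_insufficient_data("epoch shorter than one Welch segment")
  }
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- hann_window(nper)
  U <- sum(w^2)                       # window power normalisation
  nfreq <- nper %/% 2L + 1L
  freq <- (seq_len(nfreq) - 1L) * epoch$fs / nper
  psd <- matrix(0, nrow(epoch$data), nfreq)
  for (s in starts) {
    seg <- epoch$data[, s:(s + nper - 1L), drop = FALSE]
    tap <- sweep(seg, 2L, w, `*`)
    spec <- Mod(t(apply(tap, 1L, fft)))[, seq_len(nfreq), drop = FALSE]^2
    psd <- psd + spec
  }
  psd <- psd / (length(starts) * U * epoch$fs)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq); dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  psd <- sweep(psd, 2L, dbl, `*`)
  rownames(psd) <- epoch$channels
  structure(
    list(freq = freq, psd = psd, channels = epoch$channels,
         segment_seconds = segment_seconds, overlap = overlap,
         taper = "hann", fs = epoch$fs),
    class = "spectral_decomposition"
  )
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

## PSD values on the closed band [lo, hi], adding linearly interpolated
## edge points when the grid does not land exactly on a band edge.
band_grid <- function(freq, psd_row, lo, hi) {
  inside <- which(freq >= lo & freq <= hi)
  f <- freq[inside]
  p <- psd_row[inside]
  if (length(f) == 0L || f[1L] > lo) {
    if (lo >= min(freq) && lo <= max(freq)) {
      p <- c(approx(freq, psd_row, xout = lo)$y, p)
      f <- c(lo, f)
    }
  }
  if (f[length(f)] < hi) {
    if (hi <= max(freq)) {
      p <- c(p, approx(freq, psd_row, xout = hi)$y)
      f <- c(f, hi)
    }
  }
  list(freq = f, psd = p)
}

#' Sub-band powers from a spectral decomposition
#'
#' Trapezoidal integral of the PSD over each band's frequency interval.
#' Trapezoidal integration is additive across the shared band edges (4, 8,
#' 13, 30 Hz), so the five band powers sum to the total 0.5-45 Hz power.
#'
#' @param spec a `spectral_decomposition` from [welch_psd()].
#' @param bands band table as from [eeg_bands()].
#' @return channels x bands matrix of powers (muV^2).
#' @export
band_powers <- function(spec, bands = eeg_bands()) {
  if (min(spec$freq) > min(bands$lo) || max(spec$freq) < max(bands$hi)) {
    stop_invalid_input("frequency grid does not cover the requested bands")
  }
  out <- matrix(NA_real_, nrow(spec$psd), nrow(bands),
                dimnames = list(spec$channels, bands$band))
  for (b in seq_len(nrow(bands))) {
    for (ch in seq_len(nrow(spec$psd))) {
      g <- band_grid(spec$freq, spec$psd[ch, ], bands$lo[b], bands$hi[b])
      out[ch, b] <- trapz(g$freq, g$psd)
    }
  }
  out
}

#' Relative band-power ratios
#'
#' The five slowing ratios computed per channel from the sub-band powers:
#' Ratio1 = delta/alpha, Ratio2 = theta/alpha, Ratio3 = delta/(alpha+beta),
#' Ratio4 = theta/(alpha+beta), Ratio5 = (delta+theta)/(alpha+beta+gamma).
#' Rising values index the shift of spectral mass from fast to slow rhythms.
#'
#' @param powers channels x bands matrix from [band_powers()].
#' @return channels x 5 matrix with columns `Ratio1`..`Ratio5`.
#' @export
psd_ratios <- function(powers) {
  d <- powers[, "delta"]; t_ <- powers[, "theta"]; a <- powers[, "alpha"]
  b <- powers[, "beta"]; g <- powers[, "gamma"]
  if (any(a <= 0) || any(a + b <= 0) || any(a + b + g <= 0)) {
    stop_degenerate_input("zero denominator band power; cannot form PSD ratios")
  }
  cbind(Ratio1 = d / a,
        Ratio2 = t_ / a,
        Ratio3 = d / (a + b),
        Ratio4 = t_ / (a + b),
        Ratio5 = (d + t_) / (a + b + g))
}

#' Within-band spectral (Shannon) entropy
#'
#' Normalises the PSD bins inside one band to probabilities and returns
#' their Shannon entropy (natural log), per channel. Bounded by `ln(N)` for
#' `N` bins, with equality iff the in-band spectrum is flat.
#'
#' @param spec a `spectral_decomposition`.
#' @param band band name (`"delta"`..`"gamma"`) or a `c(lo, hi)` pair in Hz.
#' @return named numeric vector, one entropy per channel.
#' @export
psd_entropy <- function(spec, band) {
  if (is.character(band)) {
    bt <- eeg_bands()
    row <- bt[bt$band == band, ]
    if (nrow(row) != 1L) stop_invalid_config("unknown band name")
    lo <- row$lo; hi <- row$hi
  } else {
    lo <- band[1L]; hi <- band[2L]
  }
  idx <- which(spec$freq >= lo & spec$freq <= hi)
  if (length(idx) == 0L) stop_invalid_input("no frequency bins inside band")
  vapply(seq_len(nrow(spec$psd)), function(ch) {
    p <- spec$psd[ch, idx]
    tot <- sum(p)
    if (tot <= 0) stop_degenerate_input("all-zero PSD inside band")
    shannon_entropy(p / tot)
  }, numeric(1)) |> setNames(spec$channels)
}

## Shannon entropy in nats with the 0 * log(0) = 0 convention.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' All spectral features for one recording
#'
#' @param epoch a preprocessed [eeg_epoch()].
#' @param segment_seconds,overlap Welch parameters, see [welch_psd()].
#' @return Named numeric vector of 160 features (`Ratio{k}__{ch}`,
#'   `PSDE_{band}__{ch}`).
#' @export
spectral_features <- function(epoch, segment_seconds = 2, overlap = 0.5) {
  spec <- welch_psd(epoch, segment_seconds, overlap)
  pw <- band_powers(spec)
  ratios <- psd_ratios(pw)
  out <- numeric(0)
  for (k in colnames(ratios)) {
    v <- ratios[, k]
    names(v) <- paste0(k, "__", rownames(ratios))
    out <- c(out, v)
  }
  for (b in eeg_bands()$band) {
    v <- psd_entropy(spec, b)
    names(v) <- paste0("PSDE_", b, "__", spec$channels)
    out <- c(out, v)
  }
  out
}
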