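## FIR filtering backbone.
##
## All filters are linear-phase windowed-sinc (Hamming) designs from
## signal::fir1, applied forward-backward (zero phase) per channel via
## FFT convolution with odd-reflection edge padding. Filter order follows
## the transition-bandwidth rule n ~ 3.3 fs / df and is capped at a third
## of the series length so the reflection padding stays well defined.

fir_taps <- function(fs, transition_hz, n_samples) {
  n <- ceiling(3.3 * fs / transition_hz)
  cap <- max(11L, floor((n_samples - 1) / 3))
  n <- min(n, cap)
  if (n %% 2L == 1L) n <- n + 1L  # even order -> odd tap count, type I FIR
  as.integer(n)
}

## Zero-phase FIR: filter forward, then backward, with odd reflection padding.
apply_fir_zerophase <- function(x, h) {
  n <- length(x)
  L <- length(h)
  p <- min(L, n - 1L)
  pad_l <- 2 * x[1] - x[seq(p + 1, 2)]
  pad_r <- 2 * x[n] - x[seq(n - 1, n - p)]
  y <- c(pad_l, x, pad_r)
  y <- fft_conv_same(y, h)
  y <- fft_conv_same(rev(y), h)
  rev(y)[seq(p + 1, p + n)]
}

## Linear convolution (centre-aligned, "same" length) via FFT.
fft_conv_same <- function(x, h) {
  n <- length(x)
  L <- length(h)
  m <- stats::nextn(n + L - 1L, 2)
  X <- fft(c(x, numeric(m - n)))
  H <- fft(c(h, numeric(m - L)))
  full <- Re(fft(X * H, inverse = TRUE)) / m
  offset <- (L - 1L) %/% 2L
  full[seq(offset + 1L, offset + n)]
}

filter_epoch <- function(epoch, h) {
  out <- epoch
  out$data <- t(apply(epoch$data, 1L, apply_fir_zerophase, h = h))
  rownames(out$data) <- epoch$channels
  out
}

#' Preprocessing configuration
#'
#' @param bandpass_lo,bandpass_hi band-pass edges in Hz.
#' @param notch_freq power-line frequency to suppress (Hz).
#' @param target_fs sampling rate after downsampling (Hz).
#' @param segment_seconds length of the analysis segment (s).
#' @param segment_strategy how the segment is chosen; see [select_segment()].
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(bandpass_lo = 0.1, bandpass_hi = 70,
                              notch_freq = 50, target_fs = 250,
                              segment_seconds = 30,
                              segment_strategy = "lowest_peak") {
  if (!(bandpass_lo > 0 && bandpass_lo < bandpass_hi)) {
    stop_invalid_config("need 0 < bandpass_lo < bandpass_hi")
  }
  if (bandpass_hi >= target_fs / 2) {
    stop_invalid_config("bandpass_hi must lie below the post-downsampling Nyquist")
  }
  if (segment_seconds <= 0) stop_invalid_config("segment_seconds must be > 0")
  structure(
    list(bandpass_lo = bandpass_lo, bandpass_hi = bandpass_hi,
         notch_freq = notch_freq, target_fs = target_fs,
         segment_seconds = segment_seconds,
         segment_strategy = segment_strategy),
    class = "preprocess_config"
  )
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the column means of the output are zero.
#'
#' @param epoch an [eeg_epoch()].
#' @return The re-referenced epoch.
#' @export
rereference_average <- function(epoch) {
  assert_epoch(epoch)
  if (nrow(epoch$data) < 2L) {
    stop_invalid_input("average reference needs at least 2 channels")
  }
  out <- epoch
  out$data <- sweep(epoch$data, 2L, colMeans(epoch$data))
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass applied forward-backward per channel.
#' The filter order follows the low transition edge (`lo / 5`), capped at a
#' third of the recording length; very low `lo` on short recordings therefore
#' yields a gentler low edge than the nominal design.
#'
#' @param epoch an [eeg_epoch()].
#' @param lo,hi passband edges in Hz; `hi` must lie below Nyquist.
#' @return The filtered epoch.
#' @export
bandpass_fir <- function(epoch, lo, hi) {
  assert_epoch(epoch)
  if (!(lo > 0 && lo < hi)) stop_invalid_config("need 0 < lo < hi")
  if (hi >= epoch$fs / 2) stop_invalid_config("hi must be below Nyquist")
  n <- fir_taps(epoch$fs, lo / 5, ncol(epoch$data))
  h <- signal::fir1(n, c(lo, hi) / (epoch$fs / 2), type = "pass")
  filter_epoch(epoch, h)
}

#' Zero-phase FIR notch filter
#'
#' Narrow band-stop (default width 4 Hz, i.e. `freq` +- 2 Hz) suppressing
#' power-line interference while leaving neighbouring rhythms intact.
#'
#' @param epoch an [eeg_epoch()].
#' @param freq notch centre frequency in Hz.
#' @param half_width half-width of the stop band (Hz).
#' @return The filtered epoch.
#' @export
notch <- function(epoch, freq = 50, half_width = 2) {
  assert_epoch(epoch)
  if (freq - half_width <= 0 || freq + half_width >= epoch$fs / 2) {
    stop_invalid_config("notch band must lie strictly inside (0, Nyquist)")
  }
  n <- fir_taps(epoch$fs, half_width, ncol(epoch$data))
  h <- signal::fir1(n, c(freq - half_width, freq + half_width) / (epoch$fs / 2),
                    type = "stop")
  filter_epoch(epoch, h)
}

#' Downsample with anti-alias filtering
#'
#' Low-pass filters at 0.45 x the target Nyquist-defining rate, then keeps
#' every `fs / target_fs`-th sample. Only integer decimation factors are
#' supported.
#'
#' @param epoch an [eeg_epoch()].
#' @param target_fs new sampling rate (Hz); must divide `epoch$fs`.
#' @return The downsampled epoch.
#' @export
downsample <- function(epoch, target_fs) {
  assert_epoch(epoch)
  if (target_fs > epoch$fs) {
    stop_invalid_config("target_fs may not exceed the current sampling rate")
  }
  if (target_fs == epoch$fs) return(epoch)
  q <- epoch$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stop_invalid_config("target_fs must divide fs (integer decimation only)")
  }
  q <- as.integer(round(q))
  n <- fir_taps(epoch$fs, 0.1 * target_fs, ncol(epoch$data))
  h <- signal::fir1(n, 0.45 * target_fs / (epoch$fs / 2), type = "low")
  out <- filter_epoch(epoch, h)
  out$data <- out$data[, seq(1L, ncol(out$data), by = q), drop = FALSE]
  out$fs <- target_fs
  out
}

#' Select a fixed-length analysis segment
#'
#' Automated stand-in for manual segment screening: picks a contiguous window
#' of exactly `segment_seconds`. The default `"lowest_peak"` strategy scans
#' candidate start points (0.1 s hop) and returns the window whose largest
#' absolute amplitude over all channels is smallest, i.e. the quietest
#' stretch; `"first"` takes the initial window, `"offset"` a fixed start.
#'
#' @param epoch an [eeg_epoch()].
#' @param segment_seconds window length (s).
#' @param strategy `"lowest_peak"`, `"first"` or `"offset"`.
#' @param offset_seconds start of the window for `strategy = "offset"`.
#' @return The selected segment as an [eeg_epoch()].
#' @export
select_segment <- function(epoch, segment_seconds,
                           strategy = c("lowest_peak", "first", "offset"),
                           offset_seconds = 0) {
  assert_epoch(epoch)
  strategy <- match.arg(strategy)
  w <- round(segment_seconds * epoch$fs)
  n <- ncol(epoch$data)
  if (w > n) {
    stop_insufficient_data(sprintf(
      "recording is %.1f s but a %.1f s segment was requested",
      n / epoch$fs, segment_seconds))
  }
  start <- switch(strategy,
    first = 1L,
    offset = {
      s <- round(offset_seconds * epoch$fs) + 1L
      if (s + w - 1L > n) stop_invalid_config("offset window exceeds recording")
      as.integer(s)
    },
    lowest_peak = {
      peak <- apply(abs(epoch$data), 2L, max)  # worst-channel envelope
      hop <- max(1L, round(epoch$fs / 10))
      starts <- unique(c(seq(1L, n - w + 1L, by = hop), n - w + 1L))
      wmax <- vapply(starts, function(s) max(peak[s:(s + w - 1L)]), numeric(1))
      starts[which.min(wmax)]
    })
  out <- epoch
  out$data <- epoch$data[, start:(start + w - 1L), drop = FALSE]
  out
}

#' Run the full automated preprocessing chain
#'
#' Fixed stage order: average re-reference, band-pass, notch, downsample,
#' segment selection. Channel order and names are preserved throughout.
#'
#' @param epoch an [eeg_epoch()].
#' @param config a [preprocess_config()].
#' @return The preprocessed epoch at `config$target_fs`.
#' @export
preprocess_epoch <- function(epoch, config = preprocess_config()) {
  epoch <- rereference_average(epoch)
  epoch <- bandpass_fir(epoch, config$bandpass_lo, config$bandpass_hi)
  epoch <- notch(epoch, config$notch_freq)
  epoch <- downsample(epoch, config$target_fs)
  select_segment(epoch, config$segment_seconds, config$segment_strategy)
}
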