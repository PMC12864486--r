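#' Permutation entropy
#'
#' Entropy of the distribution of ordinal patterns of delay-embedded windows,
#' normalised by `ln(m!)` so that the result lies in `[0, 1]`: 0 for a
#' monotone (perfectly regular) series, approaching 1 for i.i.d. noise.
#' Rank ties within a window are broken by temporal order (stable ranking).
#'
#' @param x numeric series.
#' @param m embedding dimension (>= 2).
#' @param tau time delay in samples.
#' @param details if `TRUE`, also return the ordinal pattern distribution.
#' @return Normalised permutation entropy in `[0, 1]`, or (with
#'   `details = TRUE`) a list with `pe`, `H` (raw entropy, nats), `counts`
#'   and `probs`.
#' @export
permutation_entropy <- function(x, m = 3, tau = 1, details = FALSE) {
  if (m < 2) stop_invalid_config("embedding dimension m must be >= 2")
  if (any(!is.finite(x))) stop_invalid_input("series contains non-finite values")
  N <- length(x)
  nwin <- N - (m - 1) * tau
  if (nwin < 2L) stop_insufficient_data("series too short for the requested embedding")
  W <- vapply(0:(m - 1), function(k) x[seq(1L + k * tau, length.out = nwin)],
              numeric(nwin))
  if (nwin == 1L) W <- matrix(W, nrow = 1L)
  # stable rank of column i: 1 + #(earlier cols <= it) + #(later cols < it)
  R <- matrix(1L, nwin, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j == i) next
      R[, i] <- R[, i] + if (j < i) (W[, j] <= W[, i]) else (W[, j] < W[, i])
    }
  }
  code <- as.integer((R - 1L) %*% m^(seq_len(m) - 1L))
  counts <- tabulate(code + 1L, nbins = m^m)
  probs <- counts[counts > 0L] / nwin
  H <- -sum(probs * log(probs))
  pe <- H / log(factorial(m))
  if (!details) return(pe)
  list(pe = pe, H = H, m = m, tau = tau,
       counts = counts[counts > 0L], probs = probs, n_windows = nwin)
}

#' Sample entropy
#'
#' `SE = -ln(A/B)` where `B` counts template pairs (excluding self-matches)
#' of length `m` within Chebyshev distance `< r`, and `A` counts the same at
#' length `m + 1`. Defaults follow common EEG practice: `m = 2` and a
#' tolerance of 0.2 times the series SD. Pair counting runs in compiled
#' code; an
#' optional windowed mode averages SE over non-overlapping sub-windows.
#'
#' @param x numeric series.
#' @param m template length.
#' @param r tolerance in signal units; defaults to `r_factor * sd(x)`.
#' @param r_factor tolerance as a multiple of the series SD (used when `r`
#'   is `NULL`).
#' @param window optional sub-window length in samples; when given, SE is the
#'   mean over complete non-overlapping windows (a documented runtime knob,
#'   off by default).
#' @return Sample entropy (non-negative scalar).
#' @export
sample_entropy <- function(x, m = 2, r = NULL, r_factor = 0.2, window = NULL) {
  if (any(!is.finite(x))) stop_invalid_input("series contains non-finite values")
  if (!is.null(window)) {
    nw <- floor(length(x) / window)
    if (nw < 1L) stop_insufficient_data("series shorter than one SE window")
    vals <- vapply(seq_len(nw), function(k) {
      sample_entropy(x[((k - 1L) * window + 1L):(k * window)],
                     m = m, r = r, r_factor = r_factor)
    }, numeric(1))
    return(mean(vals))
  }
  if (length(x) < m + 2L) stop_insufficient_data("series too short for sample entropy")
  if (is.null(r)) {
    s <- sd(x)
    if (s == 0) stop_degenerate_input("constant series: sample entropy undefined")
    r <- r_factor * s
  }
  if (r <= 0) stop_invalid_config("tolerance r must be > 0")
  counts <- sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  A <- counts[1L]; B <- counts[2L]
  if (B == 0 || A == 0) {
    stop_undefined_entropy(sprintf(
      "sample entropy undefined: A = %g, B = %g template matches", A, B))
  }
  -log(A / B)
}

#' Embedding delay from the autocorrelation zero crossing
#'
#' Centres the series, forms the normalised autocorrelation
#' `R(j) = sum(d_i d_(i+j)) / sum(d_i^2)`, and scans for the first lag `j`
#' with `R(j-1) * R(j) <= 0`. The delay is then taken from the side of the
#' crossing with the *larger* absolute autocorrelation (`delay_rule =
#' "as_printed"`, the formulation adopted here) or the smaller one
#' (`"nearest_zero"`). The search is capped at `floor(N/2)`; if no crossing
#' occurs a fallback delay is returned with a warning. The result is clamped
#' to be at least 1 sample.
#'
#' @param x numeric series.
#' @param max_lag search cap in samples.
#' @param delay_rule `"as_printed"` or `"nearest_zero"`.
#' @param fallback_lag delay used when no zero crossing is found (defaults
#'   to `fs / 10` samples at the pipeline's 250 Hz, i.e. 25).
#' @return Integer delay in samples (>= 1).
#' @export
estimate_delay_autocorr <- function(x, max_lag = floor(length(x) / 2),
                                    delay_rule = c("as_printed", "nearest_zero"),
                                    fallback_lag = 25L) {
  delay_rule <- match.arg(delay_rule)
  N <- length(x)
  if (N < 4L) stop_insufficient_data("need at least 4 samples to estimate a delay")
  d <- x - mean(x)
  ssd <- sum(d * d)
  if (ssd == 0) stop_degenerate_input("constant series: delay undefined")
  r_prev <- 1  # R(0)
  for (j in seq_len(max_lag)) {
    r_j <- sum(d[seq_len(N - j)] * d[seq(j + 1L, N)]) / ssd
    if (r_prev * r_j <= 0) {
      pick_j <- abs(r_prev) <= abs(r_j)
      if (delay_rule == "nearest_zero") pick_j <- !pick_j
      return(max(1L, if (pick_j) j else j - 1L))
    }
    r_prev <- r_j
  }
  warning(sprintf(
    "no autocorrelation zero crossing within %d lags; falling back to tau = %d",
    max_lag, as.integer(fallback_lag)))
  max(1L, as.integer(round(fallback_lag)))
}

#' Median distance from the centroid of the phase-space reconstruction
#'
#' Delay-embeds the series in `m = 3` dimensions (delay from
#' [estimate_delay_autocorr()] unless supplied), computes the centroid of the
#' embedded cloud and returns the median Euclidean distance of the points
#' from it. A scale-aware summary of the attractor's spread: it shrinks with
#' overall signal amplitude and with collapse onto a low-dimensional orbit.
#'
#' @param x numeric series.
#' @param tau embedding delay in samples; estimated from `x` when `NULL`.
#' @param m embedding dimension (fixed at 3 for the feature bank).
#' @param delay_rule,fallback_lag passed to [estimate_delay_autocorr()].
#' @return Non-negative scalar.
#' @export
mdcpsr <- function(x, tau = NULL, m = 3L,
                   delay_rule = c("as_printed", "nearest_zero"),
                   fallback_lag = 25L) {
  delay_rule <- match.arg(delay_rule)
  if (is.null(tau)) {
    tau <- estimate_delay_autocorr(x, delay_rule = delay_rule,
                                   fallback_lag = fallback_lag)
  }
  tau <- as.integer(tau)
  npts <- length(x) - (m - 1L) * tau
  if (npts < 3L) stop_insufficient_data("too few embedded points for M-DCPSR")
  E <- vapply(0:(m - 1L), function(k) x[seq(1L + k * tau, length.out = npts)],
              numeric(npts))
  centroid <- colMeans(E)
  dists <- sqrt(rowSums(sweep(E, 2L, centroid)^2))
  median(dists)
}

#' All nonlinear features for one recording
#'
#' Permutation entropy, sample entropy and M-DCPSR, one value per channel.
#'
#' @param epoch a preprocessed [eeg_epoch()].
#' @param pe_m,pe_tau permutation entropy embedding parameters.
#' @param se_m,se_r_factor sample entropy parameters.
#' @param se_window_s optional sample-entropy window length in seconds
#'   (runtime knob; `NULL` = whole segment).
#' @param delay_rule delay selection rule for M-DCPSR.
#' @return Named numeric vector of 48 features (`PE__{ch}`, `SE__{ch}`,
#'   `MDCPSR__{ch}`).
#' @export
nonlinear_features <- function(epoch, pe_m = 3, pe_tau = 1,
                               se_m = 2, se_r_factor = 0.2,
                               se_window_s = NULL,
                               delay_rule = "as_printed") {
  assert_epoch(epoch)
  ch <- epoch$channels
  window <- if (!is.null(se_window_s)) round(se_window_s * epoch$fs)
  fallback <- max(1L, round(epoch$fs / 10))
  pe <- apply(epoch$data, 1L, permutation_entropy, m = pe_m, tau = pe_tau)
  se <- apply(epoch$data, 1L, sample_entropy, m = se_m,
              r_factor = se_r_factor, window = window)
  md <- apply(epoch$data, 1L, mdcpsr, delay_rule = delay_rule,
              fallback_lag = fallback)
  c(setNames(pe, paste0("PE__", ch)),
    setNames(se, paste0("SE__", ch)),
    setNames(md, paste0("MDCPSR__", ch)))
}
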