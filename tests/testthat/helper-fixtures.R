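# Deterministic fixture builders and independent oracles used across tests.

# Epoch with the same sinusoid on all 16 channels.
sine_epoch <- function(freq, fs = 250, duration = 30, amp = 1, phase = 0) {
  t <- seq(0, by = 1 / fs, length.out = round(duration * fs))
  x <- amp * sin(2 * pi * freq * t + phase)
  eeg_epoch(matrix(rep(x, each = 16), nrow = 16), fs)
}

# Epoch of iid Gaussian noise.
noise_epoch <- function(seed, fs = 250, duration = 30, sd = 1, nch = 16,
                        channels = eeg_channels()) {
  set.seed(seed)
  n <- round(duration * fs)
  eeg_epoch(matrix(rnorm(nch * n, sd = sd), nrow = nch), fs,
            channels = channels[seq_len(nch)])
}

# Independent brute-force sample-entropy oracle: plain double loop over the
# first N - m templates, Chebyshev distance, strict < r, self-matches excluded.
se_oracle <- function(x, m = 2, r = 0.2 * sd(x)) {
  N <- length(x)
  nt <- N - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in seq(i + 1, nt)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) < r) A <- A + 1
      }
    }
  }
  list(A = A, B = B, SE = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# Exhaustive pairwise AUC oracle (ties count 1/2).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small labelled feature table (no EEG) for classifier-level tests:
# n subjects, p features, the first `informative` features shifted by delta
# in the positive class.
toy_table <- function(n1 = 18, n0 = 12, p = 60, informative = 0, delta = 1,
                      seed = 1) {
  set.seed(seed)
  n <- n1 + n0
  X <- matrix(rnorm(n * p), n, p)
  y <- c(rep(1, n1), rep(0, n0))
  if (informative > 0) {
    X[y == 1, seq_len(informative)] <- X[y == 1, seq_len(informative)] + delta
  }
  colnames(X) <- paste0("f", seq_len(p))
  tab <- data.frame(subject_id = paste0("s", seq_len(n)), label = y, X,
                    check.names = FALSE)
  class(tab) <- c("longitudinal_table", "data.frame")
  tab
}
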