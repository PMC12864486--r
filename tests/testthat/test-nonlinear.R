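test_that("permutation entropy matches hand-enumerated ordinal patterns", {
  # six ordinal pairs: 4 ascending, 2 descending
  d <- permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), m = 2, tau = 1,
                           details = TRUE)
  expect_equal(sort(d$counts), c(2, 4))
  expect_equal(d$H, -(4 / 6) * log(4 / 6) - (2 / 6) * log(2 / 6))
  expect_equal(d$pe, 0.9183, tolerance = 1e-4)
})

test_that("permutation entropy hits its regularity and randomness limits", {
  expect_equal(permutation_entropy(1:50, m = 3), 0)
  expect_equal(permutation_entropy(seq(0, 1, length.out = 10), m = 2), 0)

  set.seed(8)
  expect_gte(permutation_entropy(runif(10000), m = 3), 0.99)

  expect_error(permutation_entropy(c(1, 2), m = 3, tau = 5),
               class = "eegtraj_insufficient_data")
  expect_error(permutation_entropy(1:10, m = 1),
               class = "eegtraj_invalid_config")
})

test_that("permutation entropy depends only on ordinal structure", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(500)
    expect_equal(permutation_entropy(x), permutation_entropy(exp(x)),
                 tolerance = 1e-12)
  }
})

test_that("sample entropy agrees exactly with the double-loop oracle", {
  set.seed(21)
  for (rep_i in 1:25) {
    N <- sample(30:200, 1)
    x <- rnorm(N)
    r <- 0.2 * sd(x)
    oracle <- se_oracle(x, m = 2, r = r)
    if (is.na(oracle$SE)) next
    expect_equal(sample_entropy(x, m = 2, r = r), oracle$SE,
                 tolerance = 1e-12)
  }
})

test_that("sample entropy reflects regularity", {
  periodic <- rep(c(1, 2, 3), 20)
  expect_lt(sample_entropy(periodic), 0.05)

  set.seed(5)
  noise <- rnorm(1000)
  tone <- sin(2 * pi * 10 * seq(0, by = 1 / 250, length.out = 1000))
  tone <- tone * sd(noise) / sd(tone)
  expect_gt(sample_entropy(noise), sample_entropy(tone))

  expect_error(sample_entropy(rep(1, 100)),
               class = "eegtraj_degenerate_input")
})

test_that("windowed sample entropy averages over sub-windows", {
  set.seed(9)
  x <- rnorm(600)
  manual <- mean(c(sample_entropy(x[1:200]), sample_entropy(x[201:400]),
                   sample_entropy(x[401:600])))
  expect_equal(sample_entropy(x, window = 200), manual)
})

test_that("autocorrelation delay follows the printed crossing rule", {
  t <- seq(0, by = 1 / 250, length.out = 5000)
  x <- sin(2 * pi * 10 * t)
  # R(tau) ~ cos(2 pi 10 tau / 250): crossing between lags 6 and 7,
  # |R(6)| < |R(7)| so the printed rule takes the larger-|R| side: 7
  expect_equal(estimate_delay_autocorr(x), 7L)
  expect_equal(estimate_delay_autocorr(x, delay_rule = "nearest_zero"), 6L)

  # white noise decorrelates immediately: crossings appear within a few lags
  set.seed(3)
  taus <- replicate(20, estimate_delay_autocorr(rnorm(2000)))
  expect_lte(median(taus), 2)
  expect_true(all(taus <= 12))

  expect_error(estimate_delay_autocorr(rep(2, 100)),
               class = "eegtraj_degenerate_input")
  # a strong trend keeps the autocorrelation positive past the search cap
  expect_warning(tau <- estimate_delay_autocorr(seq_len(200), max_lag = 20,
                                                fallback_lag = 25),
                 "zero crossing")
  expect_equal(tau, 25L)
})

test_that("M-DCPSR matches analytic values and scales homogeneously", {
  # identical embedded points -> zero spread
  expect_equal(mdcpsr(rep(5, 100), tau = 3), 0)

  # unit sinusoid embedded at the quarter period: points
  # (sin, cos, -sin), distances sqrt(1 + sin^2), median sqrt(1.5)
  t <- seq(0, by = 1 / 250, length.out = 8000)
  x <- sin(2 * pi * 6.25 * t)
  expect_equal(mdcpsr(x, tau = 10), sqrt(1.5), tolerance = 0.01)

  set.seed(11)
  y <- rnorm(1000)
  expect_equal(mdcpsr(3.7 * y, tau = 5), 3.7 * mdcpsr(y, tau = 5),
               tolerance = 1e-12)

  expect_error(mdcpsr(rnorm(10), tau = 4),
               class = "eegtraj_insufficient_data")
})

test_that("the nonlinear bank yields 48 named per-channel features", {
  f <- nonlinear_features(noise_epoch(6, duration = 6))
  expect_length(f, 48)
  expect_identical(names(f), feature_names("nonlinear"))
  expect_true(all(f[grepl("^PE__", names(f))] >= 0 &
                    f[grepl("^PE__", names(f))] <= 1))
  expect_true(all(f[grepl("^SE__|^MDCPSR__", names(f))] >= 0))
})
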