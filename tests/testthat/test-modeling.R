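test_that("the two-group F statistic equals the squared pooled t", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(24)
    g <- rep(c(0, 1), each = 12)
    t_ <- t.test(x[g == 0], x[g == 1], var.equal = TRUE)$statistic
    expect_equal(f_statistic(x, g), unname(t_^2), tolerance = 1e-10)
  }
})

test_that("F statistic handles degenerate features", {
  g <- rep(c(0, 1), each = 5)
  expect_equal(f_statistic(rep(c(1, 2, 3, 4, 5), 2), g), 0)
  expect_equal(f_statistic(rep(1, 10), g), 0)
  expect_equal(f_statistic(g, g), Inf)  # perfect separation, zero within-var
  expect_error(f_statistic(rnorm(10), rep(1, 10)),
               class = "eegtraj_invalid_input")
})

test_that("a separating feature outranks noise features", {
  set.seed(30)
  g <- rep(c(0, 1), each = 15)
  X <- cbind(matrix(rnorm(30 * 20), 30), g * 3 + rnorm(30, sd = 0.3))
  sel <- select_top_k(X, g, k = 5)
  expect_equal(sel$retained[1], 21L)
})

test_that("top-k selection returns exactly k, clipped and tie-stable", {
  set.seed(12)
  X <- matrix(rnorm(40 * 1968), 40)
  g <- rep(c(0, 1), 20)
  expect_length(select_top_k(X, g, k = 100)$retained, 100)
  expect_length(select_top_k(X[, 1:50], g, k = 100)$retained, 50)

  # identical columns tie; canonical column order breaks the tie
  Xt <- X[, c(1, 1, 1, 2)]
  expect_identical(select_top_k(Xt, g, k = 2)$retained[
    order(select_top_k(Xt, g, k = 2)$retained)][1], 1L)
})

test_that("confusion metrics evaluate their formulas exactly", {
  m <- compute_metrics(tp = 9, fn = 1, fp = 2, tn = 18)
  expect_equal(unname(m), c(0.9, 0.9, 0.9, 9 / 11, 18 / 21), tolerance = 1e-4)

  expect_equal(unname(compute_metrics(10, 0, 0, 10)), rep(1, 5))
  expect_equal(unname(compute_metrics(5, 5, 5, 5)["ACC"]), 0.5)

  und <- compute_metrics(0, 5, 0, 10)
  expect_true(is.na(und["PPV"]))
  expect_error(compute_metrics(-1, 0, 0, 1), class = "eegtraj_invalid_input")

  # F1 is the harmonic mean of SEN and PPV whenever both are defined
  set.seed(3)
  for (i in 1:10) {
    cts <- rmultinom(1, 40, rep(0.25, 4))
    m <- compute_metrics(cts[1], cts[2], cts[3], cts[4])
    if (!any(is.na(m[c("SEN", "PPV", "F1")])) && m["SEN"] + m["PPV"] > 0) {
      expect_equal(unname(m["F1"]),
                   unname(2 * m["SEN"] * m["PPV"] / (m["SEN"] + m["PPV"])),
                   tolerance = 1e-12)
    }
  }
})

test_that("rank-formula AUC equals exhaustive pair counting", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)

  set.seed(22)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- sample(round(rnorm(n), 1))  # rounding injects ties
    expect_equal(auc_rank(s, y), auc_oracle(s, y), tolerance = 1e-12)
  }

  # invariance under strictly monotone score transforms
  y <- c(1, 1, 0, 1, 0, 0, 1, 0)
  s <- rnorm(8)
  expect_equal(auc_rank(exp(s), y), auc_rank(s, y))
  expect_error(auc_rank(rnorm(4), rep(1, 4)), class = "eegtraj_invalid_input")
})

test_that("Mann-Whitney map behaves at its extremes and under the null", {
  x <- cbind(a = rep(1, 20), b = c(rnorm(10), rnorm(10) + 50))
  g <- rep(c("SMCI", "PMCI"), each = 10)
  mw <- mann_whitney_map(x, g)
  expect_equal(mw$p[mw$feature == "a"], 1)
  expect_lt(mw$p[mw$feature == "b"], 1e-4)

  set.seed(40)
  xnull <- matrix(rnorm(40 * 300), 40)
  colnames(xnull) <- paste0("f", 1:300)
  mw <- mann_whitney_map(xnull, rep(c("SMCI", "PMCI"), each = 20))
  expect_lt(mean(mw$p < 0.05), 0.12)  # ~5% type-I under the null

  mw_adj <- mann_whitney_map(xnull, rep(c("SMCI", "PMCI"), each = 20),
                             adjust = "BH")
  expect_true(all(mw_adj$p_adj >= mw_adj$p))
})

test_that("every classifier separates an easy toy problem", {
  tab <- toy_table(n1 = 20, n0 = 20, p = 30, informative = 10, delta = 2.5,
                   seed = 5)
  cv <- repeated_cv(tab, folds = 4, repeats = 2, k = 15, seed = 7)
  acc <- cv$summary[cv$summary$metric == "ACC", ]
  expect_true(all(acc$mean > 0.8))
  expect_setequal(acc$classifier, classifier_names())
})

test_that("the CV scheme yields folds x repeats evaluations per classifier", {
  tab <- toy_table(n1 = 12, n0 = 10, p = 25, informative = 5, seed = 2)
  cv <- repeated_cv(tab, classifiers = c("svm", "knn"), folds = 5,
                    repeats = 3, k = 10, seed = 1)
  svm_rows <- cv$per_fold[cv$per_fold$classifier == "svm", ]
  expect_equal(nrow(svm_rows), 15)
  # each subject tested exactly once per repeat
  for (r in 1:3) {
    n_tested <- sum(svm_rows$TP[svm_rows$rep == r] +
                      svm_rows$FN[svm_rows$rep == r] +
                      svm_rows$FP[svm_rows$rep == r] +
                      svm_rows$TN[svm_rows$rep == r])
    expect_equal(n_tested, 22)
  }
  # deterministic given the seed
  cv2 <- repeated_cv(tab, classifiers = c("svm", "knn"), folds = 5,
                     repeats = 3, k = 10, seed = 1)
  expect_identical(cv$per_fold, cv2$per_fold)

  expect_error(repeated_cv(toy_table(4, 3, 10), folds = 5, repeats = 1),
               class = "eegtraj_invalid_config")
})

test_that("pure-noise features yield chance-level accuracy (no leakage)", {
  tab <- toy_table(n1 = 18, n0 = 12, p = 200, informative = 0, seed = 11)
  cv <- repeated_cv(tab, classifiers = "svm", folds = 5, repeats = 4,
                    k = 50, seed = 3)
  maj <- 18 / 30
  se <- sqrt(maj * (1 - maj) / 30)
  acc <- cv$summary[cv$summary$metric == "ACC", "mean"]
  expect_lt(abs(acc - maj), 3 * se)
})
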