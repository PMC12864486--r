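#' Two-group one-way ANOVA F statistic per feature
#'
#' `F = MS_between / MS_within` for each column. For two groups this equals
#' the squared pooled-variance t statistic. Columns with zero within-group
#' variance get `F = 0` when the group means are equal and `Inf` otherwise.
#'
#' @param x numeric matrix (samples x features) or vector.
#' @param labels two-level grouping (any type coercible to factor).
#' @return Numeric vector of F statistics, one per column.
#' @export
f_statistic <- function(x, labels) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  g <- factor(labels)
  if (nlevels(g) != 2L) stop_invalid_input("exactly two groups are required")
  n_g <- tabulate(g)
  if (any(n_g < 2L)) stop_invalid_input("need >= 2 samples per group")
  n <- nrow(x)
  m_all <- colMeans(x)
  m1 <- colMeans(x[g == levels(g)[1L], , drop = FALSE])
  m2 <- colMeans(x[g == levels(g)[2L], , drop = FALSE])
  ssb <- n_g[1L] * (m1 - m_all)^2 + n_g[2L] * (m2 - m_all)^2
  centred <- x
  centred[g == levels(g)[1L], ] <- sweep(x[g == levels(g)[1L], , drop = FALSE], 2L, m1)
  centred[g == levels(g)[2L], ] <- sweep(x[g == levels(g)[2L], , drop = FALSE], 2L, m2)
  ssw <- colSums(centred^2)
  f <- (ssb / 1) / (ssw / (n - 2L))
  f[ssw == 0 & ssb == 0] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  unname(f)
}

#' Rank features by F statistic and retain the top k
#'
#' Computed from the supplied (training) rows only; ties are broken by
#' canonical column order so the selection is deterministic.
#'
#' @param x numeric matrix, training samples x features.
#' @param labels two-level outcome for the same rows.
#' @param k number of features to keep (clipped to the number available).
#' @return List with `f` (per-feature F), `ranked` (column indices by
#'   descending F) and `retained` (the first `min(k, P)` of them).
#' @export
select_top_k <- function(x, labels, k = 100) {
  if (k < 1) stop_invalid_config("k must be >= 1")
  f <- f_statistic(x, labels)
  ranked <- order(-f, seq_along(f))
  list(f = f, ranked = ranked, retained = ranked[seq_len(min(k, length(f)))])
}

#' Classification metrics from confusion counts
#'
#' PMCI is the positive class. Metrics with an undefined denominator are
#' returned as `NA` (reported, never silently zero).
#'
#' @param tp,fn,fp,tn confusion counts (non-negative).
#' @return Named vector `c(ACC, SEN, SPE, PPV, F1)`.
#' @export
compute_metrics <- function(tp, fn, fp, tn) {
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0)) stop_invalid_input("confusion counts must be >= 0")
  if (sum(counts) == 0) stop_invalid_input("at least one prediction is required")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  c(ACC = safe_div(tp + tn, tp + fn + tn + fp),
    SEN = safe_div(tp, tp + fn),
    SPE = safe_div(tn, fp + tn),
    PPV = safe_div(tp, tp + fp),
    F1 = safe_div(2 * tp, 2 * tp + fp + fn))
}

#' Rank-sum AUC
#'
#' `AUC = (sum of positive-class ranks - M(M+1)/2) / (M N)` with average
#' ranks for ties; identical to the fraction of positive-negative score pairs
#' correctly ordered, counting ties as 1/2.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- as.logical(as.integer(labels) == 1L | labels == TRUE)
  M <- sum(pos); N <- sum(!pos)
  if (M == 0L || N == 0L) stop_invalid_input("both classes must be present")
  if (any(!is.finite(scores))) stop_invalid_input("scores must be finite")
  r <- rank(scores)
  (sum(r[pos]) - M * (M + 1) / 2) / (M * N)
}

#' Per-feature Mann-Whitney group comparison
#'
#' Two-sided Wilcoxon rank-sum test of SMCI vs PMCI for every feature column
#' (exact for small tie-free samples, normal approximation with tie
#' correction otherwise, as in [stats::wilcox.test()]). Constant features get
#' `p = 1`. No multiplicity correction by default.
#'
#' @param x numeric matrix, samples x features (column names kept).
#' @param labels two-level grouping.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with `feature`, `p` (and `p_adj` when adjusted).
#' @export
mann_whitney_map <- function(x, labels, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  g <- factor(labels)
  if (nlevels(g) != 2L) stop_invalid_input("exactly two groups are required")
  a <- g == levels(g)[1L]
  p <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (length(unique(v)) == 1L) return(1)
    suppressWarnings(wilcox.test(v[a], v[!a])$p.value)
  }, numeric(1))
  out <- data.frame(
    feature = colnames(x) %||% paste0("V", seq_len(ncol(x))),
    p = p, stringsAsFactors = FALSE)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(p, "BH")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- classifiers -----------------------------------------------------------
## Each fitter returns list(class = 0/1 predictions, score = continuous,
## higher = more PMCI-like). Configurations are fixed, documented stand-ins
## for generic "default" settings: SVM linear C = 1; CART/Gini fully grown;
## Gaussian NB; pooled-covariance LDA; AdaBoost 100 stumps; 1-NN Euclidean;
## RF 100 trees with sqrt(P) candidate splits; unpenalized logistic.

#' Names of the available classifiers
#'
#' @return Character vector: `"svm"`, `"dt"`, `"nb"`, `"lda"`, `"ada"`,
#'   `"knn"`, `"rf"`, `"logreg"`.
#' @export
classifier_names <- function() {
  c("svm", "dt", "nb", "lda", "ada", "knn", "rf", "logreg")
}

fit_predict <- function(name, x_tr, y_tr, x_te) {
  y_f <- factor(y_tr, levels = c(0, 1))
  switch(name,
    svm = {
      fit <- e1071::svm(x_tr, y_f, kernel = "linear", cost = 1, scale = FALSE)
      pr <- predict(fit, x_te, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      if (colnames(attr(pr, "decision.values"))[1L] == "0/1") dv <- -dv
      list(class = as.integer(as.character(pr)), score = dv)
    },
    dt = {
      df_tr <- data.frame(.y = y_f, x_tr, check.names = TRUE)
      df_te <- data.frame(x_te, check.names = TRUE)
      names(df_te) <- names(df_tr)[-1L]
      fit <- rpart::rpart(.y ~ ., df_tr, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 4, cp = 0, maxdepth = 30, xval = 0))
      prob <- predict(fit, df_te, type = "prob")[, "1"]
      list(class = as.integer(prob > 0.5), score = prob)
    },
    nb = {
      fit <- e1071::naiveBayes(x_tr, y_f)
      prob <- predict(fit, x_te, type = "raw")[, "1"]
      list(class = as.integer(prob > 0.5), score = prob)
    },
    lda = {
      fit <- suppressWarnings(MASS::lda(x_tr, grouping = y_f))
      pr <- predict(fit, x_te)
      list(class = as.integer(as.character(pr$class)),
           score = pr$posterior[, "1"])
    },
    ada = {
      fit <- adaboost_fit(x_tr, ifelse(y_tr == 1, 1, -1), rounds = 100)
      sc <- adaboost_score(fit, x_te)
      list(class = as.integer(sc > 0), score = sc)
    },
    knn = {
      nn <- knn1_predict(x_tr, y_tr, x_te)
      list(class = nn$class, score = nn$score)
    },
    rf = {
      fit <- randomForest::randomForest(
        x_tr, y_f, ntree = 100, mtry = max(1L, floor(sqrt(ncol(x_tr)))))
      prob <- predict(fit, x_te, type = "prob")[, "1"]
      list(class = as.integer(prob > 0.5), score = prob)
    },
    logreg = {
      df_tr <- data.frame(.y = y_tr, x_tr, check.names = TRUE)
      df_te <- data.frame(x_te, check.names = TRUE)
      names(df_te) <- names(df_tr)[-1L]
      fit <- suppressWarnings(glm(.y ~ ., df_tr, family = binomial()))
      prob <- suppressWarnings(predict(fit, df_te, type = "response"))
      list(class = as.integer(prob > 0.5), score = prob)
    },
    stop_invalid_config(sprintf("unknown classifier '%s'", name))
  )
}

## Discrete AdaBoost.M1 with exhaustive decision stumps.
adaboost_fit <- function(x, y, rounds = 100) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  ords <- lapply(seq_len(ncol(x)), function(j) order(x[, j]))
  stumps <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    st <- best_stump(x, y, w, ords)
    pred <- stump_predict(st, x)
    err <- max(min(st$err, 1 - 1e-10), 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    st$alpha <- alpha
    stumps[[r]] <- st
    if (st$err <= 1e-10) { stumps <- stumps[seq_len(r)]; break }
  }
  list(stumps = stumps)
}

## Minimum weighted error stump over all features, thresholds and polarities.
## A stump predicts polarity * (+1 if x > threshold else -1).
best_stump <- function(x, y, w, ords) {
  best <- list(err = Inf, feature = 1L, threshold = -Inf, polarity = 1)
  Wtot <- sum(w)
  W0 <- sum(w[y == -1])
  n <- nrow(x)
  for (j in seq_len(ncol(x))) {
    o <- ords[[j]]
    v <- x[o, j]; yy <- y[o]; ww <- w[o]
    cpos <- cumsum(ww * (yy == 1))   # positive weight left of each split
    cneg <- cumsum(ww * (yy == -1))
    # split index i = 0..n: first i samples left (-1), rest right (+1);
    # errors are positives on the left plus negatives on the right
    err_right <- c(W0, cpos + (W0 - cneg))
    valid <- c(TRUE, v[-n] < v[-1L], TRUE)   # no threshold between ties
    err_flip <- Wtot - err_right             # reversed polarity
    e <- pmin(err_right, err_flip)
    e[!valid] <- Inf
    ii <- which.min(e)
    if (e[ii] < best$err) {
      i <- ii - 1L
      thr <- if (i == 0L) v[1L] - 1 else if (i == n) v[n] + 1 else
        (v[i] + v[i + 1L]) / 2
      best <- list(err = e[ii], feature = j, threshold = thr,
                   polarity = if (err_right[ii] <= err_flip[ii]) 1 else -1)
    }
  }
  best
}

stump_predict <- function(st, x) {
  st$polarity * ifelse(x[, st$feature] > st$threshold, 1, -1)
}

adaboost_score <- function(fit, x) {
  s <- numeric(nrow(x))
  for (st in fit$stumps) s <- s + st$alpha * stump_predict(st, x)
  s
}

## 1-nearest-neighbour with a continuous distance-ratio score for AUC:
## score = d(nearest negative) / (d(nearest positive) + d(nearest negative)).
knn1_predict <- function(x_tr, y_tr, x_te) {
  d2 <- outer(rowSums(x_te^2), rowSums(x_tr^2), `+`) -
    2 * x_te %*% t(x_tr)
  d2[d2 < 0] <- 0
  cls <- y_tr[max.col(-d2, ties.method = "first")]
  dp <- apply(d2[, y_tr == 1, drop = FALSE], 1L, min)
  dn <- apply(d2[, y_tr == 0, drop = FALSE], 1L, min)
  score <- sqrt(dn) / (sqrt(dp) + sqrt(dn))
  score[!is.finite(score)] <- 0.5
  list(class = as.integer(cls), score = as.numeric(score))
}

## ---- repeated cross-validation --------------------------------------------

## Stratified fold assignment: shuffle within class, deal folds round-robin.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < folds) {
        stop_invalid_config("a class is smaller than the number of folds")
      }
      assign[sample(idx)] <- rep(seq_len(folds), length.out = length(idx))
    }
  })
  assign
}

#' Repeated stratified k-fold cross-validated classification
#'
#' For every fold: standardize features on the training rows, rank by the
#' training-only F statistic, keep the top `k`, fit each classifier and score
#' the held-out rows. No statistic ever touches test rows before prediction
#' (leakage-safe by construction). Fold partitions are re-drawn per repeat
#' with seed `seed + repeat`.
#'
#' @param table a `longitudinal_table` (or any data.frame with `label` and
#'   feature columns).
#' @param classifiers subset of [classifier_names()].
#' @param folds,repeats CV scheme (default 5 folds x 10 repeats = 50
#'   evaluations).
#' @param k number of features retained per fold.
#' @param seed base seed for the fold partitions.
#' @return Object of class `cv_report`: list with `per_fold` (one row per
#'   classifier x fold: confusion counts and metrics), `summary` (per
#'   classifier and metric: mean, sd over defined folds, `n_undefined`) and
#'   `scheme`.
#' @export
repeated_cv <- function(table, classifiers = classifier_names(),
                        folds = 5, repeats = 10, k = 100, seed = 1L) {
  classifiers <- match.arg(classifiers, classifier_names(), several.ok = TRUE)
  feat_cols <- table_feature_cols(table)
  X <- as.matrix(table[, feat_cols, drop = FALSE])
  y <- table$label
  if (min(table(y)) < folds) {
    stop_invalid_config("each class needs at least `folds` subjects")
  }
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    fold_of <- stratified_folds(y, folds, seed + rep_i)
    for (fold_i in seq_len(folds)) {
      te <- fold_of == fold_i
      x_tr <- X[!te, , drop = FALSE]; y_tr <- y[!te]
      x_te <- X[te, , drop = FALSE];  y_te <- y[te]
      mu <- colMeans(x_tr)
      sg <- apply(x_tr, 2L, sd); sg[sg == 0] <- 1
      x_tr <- sweep(sweep(x_tr, 2L, mu), 2L, sg, `/`)
      x_te <- sweep(sweep(x_te, 2L, mu), 2L, sg, `/`)
      sel <- select_top_k(x_tr, y_tr, k)$retained
      x_tr <- x_tr[, sel, drop = FALSE]
      x_te <- x_te[, sel, drop = FALSE]
      for (cl in classifiers) {
        pr <- fit_predict(cl, x_tr, y_tr, x_te)
        tp <- sum(pr$class == 1 & y_te == 1)
        fn <- sum(pr$class == 0 & y_te == 1)
        fp <- sum(pr$class == 1 & y_te == 0)
        tn <- sum(pr$class == 0 & y_te == 0)
        met <- compute_metrics(tp, fn, fp, tn)
        auc <- if (length(unique(y_te)) == 2L) {
          auc_rank(pr$score, y_te)
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          classifier = cl, rep = rep_i, fold = fold_i,
          TP = tp, FN = fn, FP = fp, TN = tn,
          ACC = met["ACC"], SEN = met["SEN"], SPE = met["SPE"],
          PPV = met["PPV"], F1 = met["F1"], AUC = auc,
          row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("ACC", "SEN", "SPE", "PPV", "F1", "AUC")
  summ <- do.call(rbind, lapply(split(per_fold, per_fold$classifier), function(d) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- d[[m]]
      data.frame(classifier = d$classifier[1L], metric = m,
                 mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE),
                 n_undefined = sum(is.na(v)), stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(per_fold = per_fold, summary = summ,
                 scheme = list(folds = folds, repeats = repeats, k = k,
                               seed = seed, stratified = TRUE)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d x %d-fold stratified CV, top-%d features\n",
              x$scheme$repeats, x$scheme$folds, x$scheme$k))
  wide <- stats::reshape(x$summary[, c("classifier", "metric", "mean")],
                         idvar = "classifier", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}
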