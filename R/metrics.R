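#' @title Threshold-free evaluation machinery
#' @description From-scratch ROC and precision-recall curves and areas,
#'   Youden's-J operating points, confusion matrices, permutation feature
#'   importance with joint grouping, and the learning-curve power-law fit.
#'   Conventions that matter and are therefore fixed here: a sample is
#'   called positive when its score is greater than or equal to the
#'   threshold; ROC-AUC gives tied score pairs half credit so it equals the
#'   Mann-Whitney concordance probability exactly; PR-AUC uses the
#'   step-wise (average-precision) rule, which avoids the optimism of
#'   trapezoidal PR interpolation.
#' @name metrics
NULL

scores_and_labels <- function(scores, labels) {
  if (inherits(scores, "kin_scores")) {
    labels <- labels %||% scores$label
    scores <- scores$score
  }
  y <- label01(labels)
  assert_that(length(scores) == length(y), "scores/labels length mismatch")
  list(s = as.numeric(scores), y = y)
}

#' ROC curve and area
#'
#' The curve runs over the sorted unique scores as thresholds (descending;
#' `score >= t` predicts positive), prefixed with an `Inf` threshold so the
#' curve starts at (0, 0) and ends at (1, 1). The AUC is the Mann-Whitney
#' concordance probability (ties counted half), computed from ranks.
#'
#' @param scores numeric scores or a `kin_scores` object.
#' @param labels labels aligned with `scores` (`FM_minus`/1 = positive);
#'   ignored when `scores` is a `kin_scores`.
#' @return list with `curve` (data.frame `threshold`, `tpr`, `fpr`, with
#'   class counts as attributes) and `auc`.
#' @export
roc_auc <- function(scores, labels = NULL) {
  d <- scores_and_labels(scores, labels)
  npos <- sum(d$y == 1); nneg <- sum(d$y == 0)
  if (npos == 0L || nneg == 0L) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  r <- rank(d$s)  # average ranks give ties half credit
  auc <- (sum(r[d$y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(d$s), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(d$s >= t & d$y == 1) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(d$s >= t & d$y == 0) / nneg, numeric(1))
  curve <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
  attr(curve, "npos") <- npos
  attr(curve, "nneg") <- nneg
  class(curve) <- c("kin_roc", "data.frame")
  list(curve = curve, auc = auc)
}

#' Precision-recall curve and area (average precision)
#'
#' Precision/recall pairs at every unique threshold (descending); the area
#' is the step-wise average-precision sum `sum((R_i - R_{i-1}) * P_i)`, no
#' interpolation between points. With constant scores this equals the
#' positive-class prevalence — the random-chance baseline.
#'
#' @inheritParams roc_auc
#' @return list with `curve` (data.frame `threshold`, `recall`,
#'   `precision`) and `auc`.
#' @export
pr_auc <- function(scores, labels = NULL) {
  d <- scores_and_labels(scores, labels)
  npos <- sum(d$y == 1)
  if (npos == 0L) stop("pr_auc: no positives", call. = FALSE)
  thr <- sort(unique(d$s), decreasing = TRUE)
  rec <- numeric(length(thr)); prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- d$s >= thr[i]
    tp <- sum(pred & d$y == 1)
    rec[i] <- tp / npos
    prec[i] <- tp / sum(pred)
  }
  ap <- sum(diff(c(0, rec)) * prec)
  curve <- data.frame(threshold = thr, recall = rec, precision = prec)
  class(curve) <- c("kin_pr", "data.frame")
  list(curve = curve, auc = ap)
}

#' Youden's-J operating point from an ROC curve
#'
#' Returns the threshold maximizing `J = TPR(t) - FPR(t)` (equivalently
#' sensitivity + specificity - 1). Ties are broken toward the larger
#' threshold, i.e. the operating point flagging fewer infants — the
#' lower-screening-burden choice.
#'
#' @param curve the `curve` element of [roc_auc()].
#' @return list of class `kin_operating_point` with `threshold`, `tpr`,
#'   `fpr`, `j` and (when class counts are known) confusion counts.
#' @export
youden_threshold <- function(curve) {
  j <- curve$tpr - curve$fpr
  finite <- is.finite(curve$threshold)
  jmax <- max(j[finite])
  cand <- which(finite & j >= jmax - 1e-12)
  best <- cand[which.max(curve$threshold[cand])]
  op <- list(threshold = curve$threshold[best],
             tpr = curve$tpr[best], fpr = curve$fpr[best],
             j = j[best])
  npos <- attr(curve, "npos"); nneg <- attr(curve, "nneg")
  if (!is.null(npos)) {
    op$tp <- as.integer(round(op$tpr * npos)); op$fn <- npos - op$tp
    op$fp <- as.integer(round(op$fpr * nneg)); op$tn <- nneg - op$fp
  }
  class(op) <- "kin_operating_point"
  op
}

#' Confusion matrix at a fixed threshold
#'
#' Decision rule: `score >= t` predicts positive (FM-).
#'
#' @inheritParams roc_auc
#' @param t threshold in \[0, 1\].
#' @return list of class `kin_operating_point` with counts (`tp`, `fp`,
#'   `tn`, `fn`), `tpr`, `fpr` and `j`.
#' @export
confusion_at_threshold <- function(scores, labels = NULL, t = 0.5) {
  d <- scores_and_labels(scores, labels)
  pred <- d$s >= t
  tp <- sum(pred & d$y == 1); fn <- sum(!pred & d$y == 1)
  fp <- sum(pred & d$y == 0); tn <- sum(!pred & d$y == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  structure(list(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
                 tpr = tpr, fpr = fpr, j = tpr - fpr),
            class = "kin_operating_point")
}

#' @export
print.kin_operating_point <- function(x, ...) {
  cat(sprintf("operating point: t = %.4g, TPR %.1f%%, FPR %.1f%%, J = %.3f\n",
              x$threshold, 100 * x$tpr, 100 * x$fpr, x$j))
  if (!is.null(x$tp)) {
    cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  }
  invisible(x)
}

#' Permutation feature importance with joint grouping
#'
#' For each feature, the drop in ROC-AUC (`baseline - mean over permuted
#' repeats`) when that column is randomly permuted, on an evaluation set;
#' features are then grouped by joint (wrist/ankle/elbow/knee) with totals,
#' means and percent-of-total computed from the unrounded group sums.
#'
#' @param model a `kin_model`.
#' @param features evaluation feature table (canonical 38 columns).
#' @param labels aligned labels.
#' @param n_repeats independent permutations per feature (default 10).
#' @param seed integer seed.
#' @return list of class `kin_importance` with `baseline_auc`,
#'   `per_feature` (feature, joint, delta_auc mean and sd) and `grouped`
#'   (joint, n_features, total, mean, sd, pct_of_total).
#' @export
permutation_importance <- function(model, features, labels, n_repeats = 10L,
                                   seed = 1L) {
  X <- feature_matrix(features)
  y <- label01(labels)
  base <- roc_auc(predict_scores(model, X)$score, y)$auc
  p <- ncol(X)
  deltas <- matrix(NA_real_, n_repeats, p)
  seeds <- child_seeds(seed, n_repeats)
  for (r in seq_len(n_repeats)) {
    with_seed(seeds[r], {
      for (j in seq_len(p)) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        deltas[r, j] <- base - roc_auc(predict_scores(model, Xp)$score, y)$auc
      }
    })
  }
  dict <- feature_dictionary()
  joint <- dict$joint[match(colnames(X), dict$feature)]
  per_feature <- data.frame(
    feature = colnames(X), joint = joint,
    delta_auc = colMeans(deltas), delta_auc_sd = apply(deltas, 2L, stats::sd),
    stringsAsFactors = FALSE)
  grp <- split(per_feature, per_feature$joint)
  grouped <- do.call(rbind, lapply(names(grp), function(g) {
    data.frame(joint = g, n_features = nrow(grp[[g]]),
               total = sum(grp[[g]]$delta_auc),
               mean = mean(grp[[g]]$delta_auc),
               sd = stats::sd(grp[[g]]$delta_auc),
               stringsAsFactors = FALSE)
  }))
  grouped$pct_of_total <- 100 * grouped$total / sum(grouped$total)
  grouped <- grouped[order(-grouped$total), ]
  rownames(grouped) <- NULL
  structure(list(baseline_auc = base, per_feature = per_feature,
                 grouped = grouped, n_repeats = n_repeats, seed = seed),
            class = "kin_importance")
}

#' @export
print.kin_importance <- function(x, ...) {
  cat(sprintf("permutation importance (baseline AUC %.3f, %d repeats)\n",
              x$baseline_auc, x$n_repeats))
  print(x$grouped, digits = 3)
  invisible(x)
}

#' Ordinary least squares power-law fit of a learning curve
#'
#' Fits `log(1 - AUC) = intercept + slope * log(n)`; on data generated
#' exactly as `AUC = 1 - c * n^(-beta)` the slope estimate equals `-beta`.
#'
#' @param n training-set sizes (strictly increasing, positive).
#' @param auc mean AUCs in (0, 1), aligned with `n`.
#' @return list with `slope`, `intercept`, `fitted`, `residuals`.
#' @export
fit_power_law <- function(n, auc) {
  assert_that(all(diff(n) > 0), "n grid must be strictly increasing")
  assert_that(all(auc > 0 & auc < 1), "AUCs must lie in (0, 1)")
  lx <- log(n); ly <- log(1 - auc)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       fitted = as.vector(cbind(1, lx) %*% fit$coefficients),
       residuals = unname(fit$residuals))
}

#' Learning-curve scaling analysis
#'
#' Holds out a fixed stratified test set, then for each training size `n`
#' draws `cv_folds` seeded stratified subsamples from the remaining pool,
#' trains the full procedure on each, and records the test-set ROC-AUC.
#' The mean AUC per `n` is fit as a power law in log-log space
#' (`log(1 - AUC)` vs `log(n)`); the slope is expected to be negative when
#' added data helps.
#'
#' @param features feature table or matrix for the whole cohort.
#' @param labels aligned labels.
#' @param n_grid training sizes (default 50, 100, 200, 400, 800).
#' @param test_size held-out evaluation subjects (default 100).
#' @param cv_folds subsample repeats per size (default 6).
#' @param seed master seed.
#' @param config optional [train_config()] template.
#' @return list of class `kin_scaling` with `n_grid`, `auc` (matrix
#'   `cv_folds x length(n_grid)`), `auc_mean`, `slope`, `intercept`,
#'   `residuals`.
#' @export
scaling_curve <- function(features, labels,
                          n_grid = c(50, 100, 200, 400, 800),
                          test_size = 100L, cv_folds = 6L, seed = 1L,
                          config = NULL) {
  X <- feature_matrix(features)
  y <- label01(labels)
  assert_that(nrow(X) >= max(n_grid) + test_size,
              sprintf("scaling_curve: cohort (%d) smaller than max n + test size (%d)",
                      nrow(X), as.integer(max(n_grid) + test_size)))
  seeds <- child_seeds(seed, 1L + cv_folds * length(n_grid))
  # fixed stratified test set
  test_idx <- with_seed(seeds[1], {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    n1 <- round(test_size * length(idx1) / length(y))
    c(sample(idx1, n1), sample(idx0, test_size - n1))
  })
  pool <- setdiff(seq_along(y), test_idx)
  aucs <- matrix(NA_real_, cv_folds, length(n_grid))
  si <- 1L
  for (gi in seq_along(n_grid)) {
    n <- n_grid[gi]
    for (f in seq_len(cv_folds)) {
      si <- si + 1L
      tr <- with_seed(seeds[si], {
        p1 <- intersect(pool, which(y == 1)); p0 <- intersect(pool, which(y == 0))
        k1 <- max(2L, round(n * length(p1) / length(pool)))
        c(sample(p1, min(k1, length(p1))), sample(p0, n - min(k1, length(p1))))
      })
      cfg <- config %||% train_config(seed = seeds[si])
      cfg$seed <- as.integer(seeds[si])
      model <- train(X[tr, , drop = FALSE], y[tr], cfg)
      sc <- predict_scores(model, X[test_idx, , drop = FALSE])
      aucs[f, gi] <- roc_auc(sc$score, y[test_idx])$auc
    }
  }
  auc_mean <- colMeans(aucs)
  pl <- fit_power_law(n_grid, pmin(auc_mean, 1 - 1e-12))
  structure(list(n_grid = n_grid, auc = aucs, auc_mean = auc_mean,
                 slope = pl$slope, intercept = pl$intercept,
                 residuals = pl$residuals, test_size = test_size,
                 cv_folds = cv_folds, seed = seed),
            class = "kin_scaling")
}

#' @export
print.kin_scaling <- function(x, ...) {
  cat("learning-curve scaling: mean AUC by training size\n")
  print(stats::setNames(round(x$auc_mean, 3), x$n_grid))
  cat(sprintf("log-log slope %.3f (intercept %.3f)\n", x$slope, x$intercept))
  invisible(x)
}
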