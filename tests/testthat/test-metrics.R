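# Brute-force oracles for the ranking metrics, written independently of the
# implementations they check.

mw_auc_oracle <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

pr_auc_oracle <- function(s, y) {
  thr <- sort(unique(s), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in thr) {
    tp <- sum(s >= t & y == 1); fp <- sum(s >= t & y == 0)
    r <- tp / sum(y == 1); p <- tp / (tp + fp)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

test_that("ROC-AUC equals Mann-Whitney pair counting, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(20)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.3))
    s <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(roc_auc(s, y)$auc, mw_auc_oracle(s, y))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC curve is monotone with the right endpoints", {
  set.seed(21)
  s <- runif(50); y <- rbinom(50, 1, 0.4)
  cv <- roc_auc(s, y)$curve
  expect_equal(cv$tpr[1], 0); expect_equal(cv$fpr[1], 0)
  expect_equal(cv$tpr[nrow(cv)], 1); expect_equal(cv$fpr[nrow(cv)], 1)
  expect_true(all(diff(cv$tpr) >= 0))
  expect_true(all(diff(cv$fpr) >= 0))
})

test_that("PR-AUC uses the step rule and matches the sweep oracle", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # constant scores: area collapses to the prevalence baseline
  expect_equal(pr_auc(rep(0.3, 20), rep(c(1, 0, 0, 0), 5))$auc, 0.25)
  set.seed(22)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    y <- c(1, rbinom(n - 1, 1, 0.3))
    s <- round(runif(n), 2)
    expect_equal(pr_auc(s, y)$auc, pr_auc_oracle(s, y))
  }
  expect_error(pr_auc(runif(5), rep(0, 5)), "no positives")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(23)
  s <- runif(80); y <- rbinom(80, 1, 0.3); y[1] <- 1; y[2] <- 0
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(plogis(5 * s - 2), y)$auc, a0)
  expect_equal(roc_auc(s^3, y)$auc, a0)
})

test_that("Youden threshold equals the brute-force argmax with the tie rule", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  op <- youden_threshold(r$curve)
  expect_equal(op$threshold, 0.8)  # J = 1 first reached at t = 0.8
  expect_equal(op$j, 1)
  expect_equal(c(op$tp, op$fp, op$tn, op$fn), c(2L, 0L, 2L, 0L))
  set.seed(24)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.3))
    s <- round(runif(n), 2)
    cv <- roc_auc(s, y)$curve
    op <- youden_threshold(cv)
    sweep_j <- vapply(unique(s), function(t) {
      tpr <- sum(s >= t & y == 1) / sum(y == 1)
      fpr <- sum(s >= t & y == 0) / sum(y == 0)
      tpr - fpr
    }, numeric(1))
    expect_equal(op$j, max(sweep_j))
    # tie rule: no larger threshold achieves the same J
    better <- unique(s)[sweep_j >= op$j - 1e-12]
    expect_equal(op$threshold, max(better))
    # J at the returned point dominates every other threshold
    expect_true(all(op$j >= sweep_j - 1e-12))
  }
})

test_that("confusion counts follow the score >= t rule", {
  set.seed(25)
  s <- runif(100); y <- rbinom(100, 1, 0.2)
  t <- 0.42
  op <- confusion_at_threshold(s, y, t)
  expect_equal(op$tp, sum(s >= t & y == 1))
  expect_equal(op$fp, sum(s >= t & y == 0))
  expect_equal(op$tn + op$fn, sum(s < t))
  expect_equal(op$j, op$tpr - op$fpr)
  all_pos <- confusion_at_threshold(s, y, 0)
  expect_equal(all_pos$tpr, 1); expect_equal(all_pos$fpr, 1)
})

test_that("permutation importance isolates informative features", {
  set.seed(26)
  n <- 500
  X <- matrix(rnorm(n * 38), n, 38)
  colnames(X) <- feature_names()
  y <- as.integer(X[, "knee_mean_angle"] + rnorm(n, 0, 0.3) > 0)
  m <- train(X, y, train_config(seed = 1))
  imp <- permutation_importance(m, X, y, n_repeats = 10, seed = 2)
  driver <- imp$per_feature$delta_auc[imp$per_feature$feature == "knee_mean_angle"]
  # permuting the single informative feature collapses AUC to ~0.5
  expect_equal(driver, imp$baseline_auc - 0.5, tolerance = 0.05)
  others <- imp$per_feature$delta_auc[imp$per_feature$feature != "knee_mean_angle"]
  expect_lt(max(abs(others)), 0.05)
  expect_equal(sort(unique(imp$per_feature$joint)),
               c("ankle", "elbow", "knee", "wrist"))
  expect_equal(imp$grouped$n_features[match(c("wrist", "ankle", "elbow", "knee"),
                                            imp$grouped$joint)],
               c(12L, 12L, 7L, 7L))
  expect_equal(sum(imp$grouped$pct_of_total), 100, tolerance = 0.1)
})

test_that("power-law slope recovery is exact on constructed inputs", {
  n <- c(50, 100, 200, 400, 800)
  for (beta in c(0.2, 0.5, 1.1)) {
    auc <- 1 - 0.9 * n^(-beta)
    fit <- fit_power_law(n, auc)
    expect_equal(fit$slope, -beta, tolerance = 1e-10)
    expect_lt(max(abs(fit$residuals)), 1e-12)
  }
  expect_error(fit_power_law(c(2, 1), c(0.6, 0.7)), "increasing")
})

test_that("the scaling machinery runs end to end on a tractable cohort", {
  gf <- gaussian_features(n = 420, delta = 1, seed = 27)
  sc <- scaling_curve(gf$X, gf$y, n_grid = c(40, 80, 160, 300),
                      test_size = 100, cv_folds = 2, seed = 3)
  expect_equal(dim(sc$auc), c(2L, 4L))
  expect_true(all(sc$auc_mean > 0.5 & sc$auc_mean <= 1))
  expect_lt(sc$slope, 0)  # added data helps on a separable cohort
  expect_error(scaling_curve(gf$X, gf$y, n_grid = c(1000), test_size = 100,
                             seed = 1),
               "smaller than")
})
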