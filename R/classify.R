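#' @title Imbalance-aware binary classification of FM status
#' @description Trains a binary classifier of fidgety-movement absence
#'   (FM-, the positive/risk class) on the 38-feature table under the
#'   contract used by AutoML frameworks for this problem: balanced-accuracy
#'   objective, internal stratified cross-validation, inverse-prevalence
#'   class weighting, and a single final model (no ensembling). The
#'   `builtin` backend evaluates a small fixed candidate family (elastic-net
#'   logistic regression over a penalty grid; gradient-boosted stumps over
#'   a learning-rate/rounds grid); an `automl` hook lets users delegate to
#'   an external engine under the same seed/budget contract.
#' @name classify
NULL

#' Training configuration
#'
#' @param objective optimization metric; only `"balanced_accuracy"` is
#'   implemented (the appropriate choice at ~10:1 class imbalance).
#' @param cv_folds internal cross-validation folds (default 5).
#' @param seed integer seed (required; all internal shuffling derives from
#'   it).
#' @param imbalance `"class_weight"` (inverse-prevalence weights, default)
#'   or `"oversample"` (seeded minority oversampling to balance).
#' @param backend `"builtin"` or `"automl"`.
#' @param automl_fn for `backend = "automl"`: a function
#'   `(X, y, weights, seed)` returning a list with a `predict(X)` giving
#'   probabilities.
#' @return list of class `kin_train_config`.
#' @export
train_config <- function(objective = "balanced_accuracy", cv_folds = 5L,
                         seed = NULL,
                         imbalance = c("class_weight", "oversample"),
                         backend = c("builtin", "automl"),
                         automl_fn = NULL) {
  imbalance <- match.arg(imbalance)
  backend <- match.arg(backend)
  assert_that(!is.null(seed), "train_config: a seed is required")
  assert_that(identical(objective, "balanced_accuracy"),
              "only balanced_accuracy is implemented")
  structure(list(objective = objective, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), imbalance = imbalance,
                 backend = backend, automl_fn = automl_fn),
            class = "kin_train_config")
}

# ---- internal helpers -----------------------------------------------------

# coerce a feature table (data.frame with canonical columns, or matrix) to
# a numeric matrix with the canonical signature
feature_matrix <- function(features) {
  if (is.matrix(features)) {
    X <- features
  } else {
    fn <- intersect(feature_names(), names(features))
    if (length(fn) == 0L) {
      fn <- names(features)[vapply(features, is.numeric, logical(1))]
      fn <- setdiff(fn, c("subject_id", "label"))
    }
    X <- as.matrix(features[, fn, drop = FALSE])
  }
  storage.mode(X) <- "double"
  X
}

# labels -> 0/1 with FM_minus (risk) = 1
label01 <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  lab <- normalize_label(as.character(labels))
  as.integer(lab == "FM_minus")
}

balanced_accuracy <- function(y, score, threshold = 0.5) {
  pred <- as.integer(score >= threshold)
  tpr <- if (sum(y == 1) > 0) mean(pred[y == 1] == 1) else NA_real_
  tnr <- if (sum(y == 0) > 0) mean(pred[y == 0] == 0) else NA_real_
  (tpr + tnr) / 2
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# per-column standardization statistics from training rows only (anti-leakage:
# these are never computed on evaluation rows)
fit_scaler <- function(X) {
  ctr <- colMeans(X, na.rm = TRUE)
  scl <- apply(X, 2L, stats::sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl == 0] <- 1
  med <- apply(X, 2L, stats::median, na.rm = TRUE)
  list(center = ctr, scale = scl, impute = med)
}

apply_scaler <- function(X, sc) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- sc$impute[j]
  }
  sweep(sweep(X, 2L, sc$center), 2L, sc$scale, "/")
}

class_weights <- function(y) {
  n <- length(y)
  w <- numeric(n)
  w[y == 1] <- n / (2 * sum(y == 1))
  w[y == 0] <- n / (2 * sum(y == 0))
  w
}

# ---- candidate family -----------------------------------------------------

builtin_candidates <- function() {
  cands <- list()
  for (alpha in c(0, 0.5, 1)) {
    for (lambda in 10^seq(-3, 0, length.out = 5)) {
      cands[[length(cands) + 1L]] <- list(kind = "glmnet", alpha = alpha,
                                          lambda = lambda)
    }
  }
  for (lr in c(0.1, 0.3)) {
    for (rounds in c(50L, 150L)) {
      cands[[length(cands) + 1L]] <- list(kind = "stumps", learning_rate = lr,
                                          rounds = rounds)
    }
  }
  cands
}

fit_candidate <- function(cand, X, y, w) {
  if (cand$kind == "glmnet") {
    # glmnet warns on very small classes, routine in minority-class CV folds
    fit <- suppressWarnings(
      glmnet::glmnet(X, y, family = "binomial", weights = w,
                     alpha = cand$alpha, lambda = cand$lambda,
                     standardize = FALSE))
    list(cand = cand, fit = fit)
  } else {
    list(cand = cand,
         fit = fit_boosted_stumps(X, y, w, rounds = cand$rounds,
                                  lr = cand$learning_rate))
  }
}

predict_candidate <- function(model, X) {
  if (model$cand$kind == "glmnet") {
    as.numeric(stats::predict(model$fit, newx = X, type = "response",
                              s = model$cand$lambda))
  } else {
    predict_boosted_stumps(model$fit, X)
  }
}

# Gradient-boosted decision stumps for weighted binomial deviance.
# Each round fits a depth-1 regressor to the negative gradient (y - p),
# choosing the feature/quantile split with the lowest weighted SSE —
# equivalently the largest sum_left^2/w_left + sum_right^2/w_right.
# Split indicators are precomputed once so each round is one BLAS
# crossprod. Deterministic: no internal RNG; ties go to the first split in
# the fixed enumeration.
fit_boosted_stumps <- function(X, y, w, rounds = 100L, lr = 0.1,
                               n_cuts = 8L) {
  n <- nrow(X); p <- ncol(X)
  w <- w / mean(w)
  feat_of <- integer(0); cut_of <- numeric(0)
  cols <- list()
  for (j in seq_len(p)) {
    cj <- unique(stats::quantile(X[, j], probs = seq_len(n_cuts) / (n_cuts + 1),
                                 names = FALSE, type = 7))
    for (cv in cj) {
      cols[[length(cols) + 1L]] <- as.numeric(X[, j] <= cv)
      feat_of <- c(feat_of, j); cut_of <- c(cut_of, cv)
    }
  }
  M <- do.call(cbind, cols)                 # n x n_splits indicator matrix
  wl <- as.vector(crossprod(M, w))
  wr <- sum(w) - wl
  valid <- wl > 1e-12 & wr > 1e-12
  prior <- stats::qlogis(min(max(stats::weighted.mean(y, w), 1e-6), 1 - 1e-6))
  Fx <- rep(prior, n)
  stumps <- vector("list", rounds)
  for (m in seq_len(rounds)) {
    g <- y - stats::plogis(Fx)
    wg <- w * g
    suml <- as.vector(crossprod(M, wg))
    sumr <- sum(wg) - suml
    gain <- suml^2 / wl + sumr^2 / wr
    gain[!valid] <- -Inf
    s <- which.max(gain)
    ml <- suml[s] / wl[s]; mr <- sumr[s] / wr[s]
    stumps[[m]] <- list(feature = feat_of[s], cut = cut_of[s],
                        left = ml, right = mr)
    Fx <- Fx + lr * 4 * ifelse(M[, s] > 0, ml, mr)  # 1/4 bounds the hessian
  }
  list(prior = prior, lr = lr, stumps = stumps)
}

predict_boosted_stumps <- function(fit, X) {
  Fx <- rep(fit$prior, nrow(X))
  for (s in fit$stumps) {
    Fx <- Fx + fit$lr * 4 *
      ifelse(X[, s$feature] <= s$cut, s$left, s$right)
  }
  stats::plogis(Fx)
}

# ---- public API -----------------------------------------------------------

#' Train the FM- risk classifier
#'
#' Builtin backend: evaluates every candidate by stratified internal
#' cross-validation on balanced accuracy (standardization and median
#' imputation statistics computed within each training fold only), then
#' refits the single best candidate on all training data. Scores are native
#' class probabilities in \[0, 1\]; higher = more FM-minus-like.
#' Deterministic given the config seed.
#'
#' @param features feature table (data.frame with the canonical 38 columns)
#'   or numeric matrix.
#' @param labels labels aligned with rows (`FM_minus`/`FM-` = positive, or
#'   0/1).
#' @param config a [train_config()].
#' @return An object of class `kin_model` with the fitted candidate, the
#'   full-data scaler, the feature-name signature and training metadata
#'   (candidate grid, internal-CV balanced accuracies, chosen candidate).
#' @export
train <- function(features, labels, config) {
  stopifnot(inherits(config, "kin_train_config"))
  X <- feature_matrix(features)
  y <- label01(labels)
  assert_that(length(unique(y)) == 2L,
              "train: both classes must be present")

  if (config$backend == "automl") {
    assert_that(is.function(config$automl_fn),
                "backend 'automl' requires an automl_fn hook")
    sc <- fit_scaler(X)
    Xs <- apply_scaler(X, sc)
    w <- class_weights(y)
    fit <- config$automl_fn(Xs, y, w, config$seed)
    model <- structure(list(backend = "automl", fit = fit, scaler = sc,
                            feature_signature = colnames(X),
                            meta = list(seed = config$seed)),
                       class = "kin_model")
    return(model)
  }

  cands <- builtin_candidates()
  # internal folds cannot exceed the minority-class count
  k <- max(2L, min(config$cv_folds, sum(y == 1), sum(y == 0)))
  fold <- stratified_folds(y, k, config$seed)
  cv_ba <- matrix(NA_real_, nrow = length(cands), ncol = k)
  for (f in seq_len(k)) {
    tr <- fold != f
    sc <- fit_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(X[tr, , drop = FALSE], sc)
    Xte <- apply_scaler(X[!tr, , drop = FALSE], sc)
    ytr <- y[tr]
    if (min(sum(ytr == 1), sum(ytr == 0)) < 2L) next
    w <- training_weights(ytr, config)
    dat <- resample_if_needed(Xtr, ytr, w, config, config$seed + f)
    for (ci in seq_along(cands)) {
      m <- fit_candidate(cands[[ci]], dat$X, dat$y, dat$w)
      cv_ba[ci, f] <- balanced_accuracy(y[!tr], predict_candidate(m, Xte))
    }
  }
  mean_ba <- rowMeans(cv_ba, na.rm = TRUE)
  best_i <- if (any(is.finite(mean_ba))) which.max(mean_ba) else 1L
  # ties: first candidate in the fixed grid

  sc <- fit_scaler(X)
  Xs <- apply_scaler(X, sc)
  w <- training_weights(y, config)
  dat <- resample_if_needed(Xs, y, w, config, config$seed)
  final <- fit_candidate(cands[[best_i]], dat$X, dat$y, dat$w)

  structure(list(
    backend = "builtin", fit = final, scaler = sc,
    feature_signature = colnames(X),
    meta = list(seed = config$seed,
                candidates = cands,
                internal_cv_balanced_accuracy = mean_ba,
                chosen = cands[[best_i]],
                chosen_index = best_i,
                internal_cv_ba_best = mean_ba[best_i])
  ), class = "kin_model")
}

training_weights <- function(y, config) {
  if (config$imbalance == "class_weight") class_weights(y) else rep(1, length(y))
}

resample_if_needed <- function(X, y, w, config, seed) {
  if (config$imbalance != "oversample") return(list(X = X, y = y, w = w))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) return(list(X = X, y = y, w = w))
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  idx <- which(y == minority)
  extra <- with_seed(seed, sample(idx, need, replace = TRUE))
  list(X = rbind(X, X[extra, , drop = FALSE]), y = c(y, y[extra]),
       w = c(w, w[extra]))
}

#' @export
print.kin_model <- function(x, ...) {
  if (x$backend == "builtin") {
    ch <- x$meta$chosen
    desc <- if (ch$kind == "glmnet") {
      sprintf("elastic-net logistic (alpha %.1f, lambda %.4g)", ch$alpha, ch$lambda)
    } else {
      sprintf("boosted stumps (lr %.2f, %d rounds)", ch$learning_rate, ch$rounds)
    }
    cat(sprintf("kin_model [builtin]: %s, internal-CV balanced accuracy %.3f\n",
                desc, x$meta$internal_cv_ba_best))
  } else cat("kin_model [automl backend]\n")
  invisible(x)
}

#' Score feature rows with a trained model
#'
#' @param model a `kin_model`.
#' @param features feature table or matrix; its columns must match the
#'   model's feature signature.
#' @param ids optional subject ids (taken from a `subject_id` column when
#'   present).
#' @param labels optional true labels to carry along.
#' @return An object of class `kin_scores`: data.frame with `subject_id`,
#'   `score` in \[0, 1\] and `label`.
#' @export
predict_scores <- function(model, features, ids = NULL, labels = NULL) {
  stopifnot(inherits(model, "kin_model"))
  X <- feature_matrix(features)
  if (!identical(colnames(X), model$feature_signature)) {
    stop("predict_scores: feature signature mismatch", call. = FALSE)
  }
  Xs <- apply_scaler(X, model$scaler)
  s <- if (model$backend == "automl") model$fit$predict(Xs)
       else predict_candidate(model$fit, Xs)
  s <- pmin(1, pmax(0, as.numeric(s)))
  if (is.null(ids) && is.data.frame(features) && "subject_id" %in% names(features)) {
    ids <- features$subject_id
  }
  if (is.null(labels) && is.data.frame(features) && "label" %in% names(features)) {
    labels <- features$label
  }
  out <- data.frame(subject_id = ids %||% as.character(seq_len(nrow(X))),
                    score = s,
                    label = if (is.null(labels)) NA_character_ else as.character(labels),
                    stringsAsFactors = FALSE)
  class(out) <- c("kin_scores", "data.frame")
  out
}

#' Repeated stratified cross-validation of the full training procedure
#'
#' Subject-wise stratified k-fold cross-validation, repeated with several
#' derived seeds; reports per-fold ROC-AUCs and their mean and standard
#' deviation. Callers evaluating a preregistered design must pass only
#' development (Train/Val) subjects — lock-box ids never belong here.
#'
#' @param features feature table or matrix.
#' @param labels aligned labels.
#' @param k folds (default 5).
#' @param n_seeds number of repeats with different shuffles (default 6).
#' @param seed master seed; repeat seeds are derived from it.
#' @param config optional [train_config()] template (its seed is replaced
#'   per repeat).
#' @return list with `auc` (n_seeds x k matrix), `mean`, `sd`.
#' @export
cross_validate <- function(features, labels, k = 5L, n_seeds = 6L, seed = 1L,
                           config = NULL) {
  X <- feature_matrix(features)
  y <- label01(labels)
  assert_that(k >= 2L, "cross_validate: k must be >= 2")
  if (sum(y == 1) < k || sum(y == 0) < k) {
    stop("cross_validate: too few subjects in a class for ", k,
         " stratified folds; use fewer folds", call. = FALSE)
  }
  seeds <- child_seeds(seed, n_seeds)
  aucs <- matrix(NA_real_, n_seeds, k)
  for (r in seq_len(n_seeds)) {
    fold <- stratified_folds(y, k, seeds[r])
    for (f in seq_len(k)) {
      tr <- fold != f
      cfg <- config %||% train_config(seed = seeds[r])
      cfg$seed <- as.integer(seeds[r])
      model <- train(X[tr, , drop = FALSE], y[tr], cfg)
      sc <- predict_scores(model, X[!tr, , drop = FALSE])
      aucs[r, f] <- roc_auc(sc$score, y[!tr])$auc
    }
  }
  list(auc = aucs, mean = mean(aucs), sd = stats::sd(as.vector(aucs)))
}
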