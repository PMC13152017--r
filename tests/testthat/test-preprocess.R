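# Independent oracles for the preprocessing stages are coded inline here,
# deliberately without reusing any package internals.

brute_roll <- function(v, h, fun) {
  n <- length(v)
  vapply(seq_len(n), function(i) fun(v[max(1, i - h):min(n, i + h)]),
         numeric(1))
}

test_that("best-detection selection equals a brute-force argmax scan", {
  set.seed(42)
  n <- 200
  x <- matrix(runif(n * 17), n, 17); y <- matrix(runif(n * 17), n, 17)
  conf <- matrix(runif(n * 17), n, 17)
  score <- runif(n)
  extra <- list()
  expected_best <- score
  expected_x1 <- x[, 1]
  for (i in seq_len(n)) {
    for (d in seq_len(sample(0:2, 1))) {
      cand <- list(frame = i - 1L, x = runif(17), y = runif(17),
                   conf = runif(17), score = runif(1))
      extra[[length(extra) + 1L]] <- cand
      if (cand$score > expected_best[i]) {
        expected_best[i] <- cand$score
        expected_x1[i] <- cand$x[1]
      }
    }
  }
  raw <- raw_detections(x, y, conf, score, extra, fps = 30)
  seq <- select_best_detection(raw)
  expect_equal(seq$x[, 1], expected_x1)
})

test_that("score fallback uses mean keypoint confidence", {
  raw <- random_raw(n = 5, seed = 1, extra = FALSE)
  raw$score[] <- NA_real_
  seq <- select_best_detection(raw)
  expect_identical(seq$x, raw$x)  # single candidate kept regardless
})

test_that("confidence masking matches a direct count and is idempotent", {
  set.seed(7)
  raw <- random_raw(n = 300, seed = 7, extra = FALSE)
  seq <- select_best_detection(raw)
  m1 <- mask_low_confidence(seq, 0.8)
  expect_equal(sum(is.na(m1$x)), sum(raw$conf < 0.8))
  expect_equal(attr(m1, "retention"), mean(raw$conf >= 0.8))
  m2 <- mask_low_confidence(m1, 0.8)
  expect_identical(m2$x, m1$x)  # idempotent
  # retention monotone non-increasing in threshold
  rets <- vapply(c(0, 0.25, 0.5, 0.8, 1),
                 function(t) attr(mask_low_confidence(seq, t), "retention"),
                 numeric(1))
  expect_true(all(diff(rets) <= 0))
  # frame mode masks whole frames
  mf <- mask_low_confidence(seq, 0.8, mask_mode = "frame")
  bad_frames <- apply(raw$conf < 0.8, 1, any)
  expect_true(all(is.na(mf$x[bad_frames, ])))
})

test_that("gap interpolation is exact and matches a two-point oracle", {
  # forced linear fill
  seq <- list(x = matrix(c(0, NA, NA, 3), 4, 17), y = matrix(0, 4, 17),
              conf = matrix(1, 4, 17), fps = 30, subject_id = "t")
  out <- interpolate_gaps(seq)
  expect_equal(out$x[, 1], c(0, 1, 2, 3))
  expect_identical(interpolate_gaps(out)$x, out$x)  # no gaps -> identity

  # random walk with random mask vs independent oracle
  set.seed(9)
  v <- cumsum(rnorm(200))
  mask <- sample(200, 60)
  mask <- setdiff(mask, c(1, 200))
  vm <- v; vm[mask] <- NA
  oracle <- vm
  obs <- which(!is.na(vm))
  for (i in which(is.na(vm))) {
    lo <- max(obs[obs < i]); hi <- min(obs[obs > i])
    oracle[i] <- vm[lo] + (vm[hi] - vm[lo]) * (i - lo) / (hi - lo)
  }
  seq$x <- matrix(vm, 200, 17); seq$y <- matrix(0, 200, 17)
  expect_equal(interpolate_gaps(seq)$x[, 3], oracle)

  # unrecoverable track
  seq$x[, 5] <- NA; seq$x[1, 5] <- 1
  expect_error(interpolate_gaps(seq), "right_ear")
})

test_that("rolling median and mean equal brute-force sliding windows", {
  set.seed(13)
  v <- rnorm(257)
  n <- length(v)
  base <- list(x = matrix(v, n, 17), y = matrix(rev(v), n, 17),
               conf = matrix(1, n, 17), fps = 30, subject_id = "t")
  med <- rolling_median_despike(base, window_s = 1)
  h <- 15L  # round(30)/2 forced odd -> 31 -> h = 15
  expect_equal(med$x[, 1], brute_roll(v, h, median))
  mn <- rolling_mean_smooth(base, window_s = 1)
  expect_equal(mn$x[, 1], brute_roll(v, h, mean))
  # window longer than the video errors
  expect_error(rolling_median_despike(base, window_s = 10), "shorter")
})

test_that("despiking removes isolated spikes and preserves ramps", {
  n <- 120
  v <- rep(5, n); v[60] <- 105
  base <- list(x = matrix(v, n, 17), y = matrix(seq_len(n) / 10, n, 17),
               conf = matrix(1, n, 17), fps = 30, subject_id = "t")
  out <- rolling_median_despike(base, window_s = 1)
  expect_equal(out$x[, 1], rep(5, n))           # spike gone
  expect_equal(out$y[16:105, 1], base$y[16:105, 1])  # interior ramp untouched
  # despike property for the minimum window: any isolated excursion removed
  v2 <- rep(1, n); v2[37] <- -50
  base$x <- matrix(v2, n, 17)
  out2 <- rolling_median_despike(base, window_s = 0.1)  # w = 3
  expect_equal(out2$x[, 1], rep(1, n))
})

test_that("alternating signal is attenuated by the rolling mean", {
  n <- 300
  v <- rep(c(1, -1), length.out = n)
  base <- list(x = matrix(v, n, 17), y = matrix(0, n, 17),
               conf = matrix(1, n, 17), fps = 30, subject_id = "t")
  out <- rolling_mean_smooth(base, window_s = 1)
  # mean of 31 alternating values is +-1/31
  expect_true(all(abs(out$x[16:(n - 15), 1]) <= 1 / 31 + 1e-12))
})

test_that("the full pipeline is deterministic and accounts for retention", {
  s <- generate_subject(synth_class_params(1)$FM_plus, fps = 30,
                        duration_s = 30, seed = 5,
                        noise = list(jitter_sd_px = 1, dropout_prob = 0.05,
                                     spike_prob = 0.01,
                                     spike_magnitude_px = 100,
                                     extra_detection_prob = 0))
  a <- preprocess_pipeline(s$raw)
  b <- preprocess_pipeline(s$raw)
  expect_identical(a$x, b$x)
  expect_equal(a$retention, 0.95, tolerance = 0.02)
  expect_false(anyNA(a$x))
  # clean input: retention 1, nothing masked
  s2 <- generate_subject(synth_class_params(1)$FM_plus, fps = 30,
                         duration_s = 30, seed = 5, noise = quiet_noise())
  cl <- preprocess_pipeline(s2$raw)
  expect_equal(cl$retention, 1.0)
  expect_equal(sum(cl$mask_log), 0)
})

test_that("pipeline output is invariant to FPS relabeling with fixed data", {
  # windows are specified in seconds: relabeling fps 30 -> 60 while halving
  # window_s leaves w identical, so outputs must match exactly
  raw <- random_raw(n = 200, seed = 21, extra = FALSE)
  raw$conf[] <- 1
  cfg30 <- preprocess_config(median_window_s = 1, mean_window_s = 1)
  out30 <- preprocess_pipeline(raw, cfg30)
  raw60 <- raw; raw60$fps <- 60
  cfg60 <- preprocess_config(median_window_s = 0.5, mean_window_s = 0.5)
  out60 <- preprocess_pipeline(raw60, cfg60)
  expect_identical(out30$x, out60$x)
})
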