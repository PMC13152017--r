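test_that("finite differences match an independent oracle", {
  expect_equal(finite_difference(rep(3, 50), 30, 1), rep(0, 50))
  # linear ramp x = 2 t
  fps <- 30
  x <- 2 * (0:59) / fps
  expect_equal(finite_difference(x, fps, 1), rep(2, 60))
  expect_equal(finite_difference(x, fps, 2), rep(0, 60))
  # independent oracle: explicit index arithmetic
  set.seed(3)
  v <- rnorm(40)
  d <- finite_difference(v, 25, 1)
  oracle <- numeric(40)
  for (i in 2:39) oracle[i] <- (v[i + 1] - v[i - 1]) / 2 * 25
  oracle[1] <- (v[2] - v[1]) * 25
  oracle[40] <- (v[40] - v[39]) * 25
  expect_equal(d, oracle)
  expect_error(finite_difference(1, 30, 1), "too short")
})

test_that("joint angles agree with an atan2 oracle", {
  # build a 2-frame sequence placing shoulder/elbow/wrist explicitly
  mk <- function(sx, sy, ex, ey, wx, wy) {
    x <- matrix(0, 2, 17); y <- matrix(0, 2, 17)
    x[, 6] <- sx; y[, 6] <- sy
    x[, 8] <- ex; y[, 8] <- ey
    x[, 10] <- wx; y[, 10] <- wy
    list(x = x, y = y, fps = 30, subject_id = "t")
  }
  expect_equal(joint_angle(mk(0, 0, 1, 0, 2, 0), "elbow", "left")[1], 180)
  expect_equal(joint_angle(mk(0, 0, 1, 0, 1, 5), "elbow", "left")[1], 90)
  set.seed(12)
  for (i in 1:20) {
    p <- runif(6, -5, 5)
    seqq <- mk(p[1], p[2], p[3], p[4], p[5], p[6])
    got <- joint_angle(seqq, "elbow", "left")[1]
    a1 <- atan2(p[2] - p[4], p[1] - p[3])
    a2 <- atan2(p[6] - p[4], p[5] - p[3])
    oracle <- abs(((a1 - a2) * 180 / pi + 180) %% 360 - 180)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("robust statistics match closed forms and a sort-based oracle", {
  rs <- robust_stats(c(1, 2, 3, 4, 5))
  expect_equal(rs$median, 3); expect_equal(rs$iqr, 2); expect_equal(rs$mean, 3)
  rc <- robust_stats(rep(4, 10))
  expect_equal(rc$iqr, 0); expect_equal(rc$sd, 0)
  set.seed(8)
  v <- rnorm(101)
  rs <- robust_stats(v)
  sv <- sort(v)
  expect_equal(rs$median, sv[51])
  q <- function(p) {  # type-7 linear interpolation oracle
    hh <- (length(sv) - 1) * p
    sv[floor(hh) + 1] + (hh - floor(hh)) * (sv[floor(hh) + 2] - sv[floor(hh) + 1])
  }
  expect_equal(rs$iqr, q(0.75) - q(0.25))
  expect_error(robust_stats(1), "at least 2")
})

test_that("binned entropy matches a hand-rolled histogram oracle", {
  expect_equal(shannon_entropy(rep(2, 100)), 0)
  # exactly uniform over 50 bins: entropy = log2(50)
  x <- rep(seq(0.5, 49.5), each = 4) / 50
  expect_equal(shannon_entropy(x, n_bins = 50, qrange = c(0, 1)), log2(50))
  set.seed(4)
  v <- rnorm(500)
  q <- quantile(v, c(0.01, 0.99), names = FALSE)
  vc <- pmin(q[2], pmax(q[1], v))
  cnt <- table(cut(vc, seq(q[1], q[2], length.out = 51), include.lowest = TRUE))
  p <- as.numeric(cnt) / 500
  p <- p[p > 0]
  expect_equal(shannon_entropy(v), -sum(p * log2(p)), tolerance = 1e-12)
})

test_that("max cross-correlation recovers lags and respects conventions", {
  fps <- 30
  t <- (0:299) / fps
  s <- sin(2 * pi * 1.3 * t)
  expect_equal(max_xcorr(s, s, fps)$value, 1)
  expect_equal(max_xcorr(s, s, fps)$lag, 0L)
  expect_equal(max_xcorr(s, -s, fps)$value, 1)  # absolute correlation
  shifted <- sin(2 * pi * 1.3 * (t + 0.2))
  res <- max_xcorr(s, shifted, fps, max_lag_s = 0.5)
  expect_gte(res$value, 0.999)
  expect_equal(abs(res$lag), round(0.2 * fps))
  # zero-variance rule
  z <- max_xcorr(rep(1, 300), s, fps)
  expect_equal(z$value, 0)
  expect_true(z$degenerate)
  # brute force over all lags
  set.seed(6)
  a <- rnorm(120); b <- rnorm(120)
  res <- max_xcorr(a, b, fps = 20, max_lag_s = 0.5)
  L <- 10
  oracle <- max(vapply(-L:L, function(tau) {
    n <- 120
    if (tau >= 0) abs(cor(a[1:(n - tau)], b[(1 + tau):n]))
    else abs(cor(a[(1 - tau):n], b[1:(n + tau)]))
  }, numeric(1)))
  expect_equal(res$value, oracle)
})

test_that("the feature vector has the preregistered structure", {
  nm <- tiny_norm(seed = 2)
  fv <- feature_vector(nm)
  expect_length(fv, 38L)
  expect_identical(names(fv), feature_names())
  counts <- table(feature_dictionary()$joint)
  expect_equal(unname(counts[c("wrist", "ankle", "elbow", "knee")]),
               c(12L, 12L, 7L, 7L), ignore_attr = TRUE)
  expect_true(all(is.finite(fv)))
  expect_true(all(fv[grepl("xcorr", names(fv))] >= 0 &
                  fv[grepl("xcorr", names(fv))] <= 1))
  expect_true(all(fv[grepl("entropy", names(fv))] >= 0))
})

test_that("a perfectly static pose yields the zero-variance feature pattern", {
  params <- list(amplitude_px = 0, amplitude_sd_px = 0,
                 k_components = c(2L, 2L), coupling = 0.5, rest_frac = 0,
                 freq_range_hz = c(0.5, 4))
  s <- generate_subject(params, fps = 30, duration_s = 20, seed = 3,
                        noise = quiet_noise())
  # remove residual shoulder sway so the pose is exactly static
  s$raw$x <- matrix(s$raw$x[1, ], nrow(s$raw$x), 17, byrow = TRUE)
  s$raw$y <- matrix(s$raw$y[1, ], nrow(s$raw$y), 17, byrow = TRUE)
  fv <- feature_vector(head_up_normalize(preprocess_pipeline(s$raw)))
  vel_acc <- grepl("iqr_velocity|iqr_acceleration|iqr_angular|abs_velocity|abs_angular",
                   names(fv))
  expect_equal(unname(fv[vel_acc]), rep(0, sum(vel_acc)))
  expect_equal(unname(fv[grepl("entropy", names(fv))]), rep(0, 4))
  expect_equal(unname(fv[grepl("xcorr", names(fv))]), rep(0, 4))
})

test_that("doubling movement amplitude increases velocity IQR features", {
  par1 <- list(amplitude_px = 25, amplitude_sd_px = 0, k_components = c(3L, 3L),
               coupling = 0.3, rest_frac = 0, freq_range_hz = c(0.5, 4))
  par2 <- par1; par2$amplitude_px <- 50
  f <- function(p) {
    s <- generate_subject(p, fps = 30, duration_s = 40, seed = 77,
                          noise = quiet_noise())
    feature_vector(head_up_normalize(preprocess_pipeline(s$raw)))
  }
  f1 <- f(par1); f2 <- f(par2)
  iqr_vel <- grepl("iqr_velocity", names(f1))
  expect_true(all(f2[iqr_vel] > f1[iqr_vel]))
})

test_that("windowed features follow the window-count formula", {
  nm <- tiny_norm(seed = 4, duration_s = 10)
  wt <- windowed_features(nm, window_s = 2, overlap_frac = 0.5)
  expect_equal(nrow(wt), 9L)  # floor((10 - 2)/1) + 1
  set.seed(15)
  for (dur in c(7.3, 12.8, 21.1)) {
    nm2 <- tiny_norm(seed = 6, duration_s = dur)
    wt2 <- windowed_features(nm2, window_s = 2, overlap_frac = 0.5)
    n_frames <- round(dur * 30)
    expect_equal(nrow(wt2), floor((n_frames / 30 - 2) / 1) + 1)
  }
  # stationary signal: window medians track the whole-video value
  nm3 <- tiny_norm(seed = 8, duration_s = 30)
  fv <- feature_vector(nm3)
  wt3 <- windowed_features(nm3)
  expect_equal(median(wt3$wrist_median_position_y),
               unname(fv["wrist_median_position_y"]), tolerance = 0.05)
  short <- nm3
  short$x <- short$x[1:30, ]; short$y <- short$y[1:30, ]  # 1 s at 30 FPS
  expect_error(windowed_features(short, window_s = 2),
               "shorter than one window")
})
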