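#' @title The preregistered 38-feature kinematic vector
#' @description Computes, from a normalized keypoint sequence, the
#'   38 clinician-motivated kinematic features: position/velocity/
#'   acceleration statistics of the wrists and ankles (per axis, left/right
#'   averaged), joint-angle statistics of the elbows and knees, binned
#'   Shannon entropy as a complexity measure, and maximum lagged bilateral
#'   cross-correlation as a left-right coordination measure. Features are
#'   aggregated over the whole video or within overlapping 2-s sliding
#'   windows.
#' @name features
NULL

#' Feature extraction configuration
#' @param entropy_bins histogram bins for the entropy estimator (default 50).
#' @param entropy_qrange robust histogram range quantiles (default 1%/99%).
#' @param max_lag_s cross-correlation lag window in seconds (default 0.5).
#' @return list of config values.
#' @export
features_config <- function(entropy_bins = 50L,
                            entropy_qrange = c(0.01, 0.99),
                            max_lag_s = 0.5) {
  assert_that(entropy_bins >= 2L, "entropy_bins must be >= 2")
  assert_that(max_lag_s > 0, "max_lag_s must be positive")
  list(entropy_bins = as.integer(entropy_bins),
       entropy_qrange = entropy_qrange, max_lag_s = max_lag_s)
}

#' Finite-difference derivative of a sampled signal
#'
#' Central differences scaled by the frame rate (units per second for
#' `order = 1`); endpoints use one-sided differences. `order = 2` is the
#' first-derivative operator applied twice.
#'
#' @param signal numeric time series.
#' @param fps sampling rate (frames/second).
#' @param order 1 (velocity) or 2 (acceleration).
#' @return numeric series of the same length.
#' @export
finite_difference <- function(signal, fps, order = 1L) {
  assert_that(order %in% c(1L, 2L), "order must be 1 or 2")
  n <- length(signal)
  assert_that(n >= order + 1L,
              sprintf("series too short (%d) for order-%d derivative", n, order))
  d1 <- function(v) {
    m <- length(v)
    out <- numeric(m)
    out[2:(m - 1)] <- (v[3:m] - v[1:(m - 2)]) / 2
    out[1] <- v[2] - v[1]
    out[m] <- v[m] - v[m - 1]
    out * fps
  }
  out <- d1(signal)
  if (order == 2L) out <- d1(out)
  out
}

#' Interior joint angle time series
#'
#' The angle at the joint vertex between the proximal segment (elbow:
#' shoulder, knee: hip) and the distal segment (elbow: wrist, knee: ankle),
#' via the arccosine of the normalized dot product (argument clipped to
#' \[-1, 1\]), in degrees within \[0, 180\]. Frames where a segment
#' degenerates to zero length get an undefined angle, which is interpolated
#' from neighboring frames and counted in the `n_undefined` attribute.
#'
#' @param seq a `kin_norm` (or any gap-free) sequence.
#' @param joint `"elbow"` or `"knee"`.
#' @param side `"left"` or `"right"`.
#' @param skeleton a [coco17_skeleton()].
#' @return numeric angle series (degrees), one value per frame.
#' @export
joint_angle <- function(seq, joint = c("elbow", "knee"),
                        side = c("left", "right"),
                        skeleton = coco17_skeleton()) {
  joint <- match.arg(joint)
  side <- match.arg(side)
  j <- skeleton$joint_groups[[joint]][[side]]
  p <- skeleton$angle_anchors[[joint]]$proximal[[side]]
  d <- skeleton$angle_anchors[[joint]]$distal[[side]]
  v1x <- seq$x[, p] - seq$x[, j]; v1y <- seq$y[, p] - seq$y[, j]
  v2x <- seq$x[, d] - seq$x[, j]; v2y <- seq$y[, d] - seq$y[, j]
  n1 <- sqrt(v1x^2 + v1y^2)
  n2 <- sqrt(v2x^2 + v2y^2)
  cosang <- (v1x * v2x + v1y * v2y) / (n1 * n2)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  undef <- n1 < 1e-12 | n2 < 1e-12
  if (any(undef)) {
    ang[undef] <- NA_real_
    ang <- fill_gaps_linear(ang)
  }
  attr(ang, "n_undefined") <- sum(undef)
  ang
}

#' Robust summary statistics
#'
#' Median and IQR use linear-interpolation quantiles (R type 7); the
#' standard deviation uses the n-1 denominator.
#'
#' @param x nonempty numeric series with at least 2 values.
#' @return list with `median`, `iqr`, `mean`, `sd`.
#' @export
robust_stats <- function(x) {
  assert_that(length(x) >= 2L, "robust_stats: need at least 2 values")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  list(median = stats::median(x), iqr = q[2] - q[1],
       mean = mean(x), sd = stats::sd(x))
}

#' Binned Shannon entropy of a signal (bits)
#'
#' Histograms the series over its robust \[q01, q99\] range into
#' `n_bins` equal bins (values outside are clipped into the end bins) and
#' returns the plug-in Shannon entropy in bits. A constant series has
#' entropy 0.
#'
#' @param x numeric series (nonempty).
#' @param n_bins number of bins (default 50).
#' @param qrange quantile pair for the histogram range.
#' @return entropy in bits, `>= 0`.
#' @export
shannon_entropy <- function(x, n_bins = 50L, qrange = c(0.01, 0.99)) {
  assert_that(length(x) >= 1L, "shannon_entropy: empty series")
  assert_that(n_bins >= 2L, "shannon_entropy: n_bins must be >= 2")
  q <- stats::quantile(x, qrange, names = FALSE, type = 7)
  # ranges at floating-point noise level count as constant signals
  if (q[2] - q[1] < 1e-9 * max(1, abs(q[1]))) return(0)
  xc <- pmin(q[2], pmax(q[1], x))
  breaks <- seq(q[1], q[2], length.out = n_bins + 1L)
  bin <- findInterval(xc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(bin, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Maximum lagged bilateral cross-correlation
#'
#' Maximum over integer lags `|tau| <= round(max_lag_s * fps)` of the
#' absolute Pearson correlation between `left(t)` and `right(t + tau)` on
#' their overlap. Ties prefer the smaller |lag|. A zero-variance series is
#' defined to have correlation 0 (flagged in the `degenerate` field).
#'
#' @param left,right numeric series of equal length, each at least
#'   `2 * max_lag_s * fps` frames.
#' @param fps sampling rate.
#' @param max_lag_s lag window in seconds (default 0.5).
#' @return list with `value` (in \[0, 1\]), `lag` (frames, at the argmax),
#'   and `degenerate` (logical).
#' @export
max_xcorr <- function(left, right, fps, max_lag_s = 0.5) {
  n <- length(left)
  assert_that(length(right) == n, "max_xcorr: series lengths differ")
  L <- round(max_lag_s * fps)
  assert_that(n >= 2 * L, "max_xcorr: series shorter than twice the lag window")
  # zero variance up to floating-point ripple from upstream filters
  near_const <- function(v) stats::sd(v) <= 1e-9 * max(1, abs(mean(v)))
  if (near_const(left) || near_const(right)) {
    return(list(value = 0, lag = 0L, degenerate = TRUE))
  }
  lags <- -L:L
  vals <- vapply(lags, function(tau) {
    if (tau >= 0) {
      l <- left[1:(n - tau)]; r <- right[(1 + tau):n]
    } else {
      l <- left[(1 - tau):n]; r <- right[1:(n + tau)]
    }
    if (stats::sd(l) == 0 || stats::sd(r) == 0) return(0)
    abs(stats::cor(l, r))
  }, numeric(1))
  # ties prefer the smallest |lag|
  ord <- order(-vals, abs(lags))
  best <- ord[1]
  list(value = vals[best], lag = as.integer(lags[best]), degenerate = FALSE)
}

pair_position_features <- function(seq, pair_idx, fps, config) {
  li <- pair_idx[["left"]]; ri <- pair_idx[["right"]]
  out <- list()
  vel <- list(); # per side per axis velocity, for speed
  for (axis in c("x", "y")) {
    m <- if (axis == "x") seq$x else seq$y
    sL <- m[, li]; sR <- m[, ri]
    vL <- finite_difference(sL, fps, 1L); vR <- finite_difference(sR, fps, 1L)
    aL <- finite_difference(sL, fps, 2L); aR <- finite_difference(sR, fps, 2L)
    vel[[axis]] <- list(L = vL, R = vR)
    rsL <- robust_stats(sL); rsR <- robust_stats(sR)
    out[[paste0("median_position_", axis)]] <- (rsL$median + rsR$median) / 2
    out[[paste0("iqr_position_", axis)]] <- (rsL$iqr + rsR$iqr) / 2
    out[[paste0("median_abs_velocity_", axis)]] <-
      (stats::median(abs(vL)) + stats::median(abs(vR))) / 2
    out[[paste0("iqr_velocity_", axis)]] <-
      (robust_stats(vL)$iqr + robust_stats(vR)$iqr) / 2
    out[[paste0("iqr_acceleration_", axis)]] <-
      (robust_stats(aL)$iqr + robust_stats(aR)$iqr) / 2
  }
  speedL <- sqrt(vel$x$L^2 + vel$y$L^2)
  speedR <- sqrt(vel$x$R^2 + vel$y$R^2)
  out$entropy_speed <- mean(c(
    shannon_entropy(speedL, n_bins = config$entropy_bins,
                    qrange = config$entropy_qrange),
    shannon_entropy(speedR, n_bins = config$entropy_bins,
                    qrange = config$entropy_qrange)))
  out$xcorr_speed <- max_xcorr(speedL, speedR, fps,
                               max_lag_s = config$max_lag_s)$value
  out
}

pair_angular_features <- function(seq, joint, fps, skeleton, config) {
  angL <- joint_angle(seq, joint, "left", skeleton)
  angR <- joint_angle(seq, joint, "right", skeleton)
  wL <- finite_difference(angL, fps, 1L); wR <- finite_difference(angR, fps, 1L)
  bL <- finite_difference(angL, fps, 2L); bR <- finite_difference(angR, fps, 2L)
  rsL <- robust_stats(angL); rsR <- robust_stats(angR)
  list(
    mean_angle = (rsL$mean + rsR$mean) / 2,
    sd_angle = (rsL$sd + rsR$sd) / 2,
    median_abs_angular_velocity =
      (stats::median(abs(wL)) + stats::median(abs(wR))) / 2,
    iqr_angular_velocity = (robust_stats(wL)$iqr + robust_stats(wR)$iqr) / 2,
    iqr_angular_acceleration = (robust_stats(bL)$iqr + robust_stats(bR)$iqr) / 2,
    entropy_angle = mean(c(
      shannon_entropy(angL, n_bins = config$entropy_bins,
                      qrange = config$entropy_qrange),
      shannon_entropy(angR, n_bins = config$entropy_bins,
                      qrange = config$entropy_qrange))),
    xcorr_angle = max_xcorr(angL, angR, fps, max_lag_s = config$max_lag_s)$value
  )
}

#' Compute the 38-feature kinematic vector
#'
#' Position block (wrists, ankles; 12 features per pair): median position,
#' IQR position, median |velocity|, IQR velocity and IQR acceleration per
#' axis (left/right averaged), plus entropy of 2D endpoint speed
#' (left/right averaged) and maximum |cross-correlation| of left/right
#' speed. Angular block (elbows,
#' knees; 7 per pair): mean and stdev of the joint angle, median |angular
#' velocity|, IQR angular velocity and acceleration, entropy of the angle,
#' and left/right angle cross-correlation. Positions are in torso units,
#' time in seconds, angles in degrees, entropy in bits.
#'
#' @param seq a `kin_norm` sequence.
#' @param skeleton a [coco17_skeleton()].
#' @param config a [features_config()].
#' @return Named numeric vector of length 38 in [feature_names()] order,
#'   with the subject id as attribute `subject_id`.
#' @export
feature_vector <- function(seq, skeleton = coco17_skeleton(),
                           config = features_config()) {
  fps <- seq$fps
  blocks <- list(
    wrist = unlist(pair_position_features(seq, skeleton$joint_groups$wrist, fps, config)),
    ankle = unlist(pair_position_features(seq, skeleton$joint_groups$ankle, fps, config)),
    elbow = unlist(pair_angular_features(seq, "elbow", fps, skeleton, config)),
    knee  = unlist(pair_angular_features(seq, "knee", fps, skeleton, config))
  )
  vals <- unlist(lapply(names(blocks), function(j) {
    stats::setNames(blocks[[j]], paste0(j, "_", names(blocks[[j]])))
  }))
  out <- vals[feature_names()]
  bad <- !is.finite(out)
  if (any(bad)) {
    stop("feature_vector: non-finite feature(s): ",
         paste(names(out)[bad], collapse = ", "), call. = FALSE)
  }
  attr(out, "subject_id") <- seq$subject_id
  out
}

#' Sliding-window feature table
#'
#' Applies [feature_vector()] within overlapping windows (default 2 s, 50%
#' overlap) laid out on a regular grid over the whole video including rest
#' periods; the last partial window is dropped.
#'
#' @param seq a `kin_norm` sequence.
#' @param window_s window length in seconds (default 2).
#' @param overlap_frac fractional overlap between consecutive windows
#'   (default 0.5).
#' @param skeleton a [coco17_skeleton()].
#' @param config a [features_config()].
#' @return data.frame with `subject_id`, `window_start_s`, `window_end_s`
#'   and the 38 features per window.
#' @export
windowed_features <- function(seq, window_s = 2.0, overlap_frac = 0.5,
                              skeleton = coco17_skeleton(),
                              config = features_config()) {
  n <- nrow(seq$x)
  dur <- n / seq$fps
  assert_that(dur >= window_s,
              "windowed_features: video shorter than one window")
  step_s <- window_s * (1 - overlap_frac)
  n_win <- floor((dur - window_s) / step_s) + 1L
  wlen <- round(window_s * seq$fps)
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    start_s <- (w - 1L) * step_s
    i0 <- round(start_s * seq$fps) + 1L
    i1 <- min(n, i0 + wlen - 1L)
    sub <- seq
    sub$x <- seq$x[i0:i1, , drop = FALSE]
    sub$y <- seq$y[i0:i1, , drop = FALSE]
    fv <- feature_vector(sub, skeleton, config)
    rows[[w]] <- data.frame(subject_id = seq$subject_id,
                            window_start_s = start_s,
                            window_end_s = start_s + window_s,
                            t(fv), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract a per-subject feature table from normalized sequences
#'
#' @param norms list of `kin_norm` sequences.
#' @param labels optional named character vector (names = subject ids) of
#'   labels to attach.
#' @param skeleton a [coco17_skeleton()].
#' @param config a [features_config()].
#' @return data.frame with `subject_id`, `label` and the 38 features.
#' @export
extract_feature_table <- function(norms, labels = NULL,
                                  skeleton = coco17_skeleton(),
                                  config = features_config()) {
  rows <- lapply(norms, function(s) {
    fv <- feature_vector(s, skeleton, config)
    data.frame(subject_id = s$subject_id, t(fv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$label <- if (!is.null(labels)) unname(labels[out$subject_id]) else NA_character_
  rownames(out) <- NULL
  out[, c("subject_id", "label", feature_names())]
}
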