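#' @title Pose normalization and dataset-level QC
#' @description Puts every pose in a canonical body frame — mid-hip at the
#'   origin, the mid-hip to mid-shoulder axis pointing "up", and the median
#'   torso length scaled to one unit — making downstream kinematics
#'   invariant to camera translation, rotation and zoom. Also provides the
#'   wingspan-to-body-length viewing-angle proxy and a two-sample
#'   Kolmogorov-Smirnov test used for duration QC.
#' @name posenorm
NULL

#' Rotate to head-up and normalize torso length
#'
#' Per frame: translate the mid-hip point to the origin and rotate so the
#' mid-hip to mid-shoulder vector points along -y ("up" in image
#' convention, where y grows downward). The scale is then fixed by the
#' per-video *median* torso length (robust to single-frame tracking
#' glitches) and applied uniformly to all frames, preserving within-video
#' amplitude dynamics. Rigid motion plus one uniform scale only.
#'
#' The head-up direction is anchored on the torso axis rather than facial
#' keypoints, which are the least reliable in infants.
#'
#' @param seq a `kin_clean` (gap-free) sequence.
#' @param skeleton a [coco17_skeleton()].
#' @return An object of class `kin_norm` with `x`, `y` in torso units,
#'   `torso_length_px` (per frame), `torso_length_median_px` and
#'   `rotation_deg` (per-frame applied rotation).
#' @export
head_up_normalize <- function(seq, skeleton = coco17_skeleton()) {
  sh <- skeleton$torso_anchors$shoulders
  hp <- skeleton$torso_anchors$hips
  msx <- (seq$x[, sh[1]] + seq$x[, sh[2]]) / 2
  msy <- (seq$y[, sh[1]] + seq$y[, sh[2]]) / 2
  mhx <- (seq$x[, hp[1]] + seq$x[, hp[2]]) / 2
  mhy <- (seq$y[, hp[1]] + seq$y[, hp[2]]) / 2
  vx <- msx - mhx
  vy <- msy - mhy
  torso <- sqrt(vx^2 + vy^2)
  degen <- torso < 1e-6
  if (mean(degen) > 0.5) {
    stop("head_up_normalize: degenerate torso (length < 1e-6 px) in more ",
         "than half the frames", call. = FALSE)
  }
  # rotation taking the torso axis onto (0, -1); identity where degenerate
  theta <- atan2(vy, vx)
  delta <- -pi / 2 - theta
  delta[degen] <- 0
  cd <- cos(delta); sd_ <- sin(delta)
  x0 <- seq$x - mhx   # recycled column-wise per frame
  y0 <- seq$y - mhy
  xr <- x0 * cd - y0 * sd_
  yr <- x0 * sd_ + y0 * cd
  s <- stats::median(torso[!degen])
  out <- seq
  out$x <- xr / s
  out$y <- yr / s
  out$torso_length_px <- torso
  out$torso_length_median_px <- s
  out$rotation_deg <- delta * 180 / pi
  class(out) <- "kin_norm"
  out
}

#' @export
print.kin_norm <- function(x, ...) {
  cat(sprintf(
    "kin_norm: subject %s, %d frames @ %.6g FPS, median torso %.1f px\n",
    x$subject_id, nrow(x$x), x$fps, x$torso_length_median_px))
  invisible(x)
}

#' Wingspan-to-body-length ratio
#'
#' Viewing-angle proxy: the range of x-coordinates divided by the range of
#' y-coordinates over the 12 body joints (shoulders, elbows, wrists, hips,
#' knees, ankles — facial keypoints excluded), computed per frame in the
#' normalized head-up frame and averaged over frames. Near-orthogonal
#' top-down recordings of supine infants concentrate around 0.7-0.8; large
#' deviations flag oblique camera angles.
#'
#' @param seq a `kin_norm` sequence.
#' @param skeleton a [coco17_skeleton()].
#' @return The mean per-frame ratio (dimensionless).
#' @export
wingspan_ratio <- function(seq, skeleton = coco17_skeleton()) {
  body <- setdiff(seq_len(17L), skeleton$head_indices)
  xb <- seq$x[, body, drop = FALSE]
  yb <- seq$y[, body, drop = FALSE]
  rx <- apply(xb, 1L, max) - apply(xb, 1L, min)
  ry <- apply(yb, 1L, max) - apply(yb, 1L, min)
  if (any(ry == 0)) {
    stop("wingspan_ratio: zero y-range in at least one frame", call. = FALSE)
  }
  mean(rx / ry)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference between the two empirical CDFs;
#' the p-value uses the standard asymptotic Kolmogorov series with the
#' effective sample size n*m/(n+m).
#'
#' @param a,b numeric samples (nonempty).
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  assert_that(length(a) >= 1L && length(b) >= 1L,
              "ks_two_sample: both samples must be nonempty")
  pooled <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pooled)
  Fb <- stats::ecdf(b)(pooled)
  D <- max(abs(Fa - Fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = D, p.value = min(1, max(0, p)))
}

#' Cohort retention report
#'
#' Summarizes the fraction of (frame, keypoint) cells retained after
#' confidence masking for each preprocessed video and flags videos that
#' fall below the expected >90% retention regime.
#'
#' @param cleans list of `kin_clean` sequences.
#' @param flag_below retention threshold for flagging (default 0.9).
#' @return data.frame with `subject_id`, `retention`, `flagged`; cohort
#'   mean/min as attributes.
#' @export
retention_report <- function(cleans, flag_below = 0.9) {
  assert_that(length(cleans) >= 1L, "retention_report: need >= 1 sequence")
  df <- data.frame(
    subject_id = vapply(cleans, function(s) s$subject_id, character(1)),
    retention = vapply(cleans, function(s) s$retention, numeric(1)),
    stringsAsFactors = FALSE)
  df$flagged <- df$retention < flag_below
  attr(df, "cohort_mean") <- mean(df$retention)
  attr(df, "cohort_min") <- min(df$retention)
  df
}
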