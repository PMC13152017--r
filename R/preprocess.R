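#' @title Keypoint time-series preprocessing
#' @description Turns raw multi-candidate detections into a clean, gap-free,
#'   smoothed keypoint time series: keep the highest-confidence detection
#'   per frame, mask keypoints with confidence below 0.8, linearly
#'   interpolate the gaps, remove single-frame outliers with a 1-s rolling
#'   median, and smooth with a 1-s rolling mean. All windows are measured in
#'   seconds and converted with the video's own frame rate, so mixed-FPS
#'   cohorts are handled uniformly.
#' @name preprocess
NULL

#' Default preprocessing configuration
#'
#' @param confidence_threshold mask keypoints with confidence below this
#'   (default 0.8).
#' @param median_window_s rolling-median window in seconds (default 1).
#' @param mean_window_s rolling-mean window in seconds (default 1).
#' @param mask_mode `"cell"` masks individual (frame, keypoint) cells;
#'   `"frame"` drops a whole frame when any keypoint falls below threshold.
#' @return list of config values (echoed into the output).
#' @export
preprocess_config <- function(confidence_threshold = 0.8,
                              median_window_s = 1.0,
                              mean_window_s = 1.0,
                              mask_mode = c("cell", "frame")) {
  mask_mode <- match.arg(mask_mode)
  assert_that(confidence_threshold >= 0 && confidence_threshold <= 1,
              "confidence_threshold must be in [0, 1]")
  assert_that(median_window_s > 0 && mean_window_s > 0,
              "window lengths must be positive")
  list(confidence_threshold = confidence_threshold,
       median_window_s = median_window_s,
       mean_window_s = mean_window_s,
       mask_mode = mask_mode)
}

#' Keep the best detection in each frame
#'
#' Selects, per frame, the candidate with the highest detection score
#' (falling back to the mean keypoint confidence when a candidate has no
#' score). Frames with no candidates become all-missing frames; they are
#' handled downstream by interpolation.
#'
#' @param raw a [raw_detections()] object.
#' @return An object of class `kin_sequence` with exactly one detection per
#'   frame (`x`, `y`, `conf` are `n x 17` matrices) and a `provenance` note.
#' @export
select_best_detection <- function(raw) {
  stopifnot(inherits(raw, "kin_raw"))
  x <- raw$x; y <- raw$y; conf <- raw$conf
  score <- raw$score
  # fall back to mean keypoint confidence where the instance score is absent
  no_score <- is.na(score) & apply(is.finite(conf), 1L, any)
  if (any(no_score)) {
    score[no_score] <- rowMeans(conf[no_score, , drop = FALSE], na.rm = TRUE)
  }
  for (e in raw$extra) {
    i <- e$frame + 1L
    sc <- e$score %||% mean(e$conf)
    if (is.na(score[i]) || sc > score[i]) {
      x[i, ] <- e$x; y[i, ] <- e$y; conf[i, ] <- e$conf
      score[i] <- sc
    }
  }
  structure(list(
    x = x, y = y, conf = conf, fps = raw$fps, resolution = raw$resolution,
    subject_id = raw$subject_id,
    provenance = "best-detection: per-frame argmax of detection score"
  ), class = "kin_sequence")
}

#' Mask low-confidence keypoints
#'
#' Every (frame, keypoint) cell whose confidence is below `threshold` (or
#' missing) has its coordinates set to `NA`. In `"frame"` mode the whole
#' frame is masked as soon as any keypoint falls below threshold. Masking
#' is idempotent and retention is monotone non-increasing in the threshold.
#'
#' @param seq a `kin_sequence`.
#' @param threshold confidence threshold in `[0, 1]` (default 0.8).
#' @param mask_mode `"cell"` or `"frame"`.
#' @return The sequence with masked coordinates plus attributes
#'   `mask_log` (per-keypoint masked-frame counts), `retention_by_keypoint`
#'   and `retention` (overall fraction of retained cells).
#' @export
mask_low_confidence <- function(seq, threshold = 0.8,
                                mask_mode = c("cell", "frame")) {
  mask_mode <- match.arg(mask_mode)
  assert_that(threshold >= 0 && threshold <= 1,
              "threshold must be in [0, 1]")
  bad <- is.na(seq$conf) | seq$conf < threshold
  if (mask_mode == "frame") {
    bad_frame <- apply(bad, 1L, any)
    bad[bad_frame, ] <- TRUE
  }
  seq$x[bad] <- NA_real_
  seq$y[bad] <- NA_real_
  attr(seq, "mask_log") <- colSums(bad)
  attr(seq, "retention_by_keypoint") <- 1 - colMeans(bad)
  attr(seq, "retention") <- 1 - mean(bad)
  seq
}

#' Fill masked gaps by linear interpolation
#'
#' Interior gaps are filled by straight-line interpolation in time,
#' per keypoint and coordinate; leading/trailing gaps are extended from the
#' nearest observed value (extension avoids inventing motion at the video
#' edges). The output has no missing cells.
#'
#' @param seq a `kin_sequence` with possibly missing coordinates.
#' @return The sequence, gap-free.
#' @export
interpolate_gaps <- function(seq) {
  nobs <- colSums(!is.na(seq$x))
  if (any(nobs < 2L)) {
    bad <- coco17_skeleton()$keypoint_names[which(nobs < 2L)]
    stop("interpolate_gaps: unrecoverable track(s), keypoint(s) observed in ",
         "fewer than 2 frames: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  seq$x <- apply(seq$x, 2L, fill_gaps_linear)
  seq$y <- apply(seq$y, 2L, fill_gaps_linear)
  seq
}

# Centered rolling window bounds: window of width w = 2h+1 clipped to the
# available frames (shrinks at the boundaries, no padding).
window_halfwidth <- function(window_s, fps, n) {
  w <- round(window_s * fps)
  if (w %% 2 == 0) w <- w + 1  # force odd: unique middle element
  if (w >= n) {
    stop(sprintf(
      "rolling window (%d frames) must be shorter than the video (%d frames)",
      as.integer(w), n), call. = FALSE)
  }
  (w - 1L) / 2L
}

rolling_median_vec <- function(v, h) {
  n <- length(v)
  w <- 2L * h + 1L
  if (h == 0L) return(v)
  out <- as.numeric(stats::runmed(v, w, endrule = "keep"))
  # boundary frames: median over the clipped window
  for (i in c(seq_len(h), seq(n - h + 1L, n))) {
    out[i] <- stats::median(v[max(1L, i - h):min(n, i + h)])
  }
  out
}

rolling_mean_vec <- function(v, h) {
  n <- length(v)
  if (h == 0L) return(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove outliers with a rolling-median filter
#'
#' Each coordinate is replaced by the median of a centered window of
#' `round(window_s * fps)` frames (forced odd); at the video edges the
#' window shrinks to the available frames. Any isolated single-frame spike
#' is fully removed for windows of 3 frames or more.
#'
#' @param seq a gap-free `kin_sequence`.
#' @param window_s window length in seconds (default 1).
#' @return The despiked sequence.
#' @export
rolling_median_despike <- function(seq, window_s = 1.0) {
  assert_that(window_s > 0, "window_s must be positive")
  h <- window_halfwidth(window_s, seq$fps, nrow(seq$x))
  seq$x <- apply(seq$x, 2L, rolling_median_vec, h = h)
  seq$y <- apply(seq$y, 2L, rolling_median_vec, h = h)
  seq
}

#' Smooth with a rolling-mean filter
#'
#' Same windowing convention as [rolling_median_despike()], with the mean.
#'
#' @param seq a gap-free `kin_sequence`.
#' @param window_s window length in seconds (default 1).
#' @return The smoothed sequence.
#' @export
rolling_mean_smooth <- function(seq, window_s = 1.0) {
  assert_that(window_s > 0, "window_s must be positive")
  h <- window_halfwidth(window_s, seq$fps, nrow(seq$x))
  seq$x <- apply(seq$x, 2L, rolling_mean_vec, h = h)
  seq$y <- apply(seq$y, 2L, rolling_mean_vec, h = h)
  seq
}

#' Full preprocessing pipeline
#'
#' Fixed composition: best-detection selection, confidence masking, linear
#' interpolation, rolling-median despiking, rolling-mean smoothing.
#' Deterministic; retention accounting is recorded before interpolation.
#'
#' @param raw a [raw_detections()] object.
#' @param config a [preprocess_config()].
#' @return An object of class `kin_clean`: gap-free smoothed `x`, `y`
#'   matrices plus `fps`, `subject_id`, `mask_log`, `retention`,
#'   `retention_by_keypoint` and the echoed `config`.
#' @export
preprocess_pipeline <- function(raw, config = preprocess_config()) {
  seq <- select_best_detection(raw)
  seq <- mask_low_confidence(seq, threshold = config$confidence_threshold,
                             mask_mode = config$mask_mode)
  retention <- attr(seq, "retention")
  retention_kp <- attr(seq, "retention_by_keypoint")
  mask_log <- attr(seq, "mask_log")
  seq <- interpolate_gaps(seq)
  seq <- rolling_median_despike(seq, config$median_window_s)
  seq <- rolling_mean_smooth(seq, config$mean_window_s)
  structure(list(
    x = seq$x, y = seq$y, fps = seq$fps, resolution = seq$resolution,
    subject_id = seq$subject_id,
    mask_log = mask_log,
    retention = retention,
    retention_by_keypoint = retention_kp,
    config = config
  ), class = "kin_clean")
}

#' @export
print.kin_clean <- function(x, ...) {
  cat(sprintf(
    "kin_clean: subject %s, %d frames @ %.6g FPS, retention %.3f\n",
    x$subject_id, nrow(x$x), x$fps, x$retention))
  invisible(x)
}
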