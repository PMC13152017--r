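#' COCO-17 skeleton convention
#'
#' Describes the 17-keypoint body convention emitted by standard 2D pose
#' estimators, plus the index bookkeeping the rest of the pipeline relies on:
#' the four extremity/joint groups used by the feature set (wrists, ankles,
#' elbows, knees), the torso anchors (shoulders, hips) used for pose
#' normalization, and the five facial keypoints excluded from body-geometry
#' QC measures.
#'
#' Indices are 1-based in COCO order: nose, left/right eye, left/right ear,
#' left/right shoulder, left/right elbow, left/right wrist, left/right hip,
#' left/right knee, left/right ankle.
#'
#' @return An object of class `kin_skeleton`: a list with `keypoint_names`
#'   (length 17), `joint_groups` (named list of `c(left =, right =)` index
#'   pairs for wrist, ankle, elbow, knee), `torso_anchors` (list with
#'   `shoulders` and `hips` index pairs), and `head_indices` (the 5 facial
#'   keypoints).
#' @examples
#' sk <- coco17_skeleton()
#' sk$joint_groups$wrist
#' @export
coco17_skeleton <- function() {
  names17 <- c(
    "nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle"
  )
  sk <- list(
    keypoint_names = names17,
    joint_groups = list(
      wrist = c(left = 10L, right = 11L),
      ankle = c(left = 16L, right = 17L),
      elbow = c(left = 8L,  right = 9L),
      knee  = c(left = 14L, right = 15L)
    ),
    torso_anchors = list(
      shoulders = c(left = 6L, right = 7L),
      hips      = c(left = 12L, right = 13L)
    ),
    head_indices = 1:5,
    # proximal/distal anchors for interior joint angles
    angle_anchors = list(
      elbow = list(proximal = c(left = 6L, right = 7L),
                   distal   = c(left = 10L, right = 11L)),
      knee  = list(proximal = c(left = 12L, right = 13L),
                   distal   = c(left = 16L, right = 17L))
    )
  )
  class(sk) <- "kin_skeleton"
  validate_skeleton(sk)
  sk
}

validate_skeleton <- function(sk) {
  stopifnot(length(sk$keypoint_names) == 17L)
  idx <- unlist(sk$joint_groups, use.names = FALSE)
  if (any(idx < 1L | idx > 17L)) {
    stop("skeleton: grouped keypoint index outside 1..17", call. = FALSE)
  }
  for (g in sk$joint_groups) {
    if (g[["left"]] == g[["right"]]) {
      stop("skeleton: left/right indices must be distinct", call. = FALSE)
    }
  }
  if (!setequal(names(sk$joint_groups), c("wrist", "ankle", "elbow", "knee"))) {
    stop("skeleton: joint groups must be wrist, ankle, elbow, knee",
         call. = FALSE)
  }
  invisible(sk)
}

# Canonical 38-feature enumeration.
#
# Position block (wrist then ankle), 12 per pair: five statistics per axis
# (median position, IQR position, median |velocity|, IQR velocity, IQR
# acceleration; x and y) plus two intrinsically bilateral statistics
# (entropy of 2D endpoint speed, max lagged |cross-correlation| of
# left/right speed). Angular block (elbow then knee), 7 per pair: mean
# angle, stdev angle, median |angular velocity|, IQR angular velocity, IQR
# angular acceleration, entropy of angle, max |cross-correlation| of
# left/right angle. Statistic names are sorted alphabetically within each
# joint block so the column order is stable across sites.
position_stat_names <- function() {
  per_axis <- c("median_position", "iqr_position", "median_abs_velocity",
                "iqr_velocity", "iqr_acceleration")
  axes <- c("x", "y")
  nm <- c(as.vector(outer(per_axis, axes, paste, sep = "_")),
          "entropy_speed", "xcorr_speed")
  sort(nm)
}

angular_stat_names <- function() {
  sort(c("mean_angle", "sd_angle", "median_abs_angular_velocity",
         "iqr_angular_velocity", "iqr_angular_acceleration",
         "entropy_angle", "xcorr_angle"))
}

#' Canonical names of the 38 kinematic features
#'
#' Position features of the wrists and ankles come first, angular features
#' of the elbows and knees second; statistics are alphabetical within each
#' joint block. This order is the contract for feature CSV columns and for
#' the model's feature signature.
#'
#' @return Character vector of length 38, e.g. `"wrist_iqr_velocity_x"`.
#' @export
feature_names <- function() {
  c(
    paste("wrist", position_stat_names(), sep = "_"),
    paste("ankle", position_stat_names(), sep = "_"),
    paste("elbow", angular_stat_names(), sep = "_"),
    paste("knee",  angular_stat_names(), sep = "_")
  )
}

#' Feature dictionary
#'
#' One row per canonical feature with its joint group, units and a short
#' description of what the statistic measures.
#'
#' @return A data.frame with columns `feature`, `joint`, `units`,
#'   `description`.
#' @export
feature_dictionary <- function() {
  fn <- feature_names()
  joint <- sub("_.*$", "", fn)
  stat <- sub("^[a-z]+_", "", fn)
  units <- vapply(stat, function(s) {
    if (grepl("position", s)) "torso units"
    else if (grepl("abs_velocity", s) || grepl("iqr_velocity", s)) {
      if (grepl("angular", s)) "deg/s" else "torso units/s"
    }
    else if (grepl("acceleration", s)) {
      if (grepl("angular", s)) "deg/s^2" else "torso units/s^2"
    }
    else if (grepl("angle", s) && grepl("entropy", s)) "bits"
    else if (grepl("entropy", s)) "bits"
    else if (grepl("xcorr", s)) "dimensionless"
    else if (grepl("angle", s)) "deg"
    else "unknown"
  }, character(1), USE.NAMES = FALSE)
  desc <- vapply(stat, function(s) {
    switch(sub("_[xy]$", "", s),
      median_position = "postural bias along one axis",
      iqr_position = "range of movement in position",
      median_abs_velocity = "typical speed of movement",
      iqr_velocity = "movement smoothness (spread of velocity)",
      iqr_acceleration = "abruptness of movement",
      entropy_speed = "movement variability/complexity of endpoint speed",
      xcorr_speed = "bilateral coordination of endpoint speed",
      mean_angle = "typical joint posture; deviations may indicate abnormal tone",
      sd_angle = "variability of joint angle; reduced variance = restricted movement",
      median_abs_angular_velocity = "typical angular speed (rigidity)",
      iqr_angular_velocity = "smoothness of joint rotation",
      iqr_angular_acceleration = "proxy for spasticity/stiffness",
      entropy_angle = "complexity of joint-angle signal",
      xcorr_angle = "bilateral coordination of joint angles",
      "")
  }, character(1), USE.NAMES = FALSE)
  data.frame(feature = fn, joint = joint, units = units,
             description = desc, stringsAsFactors = FALSE)
}
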