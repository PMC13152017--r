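#' @title Keypoint and cohort file I/O
#' @description Readers and writers for per-frame COCO-17 keypoint
#'   detections (JSON or flat CSV), feature tables, and cohort/subject
#'   tables. All schemas carry a `schema_version` field. Multiple candidate
#'   detections per frame are preserved at read time; picking one is a
#'   preprocessing decision, never an I/O side effect.
#' @name keypoint_io
NULL

KIN_SCHEMA_VERSION <- "1.0"

#' Construct a raw multi-candidate detection container
#'
#' The container stores the first candidate of every frame as dense
#' `n x 17` coordinate/confidence matrices (rows of `NA` for frames with no
#' detection) plus a sparse list of any additional candidates. Frame
#' indices are 0-based, coordinates are image pixels (origin top-left, y
#' down).
#'
#' @param x,y,conf numeric `n_frames x 17` matrices for the primary
#'   candidate.
#' @param score numeric vector of detection scores (NA where no candidate).
#' @param extra list of extra candidates, each a list with `frame`
#'   (0-based), `x`, `y`, `conf` (length-17), `score`.
#' @param fps frames per second (> 0).
#' @param resolution integer `c(width, height)` in pixels.
#' @param subject_id opaque subject identifier.
#' @return An object of class `kin_raw`.
#' @export
raw_detections <- function(x, y, conf, score, extra = list(), fps,
                           resolution = c(1280L, 720L),
                           subject_id = "unknown") {
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  assert_that(ncol(x) == 17L && ncol(y) == 17L && ncol(conf) == 17L,
              "raw_detections: keypoint matrices must have 17 columns")
  assert_that(nrow(x) >= 1L, "raw_detections: at least one frame required")
  assert_that(is.numeric(fps) && length(fps) == 1L && fps > 0,
              "raw_detections: fps must be a positive scalar")
  cc <- conf[is.finite(conf)]
  assert_that(all(cc >= 0 & cc <= 1),
              "raw_detections: confidences must lie in [0, 1]")
  structure(list(
    x = x, y = y, conf = conf,
    score = as.numeric(score), extra = extra,
    fps = fps, resolution = as.integer(resolution),
    subject_id = as.character(subject_id),
    schema_version = KIN_SCHEMA_VERSION
  ), class = "kin_raw")
}

#' @export
print.kin_raw <- function(x, ...) {
  cat(sprintf(
    "kin_raw: subject %s, %d frames @ %.6g FPS, %dx%d px, %d extra candidate(s)\n",
    x$subject_id, nrow(x$x), x$fps, x$resolution[1], x$resolution[2],
    length(x$extra)))
  invisible(x)
}

n_frames <- function(obj) nrow(obj$x)

#' Read per-frame keypoint detections
#'
#' JSON dialect: one object per recording with `subject_id`, `fps`,
#' `resolution` and a `frames` array; each frame object carries a 0-based
#' `frame` index and a `detections` array whose elements have a `score` and
#' a flat 51-number `keypoints` array (x, y, confidence per keypoint).
#' CSV dialect: metadata in `#key=value` header comments, then one row per
#' (frame, detection) with `frame`, `detection`, `score` and 51 keypoint
#' columns. Missing frame indices become frames with an empty candidate
#' list; no frame is ever silently dropped.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @param skeleton a [coco17_skeleton()] (used for column naming checks).
#' @return A [raw_detections()] object.
#' @export
read_keypoints <- function(path, format = c("auto", "json", "csv"),
                           skeleton = coco17_skeleton()) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") read_keypoints_json(path) else read_keypoints_csv(path)
}

read_keypoints_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("parse error reading ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$fps)) stop("metadata error: missing fps in ", path,
                             call. = FALSE)
  frames <- doc$frames %||% list()
  if (length(frames) == 0L) stop("parse error: no frames in ", path,
                                 call. = FALSE)
  idx <- vapply(frames, function(f) as.integer(f$frame), integer(1))
  nfr <- max(idx) + 1L
  x <- matrix(NA_real_, nfr, 17L); y <- x; conf <- x
  score <- rep(NA_real_, nfr)
  extra <- list()
  for (f in frames) {
    i <- as.integer(f$frame) + 1L
    dets <- f$detections %||% list()
    for (d in seq_along(dets)) {
      kp <- unlist(dets[[d]]$keypoints)
      if (length(kp) != 51L) {
        stop(sprintf(
          "schema error at frame %d: expected 51 keypoint values, got %d",
          i - 1L, length(kp)), call. = FALSE)
      }
      kp <- matrix(kp, ncol = 3L, byrow = TRUE)
      sc <- dets[[d]]$score %||% mean(kp[, 3L])
      if (d == 1L) {
        x[i, ] <- kp[, 1L]; y[i, ] <- kp[, 2L]; conf[i, ] <- kp[, 3L]
        score[i] <- sc
      } else {
        extra[[length(extra) + 1L]] <- list(
          frame = i - 1L, x = kp[, 1L], y = kp[, 2L], conf = kp[, 3L],
          score = sc)
      }
    }
  }
  raw_detections(x, y, conf, score, extra, fps = as.numeric(doc$fps),
                 resolution = unlist(doc$resolution) %||% c(NA_integer_, NA_integer_),
                 subject_id = doc$subject_id %||% "unknown")
}

kp_colnames <- function() {
  nm <- coco17_skeleton()$keypoint_names
  as.vector(t(outer(nm, c("x", "y", "c"), paste, sep = "_")))
}

read_keypoints_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(meta$fps)) stop("metadata error: missing fps header in ", path,
                              call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  kpc <- kp_colnames()
  missing_cols <- setdiff(kpc, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing keypoint columns: ",
         paste(utils::head(missing_cols, 3), collapse = ", "), call. = FALSE)
  }
  nfr <- max(df$frame) + 1L
  x <- matrix(NA_real_, nfr, 17L); y <- x; conf <- x
  score <- rep(NA_real_, nfr)
  extra <- list()
  xi <- seq(1L, 51L, by = 3L); yi <- xi + 1L; ci <- xi + 2L
  kpm <- as.matrix(df[, kpc])
  ord <- order(df$frame, df$detection)
  for (r in ord) {
    i <- df$frame[r] + 1L
    if (df$detection[r] == 0L || is.na(score[i])) {
      x[i, ] <- kpm[r, xi]; y[i, ] <- kpm[r, yi]; conf[i, ] <- kpm[r, ci]
      score[i] <- df$score[r]
    } else {
      extra[[length(extra) + 1L]] <- list(
        frame = i - 1L, x = unname(kpm[r, xi]), y = unname(kpm[r, yi]),
        conf = unname(kpm[r, ci]), score = df$score[r])
    }
  }
  raw_detections(
    x, y, conf, score, extra, fps = as.numeric(meta$fps),
    resolution = c(as.integer(meta$width %||% NA), as.integer(meta$height %||% NA)),
    subject_id = meta$subject_id %||% "unknown")
}

#' Write keypoint detections
#'
#' Inverse of [read_keypoints()]; `write` then `read` reproduces all
#' coordinates bit-exactly (values are serialized at full precision).
#'
#' @param raw a `kin_raw` object.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_keypoints <- function(raw, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(raw, "kin_raw"))
  if (format == "json") {
    # numbers are written with %.17g so the read/write cycle is bit-exact
    num <- function(v) sprintf("%.17g", v)
    det_json <- function(score, x, y, conf) {
      sprintf("{\"score\":%s,\"keypoints\":[%s]}", num(score),
              paste(num(as.vector(rbind(x, y, conf))), collapse = ","))
    }
    frame_dets <- vector("list", n_frames(raw))
    for (i in seq_len(n_frames(raw))) {
      if (!is.na(raw$score[i]) || any(is.finite(raw$x[i, ]))) {
        frame_dets[[i]] <- det_json(raw$score[i], raw$x[i, ], raw$y[i, ],
                                    raw$conf[i, ])
      } else frame_dets[[i]] <- character(0)
    }
    for (e in raw$extra) {
      i <- e$frame + 1L
      frame_dets[[i]] <- c(frame_dets[[i]], det_json(e$score, e$x, e$y, e$conf))
    }
    frames <- vapply(seq_along(frame_dets), function(i) {
      sprintf("{\"frame\":%d,\"detections\":[%s]}", i - 1L,
              paste(frame_dets[[i]], collapse = ","))
    }, character(1))
    writeLines(sprintf(
      "{\"schema_version\":\"%s\",\"subject_id\":\"%s\",\"fps\":%s,\"resolution\":[%d,%d],\"frames\":[\n%s\n]}",
      raw$schema_version, raw$subject_id, num(raw$fps),
      raw$resolution[1], raw$resolution[2],
      paste(frames, collapse = ",\n")), path)
  } else {
    hdr <- c(sprintf("#schema_version=%s", raw$schema_version),
             sprintf("#subject_id=%s", raw$subject_id),
             sprintf("#fps=%.17g", raw$fps),
             sprintf("#width=%d", raw$resolution[1]),
             sprintf("#height=%d", raw$resolution[2]))
    rows <- character(0)
    fmt_row <- function(frame, det, score, x, y, conf) {
      paste(c(frame, det, sprintf("%.17g", score),
              sprintf("%.17g", as.vector(rbind(x, y, conf)))), collapse = ",")
    }
    for (i in seq_len(n_frames(raw))) {
      if (!is.na(raw$score[i]) || any(is.finite(raw$x[i, ]))) {
        rows <- c(rows, fmt_row(i - 1L, 0L, raw$score[i],
                                raw$x[i, ], raw$y[i, ], raw$conf[i, ]))
      }
    }
    det_counter <- new.env()
    for (e in raw$extra) {
      key <- as.character(e$frame)
      d <- (get0(key, det_counter) %||% 0L) + 1L
      assign(key, d, det_counter)
      rows <- c(rows, fmt_row(e$frame, d, e$score, e$x, e$y, e$conf))
    }
    header <- paste(c("frame", "detection", "score", kp_colnames()),
                    collapse = ",")
    writeLines(c(hdr, header, rows), path)
  }
  invisible(path)
}

#' Write a feature table to CSV
#'
#' Columns are `subject_id`, `label`, then the 38 canonical feature names
#' in the documented order ([feature_names()]). Values are serialized at
#' full precision so a write/read round trip is exact.
#'
#' @param table data.frame with `subject_id`, `label` and the 38 features.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  assert_that(is.data.frame(table) && nrow(table) >= 1L,
              "write_feature_table: table must be a nonempty data.frame")
  fn <- feature_names()
  missing_cols <- setdiff(fn, names(table))
  assert_that(length(missing_cols) == 0L,
              paste("write_feature_table: missing feature columns:",
                    paste(utils::head(missing_cols, 3), collapse = ", ")))
  vals <- as.matrix(table[, fn])
  if (any(is.nan(vals))) {
    stop("write_feature_table: NaN feature values present (unflagged NaN)",
         call. = FALSE)
  }
  out <- data.frame(subject_id = table$subject_id,
                    label = table$label %||% NA_character_,
                    stringsAsFactors = FALSE)
  for (f in fn) out[[f]] <- sprintf("%.17g", table[[f]])
  lines <- c(sprintf("#schema_version=%s", KIN_SCHEMA_VERSION),
             paste(names(out), collapse = ","),
             apply(out, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with `subject_id`, `label` and the 38 features.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  fn <- feature_names()
  assert_that(all(fn %in% names(df)),
              "read_feature_table: file lacks the 38 canonical columns")
  for (f in fn) df[[f]] <- as.numeric(df[[f]])
  df
}

KIN_LABELS <- c("FM_plus", "FM_minus", "atypical", "unknown")

normalize_label <- function(lab) {
  lab <- trimws(lab)
  map <- c("FM+" = "FM_plus", "FM-" = "FM_minus",
           "FM_plus" = "FM_plus", "FM_minus" = "FM_minus",
           "atypical" = "atypical", "unknown" = "unknown")
  out <- unname(map[lab])
  if (any(is.na(out))) {
    bad <- unique(lab[is.na(out)])
    stop("read_cohort: unknown label string(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a cohort (subject) table
#'
#' Expects CSV columns `subject_id` and `label` (accepted label spellings:
#' `FM+`/`FM_plus`, `FM-`/`FM_minus`, `atypical`, `unknown`); optional
#' strata columns `sex`, `age_weeks`, `race_ethnicity` are carried through.
#' Subjects labelled `atypical` are valid records but flagged non-trainable
#' (they are excluded from model training, as is standard when a class is
#' too rare to learn).
#'
#' @param path CSV path.
#' @return data.frame of subject records with a logical `trainable` column.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  assert_that(all(c("subject_id", "label") %in% names(df)),
              "read_cohort: need subject_id and label columns")
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0L) {
    stop("read_cohort: duplicate subject_id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df$label <- normalize_label(df$label)
  df$trainable <- df$label %in% c("FM_plus", "FM_minus")
  df
}
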