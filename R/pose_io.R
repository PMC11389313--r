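#' Construct a pose sequence
#'
#' A `pose_sequence` holds per-frame keypoint coordinates for a single
#' subject: three `n_frames x 26` matrices (x, y, confidence) with keypoint
#' names as column names, 0-based frame indices, and recording metadata.
#' Image coordinates are assumed: y increases downward, so ground contact
#' corresponds to a local *maximum* of a foot keypoint's y trajectory.
#'
#' @param x,y,conf Numeric matrices, one row per frame, one column per
#'   keypoint (26 Halpe labels, in order).
#' @param frame_indices Integer vector of 0-based frame indices, strictly
#'   increasing; defaults to `0:(nrow(x) - 1)`.
#' @param fps Frames per second (default 30).
#' @param subject_id Opaque subject identifier.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(x, y, conf, frame_indices = NULL, fps = 30,
                          subject_id = "subject") {
  kp <- halpe_keypoints()
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  stopifnot(ncol(x) == 26L, all(dim(x) == dim(y)), all(dim(x) == dim(conf)))
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  if (is.null(frame_indices)) frame_indices <- seq_len(nrow(x)) - 1L
  frame_indices <- as.integer(frame_indices)
  if (length(frame_indices) != nrow(x) ||
      (length(frame_indices) > 1L && any(diff(frame_indices) <= 0L))) {
    stop("frame_indices must be strictly increasing, one per frame", call. = FALSE)
  }
  colnames(x) <- colnames(y) <- colnames(conf) <- kp
  structure(
    list(x = x, y = y, conf = conf, frame_indices = frame_indices,
         fps = fps, subject_id = subject_id),
    class = "pose_sequence"
  )
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> subject '%s': %d frames @ %g fps (%.2f s)\n",
              x$subject_id, nrow(x$y), x$fps, nrow(x$y) / x$fps))
  invisible(x)
}

#' @export
length.pose_sequence <- function(x) nrow(x$y)

#' Read AlphaPose-style results JSON
#'
#' Parses the flat-keypoints JSON dialect written by AlphaPose with the Halpe
#' full-body model: a top-level array of per-detection records, each with an
#' image identifier and a `keypoints` array of 26 (x, y, confidence) triplets.
#' Multiple detections on the same frame are collapsed to the one with the
#' highest summed confidence (single-subject TUG recordings). Frame gaps are
#' tolerated here and reported by [validate_sequence()].
#'
#' @param path Path to a results JSON file.
#' @param fps Frames per second; used when the file carries no rate metadata.
#' @param subject_id Subject identifier to attach.
#' @return A [pose_sequence()].
#' @export
read_pose_json <- function(path, fps = 30, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty pose file: ", path, call. = FALSE)
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0L) stop("pose file contains no detections: ", path, call. = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }

  frame_of <- function(rec) {
    id <- rec$image_id
    if (is.null(id)) stop("detection record lacks an image_id", call. = FALSE)
    fr <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", as.character(id))))
    if (is.na(fr)) stop("cannot parse frame number from image_id '", id, "'",
                        call. = FALSE)
    fr
  }

  kps <- lapply(recs, function(rec) {
    v <- unlist(rec$keypoints, use.names = FALSE)
    if (!is.numeric(v) || length(v) %% 3L != 0L || length(v) != 78L) {
      stop("keypoints array must hold 26 (x, y, confidence) triplets; got length ",
           length(v), call. = FALSE)
    }
    v
  })
  frames <- vapply(recs, frame_of, integer(1))
  total_conf <- vapply(kps, function(v) sum(v[seq(3, 78, by = 3)]), numeric(1))

  # collapse multi-detection frames: keep highest total confidence
  keep <- order(frames, -total_conf)
  keep <- keep[!duplicated(frames[keep])]
  keep <- keep[order(frames[keep])]

  mat <- do.call(rbind, kps[keep])
  pose_sequence(
    x = mat[, seq(1, 78, by = 3), drop = FALSE],
    y = mat[, seq(2, 78, by = 3), drop = FALSE],
    conf = mat[, seq(3, 78, by = 3), drop = FALSE],
    frame_indices = frames[keep],
    fps = fps, subject_id = subject_id
  )
}

#' Write a pose sequence back to AlphaPose-style JSON
#'
#' Inverse of [read_pose_json()]; keypoint values survive a round trip
#' bit-exactly (numbers are serialised at full precision).
#'
#' @param seq A [pose_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_json <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  recs <- lapply(seq_len(nrow(seq$y)), function(i) {
    flat <- as.vector(rbind(seq$x[i, ], seq$y[i, ], seq$conf[i, ]))
    list(image_id = sprintf("%d.jpg", seq$frame_indices[i]),
         keypoints = flat,
         score = sum(seq$conf[i, ]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Single-keypoint coordinate trajectory
#'
#' A `gait_signal` is one coordinate of one keypoint over the frames of a
#' recording: sample values, their 0-based frame indices, the frame rate and
#' a flag per sample marking values filled in by interpolation.
#'
#' @param values Numeric samples (pixels).
#' @param frame_indices 0-based integer sample positions, strictly increasing.
#' @param fps Frames per second.
#' @param interpolated Logical flags, one per sample.
#' @return An object of class `gait_signal`.
#' @export
gait_signal <- function(values, frame_indices = seq_along(values) - 1L,
                        fps = 30, interpolated = logical(length(values))) {
  values <- as.numeric(values)
  frame_indices <- as.integer(frame_indices)
  if (length(values) != length(frame_indices)) {
    stop("values and frame_indices must have equal length", call. = FALSE)
  }
  if (length(frame_indices) > 1L && any(diff(frame_indices) <= 0L)) {
    stop("frame_indices must be strictly increasing", call. = FALSE)
  }
  structure(list(values = values, frame_indices = frame_indices, fps = fps,
                 interpolated = interpolated),
            class = "gait_signal")
}

#' @export
length.gait_signal <- function(x) length(x$values)

#' @export
print.gait_signal <- function(x, ...) {
  cat(sprintf("<gait_signal> %d samples @ %g fps (%d interpolated)\n",
              length(x$values), x$fps, sum(x$interpolated)))
  invisible(x)
}

#' Extract a keypoint coordinate as a time series
#'
#' Pulls one coordinate axis of one named keypoint out of a pose sequence.
#' Samples whose detection confidence falls below `min_conf` are treated as
#' missing and filled by linear interpolation between the nearest valid
#' neighbours; leading/trailing missing samples are held at the nearest valid
#' value (never extrapolated). Filled samples are flagged in the result.
#'
#' With `y_up = TRUE` the y axis is negated, for sources using an
#' upward-positive y convention, so that ground contact is always a local
#' maximum of the returned signal.
#'
#' @param seq A [pose_sequence()].
#' @param keypoint_name One of the 26 Halpe labels.
#' @param axis `"x"` or `"y"`.
#' @param min_conf Confidence below which a sample counts as missing
#'   (default 0.1).
#' @param y_up Negate y for upward-positive sources (default FALSE).
#' @return A [gait_signal()].
#' @export
extract_trajectory <- function(seq, keypoint_name, axis = c("y", "x"),
                               min_conf = 0.1, y_up = FALSE) {
  stopifnot(inherits(seq, "pose_sequence"))
  axis <- match.arg(axis)
  .assert_keypoint(keypoint_name)
  vals <- if (axis == "x") seq$x[, keypoint_name] else seq$y[, keypoint_name]
  conf <- seq$conf[, keypoint_name]
  missing <- !is.finite(vals) | conf < min_conf
  if (all(missing)) {
    stop("all samples of ", keypoint_name, " are missing or below confidence ",
         min_conf, call. = FALSE)
  }
  if (any(missing)) {
    idx <- seq$frame_indices
    vals[missing] <- stats::approx(idx[!missing], vals[!missing],
                                   xout = idx[missing], rule = 2)$y
  }
  if (axis == "y" && y_up) vals <- -vals
  gait_signal(vals, seq$frame_indices, seq$fps, interpolated = missing)
}

#' Validate a pose sequence
#'
#' Report-only sanity checks: frame gaps, fps plausibility, missing gait
#' keypoints, and recording duration. Never throws.
#'
#' @param seq A [pose_sequence()].
#' @param min_conf Confidence threshold used to count missing gait-keypoint
#'   samples.
#' @return A list with `issues` (data.frame: severity, code, message,
#'   start_frame, end_frame), `duration_s` and `n_frames`.
#' @export
validate_sequence <- function(seq, min_conf = 0.1) {
  stopifnot(inherits(seq, "pose_sequence"))
  issues <- list()
  add <- function(severity, code, message, start_frame = NA, end_frame = NA) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, code = code, message = message,
      start_frame = start_frame, end_frame = end_frame,
      stringsAsFactors = FALSE)
  }
  if (!is.finite(seq$fps) || seq$fps <= 0) {
    add("fatal", "bad_fps", sprintf("fps is %s; must be > 0", format(seq$fps)))
  } else if (seq$fps != 30) {
    add("warning", "nonstandard_fps",
        sprintf("fps is %g; TUG protocol records at 30", seq$fps))
  }
  d <- diff(seq$frame_indices)
  for (g in which(d > 1L)) {
    add("warning", "frame_gap",
        sprintf("%d missing frame(s)", d[g] - 1L),
        start_frame = seq$frame_indices[g], end_frame = seq$frame_indices[g + 1L])
  }
  for (kp in .gait_keypoints) {
    n_bad <- sum(seq$conf[, kp] < min_conf | !is.finite(seq$y[, kp]))
    if (n_bad > 0L) {
      add("warning", "low_confidence",
          sprintf("%s: %d sample(s) below confidence %g (interpolated on extraction)",
                  kp, n_bad, min_conf))
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), code = character(), message = character(),
               start_frame = integer(), end_frame = integer())
  dur <- if (is.finite(seq$fps) && seq$fps > 0) nrow(seq$y) / seq$fps else NA_real_
  list(issues = issues, duration_s = dur, n_frames = nrow(seq$y))
}
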