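#' Locate the deepest heel-strike maxima
#'
#' During the mid-walk turn of a TUG trial the subject pauses and adjusts
#' both feet without a full swing, so the heel-strike maxima inside the turn
#' have the lowest values of the recording. This pools the heel-strike peaks
#' of both feet and returns the frames of the lowest-valued (deepest) and
#' second-lowest peak, each tagged with the foot it came from. Ties in peak
#' value are broken toward the earlier frame.
#'
#' @param left_hs,right_hs Heel-strike [event_series()] for the two feet.
#' @return List with `deepest_index`, `deepest_index2` (frames),
#'   `deepest_foot`, `deepest2_foot`.
#' @export
find_deepest_maxima <- function(left_hs, right_hs) {
  stopifnot(inherits(left_hs, "event_series"), inherits(right_hs, "event_series"))
  frames <- c(left_hs$frame_indices, right_hs$frame_indices)
  values <- c(left_hs$peak_values, right_hs$peak_values)
  foot <- c(rep("left", length(left_hs$frame_indices)),
            rep("right", length(right_hs$frame_indices)))
  if (length(frames) < 2L) {
    stop("need at least 2 heel-strike events in total to locate the turn; got ",
         length(frames), call. = FALSE)
  }
  ord <- order(values, frames)
  list(deepest_index = frames[ord[1L]],
       deepest_index2 = frames[ord[2L]],
       deepest_foot = foot[ord[1L]],
       deepest2_foot = foot[ord[2L]])
}

#' Compute the turning window of a TUG walk
#'
#' Brackets the turning motion from the two deepest heel-strike maxima:
#' the heel-strike frame (either foot) immediately preceding the
#' second-deepest peak marks the last contact before the turn, the frame
#' immediately following the deepest peak marks the first contact after it,
#' and the window bounds are the medians (midpoints, floored to a frame) of
#' each pair:
#' `start = floor(median(index_before_deepest, deepest_index2))`,
#' `end = floor(median(index_after_deepest, deepest_index))`.
#'
#' If no event precedes the second-deepest peak the start falls back to that
#' peak's own frame (flagged); symmetrically for the end. If the computed
#' bounds come out reversed (deepest peak earlier than the second-deepest
#' with no event between), they are swapped and flagged.
#'
#' @param left_hs,right_hs Heel-strike [event_series()] per foot.
#' @return A `turning_window` object: `start_turning`, `end_turning`,
#'   `deepest_index`, `deepest_index2`, `index_before_deepest`,
#'   `index_after_deepest`, foot tags and `flags` (character vector).
#' @export
compute_turning_window <- function(left_hs, right_hs) {
  deep <- find_deepest_maxima(left_hs, right_hs)
  frames <- sort(c(left_hs$frame_indices, right_hs$frame_indices))
  flags <- character(0)

  before <- frames[frames < deep$deepest_index2]
  if (length(before) == 0L) {
    index_before <- deep$deepest_index2
    flags <- c(flags, "no_event_before_second_deepest")
  } else {
    index_before <- max(before)
  }
  after <- frames[frames > deep$deepest_index]
  if (length(after) == 0L) {
    index_after <- deep$deepest_index
    flags <- c(flags, "no_event_after_deepest")
  } else {
    index_after <- min(after)
  }

  start_turning <- floor((index_before + deep$deepest_index2) / 2)
  end_turning <- floor((index_after + deep$deepest_index) / 2)
  if (start_turning > end_turning) {
    tmp <- start_turning
    start_turning <- end_turning
    end_turning <- tmp
    flags <- c(flags, "bounds_swapped")
  }

  structure(list(start_turning = as.integer(start_turning),
                 end_turning = as.integer(end_turning),
                 deepest_index = deep$deepest_index,
                 deepest_index2 = deep$deepest_index2,
                 index_before_deepest = as.integer(index_before),
                 index_after_deepest = as.integer(index_after),
                 deepest_foot = deep$deepest_foot,
                 deepest2_foot = deep$deepest2_foot,
                 flags = flags),
            class = "turning_window")
}

#' @export
print.turning_window <- function(x, ...) {
  cat(sprintf("<turning_window> frames [%d, %d] (deepest %d on %s, 2nd %d on %s)\n",
              x$start_turning, x$end_turning, x$deepest_index, x$deepest_foot,
              x$deepest_index2, x$deepest2_foot))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Drop events inside the turning window
#'
#' Removes every event whose frame lies in `[start_turning, end_turning]`
#' (inclusive bounds), so the turn's non-normal-pace contacts never enter
#' gait-feature extraction. The input series is not modified.
#'
#' @param events An [event_series()].
#' @param window A `turning_window` from [compute_turning_window()].
#' @return A new [event_series()] with the in-window events removed.
#' @export
exclude_turning_events <- function(events, window) {
  stopifnot(inherits(events, "event_series"), inherits(window, "turning_window"))
  keep <- events$frame_indices < window$start_turning |
    events$frame_indices > window$end_turning
  event_series(events$foot, events$event_type,
               events$frame_indices[keep], events$peak_values[keep],
               fps = events$fps, subject_id = events$subject_id)
}

#' Write a turning window to a JSON sidecar
#'
#' @param window A `turning_window`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_turning_json <- function(window, path) {
  stopifnot(inherits(window, "turning_window"))
  jsonlite::write_json(
    list(start_turning = window$start_turning, end_turning = window$end_turning,
         deepest_index = window$deepest_index,
         deepest_index2 = window$deepest_index2),
    path, auto_unbox = TRUE)
  invisible(path)
}
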