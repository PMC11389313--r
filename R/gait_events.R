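#' Savitzky-Golay smoothing parameters
#'
#' @param window_length Odd window length in samples (default 11).
#' @param polyorder Polynomial order fitted within each window (default 3).
#'   Must satisfy `polyorder < window_length`.
#' @return A `smoothing_params` list.
#' @export
smoothing_params <- function(window_length = 11L, polyorder = 3L) {
  window_length <- as.integer(window_length)
  polyorder <- as.integer(polyorder)
  if (window_length %% 2L == 0L) {
    stop("window_length must be odd, got ", window_length, call. = FALSE)
  }
  if (polyorder < 0L || polyorder >= window_length) {
    stop("polyorder must satisfy 0 <= polyorder < window_length", call. = FALSE)
  }
  structure(list(window_length = window_length, polyorder = polyorder),
            class = "smoothing_params")
}

#' Peak detection parameters
#'
#' @param min_distance Minimum separation between accepted peaks, in frames
#'   (default 15, about half a second at 30 fps — below any plausible stride
#'   interval, so genuine consecutive contacts are never merged).
#' @param prominence Optional minimum prominence (peak value minus the higher
#'   of the two flanking minima); `NULL` disables the check.
#' @return A `peak_params` list.
#' @export
peak_params <- function(min_distance = 15L, prominence = NULL) {
  min_distance <- as.integer(min_distance)
  if (min_distance < 1L) stop("min_distance must be >= 1", call. = FALSE)
  structure(list(min_distance = min_distance, prominence = prominence),
            class = "peak_params")
}

# least-squares polynomial fit over the given sample values, evaluated at
# offset `at` (relative position within the window)
.polyfit_eval <- function(offsets, values, order, at) {
  order <- min(order, length(offsets) - 1L)
  X <- outer(offsets, 0:order, "^")
  beta <- qr.coef(qr(X), values)
  sum(at^(0:order) * beta)
}

#' Savitzky-Golay smoothing
#'
#' Replaces each sample with the value of a least-squares polynomial of order
#' `polyorder` fitted to the `window_length` samples centred on it
#' (equivalently a fixed convolution with the SG coefficients in the
#' interior). Near the boundaries the window is truncated to the available
#' samples and the polynomial refitted — no padding, so no fabricated samples
#' at the start or end of the walk where events matter.
#'
#' @param signal A [gait_signal()] or numeric vector.
#' @param params A [smoothing_params()].
#' @return Same type as `signal`, smoothed; length unchanged.
#' @export
#' @examples
#' savgol_smooth(sin(seq(0, 6, length.out = 50)) + rnorm(50, sd = 0.05))
savgol_smooth <- function(signal, params = smoothing_params()) {
  stopifnot(inherits(params, "smoothing_params"))
  vals <- if (inherits(signal, "gait_signal")) signal$values else as.numeric(signal)
  n <- length(vals)
  w <- params$window_length
  p <- params$polyorder
  if (n < w) {
    stop("signal length (", n, ") shorter than window_length (", w, ")",
         call. = FALSE)
  }
  k <- (w - 1L) %/% 2L

  # interior: one convolution with the central SG coefficient row
  offs <- -k:k
  X <- outer(offs, 0:p, "^")
  # value of the fit at offset 0 is e1' (X'X)^-1 X' y
  coef_row <- solve(crossprod(X), t(X))[1L, ]
  out <- as.numeric(stats::filter(vals, rev(coef_row), sides = 2))

  # edges: refit on the truncated window
  for (i in c(seq_len(k), seq.int(n - k + 1L, n))) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    out[i] <- .polyfit_eval(seq.int(lo, hi) - i, vals[lo:hi], p, 0)
  }

  if (inherits(signal, "gait_signal")) {
    gait_signal(out, signal$frame_indices, signal$fps, signal$interpolated)
  } else {
    out
  }
}

#' Find constrained local maxima
#'
#' Detects samples strictly greater than both neighbours (a run of equal
#' values flanked by lower ones counts as one peak at its first sample), then
#' greedily enforces the minimum peak separation: peaks are considered in
#' decreasing height order (earlier frame first on ties) and kept only if no
#' already-kept peak lies closer than `min_distance` frames — so the higher
#' peak wins a conflict.
#'
#' @param signal A [gait_signal()] or numeric vector (vector input is indexed
#'   by 0-based position).
#' @param params A [peak_params()].
#' @return Sorted integer vector of peak frame indices (possibly empty).
#' @export
#' @examples
#' find_local_maxima(c(0, 1, 0, 2, 0), peak_params(min_distance = 3)) # 3
find_local_maxima <- function(signal, params = peak_params()) {
  stopifnot(inherits(params, "peak_params"))
  is_sig <- inherits(signal, "gait_signal")
  vals <- if (is_sig) signal$values else as.numeric(signal)
  frames <- if (is_sig) signal$frame_indices else seq_along(vals) - 1L
  n <- length(vals)
  if (n < 3L) return(integer(0))

  # run-length encode so plateaus resolve to their first sample
  r <- rle(vals)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  cand <- integer(0)
  if (m >= 3L) {
    interior <- 2:(m - 1L)
    hit <- r$values[interior] > r$values[interior - 1L] &
      r$values[interior] > r$values[interior + 1L]
    cand <- starts[interior][hit]
  }
  if (length(cand) == 0L) return(integer(0))

  if (!is.null(params$prominence)) {
    keep <- vapply(cand, function(i) {
      left_min <- min(vals[1:i])
      right_min <- min(vals[i:n])
      (vals[i] - max(left_min, right_min)) >= params$prominence
    }, logical(1))
    cand <- cand[keep]
    if (length(cand) == 0L) return(integer(0))
  }

  # greedy distance pruning, higher peak first (earlier index breaks ties)
  ord <- order(-vals[cand], frames[cand])
  kept <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(frames[kept] - frames[i]) >= params$min_distance)) {
      kept <- c(kept, i)
    }
  }
  sort(frames[kept])
}

#' Heel-strike / toe-off event series
#'
#' @param foot `"left"` or `"right"`.
#' @param event_type `"heel_strike"` or `"toe_off"`.
#' @param frame_indices Sorted integer event frames.
#' @param peak_values Smoothed signal values at those frames.
#' @param fps Frames per second.
#' @param subject_id Subject identifier.
#' @return An `event_series` object.
#' @export
event_series <- function(foot, event_type, frame_indices, peak_values,
                         fps = 30, subject_id = "subject") {
  foot <- match.arg(foot, c("left", "right"))
  event_type <- match.arg(event_type, c("heel_strike", "toe_off"))
  frame_indices <- as.integer(frame_indices)
  if (length(frame_indices) > 1L && any(diff(frame_indices) <= 0L)) {
    stop("event frame_indices must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(peak_values) == length(frame_indices))
  structure(list(foot = foot, event_type = event_type,
                 frame_indices = frame_indices,
                 peak_values = as.numeric(peak_values),
                 fps = fps, subject_id = subject_id),
            class = "event_series")
}

#' @export
length.event_series <- function(x) length(x$frame_indices)

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s %s: %d events\n",
              x$foot, x$event_type, length(x$frame_indices)))
  invisible(x)
}

#' Detect gait events in a pose sequence
#'
#' Full single-signal event pipeline: extract the y trajectory of the
#' relevant keypoint (heel for heel strikes, big toe for toe-offs), smooth it
#' with a Savitzky-Golay filter, and take constrained local maxima as event
#' frames. In image coordinates y grows downward, so ground contact is the
#' maximum of the raw vertical trajectory.
#'
#' @param seq A [pose_sequence()].
#' @param foot `"left"` or `"right"`.
#' @param event_type `"heel_strike"` (uses LHeel/RHeel) or `"toe_off"` (uses
#'   LBigToe/RBigToe).
#' @param smoothing A [smoothing_params()].
#' @param peaks A [peak_params()]. The default requires 10 px of prominence:
#'   genuine foot-lift excursions in side-view video span tens of pixels,
#'   while smoothing ripple and detection jitter stay in the low single
#'   digits, so sub-threshold maxima are artefacts, not contacts.
#' @param y_up Set for upward-positive y sources; see [extract_trajectory()].
#' @return An [event_series()].
#' @export
detect_events <- function(seq, foot = c("left", "right"),
                          event_type = c("heel_strike", "toe_off"),
                          smoothing = smoothing_params(),
                          peaks = peak_params(prominence = 10), y_up = FALSE) {
  foot <- match.arg(foot)
  event_type <- match.arg(event_type)
  side <- if (foot == "left") "L" else "R"
  kp <- paste0(side, if (event_type == "heel_strike") "Heel" else "BigToe")
  sig <- extract_trajectory(seq, kp, axis = "y", y_up = y_up)
  smoothed <- savgol_smooth(sig, smoothing)
  frames <- find_local_maxima(smoothed, peaks)
  event_series(foot, event_type, frames,
               smoothed$values[match(frames, smoothed$frame_indices)],
               fps = seq$fps, subject_id = seq$subject_id)
}

#' Write event series to CSV
#'
#' One row per event: subject_id, foot, event_type, frame, time_s, y_value.
#'
#' @param events A single [event_series()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  if (inherits(events, "event_series")) events <- list(events)
  rows <- lapply(events, function(e) {
    if (length(e$frame_indices) == 0L) return(NULL)
    data.frame(subject_id = e$subject_id, foot = e$foot, event_type = e$event_type,
               frame = e$frame_indices, time_s = e$frame_indices / e$fps,
               y_value = e$peak_values, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(subject_id = character(), foot = character(),
                     event_type = character(), frame = integer(),
                     time_s = numeric(), y_value = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
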