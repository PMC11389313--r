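#' Full single-recording gait pipeline
#'
#' Runs the complete per-recording chain: detect heel strikes and toe-offs
#' for both feet (SG smoothing + constrained local maxima), locate the
#' turning window from the deepest heel-strike maxima, exclude in-window
#' events, and aggregate the survivors into one temporal gait feature row.
#'
#' @param seq A [pose_sequence()].
#' @param smoothing A [smoothing_params()].
#' @param peaks A [peak_params()]; defaults to the event detector's
#'   10 px prominence floor (see [detect_events()]).
#' @param schema Output schema for the feature row.
#' @param step_time_convention See [build_feature_row()].
#' @param label Optional class label to attach.
#' @param y_up Set for upward-positive y sources.
#' @return List with `features` (one-row data.frame), `window`
#'   (`turning_window`), and `events` (nested list:
#'   `events$left$heel_strike`, ... — turning-excluded series).
#' @export
#' @examples
#' sim <- simulate_tug(gait_sim_params(seed = 7))
#' extract_gait_features(sim$pose)$features
extract_gait_features <- function(seq, smoothing = smoothing_params(),
                                  peaks = peak_params(prominence = 10),
                                  schema = c("per_foot", "averaged"),
                                  step_time_convention = c("paper", "contralateral_hs"),
                                  label = NA_character_, y_up = FALSE) {
  schema <- match.arg(schema)
  step_time_convention <- match.arg(step_time_convention)
  ev <- list()
  for (foot in c("left", "right")) {
    ev[[foot]] <- list(
      heel_strike = detect_events(seq, foot, "heel_strike", smoothing, peaks,
                                  y_up = y_up),
      toe_off = detect_events(seq, foot, "toe_off", smoothing, peaks,
                              y_up = y_up)
    )
  }
  window <- compute_turning_window(ev$left$heel_strike, ev$right$heel_strike)
  row <- build_feature_row(ev$left, ev$right, window = window, fps = seq$fps,
                           schema = schema,
                           step_time_convention = step_time_convention,
                           subject_id = seq$subject_id, label = label)
  excluded <- lapply(ev, lapply, exclude_turning_events, window = window)
  list(features = row, window = window, events = excluded)
}
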