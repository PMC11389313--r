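#' Temporal gait feature primitives
#'
#' Frame-index arithmetic behind the temporal gait features, all returning
#' seconds (cadence excepted):
#' \describe{
#'   \item{stance time}{`(toe_off - heel_strike) / fps` — time the foot spends
#'     on the ground within a gait cycle.}
#'   \item{stride time}{`(next same-foot heel strike - heel strike) / fps` —
#'     duration of a full gait cycle.}
#'   \item{step time}{`(following opposite-foot toe-off - heel strike) / fps`
#'     — the per-step interval as defined by this protocol (see
#'     `step_time_convention` in [build_feature_row()] for the conventional
#'     contralateral heel-strike variant).}
#'   \item{cadence}{steps per minute.}
#' }
#' All are vectorised over their frame arguments.
#'
#' @param heel_strike,toe_off,hs_i,hs_next,opposite_toe_off_i Event frame
#'   indices.
#' @param fps Frames per second.
#' @param n_steps Number of steps taken.
#' @param duration_min Elapsed time in minutes.
#' @return Numeric vector of seconds (or steps/min for `cadence`).
#' @name gait_feature_primitives
NULL

#' @rdname gait_feature_primitives
#' @export
#' @examples
#' stance_time(30, 45, fps = 30) # 0.5 s
stance_time <- function(heel_strike, toe_off, fps) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (any(toe_off <= heel_strike)) {
    stop("toe_off must come after heel_strike", call. = FALSE)
  }
  (toe_off - heel_strike) / fps
}

#' @rdname gait_feature_primitives
#' @export
stride_time <- function(hs_i, hs_next, fps) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (any(hs_next <= hs_i)) {
    stop("the next heel strike must come after the current one", call. = FALSE)
  }
  (hs_next - hs_i) / fps
}

#' @rdname gait_feature_primitives
#' @export
step_time <- function(hs_i, opposite_toe_off_i, fps) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (any(opposite_toe_off_i <= hs_i)) {
    stop("the opposite foot's toe-off must come after the heel strike",
         call. = FALSE)
  }
  (opposite_toe_off_i - hs_i) / fps
}

#' @rdname gait_feature_primitives
#' @export
cadence <- function(n_steps, duration_min) {
  if (any(duration_min <= 0)) stop("duration must be positive", call. = FALSE)
  if (any(n_steps < 0)) stop("n_steps must be non-negative", call. = FALSE)
  n_steps / duration_min
}

# column sets of the two experimental schemas
.schema_cols <- list(
  per_foot = c("left_stride_time", "right_stride_time",
               "left_step_time", "right_step_time",
               "left_stance_time", "right_stance_time",
               "cadence", "label"),
  averaged = c("average_stride_time", "average_step_time",
               "average_stance_time", "cadence", "label")
)

#' Column names of a feature-table schema
#'
#' @param schema `"per_foot"` (per-foot columns, Experiment-1 layout) or
#'   `"averaged"` (left/right averages, Experiment-2 layout).
#' @return Character vector of column names, label included.
#' @export
feature_schema_cols <- function(schema = c("per_foot", "averaged")) {
  .schema_cols[[match.arg(schema)]]
}

#' Infer the schema of a feature table
#'
#' @param table A feature data.frame.
#' @return `"per_foot"` or `"averaged"`.
#' @export
feature_schema <- function(table) {
  for (s in names(.schema_cols)) {
    if (all(.schema_cols[[s]] %in% names(table))) return(s)
  }
  stop("table matches neither the per-foot nor the averaged feature schema",
       call. = FALSE)
}

# segment id relative to a turning window: 0 before, 1 after
.segment_of <- function(frames, window) {
  if (is.null(window)) return(rep(0L, length(frames)))
  ifelse(frames < window$start_turning, 0L, 1L)
}

# pair each heel strike with the first qualifying event after it, within the
# same segment and before the next same-foot heel strike
.pair_after <- function(hs_frames, hs_seg, cand_frames, cand_seg) {
  out <- rep(NA_integer_, length(hs_frames))
  nxt <- c(hs_frames[-1L], Inf)
  nxt_seg <- c(hs_seg[-1L], NA)
  for (i in seq_along(hs_frames)) {
    lim <- if (!is.na(nxt_seg[i]) && nxt_seg[i] == hs_seg[i]) nxt[i] else Inf
    ok <- cand_frames > hs_frames[i] & cand_frames < lim & cand_seg == hs_seg[i]
    if (any(ok)) out[i] <- cand_frames[which(ok)[1L]]
  }
  out
}

#' Build one subject's gait feature row
#'
#' Aggregates turning-excluded event series into a single row of temporal
#' gait features. Stride, stance and step times are averaged over all valid
#' gait cycles of each foot; a cycle is valid when both of its events fall on
#' the same side of the turning window, so no interval ever spans the turn.
#' Cadence is the number of step intervals (consecutive heel strikes of
#' either foot within a contiguous walking segment) divided by the summed
#' duration of those segments, in minutes — the turning pause never enters
#' the denominator.
#'
#' @param left_events,right_events Lists with elements `heel_strike` and
#'   `toe_off`, each an [event_series()] of the matching foot.
#' @param window Optional `turning_window`; its events are excluded and it
#'   splits the recording into the out and back walking segments.
#' @param fps Frames per second; defaults to the rate carried by the events.
#' @param schema Output layout, `"per_foot"` or `"averaged"`.
#' @param step_time_convention `"paper"` pairs each heel strike with the
#'   following opposite-foot toe-off; `"contralateral_hs"` uses the opposite
#'   foot's next heel strike (the textbook definition).
#' @param subject_id Subject identifier for the row.
#' @param label Optional class label (`"faller"` / `"non_faller"`).
#' @return One-row data.frame in the requested schema, with `subject_id` and
#'   `provenance` columns prepended.
#' @export
build_feature_row <- function(left_events, right_events, window = NULL,
                              fps = NULL, schema = c("per_foot", "averaged"),
                              step_time_convention = c("paper", "contralateral_hs"),
                              subject_id = NULL, label = NA_character_) {
  schema <- match.arg(schema)
  step_time_convention <- match.arg(step_time_convention)
  ev <- list(left = left_events, right = right_events)
  for (side in names(ev)) {
    for (etype in c("heel_strike", "toe_off")) {
      e <- ev[[side]][[etype]]
      if (!inherits(e, "event_series")) {
        stop(side, "_events$", etype, " must be an event_series", call. = FALSE)
      }
      if (!is.null(window)) e <- exclude_turning_events(e, window)
      ev[[side]][[etype]] <- e
    }
  }
  if (is.null(fps)) fps <- ev$left$heel_strike$fps
  if (is.null(subject_id)) subject_id <- ev$left$heel_strike$subject_id

  for (side in names(ev)) {
    if (length(ev[[side]]$heel_strike) < 2L || length(ev[[side]]$toe_off) < 1L) {
      stop("insufficient events after turning exclusion for the ", side,
           " foot (need >= 2 heel strikes and >= 1 toe-off)", call. = FALSE)
    }
  }

  hs <- lapply(ev, function(e) e$heel_strike$frame_indices)
  to <- lapply(ev, function(e) e$toe_off$frame_indices)
  seg_hs <- lapply(hs, .segment_of, window = window)
  seg_to <- lapply(to, .segment_of, window = window)

  per_foot <- lapply(c(left = "left", right = "right"), function(side) {
    opp <- if (side == "left") "right" else "left"
    h <- hs[[side]]; sh <- seg_hs[[side]]

    same_seg <- sh[-length(sh)] == sh[-1L]
    strides <- if (any(same_seg)) {
      stride_time(h[-length(h)][same_seg], h[-1L][same_seg], fps)
    } else numeric(0)

    to_own <- .pair_after(h, sh, to[[side]], seg_to[[side]])
    stances <- if (any(!is.na(to_own))) {
      stance_time(h[!is.na(to_own)], to_own[!is.na(to_own)], fps)
    } else numeric(0)

    opp_cand <- if (step_time_convention == "paper") to[[opp]] else hs[[opp]]
    opp_seg <- if (step_time_convention == "paper") seg_to[[opp]] else seg_hs[[opp]]
    opp_ev <- .pair_after(h, sh, opp_cand, opp_seg)
    steps <- if (any(!is.na(opp_ev))) {
      step_time(h[!is.na(opp_ev)], opp_ev[!is.na(opp_ev)], fps)
    } else numeric(0)

    if (!length(strides) || !length(stances) || !length(steps)) {
      stop("no valid ", side, "-foot gait cycles survive the turning exclusion",
           call. = FALSE)
    }
    c(stride = mean(strides), step = mean(steps), stance = mean(stances))
  })

  pooled <- sort(c(hs$left, hs$right))
  pooled_seg <- .segment_of(pooled, window)
  n_int <- 0L
  dur_s <- 0
  for (s in unique(pooled_seg)) {
    f <- pooled[pooled_seg == s]
    if (length(f) >= 2L) {
      n_int <- n_int + length(f) - 1L
      dur_s <- dur_s + (max(f) - min(f)) / fps
    }
  }
  if (n_int == 0L) stop("too few heel strikes to compute cadence", call. = FALSE)
  cad <- cadence(n_int, dur_s / 60)

  row <- data.frame(
    subject_id = subject_id,
    left_stride_time = per_foot$left[["stride"]],
    right_stride_time = per_foot$right[["stride"]],
    left_step_time = per_foot$left[["step"]],
    right_step_time = per_foot$right[["step"]],
    left_stance_time = per_foot$left[["stance"]],
    right_stance_time = per_foot$right[["stance"]],
    cadence = cad,
    label = label,
    provenance = "primary",
    stringsAsFactors = FALSE
  )
  if (schema == "averaged") as_averaged_schema(row) else row
}

#' Convert a per-foot feature table to the averaged schema
#'
#' Averages the left/right column pairs (Experiment-2 layout); a
#' deterministic, exact function of the per-foot table.
#'
#' @param table A per-foot-schema feature data.frame.
#' @return The same rows in the averaged schema; `subject_id`/`provenance`
#'   carried over when present.
#' @export
as_averaged_schema <- function(table) {
  stopifnot(feature_schema(table) == "per_foot")
  out <- data.frame(
    average_stride_time = (table$left_stride_time + table$right_stride_time) / 2,
    average_step_time = (table$left_step_time + table$right_step_time) / 2,
    average_stance_time = (table$left_stance_time + table$right_stance_time) / 2,
    cadence = table$cadence,
    label = table$label,
    stringsAsFactors = FALSE
  )
  for (extra in c("subject_id", "provenance")) {
    if (extra %in% names(table)) out[[extra]] <- table[[extra]]
  }
  out[, c(intersect("subject_id", names(out)), .schema_cols$averaged,
          intersect("provenance", names(out))), drop = FALSE]
}

# external (POMA-assessed elderly cohort) -> per-foot schema column mapping;
# Single_Support maps onto stance time, cadence is the mean of the two sides
.external_required <- c("Left_Stride_Time", "Right_Stride_Time",
                        "Left_Step_Time", "Right_Step_Time",
                        "Left_Single_Support", "Right_Single_Support",
                        "Left_Cadence", "Right_Cadence")

#' Map an external gait table onto the per-foot schema
#'
#' Aligns the attribute names of the external elderly-cohort dialect with
#' the per-foot (Experiment-1) schema: `*_Stride_Time` and `*_Step_Time`
#' rename directly, `*_Single_Support` columns become the stance times,
#' `cadence` is the mean of `Left_Cadence` and `Right_Cadence`, and any
#' spatial columns are dropped. Works on one row or a whole table.
#'
#' @param external_row Data.frame in the external dialect; must carry a
#'   `Label` (or `label`) column.
#' @return Data.frame in the per-foot schema, `provenance = "external"`.
#' @export
map_external_attributes <- function(external_row) {
  df <- as.data.frame(external_row, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.external_required, names(df))
  if (length(missing_cols)) {
    stop("external table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  label_col <- intersect(c("Label", "label"), names(df))
  if (!length(label_col)) {
    stop("external table is missing mandatory column(s): Label", call. = FALSE)
  }
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(df)) df$subject_id else
      sprintf("external_%03d", seq_len(nrow(df))),
    left_stride_time = df$Left_Stride_Time,
    right_stride_time = df$Right_Stride_Time,
    left_step_time = df$Left_Step_Time,
    right_step_time = df$Right_Step_Time,
    left_stance_time = df$Left_Single_Support,
    right_stance_time = df$Right_Single_Support,
    cadence = (df$Left_Cadence + df$Right_Cadence) / 2,
    label = df[[label_col[1L]]],
    provenance = "external",
    stringsAsFactors = FALSE
  )
  out
}

#' Merge two feature tables
#'
#' Concatenates a primary and an external feature table after checking they
#' share one schema; per-row provenance is preserved (missing provenance
#' columns are filled with `"primary"` / `"external"` respectively).
#'
#' @param primary,external Feature data.frames in the same schema.
#' @return Combined data.frame.
#' @export
merge_tables <- function(primary, external) {
  if (nrow(external) == 0L) return(primary)
  if (nrow(primary) == 0L) return(external)
  s1 <- feature_schema(primary)
  s2 <- feature_schema(external)
  if (s1 != s2) {
    stop("schema mismatch: primary is '", s1, "', external is '", s2, "'",
         call. = FALSE)
  }
  fill <- function(df, prov) {
    if (!"provenance" %in% names(df)) df$provenance <- prov
    if (!"subject_id" %in% names(df)) {
      df$subject_id <- sprintf("%s_%03d", prov, seq_len(nrow(df)))
    }
    df[, c("subject_id", .schema_cols[[s1]], "provenance"), drop = FALSE]
  }
  rbind(fill(primary, "primary"), fill(external, "external"))
}

#' Read / write feature tables as CSV
#'
#' `write_feature_csv()` writes exactly the schema columns (features plus
#' `label`), reproducing the tabular layouts of the two experiments;
#' `read_feature_csv()` reads a CSV and checks it matches one of the schemas.
#'
#' @param table Feature data.frame.
#' @param path CSV path.
#' @return `write_feature_csv()`: `path` invisibly; `read_feature_csv()`:
#'   the table with `provenance = "external"` unless a provenance column is
#'   present.
#' @export
write_feature_csv <- function(table, path) {
  s <- feature_schema(table)
  utils::write.csv(table[, .schema_cols[[s]], drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feature_schema(df) # validates
  if (!"provenance" %in% names(df)) df$provenance <- "external"
  df
}
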