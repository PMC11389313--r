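#' Parameters for the synthetic TUG walk generator
#'
#' Describes an out-and-back walk at the TUG protocol's recording rate:
#' `n_strides_out` strides away from the chair, a mid-sequence pause of
#' `turn_pause` seconds in which the subject makes two reduced-amplitude foot
#' adjustments to turn around, then `n_strides_back` strides back. Vertical
#' (image-convention, downward-positive) heel and big-toe trajectories are
#' generated, so ground contact is a local maximum of y.
#'
#' @param fps Frames per second (default 30, the protocol's camera rate).
#' @param n_strides_out,n_strides_back Strides per direction (default 4,
#'   about what a 3 m walkway allows including gait initiation).
#' @param stride_period Stride duration in seconds (default 1.2, a normal
#'   self-selected pace).
#' @param stance_fraction Fraction of the stride spent in stance
#'   (default 0.6, the physiological ~60/40 stance/swing division).
#' @param step_phase_offset Phase lag of the right foot as a fraction of the
#'   stride (default 0.5: symmetric gait).
#' @param foot_lift_amplitude Vertical swing excursion in pixels (default 60).
#' @param baseline_y Ground-contact y level in pixels (default 500).
#' @param turn_pause Turn duration in seconds (default 2; 0 = no turn).
#' @param turn_depth How many pixels shallower the turn-adjustment contacts
#'   peak compared with `baseline_y` (default 20); the second adjustment is
#'   1.5x deeper, keeping the deepest/second-deepest ordering untied.
#' @param noise_sigma Gaussian pixel noise added to every trajectory
#'   (default 0).
#' @param seed Integer seed.
#' @return A `gait_sim_params` list.
#' @export
gait_sim_params <- function(fps = 30, n_strides_out = 4L, n_strides_back = 4L,
                            stride_period = 1.2, stance_fraction = 0.6,
                            step_phase_offset = 0.5, foot_lift_amplitude = 60,
                            baseline_y = 500, turn_pause = 2, turn_depth = 20,
                            noise_sigma = 0, seed = 1L) {
  if (stride_period <= 0) stop("stride_period must be > 0", call. = FALSE)
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    stop("stance_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  if (turn_pause < 0) stop("turn_pause must be >= 0", call. = FALSE)
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (n_strides_out < 2L || n_strides_back < 2L) {
    stop("need at least 2 strides per direction", call. = FALSE)
  }
  structure(list(fps = fps, n_strides_out = as.integer(n_strides_out),
                 n_strides_back = as.integer(n_strides_back),
                 stride_period = stride_period,
                 stance_fraction = stance_fraction,
                 step_phase_offset = step_phase_offset,
                 foot_lift_amplitude = foot_lift_amplitude,
                 baseline_y = baseline_y, turn_pause = turn_pause,
                 turn_depth = turn_depth, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "gait_sim_params")
}

# place raised-cosine bumps (peak height h_i at frame f_i) on a flat valley;
# widths are half the gap to the nearest neighbouring peak, so bumps never
# overlap and each peak is a strict, locally symmetric maximum
.bump_signal <- function(n_frames, frames, heights, valley) {
  y <- rep(valley, n_frames)
  if (length(frames) == 0L) return(y)
  ord <- order(frames)
  frames <- frames[ord]; heights <- heights[ord]
  gaps <- diff(frames)
  for (i in seq_along(frames)) {
    gl <- if (i > 1L) gaps[i - 1L] else Inf
    gr <- if (i < length(frames)) gaps[i] else Inf
    w <- max(2L, floor(min(gl, gr, 40) / 2))
    t <- seq.int(max(0L, frames[i] - w), min(n_frames - 1L, frames[i] + w))
    y[t + 1L] <- pmax(y[t + 1L],
                      valley + (heights[i] - valley) *
                        0.5 * (1 + cos(pi * (t - frames[i]) / w)))
  }
  y
}

#' Simulate a TUG walk with known ground truth
#'
#' Generates a full 26-keypoint pose sequence whose four gait keypoints
#' (heels and big toes) carry vertical trajectories with ground contacts at
#' known frames: stance contacts peak at `baseline_y`, swings dip by
#' `foot_lift_amplitude`, and the mid-walk turn contributes one
#' reduced-amplitude adjustment contact per foot whose peaks are the lowest
#' of the recording — the premise the turning detector relies on. All true
#' event frames, the true turning interval and the realised gait parameters
#' are returned alongside.
#'
#' @param params A [gait_sim_params()].
#' @return List with `pose` (a [pose_sequence()]) and `truth` (a
#'   `tug_ground_truth`: per-foot `heel_strikes` / `toe_offs` straight-walk
#'   frames, `turn_heel` / `turn_toe` adjustment frames, `turning_window`
#'   `[start, end]` or `NULL`, realised `stride_frames` / `stance_frames` /
#'   `half_stride_frames`, and the generated noiseless + noisy gait signals).
#' @export
simulate_tug <- function(params = gait_sim_params()) {
  stopifnot(inherits(params, "gait_sim_params"))
  fps <- params$fps
  S <- round(params$stride_period * fps)
  st <- round(params$stance_fraction * S)
  H <- round(params$step_phase_offset * S)
  if (st < 1L || st >= S) {
    stop("infeasible timing: stance must occupy [1, stride) frames; got stance ",
         st, " of stride ", S, call. = FALSE)
  }
  P <- round(params$turn_pause * fps)
  has_turn <- P > 0L
  if (has_turn && P < fps) {
    stop("turn_pause too short to hold the foot adjustments; need >= 1 s",
         call. = FALSE)
  }

  pad <- max(6L, as.integer(round(fps / 2))) # lead-in/out, scales with fps
  t0 <- pad
  out_hs <- list(left = t0 + (seq_len(params$n_strides_out) - 1L) * S,
                 right = t0 + H + (seq_len(params$n_strides_out) - 1L) * S)
  last_out <- max(unlist(out_hs)) + st

  if (has_turn) {
    p1 <- last_out + max(1L, round(0.45 * P)) # left adjustment
    p2 <- last_out + round(0.70 * P)          # right adjustment, deeper
    ta <- max(3L, round(0.15 * P))
    turn_heel <- list(left = p1, right = p2)
    turn_toe <- list(left = p1 + ta, right = p2 + ta)
    b0 <- last_out + P + (S - st)
    window <- c(start = last_out + 1L, end = last_out + P)
  } else {
    turn_heel <- list(left = integer(0), right = integer(0))
    turn_toe <- list(left = integer(0), right = integer(0))
    b0 <- last_out + (S - st)
    window <- NULL
  }
  back_hs <- list(left = b0 + (seq_len(params$n_strides_back) - 1L) * S,
                  right = b0 + H + (seq_len(params$n_strides_back) - 1L) * S)

  hs <- list(left = c(out_hs$left, back_hs$left),
             right = c(out_hs$right, back_hs$right))
  to <- lapply(hs, function(f) f + st)
  n_frames <- max(unlist(to), unlist(turn_toe)) + pad + 1L

  B <- params$baseline_y
  td <- params$turn_depth
  heel_h <- function(side) {
    c(rep(B, length(hs[[side]])),
      rep(B - td * (if (side == "left") 1 else 1.5), length(turn_heel[[side]])))
  }
  valley <- B - params$foot_lift_amplitude
  clean <- list()
  for (side in c("left", "right")) {
    clean[[paste0(side, "_heel")]] <- .bump_signal(
      n_frames, c(hs[[side]], turn_heel[[side]]), heel_h(side), valley)
    clean[[paste0(side, "_toe")]] <- .bump_signal(
      n_frames, c(to[[side]], turn_toe[[side]]), heel_h(side), valley)
  }

  set.seed(params$seed)
  noisy <- lapply(clean, function(v) v + stats::rnorm(n_frames, 0, params$noise_sigma))

  # assemble the full 26-keypoint sequence: gait keypoints carry the signals,
  # the rest get plausible static y levels; x sweeps out and back
  kp <- halpe_keypoints()
  y <- matrix(0, n_frames, 26L, dimnames = list(NULL, kp))
  static_y <- c(Nose = 80, LEye = 75, REye = 75, LEar = 78, REar = 78,
                LShoulder = 150, RShoulder = 150, LElbow = 210, RElbow = 210,
                LWrist = 270, RWrist = 270, LHip = 280, RHip = 280,
                LKnee = 380, RKnee = 380, LAnkle = 470, RAnkle = 470,
                Head = 60, Neck = 120, Hip = 280,
                LSmallToe = 495, RSmallToe = 495)
  for (k in names(static_y)) {
    y[, k] <- static_y[[k]] + stats::rnorm(n_frames, 0, params$noise_sigma)
  }
  y[, "LHeel"] <- noisy$left_heel
  y[, "RHeel"] <- noisy$right_heel
  y[, "LBigToe"] <- noisy$left_toe
  y[, "RBigToe"] <- noisy$right_toe

  mid <- if (has_turn) last_out + round(P / 2) else last_out
  xpos <- c(seq(100, 700, length.out = mid + 1L),
            seq(700, 100, length.out = n_frames - mid)[-1L])
  x <- matrix(rep(xpos, 26L), n_frames, 26L, dimnames = list(NULL, kp))
  conf <- matrix(0.9, n_frames, 26L, dimnames = list(NULL, kp))

  pose <- pose_sequence(x, y, conf, fps = fps,
                        subject_id = sprintf("sim_seed%d", params$seed))
  truth <- structure(list(
    heel_strikes = hs, toe_offs = to,
    turn_heel = turn_heel, turn_toe = turn_toe,
    turning_window = window,
    stride_frames = S, stance_frames = st, half_stride_frames = H,
    fps = fps, params = params,
    signals_clean = clean, signals_noisy = noisy
  ), class = "tug_ground_truth")
  list(pose = pose, truth = truth)
}

# minimal turning_window wrapping the simulator's true pause interval
.truth_window <- function(truth) {
  if (is.null(truth$turning_window)) return(NULL)
  structure(list(start_turning = as.integer(truth$turning_window[["start"]]),
                 end_turning = as.integer(truth$turning_window[["end"]]),
                 deepest_index = NA_integer_, deepest_index2 = NA_integer_,
                 index_before_deepest = NA_integer_,
                 index_after_deepest = NA_integer_,
                 deepest_foot = NA_character_, deepest2_foot = NA_character_,
                 flags = "ground_truth"),
            class = "turning_window")
}

#' Gait features implied by simulator ground truth
#'
#' Applies the same event pairing and feature formulas as
#' [build_feature_row()] to the *true* event frames of a simulated walk
#' (straight-walk contacts only, segmented at the true turning interval),
#' giving the recovery target for end-to-end pipeline tests. For a symmetric
#' noiseless walk this reduces to the closed forms: stride time =
#' `stride_frames / fps`, stance time = `stance_frames / fps`, cadence =
#' `120 / stride time`.
#'
#' @param truth A `tug_ground_truth` from [simulate_tug()].
#' @param schema Output schema (default `"per_foot"`).
#' @param step_time_convention Passed to [build_feature_row()].
#' @return One-row feature data.frame.
#' @export
ground_truth_features <- function(truth, schema = "per_foot",
                                  step_time_convention = "paper") {
  stopifnot(inherits(truth, "tug_ground_truth"))
  mk <- function(side, etype, frames) {
    event_series(side, etype, frames, rep(truth$params$baseline_y, length(frames)),
                 fps = truth$fps, subject_id = "ground_truth")
  }
  build_feature_row(
    left_events = list(heel_strike = mk("left", "heel_strike", truth$heel_strikes$left),
                       toe_off = mk("left", "toe_off", truth$toe_offs$left)),
    right_events = list(heel_strike = mk("right", "heel_strike", truth$heel_strikes$right),
                        toe_off = mk("right", "toe_off", truth$toe_offs$right)),
    window = .truth_window(truth),
    fps = truth$fps, schema = schema,
    step_time_convention = step_time_convention,
    subject_id = "ground_truth")
}

#' Class-conditional population parameters for synthetic feature tables
#'
#' Encodes the faller / non-faller contrasts the analysis assumes: fallers
#' walk with longer stance and stride times, higher cadence and shorter step
#' times, with wider stride-time and cadence spread. Values are means (sd)
#' per class; times in seconds, cadence in steps/min. Defaults place the two
#' classes roughly one standard deviation apart with substantial overlap.
#'
#' @param n_fallers,n_nonfallers Class sizes (defaults 44 / 21, the merged
#'   cohort's composition).
#' @param non_faller,faller Named lists with elements `stance`, `stride`,
#'   `step`, `cadence`, each `c(mean, sd)`.
#' @param asymmetry_sd Relative left/right within-subject scatter
#'   (default 0.02).
#' @param seed Integer seed.
#' @return A `population_params` list.
#' @export
population_params <- function(n_fallers = 44L, n_nonfallers = 21L,
                              non_faller = list(stance = c(0.62, 0.08),
                                                stride = c(1.05, 0.08),
                                                step = c(0.55, 0.07),
                                                cadence = c(105, 8)),
                              faller = list(stance = c(0.72, 0.05),
                                            stride = c(1.12, 0.15),
                                            step = c(0.46, 0.05),
                                            cadence = c(116, 12)),
                              asymmetry_sd = 0.02, seed = 1L) {
  if (n_fallers <= 0L || n_nonfallers <= 0L) {
    stop("class sizes must be positive", call. = FALSE)
  }
  for (cl in list(non_faller, faller)) {
    stopifnot(setequal(names(cl), c("stance", "stride", "step", "cadence")))
    if (any(unlist(cl) <= 0)) {
      stop("all class means and standard deviations must be > 0", call. = FALSE)
    }
  }
  structure(list(n_fallers = as.integer(n_fallers),
                 n_nonfallers = as.integer(n_nonfallers),
                 non_faller = non_faller, faller = faller,
                 asymmetry_sd = asymmetry_sd, seed = as.integer(seed)),
            class = "population_params")
}

# normal truncated to positive support, by rejection
.rtnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= 0)) {
    bad <- out <= 0
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Simulate a labelled gait feature table
#'
#' Draws per-subject feature vectors from the class-conditional
#' truncated-normal distributions of [population_params()]. Each subject
#' gets a latent value per feature; the left and right columns perturb it by
#' a small relative asymmetry, so the per-foot schema is populated with
#' realistically correlated sides.
#'
#' @param params A [population_params()].
#' @return Per-foot-schema data.frame (`provenance = "synthetic"`), fallers
#'   first.
#' @export
simulate_feature_table <- function(params = population_params()) {
  stopifnot(inherits(params, "population_params"))
  set.seed(params$seed)
  one_class <- function(n, cl, label) {
    lat <- lapply(params[[cl]], function(ms) .rtnorm_pos(n, ms[1L], ms[2L]))
    asym <- function(v) {
      list(left = v * (1 + stats::rnorm(n, 0, params$asymmetry_sd)),
           right = v * (1 + stats::rnorm(n, 0, params$asymmetry_sd)))
    }
    stance <- asym(lat$stance); stride <- asym(lat$stride); step <- asym(lat$step)
    data.frame(subject_id = sprintf("%s_%03d", label, seq_len(n)),
               left_stride_time = stride$left, right_stride_time = stride$right,
               left_step_time = step$left, right_step_time = step$right,
               left_stance_time = stance$left, right_stance_time = stance$right,
               cadence = lat$cadence, label = label,
               provenance = "synthetic", stringsAsFactors = FALSE)
  }
  rbind(one_class(params$n_fallers, "faller", "faller"),
        one_class(params$n_nonfallers, "non_faller", "non_faller"))
}
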