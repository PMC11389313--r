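# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# per-window least-squares polynomial fit, truncated at the boundaries
oracle_savgol <- function(x, window_length, polyorder) {
  n <- length(x)
  k <- (window_length - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    off <- (lo:hi) - i
    deg <- min(polyorder, length(off) - 1L)
    X <- outer(off, 0:deg, "^")
    beta <- stats::coef(stats::lm(x[lo:hi] ~ X - 1))
    beta[[1L]] # intercept = fitted value at offset 0
  }, numeric(1))
}

# O(n^2) peak oracle: nearest differing neighbour comparison (plateaus count
# once, at their first sample), then iterative removal of the lowest peak
# involved in any min-distance conflict (later index loses ties)
oracle_peaks <- function(x, min_distance) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1L)) {
    if (i > 1L && x[i - 1L] == x[i]) next # not the first sample of a plateau
    l <- i - 1L
    while (l >= 1L && x[l] == x[i]) l <- l - 1L
    r <- i + 1L
    while (r <= n && x[r] == x[i]) r <- r + 1L
    if (l >= 1L && r <= n && x[i] > x[l] && x[i] > x[r]) cand <- c(cand, i)
  }
  # greedy pruning spelt out longhand: visit candidates from highest value
  # (earlier sample first on ties), keep those far enough from all kept peaks
  remaining <- cand
  kept <- integer(0)
  while (length(remaining)) {
    best <- remaining[1L]
    for (p in remaining) if (x[p] > x[best]) best <- p
    if (all(abs(kept - best) >= min_distance)) kept <- c(kept, best)
    remaining <- setdiff(remaining, best)
  }
  sort(kept) - 1L # 0-based frames
}

# AlphaPose-dialect JSON written independently of write_pose_json()
write_fixture_pose_json <- function(path, frames) {
  recs <- lapply(frames, function(fr) {
    list(image_id = fr$image_id, keypoints = fr$keypoints,
         score = sum(fr$keypoints[seq(3, length(fr$keypoints), by = 3)]))
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = I(17)), path)
  path
}

# flat 26-keypoint triplet vector with every keypoint at (x0, y0, conf)
flat_keypoints <- function(x0 = 100, y0 = 500, conf = 0.9,
                           override = list()) {
  kp <- halpe_keypoints()
  v <- rep(c(x0, y0, conf), times = 26)
  for (nm in names(override)) {
    j <- (match(nm, kp) - 1L) * 3L
    v[j + 1:3] <- override[[nm]]
  }
  v
}

# event series shorthand
es <- function(foot, type, frames, values = rep(500, length(frames)), fps = 30) {
  event_series(foot, type, frames, values, fps = fps, subject_id = "fixture")
}

# zero-separation population (both classes share the non-faller parameters)
null_population <- function(n_per_class, seed) {
  nf <- list(stance = c(0.62, 0.08), stride = c(1.05, 0.08),
             step = c(0.55, 0.07), cadence = c(105, 8))
  population_params(n_fallers = n_per_class, n_nonfallers = n_per_class,
                    non_faller = nf, faller = nf, seed = seed)
}
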