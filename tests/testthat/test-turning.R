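left3 <- function() es("left", "heel_strike", c(10, 40, 70), c(10, 3, 9))
right3 <- function() es("right", "heel_strike", c(25, 55, 85), c(8, 2, 11))

test_that("deepest maxima are found across both feet with the earlier-frame tie rule", {
  d <- find_deepest_maxima(left3(), right3())
  expect_equal(d$deepest_index, 55L)
  expect_equal(d$deepest_foot, "right")
  expect_equal(d$deepest_index2, 40L)
  expect_equal(d$deepest2_foot, "left")

  tied <- find_deepest_maxima(es("left", "heel_strike", c(10, 50), c(2, 9)),
                              es("right", "heel_strike", c(30, 70), c(2, 9)))
  expect_equal(tied$deepest_index, 10L) # earlier frame wins the value tie

  expect_error(find_deepest_maxima(es("left", "heel_strike", 5, 1),
                                   es("right", "heel_strike", integer(0), numeric(0))),
               "at least 2")
})

test_that("turning window bounds are floored midpoints of the stated pairs", {
  w <- compute_turning_window(left3(), right3())
  # before 2nd-deepest (40) lies 25; after deepest (55) lies 70
  expect_equal(w$index_before_deepest, 25L)
  expect_equal(w$index_after_deepest, 70L)
  expect_equal(w$start_turning, 32L) # floor((25 + 40) / 2)
  expect_equal(w$end_turning, 62L)   # floor((70 + 55) / 2)
  expect_true(w$start_turning >= w$index_before_deepest)
  expect_true(w$end_turning <= w$index_after_deepest)
  expect_length(w$flags, 0L)

  # spec-style arithmetic: before 40, d2 60, d 80, after 100 -> [50, 90]
  wl <- es("left", "heel_strike", c(40, 60, 80), c(9, 2, 1))
  wr <- es("right", "heel_strike", c(100, 130), c(9, 10))
  w2 <- compute_turning_window(wl, wr)
  expect_equal(w2$start_turning, 50L)
  expect_equal(w2$end_turning, 90L)

  # no event before the second-deepest: start falls back, flagged
  w3 <- compute_turning_window(es("left", "heel_strike", c(10, 40), c(2, 1)),
                               es("right", "heel_strike", c(70, 100), c(9, 8)))
  expect_true("no_event_before_second_deepest" %in% w3$flags)
})

test_that("turning exclusion removes in-window events inclusively and is idempotent", {
  ev <- es("left", "heel_strike", c(10, 50, 55, 60, 90))
  w <- structure(list(start_turning = 50L, end_turning = 60L,
                      deepest_index = 55L, deepest_index2 = 50L,
                      index_before_deepest = 10L, index_after_deepest = 90L,
                      deepest_foot = "left", deepest2_foot = "left",
                      flags = character(0)), class = "turning_window")
  out <- exclude_turning_events(ev, w)
  expect_equal(out$frame_indices, c(10L, 90L))
  expect_equal(ev$frame_indices, c(10L, 50L, 55L, 60L, 90L)) # input untouched
  expect_equal(exclude_turning_events(out, w)$frame_indices, out$frame_indices)

  # window outside the event range changes nothing
  w$start_turning <- 200L; w$end_turning <- 300L
  expect_equal(exclude_turning_events(ev, w)$frame_indices, ev$frame_indices)
})

test_that("simulated turning windows bracket the pause and spare straight-walk strikes", {
  for (s in 1:6) {
    sim <- simulate_tug(gait_sim_params(seed = s, noise_sigma = 1))
    lhs <- detect_events(sim$pose, "left", "heel_strike")
    rhs <- detect_events(sim$pose, "right", "heel_strike")
    d <- find_deepest_maxima(lhs, rhs)
    truth_win <- sim$truth$turning_window
    expect_true(d$deepest_index >= truth_win["start"] &&
                  d$deepest_index <= truth_win["end"])
    expect_true(d$deepest_index2 >= truth_win["start"] &&
                  d$deepest_index2 <= truth_win["end"])

    w <- compute_turning_window(lhs, rhs)
    expect_true(w$start_turning <= truth_win["end"] &&
                  w$end_turning >= truth_win["start"]) # overlap
    straight <- sort(unlist(sim$truth$heel_strikes))
    expect_false(any(straight >= w$start_turning & straight <= w$end_turning))

    # surviving events = true straight-walk events (within detection jitter)
    for (ser in list(lhs, rhs)) {
      kept <- exclude_turning_events(ser, w)
      truth_f <- sort(sim$truth$heel_strikes[[ser$foot]])
      expect_length(kept$frame_indices, length(truth_f))
      expect_true(all(abs(kept$frame_indices - truth_f) <= 2L))
    }
  }
})

test_that("widening the pause never shrinks the set of excluded events", {
  excluded_count <- vapply(c(1.5, 2, 3, 4), function(tp) {
    sim <- simulate_tug(gait_sim_params(seed = 9, turn_pause = tp))
    ev <- extract_gait_features(sim$pose)$events
    all_detected <- length(detect_events(sim$pose, "left", "heel_strike")) +
      length(detect_events(sim$pose, "right", "heel_strike"))
    all_detected - length(ev$left$heel_strike) - length(ev$right$heel_strike)
  }, numeric(1))
  expect_true(all(diff(excluded_count) >= 0))
})
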