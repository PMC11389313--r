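test_that("the simulator is deterministic under a fixed seed", {
  a <- simulate_tug(gait_sim_params(seed = 5, noise_sigma = 2))
  b <- simulate_tug(gait_sim_params(seed = 5, noise_sigma = 2))
  expect_identical(a$pose$y, b$pose$y)
  expect_identical(a$truth$heel_strikes, b$truth$heel_strikes)
  c <- simulate_tug(gait_sim_params(seed = 6, noise_sigma = 2))
  expect_false(identical(a$pose$y, c$pose$y))
})

test_that("doubling fps doubles event frames and leaves true times unchanged", {
  # parameters whose stance/stride products are integral at both rates
  p30 <- gait_sim_params(fps = 30, stride_period = 1.2, stance_fraction = 2 / 3,
                         seed = 1)
  p60 <- gait_sim_params(fps = 60, stride_period = 1.2, stance_fraction = 2 / 3,
                         seed = 1)
  t30 <- simulate_tug(p30)$truth
  t60 <- simulate_tug(p60)$truth
  for (side in c("left", "right")) {
    expect_equal(t60$heel_strikes[[side]], 2L * t30$heel_strikes[[side]])
    expect_equal(t60$toe_offs[[side]], 2L * t30$toe_offs[[side]])
  }
  g30 <- ground_truth_features(t30)
  g60 <- ground_truth_features(t60)
  cols <- setdiff(feature_schema_cols("per_foot"), "label")
  expect_equal(unlist(g60[cols]), unlist(g30[cols]), tolerance = 1e-12)
})

test_that("extracted trajectories reproduce the stored simulator signals", {
  sim <- simulate_tug(gait_sim_params(seed = 12, noise_sigma = 1.5))
  lh <- extract_trajectory(sim$pose, "LHeel", "y")
  expect_equal(lh$values, sim$truth$signals_noisy$left_heel)
  rt <- extract_trajectory(sim$pose, "RBigToe", "y")
  expect_equal(rt$values, sim$truth$signals_noisy$right_toe)
})

test_that("ground-truth features match the simulator's closed forms", {
  # stride 1.0 s, stance 0.6 -> stance time exactly 0.6 s, stride 1.0 s
  sim <- simulate_tug(gait_sim_params(stride_period = 1.0, stance_fraction = 0.6,
                                      seed = 2))
  gt <- ground_truth_features(sim$truth)
  expect_equal(gt$left_stride_time, 1.0)
  expect_equal(gt$right_stride_time, 1.0)
  expect_equal(gt$left_stance_time, 0.6)
  expect_equal(gt$right_stance_time, 0.6)
  # symmetric gait: cadence = 60 * 2 / stride_period
  expect_equal(gt$cadence, 120)

  gt12 <- ground_truth_features(simulate_tug(gait_sim_params(seed = 3))$truth)
  expect_equal(gt12$left_stride_time, 1.2)
  expect_equal(gt12$cadence, 100)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(gait_sim_params(stance_fraction = 1.2), "stance_fraction")
  expect_error(gait_sim_params(turn_pause = -1), "turn_pause")
  expect_error(simulate_tug(gait_sim_params(turn_pause = 0.2)), "turn_pause")
  # no-turn walk carries no turning ground truth
  no_turn <- simulate_tug(gait_sim_params(turn_pause = 0, seed = 1))
  expect_null(no_turn$truth$turning_window)
  expect_length(no_turn$truth$turn_heel$left, 0L)
})

test_that("simulated feature tables match their configured population", {
  tab <- simulate_feature_table(population_params(seed = 7))
  expect_equal(nrow(tab), 65L)
  expect_equal(as.vector(table(tab$label)[c("faller", "non_faller")]),
               c(44L, 21L))
  expect_equal(feature_schema(tab), "per_foot")
  expect_true(all(tab[setdiff(feature_schema_cols("per_foot"), "label")] > 0))

  # sample means within 3 standard errors of the configured class means
  pp <- population_params(n_fallers = 200, n_nonfallers = 200, seed = 11)
  big <- simulate_feature_table(pp)
  checks <- list(
    c("faller", "left_stance_time", "stance"),
    c("faller", "cadence", "cadence"),
    c("non_faller", "left_step_time", "step"),
    c("non_faller", "left_stride_time", "stride"))
  for (ch in checks) {
    cls <- big[big$label == ch[1L], ]
    conf <- pp[[ch[1L]]][[ch[3L]]]
    se <- conf[2L] / sqrt(nrow(cls))
    expect_lt(abs(mean(cls[[ch[2L]]]) - conf[1L]), 3.5 * se,
              label = paste(ch[1L], ch[2L]))
  }

  # configured faller shifts are realised in the expected directions
  agg <- stats::aggregate(big[c("left_stance_time", "left_stride_time",
                                "left_step_time", "cadence")],
                          by = list(label = big$label), FUN = mean)
  f <- agg[agg$label == "faller", ]; n <- agg[agg$label == "non_faller", ]
  expect_gt(f$left_stance_time, n$left_stance_time)
  expect_gt(f$left_stride_time, n$left_stride_time)
  expect_gt(f$cadence, n$cadence)
  expect_lt(f$left_step_time, n$left_step_time)
})

test_that("zero class separation leaves feature t-tests non-significant at the nominal rate", {
  feats <- setdiff(feature_schema_cols("per_foot"), "label")
  nonsig <- 0L
  total <- 0L
  for (s in 1:60) {
    tab <- simulate_feature_table(null_population(25, seed = 300 + s))
    for (f in feats) {
      p <- stats::t.test(tab[[f]] ~ tab$label)$p.value
      nonsig <- nonsig + (p > 0.05)
      total <- total + 1L
    }
  }
  expect_gt(nonsig / total, 0.90) # nominal 95%, with simulation slack
})
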