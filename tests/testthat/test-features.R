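test_that("temporal feature primitives follow the frame arithmetic", {
  expect_equal(stance_time(30, 45, 30), 0.5)
  expect_equal(stance_time(0, 30, 30), 1.0)
  expect_error(stance_time(45, 30, 30), "after")

  expect_equal(stride_time(30, 63, 30), 1.1)
  expect_equal(stride_time(0, 30, 30), 1.0)
  expect_error(stride_time(30, 30, 30), "after")

  expect_equal(step_time(30, 45, 30), 0.5)
  expect_equal(step_time(60, 75, 30), 0.5)

  expect_equal(cadence(30, 0.5), 60)
  expect_equal(cadence(0, 1), 0)
  expect_error(cadence(10, 0), "positive")
})

hand_events <- function(fps = 30) {
  # left HS 0,30,60 / TO 18,48,78; right HS 15,45,75 / TO 33,63,93
  list(
    left = list(heel_strike = es("left", "heel_strike", c(0, 30, 60), fps = fps),
                toe_off = es("left", "toe_off", c(18, 48, 78), fps = fps)),
    right = list(heel_strike = es("right", "heel_strike", c(15, 45, 75), fps = fps),
                 toe_off = es("right", "toe_off", c(33, 63, 93), fps = fps))
  )
}

test_that("feature row equals hand arithmetic on constructed events", {
  ev <- hand_events()
  row <- build_feature_row(ev$left, ev$right, fps = 30)
  # strides: (30, 30)/30 -> 1.0 both feet
  expect_equal(row$left_stride_time, 1.0)
  expect_equal(row$right_stride_time, 1.0)
  # stances: every TO is HS + 18 frames -> 0.6 s
  expect_equal(row$left_stance_time, 0.6)
  expect_equal(row$right_stance_time, 0.6)
  # steps: first left HS has no qualifying opposite TO before the next HS;
  # remaining cycles give (33-30, 63-60)/30 = 0.1 and (18-15, 48-45, 78-75)/30
  expect_equal(row$left_step_time, 0.1)
  expect_equal(row$right_step_time, 0.1)
  # cadence: pooled strikes 0,15,...,75 -> 5 intervals over 2.5 s
  expect_equal(row$cadence, 120)
})

test_that("averaged schema is the pairwise mean of the per-foot schema", {
  ev <- hand_events()
  pf <- build_feature_row(ev$left, ev$right, fps = 30)
  av <- build_feature_row(ev$left, ev$right, fps = 30, schema = "averaged")
  expect_named(av, c("subject_id", feature_schema_cols("averaged"), "provenance"))
  expect_equal(av$average_stride_time, (pf$left_stride_time + pf$right_stride_time) / 2)
  expect_equal(av$average_step_time, (pf$left_step_time + pf$right_step_time) / 2)
  expect_equal(av$average_stance_time, (pf$left_stance_time + pf$right_stance_time) / 2)
  expect_equal(av$cadence, pf$cadence)
  expect_equal(as_averaged_schema(pf)$average_stride_time, av$average_stride_time)
})

test_that("features scale as 1/fps when the same frames are re-indexed faster", {
  ev30 <- hand_events(fps = 30)
  ev60 <- hand_events(fps = 60)
  r30 <- build_feature_row(ev30$left, ev30$right, fps = 30)
  r60 <- build_feature_row(ev60$left, ev60$right, fps = 60)
  for (f in c("left_stride_time", "right_stride_time", "left_step_time",
              "right_step_time", "left_stance_time", "right_stance_time")) {
    expect_equal(r60[[f]], r30[[f]] / 2, info = f)
  }
  expect_equal(r60$cadence, r30$cadence * 2)
})

test_that("symmetric simulated gait yields near-equal left/right features", {
  sim <- simulate_tug(gait_sim_params(seed = 4, noise_sigma = 1))
  row <- extract_gait_features(sim$pose)$features
  frame_s <- 1 / 30
  expect_lt(abs(row$left_step_time - row$right_step_time), frame_s)
  expect_lt(abs(row$left_stride_time - row$right_stride_time), 2 * frame_s)
  expect_lt(abs(row$left_stance_time - row$right_stance_time), 2 * frame_s)
})

test_that("periodic gait ties the features together through the stride period", {
  sim <- simulate_tug(gait_sim_params(seed = 13))
  gt <- ground_truth_features(sim$truth,
                              step_time_convention = "contralateral_hs")
  frame_s <- 1 / 30
  # under the contralateral heel-strike convention the symmetric walk obeys
  # stride = 2 x step and cadence = 60 / step
  expect_lt(abs(gt$left_stride_time - 2 * gt$left_step_time), frame_s)
  expect_lt(abs(gt$cadence - 60 / gt$left_step_time), 1e-9)
})

test_that("external attribute mapping renames, averages cadence and drops spatial columns", {
  ext <- data.frame(
    Left_Stride_Time = 1.1, Right_Stride_Time = 1.2,
    Left_Step_Time = 0.5, Right_Step_Time = 0.55,
    Left_Single_Support = 0.6, Right_Single_Support = 0.62,
    Left_Cadence = 100, Right_Cadence = 104,
    Left_Stride_Length = 1.3, Speed = 1.1, # spatial extras to drop
    Label = "faller", stringsAsFactors = FALSE)
  got <- map_external_attributes(ext)
  expect_equal(got$cadence, 102)
  expect_equal(got$left_stance_time, 0.6)
  expect_equal(sort(setdiff(names(got), c("subject_id", "provenance"))),
               sort(feature_schema_cols("per_foot")))
  expect_false(any(grepl("Length|Speed", names(got))))

  expect_error(map_external_attributes(ext[, -1]), "Left_Stride_Time")
})

test_that("merging preserves counts, provenance and schema", {
  prim <- simulate_feature_table(population_params(n_fallers = 1, n_nonfallers = 20,
                                                   seed = 1))
  prim <- prim[prim$label == "non_faller", ] # 20 rows primary non-fallers
  prim$provenance <- "primary"
  ext <- simulate_feature_table(population_params(n_fallers = 44, n_nonfallers = 1,
                                                  seed = 2))
  ext <- ext[ext$label == "faller", ]
  ext$provenance <- "external"
  extra <- simulate_feature_table(population_params(n_fallers = 1, n_nonfallers = 1,
                                                    seed = 3))[2, ]
  extra$provenance <- "primary"
  prim <- rbind(prim, extra) # 21 non-fallers

  merged <- merge_tables(prim, ext)
  expect_equal(nrow(merged), 65L)
  expect_equal(as.vector(table(merged$label)[c("faller", "non_faller")]),
               c(44L, 21L))
  expect_equal(sum(merged$provenance == "primary"), 21L)
  expect_equal(sum(merged$provenance == "external"), 44L)
  expect_equal(merge_tables(prim, prim[0, ]), prim) # empty merge is identity

  av <- as_averaged_schema(ext)
  expect_error(merge_tables(prim, av), "schema mismatch")
})

test_that("feature CSVs carry the exact schema headers", {
  tab <- simulate_feature_table(population_params(n_fallers = 3, n_nonfallers = 3,
                                                  seed = 1))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, f1)
  expect_identical(names(utils::read.csv(f1)), feature_schema_cols("per_foot"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(as_averaged_schema(tab), f2)
  expect_identical(names(utils::read.csv(f2)), feature_schema_cols("averaged"))

  back <- read_feature_csv(f1)
  expect_equal(feature_schema(back), "per_foot")
})
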