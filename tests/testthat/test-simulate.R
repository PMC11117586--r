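small_config <- function(n_per_condition = c(NVR = 3, PFFV = 3, FV = 3), ...) {
  simulation_config(n_per_condition = n_per_condition,
                    inspection_time_median_s = c(NVR = 1.2, PFFV = 2.0, FV = 3.2),
                    ...)
}

test_that("the stimulus catalog is balanced over emotion and gender", {
  cat30 <- generate_stimulus_catalog(30)
  expect_equal(nrow(cat30), 30)
  expect_equal(as.integer(table(cat30$emotion)), rep(6L, 5))
  expect_equal(as.integer(table(cat30$face_gender)), rep(15L, 2))
  expect_true(all(table(cat30$emotion, cat30$face_gender) == 3))
  expect_equal(dplyr::n_distinct(cat30$stimulus_id), 30)
  cat60 <- generate_stimulus_catalog(60)
  expect_equal(as.integer(table(cat60$emotion)), rep(12L, 5))
  expect_error(generate_stimulus_catalog(10 + 5), "divisible")
})

test_that("seeded simulation is bit-reproducible", {
  cfg <- small_config(binocular = FALSE)
  a <- simulate_study(cfg, seed = 123)
  b <- simulate_study(cfg, seed = 123)
  expect_identical(a$gaze, b$gaze)
  expect_identical(a$records, b$records)
  c <- simulate_study(cfg, seed = 124)
  expect_false(identical(a$records$response_emotion,
                         c$records$response_emotion))
})

test_that("each participant sees every emotion exactly 6 times", {
  sim <- simulate_study(small_config(binocular = FALSE), seed = 3)
  counts <- table(sim$records$participant_id, sim$records$emotion_true)
  expect_true(all(counts == 6))
  expect_equal(as.integer(table(sim$records$face_gender)), rep(9 * 15L, 2))
})

test_that("recorded inspection times follow the planted condition ordering", {
  cfg <- simulation_config(n_per_condition = c(NVR = 12, PFFV = 12, FV = 12),
                           inspection_time_median_s = c(NVR = 1.0, PFFV = 2.2, FV = 4.4),
                           binocular = FALSE)
  sim <- simulate_study(cfg, seed = 11)
  med <- tapply(sim$records$inspection_time_s, sim$records$condition, median)
  expect_true(med[["NVR"]] < med[["PFFV"]])
  expect_true(med[["PFFV"]] < med[["FV"]])
  # recorded times equal the planted gaze-window spans
  joined <- dplyr::left_join(sim$records, sim$windows,
                             by = c("participant_id", "trial_index"))
  expect_equal(joined$inspection_time_s,
               inspection_time(joined$onset_ms, joined$offset_ms),
               tolerance = 1e-9)
})

test_that("detection recovers the planted fixation counts and centers", {
  cfg <- small_config(invalid_rate = 0, binocular = FALSE)
  sim <- simulate_study(cfg, seed = 5)
  fx <- detect_fixations(sim$gaze)
  planted_ok <- sim$planted |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::summarise(n_planted = sum(.data$duration_ms >= 80), .groups = "drop")
  detected <- fx |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::summarise(n_detected = dplyr::n(), .groups = "drop")
  cmp <- dplyr::left_join(planted_ok, detected,
                          by = c("participant_id", "trial_index"))
  expect_equal(cmp$n_detected, cmp$n_planted)
})

test_that("judgments reproduce the planted confusion template within 3 sigma", {
  cfg <- simulation_config(n_per_condition = c(FV = 50), binocular = FALSE,
                           inspection_time_median_s = c(FV = 0.8))
  sim <- simulate_study(cfg, seed = 8)
  m <- confusion_matrix(sim$records)
  template <- default_confusion_templates()$FV
  n_row <- 50 * 6
  for (e in EMOTIONS) {
    sigma <- sqrt(pmax(template[e, ] * (1 - template[e, ]), 1e-6) / n_row)
    expect_true(all(abs(m[e, ] - template[e, ]) <= 3 * sigma + 1e-9))
  }
})

test_that("confidence draws reproduce the planted Likert distributions", {
  cfg <- simulation_config(n_per_condition = c(NVR = 60), binocular = FALSE,
                           inspection_time_median_s = c(NVR = 0.8))
  sim <- simulate_study(cfg, seed = 13)
  happy <- sim$records$confidence_raw[sim$records$emotion_true == "happiness"]
  p_hat <- tabulate(happy, 5) / length(happy)
  p0 <- default_likert_templates()$happiness
  expect_true(all(abs(p_hat - p0) <=
                    3 * sqrt(pmax(p0 * (1 - p0), 1e-6) / length(happy)) + 1e-9))
})

test_that("binocular logs carry paired eyes that merge to the cyclopean mean", {
  cfg <- small_config(n_per_condition = c(NVR = 1), invalid_rate = 0)
  sim <- simulate_study(cfg, seed = 2)
  expect_setequal(unique(sim$gaze$eye), c("left", "right"))
  trial1 <- sim$gaze[sim$gaze$trial_index == 1, ]
  left <- trial1[trial1$eye == "left", ]
  right <- trial1[trial1$eye == "right", ]
  m <- merge_binocular(left, right)
  expect_equal(m$x_px, (left$x_px + right$x_px) / 2)
  merged_all <- gazewin:::merge_binocular_log(sim$gaze)
  expect_equal(nrow(merged_all), nrow(sim$gaze) / 2)
})

test_that("write_dataset emits the delimited files plus a manifest", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(small_config(n_per_condition = c(NVR = 1),
                                     binocular = FALSE), seed = 4)
  write_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "gaze_log.csv", "judgments.csv", "trial_windows.csv",
    "stimulus_catalog.csv", "manifest.json")))))
  back <- read_gaze_log(file.path(dir, "gaze_log.csv"))
  expect_equal(nrow(back), nrow(sim$gaze))
  expect_equal(back$x_px, sim$gaze$x_px, tolerance = 1e-9)
  rec <- read_judgments(file.path(dir, "judgments.csv"))
  expect_equal(rec$response_emotion, sim$records$response_emotion)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 4)
  expect_equal(manifest$n_trials, 30)
})
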