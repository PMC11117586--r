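test_that("a steady 500 ms gaze yields one fixation at its centroid", {
  t <- seq(0, by = 1000 / 60, length.out = 30)  # ~483 ms span
  s <- tibble::tibble(t_ms = t, x_px = 100, y_px = 100, validity = TRUE)
  fx <- detect_fixations(s)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$centroid_x_px, 100)
  expect_equal(fx$centroid_y_px, 100)
  expect_equal(fx$duration_ms, 29 * 1000 / 60, tolerance = 1e-9)
  expect_equal(fx$n_samples, 30L)
})

test_that("clusters below the minimum duration are rejected", {
  t <- seq(0, 60, by = 1000 / 60)  # 4 samples, 50 ms span
  s <- tibble::tibble(t_ms = t, x_px = 500, y_px = 500, validity = TRUE)
  expect_equal(nrow(detect_fixations(s)), 0)
  # and fewer than 2 valid samples is an empty result, not an error
  one <- tibble::tibble(t_ms = 0, x_px = 1, y_px = 1, validity = TRUE)
  expect_equal(nrow(detect_fixations(one)), 0)
})

test_that("two planted clusters separated by a saccade are both recovered", {
  set.seed(11)
  centers <- rbind(c(400, 500), c(600, 500))  # 200 px apart
  s <- plant_stream(centers, durations_ms = c(300, 300), gap_ms = 50,
                    jitter_sd = 2)
  fx <- detect_fixations(s)
  expect_equal(nrow(fx), 2)
  expect_lt(abs(fx$centroid_x_px[1] - 400), 1)
  expect_lt(abs(fx$centroid_x_px[2] - 600), 1)
  expect_lt(max(abs(fx$centroid_y_px - 500)), 1)
})

test_that("a gap longer than max_gap_ms closes the cluster", {
  t <- c(seq(0, 150, by = 1000 / 60), seq(300, 450, by = 1000 / 60))
  s <- tibble::tibble(t_ms = t, x_px = 100, y_px = 100, validity = TRUE)
  fx <- detect_fixations(s)  # 150 ms gap > 100 ms default
  expect_equal(nrow(fx), 2)
  fx2 <- detect_fixations(s, fixation_params(max_gap_ms = 200))
  expect_equal(nrow(fx2), 1)
})

test_that("invalid samples are skipped but do not split a cluster", {
  t <- seq(0, by = 1000 / 60, length.out = 30)
  s <- tibble::tibble(t_ms = t, x_px = 100, y_px = 100, validity = TRUE)
  s$validity[14:15] <- FALSE
  s$x_px[14] <- 5000  # invalid coordinates must be ignored entirely
  fx <- detect_fixations(s)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$n_samples, 28L)
  expect_equal(fx$centroid_x_px, 100)
})

test_that("secondary tolerance drops outliers and recomputes the centroid once", {
  # drifting stream: each sample sits 38 px from the running centroid, so it
  # always joins (38 <= 40), yet the early samples end up ~60 px from the
  # final centroid and must be dropped when the secondary radius is active
  x <- rep(0, 10)
  cen <- 0
  for (i in 1:40) {
    x <- c(x, cen + 38)
    cen <- mean(x)
  }
  s <- tibble::tibble(t_ms = seq_along(x) * 1000 / 60, x_px = x, y_px = 0,
                      validity = TRUE)
  plain <- detect_fixations(s, fixation_params(tolerance_px = 40))
  expect_equal(plain$n_samples, 50L)
  with_t2 <- detect_fixations(s, fixation_params(tolerance_px = 40,
                                                 secondary_tolerance_px = 40))
  keep <- abs(x - mean(x)) <= 40
  expect_equal(with_t2$n_samples, sum(keep))
  expect_equal(with_t2$centroid_x_px, mean(x[keep]), tolerance = 1e-9)
  # when every member lies within t2 of the centroid, t2 is a no-op
  tight <- plant_stream(rbind(c(500, 500)), 400, jitter_sd = 1)
  expect_equal(detect_fixations(tight, fixation_params(secondary_tolerance_px = 60)),
               detect_fixations(tight))
  expect_error(fixation_params(secondary_tolerance_px = 10), "")
})

test_that("detector equals the brute-force oracle on random streams", {
  set.seed(301)
  for (i in 1:60) {
    s <- random_stream(sample(20:200, 1))
    got <- detect_fixations(s)
    want <- oracle_fixations(s)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$onset_ms, want$onset_ms)
    expect_equal(got$centroid_x_px, want$centroid_x_px, tolerance = 1e-9)
    expect_equal(got$n_samples, want$n_samples)
  }
})

test_that("every fixation respects the duration threshold and time order", {
  set.seed(302)
  for (i in 1:25) {
    s <- random_stream(150)
    fx <- detect_fixations(s)
    if (nrow(fx) == 0) next
    expect_true(all(fx$duration_ms >= 80))
    expect_true(all(diff(fx$onset_ms) > 0))
    expect_true(all(fx$onset_ms[-1] > fx$offset_ms[-nrow(fx)]))
  }
})

test_that("raising the duration threshold never adds fixations", {
  set.seed(303)
  for (i in 1:15) {
    s <- random_stream(150)
    counts <- vapply(c(40, 80, 120, 200, 400), function(md)
      nrow(detect_fixations(s, fixation_params(min_duration_ms = md))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("first-point membership rule is available and differs from centroid", {
  # drifting positions: each step within tolerance of the previous centroid
  # but eventually far from the first point
  t <- seq(0, by = 1000 / 60, length.out = 60)
  s <- tibble::tibble(t_ms = t, x_px = 100 + seq(0, 118, by = 2), y_px = 100,
                      validity = TRUE)
  by_centroid <- detect_fixations(s, fixation_params(tolerance_px = 40))
  by_first <- detect_fixations(s, fixation_params(tolerance_px = 40,
                                                  membership = "first"))
  expect_gt(nrow(by_first), nrow(by_centroid))
})

test_that("trial segmentation uses the closed-open window convention", {
  w <- tibble::tibble(trial_index = 1:3, onset_ms = c(0, 1000, 2000),
                      offset_ms = c(500, 1500, 2500))
  raw <- tibble::tibble(t_ms = c(1000, 1100, 1499.9, 1500, 700, 2600),
                        x_px = 1, y_px = 1, validity = TRUE)
  out <- suppressMessages(segment_trials(raw, w))
  expect_equal(nrow(out), 3)
  expect_equal(unique(out$trial_index), 2L)  # onset inclusive, offset exclusive
  expect_equal(attr(out, "dropped_samples"), 3)
  expect_error(segment_trials(raw, tibble::tibble(
    trial_index = 1:2, onset_ms = c(0, 400), offset_ms = c(500, 900))),
    "overlap")
})

test_that("segmentation recovers per-window counts planted by the generator", {
  set.seed(42)
  sim <- simulate_participant(simulation_config(binocular = FALSE),
                              "P01", "NVR", generate_stimulus_catalog(), 99)
  raw <- dplyr::select(sim$gaze, -"trial_index")
  reseg <- segment_trials(raw, sim$windows)
  expect_equal(attr(reseg, "dropped_samples"), 0)
  expect_equal(table(reseg$trial_index), table(sim$gaze$trial_index))
})

test_that("binocular merging averages valid eyes and flags double dropouts", {
  left <- tibble::tibble(t_ms = c(0, 16, 32), x_px = c(100, 100, 100),
                         y_px = c(100, 100, 100),
                         validity = c(TRUE, FALSE, FALSE), eye = "left")
  right <- tibble::tibble(t_ms = c(0, 16, 32), x_px = c(102, 102, 102),
                          y_px = c(100, 100, 100),
                          validity = c(TRUE, TRUE, FALSE), eye = "right")
  m <- merge_binocular(left, right)
  expect_equal(m$x_px[1], 101)   # both valid: mean
  expect_equal(m$x_px[2], 102)   # left invalid: right's coordinates
  expect_false(m$validity[3])    # both invalid
  expect_true(all(m$eye == "merged"))
  right$t_ms[2] <- 17
  expect_error(merge_binocular(left, right), "timestamps")
})

test_that("inspection time is the presentation span in seconds", {
  expect_equal(inspection_time(1000, 5510), 4.51)
  expect_equal(inspection_time(0, 0), 0)
  expect_error(inspection_time(100, 50), "negative")
})
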