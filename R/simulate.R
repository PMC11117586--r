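default_confusion_templates <- function() {
  tpl <- function(...) {
    m <- matrix(c(...), nrow = 5, byrow = TRUE,
                dimnames = list(expected = EMOTIONS, judged = EMOTIONS))
    stopifnot(all(abs(rowSums(m) - 1) < 1e-9))
    m
  }
  list(
    NVR = tpl(0.97, 0.010, 0.010, 0.005, 0.005,
              0.01, 0.920, 0.040, 0.020, 0.010,
              0.02, 0.040, 0.900, 0.020, 0.020,
              0.01, 0.020, 0.030, 0.920, 0.020,
              0.01, 0.020, 0.020, 0.020, 0.930),
    PFFV = tpl(0.96, 0.010, 0.020, 0.005, 0.005,
               0.01, 0.850, 0.080, 0.040, 0.020,
               0.02, 0.060, 0.850, 0.030, 0.040,
               0.01, 0.030, 0.040, 0.900, 0.020,
               0.01, 0.020, 0.030, 0.020, 0.920),
    FV = tpl(0.97, 0.010, 0.010, 0.005, 0.005,
             0.01, 0.620, 0.180, 0.120, 0.070,
             0.02, 0.070, 0.830, 0.040, 0.040,
             0.01, 0.030, 0.050, 0.880, 0.030,
             0.02, 0.050, 0.060, 0.070, 0.800))
}

default_likert_templates <- function() {
  # mass over raw categories 1..5 (SA..SD): confident overall, least so for
  # sadness/neutrality, mirroring the qualitative confidence pattern
  list(happiness = c(0.80, 0.13, 0.04, 0.02, 0.01),
       sadness = c(0.55, 0.25, 0.12, 0.05, 0.03),
       neutrality = c(0.55, 0.27, 0.10, 0.05, 0.03),
       fear = c(0.62, 0.24, 0.09, 0.03, 0.02),
       anger = c(0.68, 0.20, 0.07, 0.03, 0.02))
}

#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The defaults reproduce the
#' design the analysis targets: three independent arms (no restriction,
#' 5-degree and 2-degree moving-window apertures) of 54 / 59 / 50
#' participants, 30 trials each over a balanced 5-emotion x 2-gender x
#' 3-exemplar stimulus set, 60 Hz binocular sampling, log-normal
#' inspection-time and fixation-duration models anchored at the
#' condition-wise medians 4.51 / 10.90 / 19.64 s and 356 / 520 / 794 ms,
#' diagonal-dominant per-condition confusion templates (with degraded
#' sadness/anger recognition under the foveal-only window), and
#' per-expression confidence distributions.
#'
#' @param n_per_condition Named integer vector of participants per
#'   condition.
#' @param rate_hz Gaze sampling rate.
#' @param n_stimuli Stimuli per session; must be divisible by 10
#'   (5 emotions x 2 genders).
#' @param inspection_time_median_s,inspection_time_sdlog Per-condition
#'   log-normal medians (s) and common log-scale SD for the trial
#'   inspection time.
#' @param fixation_duration_median_ms,fixation_duration_sdlog Per-condition
#'   log-normal medians (ms) and common log-scale SD for single-fixation
#'   durations.
#' @param fixation_jitter_sd_px Gaussian jitter SD of samples around their
#'   fixation center, per axis; well below the detector tolerance.
#' @param saccade_gap_ms Range (min, max) of inter-fixation gaps during
#'   which no samples are emitted.
#' @param min_center_sep_px Minimum distance between consecutive fixation
#'   centers, above twice the detector tolerance so planted fixations stay
#'   separable.
#' @param face_region Pixel box (xmin, xmax, ymin, ymax) from which fixation
#'   centers are drawn; defaults to the central face area of a 1920 x 1080
#'   display.
#' @param invalid_rate Fraction of samples marked invalid (tracking
#'   dropouts).
#' @param binocular Emit left and right eye rows (`TRUE`, default) or a
#'   single merged stream.
#' @param confusion_templates Named list (per condition) of 5 x 5
#'   row-stochastic judgment templates, rows = presented emotion.
#' @param likert_templates Named list (per expression) of length-5
#'   confidence probabilities over raw categories 1..5.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_condition = c(NVR = 54, PFFV = 59, FV = 50),
                              rate_hz = 60,
                              n_stimuli = 30,
                              inspection_time_median_s = c(NVR = 4.51, PFFV = 10.90, FV = 19.64),
                              inspection_time_sdlog = 0.55,
                              fixation_duration_median_ms = c(NVR = 356, PFFV = 520, FV = 794),
                              fixation_duration_sdlog = 0.18,
                              fixation_jitter_sd_px = 3,
                              saccade_gap_ms = c(20, 80),
                              min_center_sep_px = 120,
                              face_region = c(610, 1310, 90, 990),
                              invalid_rate = 0.02,
                              binocular = TRUE,
                              confusion_templates = default_confusion_templates(),
                              likert_templates = default_likert_templates()) {
  stopifnot(all(names(n_per_condition) %in% CONDITIONS),
            all(n_per_condition >= 1), rate_hz > 0,
            all(inspection_time_median_s > 0),
            all(fixation_duration_median_ms > 0),
            inspection_time_sdlog > 0, fixation_duration_sdlog > 0,
            fixation_jitter_sd_px >= 0, length(saccade_gap_ms) == 2,
            saccade_gap_ms[1] > 0, diff(saccade_gap_ms) >= 0,
            invalid_rate >= 0, invalid_rate < 1)
  for (m in confusion_templates) {
    stopifnot(all(dim(m) == c(5, 5)), all(m >= 0),
              all(abs(rowSums(m) - 1) < 1e-9))
  }
  for (p in likert_templates) {
    stopifnot(length(p) == 5, all(p >= 0), abs(sum(p) - 1) < 1e-9)
  }
  structure(list(n_per_condition = n_per_condition, rate_hz = rate_hz,
                 n_stimuli = n_stimuli,
                 inspection_time_median_s = inspection_time_median_s,
                 inspection_time_sdlog = inspection_time_sdlog,
                 fixation_duration_median_ms = fixation_duration_median_ms,
                 fixation_duration_sdlog = fixation_duration_sdlog,
                 fixation_jitter_sd_px = fixation_jitter_sd_px,
                 saccade_gap_ms = saccade_gap_ms,
                 min_center_sep_px = min_center_sep_px,
                 face_region = face_region, invalid_rate = invalid_rate,
                 binocular = binocular,
                 confusion_templates = confusion_templates,
                 likert_templates = likert_templates),
            class = "simulation_config")
}

#' Balanced stimulus catalog
#'
#' A catalog of synthetic face stimuli balanced over the 5 expressions and
#' 2 face genders: with the default 30 stimuli, 6 per expression, 15 per
#' gender and 3 per gender x expression cell.
#'
#' @param n_stimuli Number of stimuli; must be divisible by 10.
#' @return A tibble with `stimulus_id`, `emotion`, `face_gender`.
#' @export
generate_stimulus_catalog <- function(n_stimuli = 30) {
  if (n_stimuli %% 10 != 0) {
    stop("n_stimuli must be divisible by 10 (5 emotions x 2 genders)",
         call. = FALSE)
  }
  per_cell <- n_stimuli / 10
  grid <- expand.grid(exemplar = seq_len(per_cell), face_gender = FACE_GENDERS,
                      emotion = EMOTIONS, stringsAsFactors = FALSE)
  tibble::tibble(
    stimulus_id = sprintf("syn_%s_%s_%02d", substr(grid$emotion, 1, 3),
                          substr(grid$face_gender, 1, 1), grid$exemplar),
    emotion = grid$emotion,
    face_gender = grid$face_gender)
}

# draw fixation centers with a minimum separation between consecutive ones
draw_centers <- function(n, region, min_sep) {
  cx <- numeric(n)
  cy <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- runif(1, region[1], region[2])
      y <- runif(1, region[3], region[4])
      if (i == 1 ||
          sqrt((x - cx[i - 1])^2 + (y - cy[i - 1])^2) >= min_sep) break
    }
    cx[i] <- x
    cy[i] <- y
  }
  cbind(cx, cy)
}

#' Simulate one participant's session
#'
#' Generates the 30-trial session of one participant under one condition:
#' a randomized stimulus order; per trial an inspection time drawn from the
#' condition's log-normal, a sequence of planted fixations (log-normal
#' durations, saccade gaps without samples, centers separated by at least
#' `min_center_sep_px`) filling that time, 60 Hz samples jittered around
#' each center (two eye rows when `binocular`), a judged emotion drawn from
#' the condition's confusion-template row for the presented expression, and
#' a confidence rating drawn from the expression's Likert template.
#'
#' Draws come from a participant-specific seeded substream, so a session is
#' reproducible independently of the rest of the study.
#'
#' @param config A [simulation_config()].
#' @param participant_id Participant identifier string.
#' @param condition One of `"NVR"`, `"PFFV"`, `"FV"`.
#' @param catalog Stimulus catalog from [generate_stimulus_catalog()].
#' @param seed Integer seed for the participant substream.
#' @return A list with tibbles `gaze` (samples), `records` (one row per
#'   trial), `windows` (trial onset/offset in session time) and `planted`
#'   (ground-truth fixations: center, onset, offset, duration, n_samples).
#' @export
simulate_participant <- function(config, participant_id, condition, catalog,
                                 seed) {
  stopifnot(inherits(config, "simulation_config"),
            condition %in% CONDITIONS)
  set.seed(seed %% .Machine$integer.max)
  dt <- 1000 / config$rate_hz
  order_idx <- sample(nrow(catalog))
  conf <- config$confusion_templates[[condition]]
  t_cursor <- 0
  gaze <- vector("list", nrow(catalog))
  planted <- vector("list", nrow(catalog))
  records <- vector("list", nrow(catalog))
  windows <- vector("list", nrow(catalog))
  for (trial in seq_along(order_idx)) {
    stim <- catalog[order_idx[trial], ]
    target_ms <- rlnorm(1, log(config$inspection_time_median_s[[condition]]),
                        config$inspection_time_sdlog) * 1000
    # plant fixations until the target inspection time is filled
    durs <- gaps <- numeric(0)
    filled <- 0
    while (filled < target_ms) {
      d <- rlnorm(1, log(config$fixation_duration_median_ms[[condition]]),
                  config$fixation_duration_sdlog)
      d <- (max(1, round(d / dt))) * dt  # snap to the sample grid
      g <- runif(1, config$saccade_gap_ms[1], config$saccade_gap_ms[2])
      durs <- c(durs, d)
      gaps <- c(gaps, g)
      filled <- filled + d + g
    }
    n_fix <- length(durs)
    centers <- draw_centers(n_fix, config$face_region, config$min_center_sep_px)
    onset <- t_cursor
    fix_start <- onset + c(0, cumsum(durs + gaps))[seq_len(n_fix)]
    fix_n <- round(durs / dt) + 1
    st <- rep(fix_start, fix_n)
    off <- unlist(lapply(fix_n, function(n) seq_len(n) - 1)) * dt
    t_s <- st + off
    fix_of_sample <- rep(seq_len(n_fix), fix_n)
    n_s <- length(t_s)
    mk_eye <- function(eye) {
      tibble::tibble(
        participant_id = participant_id, condition = condition,
        trial_index = trial, t_ms = t_s,
        x_px = centers[fix_of_sample, 1] + rnorm(n_s, 0, config$fixation_jitter_sd_px),
        y_px = centers[fix_of_sample, 2] + rnorm(n_s, 0, config$fixation_jitter_sd_px),
        validity = runif(n_s) >= config$invalid_rate,
        eye = eye)
    }
    g_trial <- if (config$binocular) {
      dplyr::bind_rows(mk_eye("left"), mk_eye("right")) |>
        dplyr::arrange(.data$t_ms, .data$eye)
    } else {
      mk_eye("merged")
    }
    trial_end <- fix_start[n_fix] + durs[n_fix] + gaps[n_fix]
    gaze[[trial]] <- g_trial
    planted[[trial]] <- tibble::tibble(
      participant_id = participant_id, condition = condition,
      trial_index = trial, fixation_index = seq_len(n_fix),
      center_x_px = centers[, 1], center_y_px = centers[, 2],
      onset_ms = fix_start, duration_ms = durs, n_samples = fix_n)
    response <- sample(EMOTIONS, 1, prob = conf[stim$emotion, ])
    confidence <- sample(1:5, 1, prob = config$likert_templates[[stim$emotion]])
    records[[trial]] <- tibble::tibble(
      participant_id = participant_id, condition = condition,
      trial_index = trial, stimulus_id = stim$stimulus_id,
      emotion_true = stim$emotion, face_gender = stim$face_gender,
      response_emotion = response, confidence_raw = confidence,
      inspection_time_s = (trial_end - onset) / 1000)
    windows[[trial]] <- tibble::tibble(
      participant_id = participant_id, trial_index = trial,
      onset_ms = onset, offset_ms = trial_end)
    # inter-trial interval: fixation point (1 s) + judgment screens (~3 s)
    t_cursor <- trial_end + 4000
  }
  list(gaze = dplyr::bind_rows(gaze), records = dplyr::bind_rows(records),
       windows = dplyr::bind_rows(windows), planted = dplyr::bind_rows(planted))
}

#' Simulate the full three-arm study
#'
#' Runs [simulate_participant()] for every participant of every arm under a
#' single master seed (each participant gets a derived substream seed, so
#' the whole dataset is bit-reproducible).
#'
#' @inheritParams simulate_participant
#' @param seed Master seed (integer).
#' @return A list with the stacked `gaze`, `records`, `windows`, `planted`
#'   tibbles plus the `catalog`, `config` and `seed` used.
#' @export
simulate_study <- function(config = simulation_config(), seed = 1) {
  catalog <- generate_stimulus_catalog(config$n_stimuli)
  out <- list()
  i <- 0
  for (cond in intersect(CONDITIONS, names(config$n_per_condition))) {
    for (p in seq_len(config$n_per_condition[[cond]])) {
      i <- i + 1
      pid <- sprintf("%s_%03d", cond, p)
      sub_seed <- (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
      out[[i]] <- simulate_participant(config, pid, cond, catalog, sub_seed)
    }
  }
  list(gaze = dplyr::bind_rows(lapply(out, `[[`, "gaze")),
       records = dplyr::bind_rows(lapply(out, `[[`, "records")),
       windows = dplyr::bind_rows(lapply(out, `[[`, "windows")),
       planted = dplyr::bind_rows(lapply(out, `[[`, "planted")),
       catalog = catalog, config = config, seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Emits the gaze log and judgment records in the pipeline's delimited
#' formats plus a JSON manifest (seed, configuration hash, row counts).
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory, created if missing.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(sim$gaze, file.path(dir, "gaze_log.csv"))
  write_table(sim$records, file.path(dir, "judgments.csv"))
  write_table(sim$windows, file.path(dir, "trial_windows.csv"))
  write_table(sim$catalog, file.path(dir, "stimulus_catalog.csv"))
  manifest <- list(seed = sim$seed,
                   config_hash = rlang::hash(sim$config),
                   n_gaze_samples = nrow(sim$gaze),
                   n_trials = nrow(sim$records),
                   n_participants = length(unique(sim$records$participant_id)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
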