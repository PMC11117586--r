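#' Read a raw gaze log
#'
#' Delimited text, one sample per row, header required, UTF-8. Expected
#' columns: `participant_id`, `condition`, `trial_index`, `t_ms`, `x_px`,
#' `y_px`, `validity`, `eye`.
#'
#' @param path File path.
#' @param delim Field delimiter, comma by default.
#' @return A tibble of gaze samples ordered by participant, trial and time.
#' @export
read_gaze_log <- function(path, delim = ",") {
  g <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           condition = readr::col_character(),
                           trial_index = readr::col_integer(),
                           t_ms = readr::col_double(),
                           x_px = readr::col_double(),
                           y_px = readr::col_double(),
                           validity = readr::col_logical(),
                           eye = readr::col_character()))
  check_columns(g, c("participant_id", "condition", "trial_index", "t_ms",
                     "x_px", "y_px", "validity", "eye"), "gaze log")
  dplyr::arrange(g, .data$participant_id, .data$trial_index, .data$t_ms)
}

#' Read judgment records
#'
#' Delimited text, one trial per row: `participant_id`, `condition`,
#' `trial_index`, `stimulus_id`, `emotion_true`, `face_gender`,
#' `response_emotion`, `confidence_raw` (integer 1-5), `inspection_time_s`.
#'
#' @inheritParams read_gaze_log
#' @return A tibble of trial records, validated against the categorical
#'   domains (three conditions, five emotions, two face genders).
#' @export
read_judgments <- function(path, delim = ",") {
  r <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           condition = readr::col_character(),
                           trial_index = readr::col_integer(),
                           stimulus_id = readr::col_character(),
                           emotion_true = readr::col_character(),
                           face_gender = readr::col_character(),
                           response_emotion = readr::col_character(),
                           confidence_raw = readr::col_integer(),
                           inspection_time_s = readr::col_double()))
  validate_judgments(r)
}

validate_judgments <- function(r) {
  check_columns(r, c("participant_id", "condition", "trial_index",
                     "emotion_true", "face_gender", "response_emotion",
                     "confidence_raw"), "judgment records")
  bad <- function(col, domain) {
    v <- unique(r[[col]])
    v[!v %in% domain]
  }
  problems <- c(
    if (length(x <- bad("condition", CONDITIONS)))
      sprintf("condition: %s", paste(x, collapse = ", ")),
    if (length(x <- bad("emotion_true", EMOTIONS)))
      sprintf("emotion_true: %s", paste(x, collapse = ", ")),
    if (length(x <- bad("response_emotion", EMOTIONS)))
      sprintf("response_emotion: %s", paste(x, collapse = ", ")),
    if (length(x <- bad("face_gender", FACE_GENDERS)))
      sprintf("face_gender: %s", paste(x, collapse = ", ")),
    if (!all(r$confidence_raw %in% 1:5))
      "confidence_raw outside 1..5")
  if (length(problems) > 0) {
    stop("invalid judgment records - ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  tibble::as_tibble(r)
}

#' Write a table as delimited text
#'
#' Thin wrapper used for every pipeline output (fixation tables, judgment
#' records, report tables).
#'
#' @param x A data frame.
#' @param path Output path; parent directories are created.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, delim = ",") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}

check_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
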