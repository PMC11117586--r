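#' Recognition accuracy
#'
#' Proportion of trials whose judged emotion equals the presented one,
#' per grouping: overall, per participant, per expression, per face gender,
#' or any crossing of record columns. Full precision is kept internally; the
#' `percent` column carries the reporting-style value on the 0-100 scale.
#'
#' @param records A tibble of trial records (see [read_judgments()]).
#' @param by Character vector of grouping columns, e.g.
#'   `c("participant_id", "condition")`; empty for a single overall row.
#' @return A tibble with the grouping columns plus `n_trials`, `n_correct`,
#'   `accuracy` (proportion) and `percent`.
#' @export
accuracy <- function(records, by = character()) {
  if (nrow(records) == 0) {
    stop("accuracy is undefined for an empty set of records", call. = FALSE)
  }
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$response_emotion == .data$emotion_true),
      accuracy = .data$n_correct / .data$n_trials,
      percent = 100 * .data$accuracy,
      .groups = "drop")
}

#' Emotion-judgment confusion matrix
#'
#' Row-normalized counts of judged vs presented expression: rows are the
#' expected ("correct") class, columns the judged class, and each presented
#' row sums to 1. Classes never presented yield `NA` rows.
#'
#' @inheritParams accuracy
#' @return A 5 x 5 numeric matrix with expression dimnames
#'   (`expected` x `judged`).
#' @seealso [confusion_long()] for the tidy long format used in reports.
#' @export
confusion_matrix <- function(records) {
  counts <- table(factor(records$emotion_true, levels = EMOTIONS),
                  factor(records$response_emotion, levels = EMOTIONS))
  m <- unclass(counts / pmax(rowSums(counts), 1))
  m[rowSums(counts) == 0, ] <- NA_real_
  names(dimnames(m)) <- c("expected", "judged")
  m
}

#' Confusion matrices in long format
#'
#' One row per (scope, expected, judged) cell with its proportion, the
#' machine-readable analog of the per-condition confusion-matrix figures;
#' optionally split by face gender.
#'
#' @inheritParams accuracy
#' @param by Scope columns, `"condition"` by default; add `"face_gender"`
#'   for the gender-split matrices.
#' @return A tibble with the scope columns plus `expected`, `judged`,
#'   `proportion`.
#' @export
confusion_long <- function(records, by = "condition") {
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::reframe({
      m <- confusion_matrix(dplyr::pick(dplyr::everything()))
      tibble::tibble(expected = rep(rownames(m), times = ncol(m)),
                     judged = rep(colnames(m), each = nrow(m)),
                     proportion = as.vector(m))
    })
}

#' Per-expression eye-movement and judgment aggregates
#'
#' Joins detected fixations to trial records and aggregates per participant
#' x expression (optionally also by face gender): mean inspection time, the
#' fixation count per presentation (total fixations divided by the number of
#' presentations of that expression), and the fixation duration under one of
#' two conventions:
#'
#' * `mean_per_fixation` (default) - total fixation duration divided by the
#'   number of fixations, the per-fixation average;
#' * `total_per_presentation` - total fixation duration divided by the
#'   number of presentations, the per-trial dwell total.
#'
#' @param fixations Fixation tibble from [detect_fixations()] carrying
#'   `participant_id`, `trial_index`, `duration_ms`.
#' @param records Trial records matching the fixations' keys.
#' @param convention Fixation-duration convention, see above.
#' @param by_gender Also split by `face_gender`.
#' @return A tibble per participant x condition x expression with
#'   `n_presentations`, `mean_inspection_time_s`,
#'   `fixation_count_per_presentation`, `fixation_duration_ms`.
#' @export
expression_aggregates <- function(fixations, records,
                                  convention = c("mean_per_fixation",
                                                 "total_per_presentation"),
                                  by_gender = FALSE) {
  convention <- match.arg(convention)
  keys <- c("participant_id", "trial_index")
  orphan <- dplyr::anti_join(fixations, records, by = keys)
  if (nrow(orphan) > 0) {
    stop(sprintf("%d fixation row(s) have no matching trial record", nrow(orphan)),
         call. = FALSE)
  }
  per_trial <- fixations |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_fix = dplyr::n(),
                     total_dur = sum(.data$duration_ms), .groups = "drop")
  joined <- records |>
    dplyr::left_join(per_trial, by = keys) |>
    dplyr::mutate(n_fix = dplyr::coalesce(.data$n_fix, 0L),
                  total_dur = dplyr::coalesce(.data$total_dur, 0))
  grp <- c("participant_id", "condition", "emotion_true",
           if (by_gender) "face_gender")
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_presentations = dplyr::n(),
      mean_inspection_time_s = mean(.data$inspection_time_s),
      fixation_count_per_presentation = sum(.data$n_fix) / .data$n_presentations,
      fixation_duration_ms = if (convention == "mean_per_fixation") {
        ifelse(sum(.data$n_fix) > 0, sum(.data$total_dur) / sum(.data$n_fix), 0)
      } else {
        sum(.data$total_dur) / .data$n_presentations
      },
      .groups = "drop")
}

#' Confidence consensus report
#'
#' Likert mean, Shannon entropy, Tastle-Wierman consensus and the semantic
#' label of the mean, per scope. The default scope pools all participants'
#' trials within condition x expression, mirroring per-expression confidence
#' reporting; pass `by = c("participant_id", "condition", "emotion_true")`
#' for a per-participant robustness variant.
#'
#' @inheritParams accuracy
#' @param by Scope columns; default condition x expression.
#' @return A tibble with the scope columns plus `n_trials`, `mean_x`,
#'   `entropy_bits`, `consensus`, `label`.
#' @export
consensus_report <- function(records, by = c("condition", "emotion_true")) {
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_x = likert_mean(likert_from_responses(.data$confidence_raw)),
      entropy_bits = likert_entropy(likert_from_responses(.data$confidence_raw)),
      consensus = likert_consensus(likert_from_responses(.data$confidence_raw)),
      .groups = "drop") |>
    dplyr::mutate(label = semantic_label(.data$mean_x))
}
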