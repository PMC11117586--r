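# participant-level aggregates for one grouping (overall, per expression,
# per face gender); `by` adds grouping columns beyond participant x condition
aggregate_metrics <- function(fixations, records, convention, by = character()) {
  keys <- c("participant_id", "trial_index")
  per_trial <- fixations |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_fix = dplyr::n(),
                     total_dur = sum(.data$duration_ms), .groups = "drop")
  records |>
    dplyr::left_join(per_trial, by = keys) |>
    dplyr::mutate(n_fix = dplyr::coalesce(.data$n_fix, 0L),
                  total_dur = dplyr::coalesce(.data$total_dur, 0)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant_id", "condition", by)))) |>
    dplyr::summarise(
      accuracy = 100 * mean(.data$response_emotion == .data$emotion_true),
      inspection_time_s = mean(.data$inspection_time_s),
      fixation_count = sum(.data$n_fix) / dplyr::n(),
      fixation_duration_ms = if (convention == "mean_per_fixation") {
        ifelse(sum(.data$n_fix) > 0, sum(.data$total_dur) / sum(.data$n_fix), 0)
      } else {
        sum(.data$total_dur) / dplyr::n()
      },
      .groups = "drop")
}

MEASURES <- c("accuracy", "inspection_time_s", "fixation_count",
              "fixation_duration_ms")

# long per-participant measure table over the three scopes
participant_measures <- function(fixations, records,
                                 convention = "mean_per_fixation") {
  pivot <- function(df, scope_col, gender_col) {
    df |>
      tidyr::pivot_longer(dplyr::all_of(MEASURES), names_to = "measure",
                          values_to = "value") |>
      dplyr::mutate(scope = scope_col, face_gender = gender_col,
                    .before = "measure")
  }
  dplyr::bind_rows(
    aggregate_metrics(fixations, records, convention) |>
      pivot("overall", "all"),
    aggregate_metrics(fixations, records, convention, "emotion_true") |>
      dplyr::rename(scope = "emotion_true") |>
      tidyr::pivot_longer(dplyr::all_of(MEASURES), names_to = "measure",
                          values_to = "value") |>
      dplyr::mutate(face_gender = "all", .before = "measure"),
    aggregate_metrics(fixations, records, convention, "face_gender") |>
      tidyr::pivot_longer(dplyr::all_of(MEASURES), names_to = "measure",
                          values_to = "value") |>
      dplyr::mutate(scope = "overall", .before = "face_gender"))
}

#' Run the full inferential layer
#'
#' For every measure (accuracy, inspection time, fixation count, fixation
#' duration) and scope (overall, per expression, per face gender), compares
#' the three conditions with a Kruskal-Wallis test (adjusted eta-squared)
#' followed by Dunn's Bonferroni-corrected pairwise post hocs on the
#' per-participant values; within each condition, compares male vs female
#' faces with a paired Wilcoxon signed-rank test (rank-biserial effect
#' size). Scopes missing a condition are skipped with a warning.
#'
#' @param fixations Fixation table from [detect_fixations()].
#' @param records Matching trial records.
#' @param convention Fixation-duration convention, see
#'   [expression_aggregates()].
#' @param alpha Significance level for the post hoc flags.
#' @return A list of class `gazewin_stats`: tibbles `kruskal` (one row per
#'   measure x scope x gender subset), `dunn` (pairwise rows), `wilcoxon`
#'   (male-vs-female rows), and the underlying per-participant `measures`.
#' @export
analyze_all <- function(fixations, records,
                        convention = c("mean_per_fixation",
                                       "total_per_presentation"),
                        alpha = 0.05) {
  convention <- match.arg(convention)
  measures <- participant_measures(fixations, records, convention)
  kw_rows <- list()
  dunn_rows <- list()
  cells <- dplyr::distinct(measures, .data$scope, .data$face_gender,
                           .data$measure)
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- dplyr::semi_join(measures, cell,
                            by = c("scope", "face_gender", "measure"))
    groups <- split(sub$value, factor(sub$condition, levels = CONDITIONS))
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2) {
      warning(sprintf("scope %s/%s/%s has fewer than 2 conditions; skipped",
                      cell$scope, cell$face_gender, cell$measure))
      next
    }
    kw <- kruskal_wallis(groups)
    kw_rows[[i]] <- dplyr::bind_cols(
      cell, tibble::tibble(H = kw$H, df = kw$df, p_value = kw$p_value,
                           eta_sq = kw$eta_sq, n = kw$n))
    dunn_rows[[i]] <- dplyr::bind_cols(
      cell[rep(1, length(groups) * (length(groups) - 1) / 2), ],
      dunn_posthoc(groups, alpha = alpha))
  }
  wil_rows <- list()
  gender_vals <- measures |>
    dplyr::filter(.data$scope == "overall", .data$face_gender != "all")
  for (cond in intersect(CONDITIONS, unique(gender_vals$condition))) {
    for (m in MEASURES) {
      wide <- gender_vals |>
        dplyr::filter(.data$condition == cond, .data$measure == m) |>
        tidyr::pivot_wider(id_cols = "participant_id",
                           names_from = "face_gender",
                           values_from = "value") |>
        tidyr::drop_na(dplyr::any_of(c("male", "female")))
      if (nrow(wide) == 0 || !all(c("male", "female") %in% names(wide))) next
      wt <- wilcoxon_paired(wide$female, wide$male)
      wil_rows[[paste(cond, m)]] <- tibble::tibble(
        condition = cond, measure = m, comparison = "female_vs_male",
        W = wt$W, p_value = wt$p_value, effect_size_rho = wt$effect_size_rho,
        n_pairs = wt$n_pairs, degenerate = wt$degenerate)
    }
  }
  structure(list(kruskal = dplyr::bind_rows(kw_rows),
                 dunn = dplyr::bind_rows(dunn_rows),
                 wilcoxon = dplyr::bind_rows(wil_rows),
                 measures = measures, alpha = alpha,
                 convention = convention),
            class = "gazewin_stats")
}

#' Median (IQR) summary tables
#'
#' Per-condition median and interquartile range of the per-participant
#' values of one measure, in the reporting convention "median (q1-q3)" used
#' for descriptive tables.
#'
#' @param measures Long measure table from [analyze_all()]`$measures`.
#' @param measure One of `"accuracy"`, `"inspection_time_s"`,
#'   `"fixation_count"`, `"fixation_duration_ms"`.
#' @param digits Digits for the formatted column.
#' @return A tibble with one row per scope and one column per condition
#'   (formatted), plus numeric `median`/`q1`/`q3` columns in long form as
#'   attribute `"long"`.
#' @export
summary_table <- function(measures, measure, digits = 2) {
  long <- measures |>
    dplyr::filter(.data$measure == !!measure, .data$face_gender == "all") |>
    dplyr::group_by(.data$scope, .data$condition) |>
    dplyr::summarise(median = median(.data$value),
                     q1 = quantile(.data$value, 0.25, names = FALSE),
                     q3 = quantile(.data$value, 0.75, names = FALSE),
                     .groups = "drop")
  fmt <- function(m, a, b) {
    sprintf("%.*f (%.*f-%.*f)", digits, m, digits, a, digits, b)
  }
  wide <- long |>
    dplyr::mutate(cell = fmt(.data$median, .data$q1, .data$q3)) |>
    tidyr::pivot_wider(id_cols = "scope", names_from = "condition",
                       values_from = "cell") |>
    dplyr::arrange(match(.data$scope, c(EMOTIONS, "overall")))
  attr(wide, "long") <- long
  wide
}

#' Load a run configuration
#'
#' Reads a YAML or JSON run configuration holding the screen-model block,
#' fixation-detection parameters, analysis options and simulation overrides.
#' Every block is optional; omitted values fall back to the package
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `screen` ([screen_model()]),
#'   `fixation_params` ([fixation_params()]), `analysis` (list with
#'   `convention`, `alpha`), `simulation` ([simulation_config()]) and
#'   `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  screen <- if (!is.null(raw$screen)) {
    s <- raw$screen
    if (!is.null(s$diagonal_inches)) {
      screen_model_from_diagonal(s$width_px, s$height_px, s$diagonal_inches,
                                 s$viewing_distance_cm,
                                 aspect = s$aspect %||% c(16, 9))
    } else {
      screen_model(s$width_px, s$height_px, s$physical_width_cm,
                   s$physical_height_cm, s$viewing_distance_cm)
    }
  } else {
    screen_model_from_diagonal(1920, 1080, 23, 57)
  }
  fp <- do.call(fixation_params, raw$fixation_params %||% list())
  analysis <- modifyList(list(convention = "mean_per_fixation", alpha = 0.05),
                         raw$analysis %||% list())
  sim_args <- raw$simulation %||% list()
  # YAML maps/sequences arrive as lists; the config wants named vectors
  for (f in c("n_per_condition", "inspection_time_median_s",
              "fixation_duration_median_ms", "saccade_gap_ms",
              "face_region")) {
    if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
  }
  sim <- do.call(simulation_config, sim_args)
  list(screen = screen, fixation_params = fp, analysis = analysis,
       simulation = sim, seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline stage: simulate
#'
#' Generates a synthetic dataset (optionally writing it to `out_dir`) from a
#' run configuration.
#'
#' @param config Run configuration from [read_run_config()], or `NULL` for
#'   defaults.
#' @param seed Master seed; overrides the configuration's.
#' @param out_dir Optional output directory for [write_dataset()].
#' @return The [simulate_study()] result, invisibly when writing.
#' @export
pipeline_simulate <- function(config = NULL, seed = NULL, out_dir = NULL) {
  sim_cfg <- config$simulation %||% simulation_config()
  sim <- simulate_study(sim_cfg, seed %||% config$seed %||% 1L)
  if (!is.null(out_dir)) {
    write_dataset(sim, out_dir)
    return(invisible(sim))
  }
  sim
}

#' Pipeline stage: fixation detection
#'
#' Merges binocular streams (when an `eye` column distinguishes left/right
#' rows) and detects fixations per trial.
#'
#' @param gaze A gaze log tibble (e.g. from [read_gaze_log()] or
#'   [simulate_study()]`$gaze`).
#' @param params A [fixation_params()].
#' @return A fixation tibble keyed by participant, condition, trial.
#' @export
pipeline_fixations <- function(gaze, params = fixation_params()) {
  detect_fixations(merge_binocular_log(gaze), params)
}

#' Pipeline stage: analyze
#'
#' Computes every report ingredient from a fixation table plus judgment
#' records: the descriptive median (IQR) tables for accuracy, inspection
#' time and the two fixation metrics; per-condition confusion matrices
#' (overall and split by face gender); the confidence consensus report; and
#' the full inferential layer ([analyze_all()]).
#'
#' @inheritParams analyze_all
#' @return A list of class `gazewin_analysis`.
#' @export
pipeline_analyze <- function(fixations, records,
                             convention = c("mean_per_fixation",
                                            "total_per_presentation"),
                             alpha = 0.05) {
  convention <- match.arg(convention)
  records <- validate_judgments(records)
  stats <- analyze_all(fixations, records, convention, alpha)
  structure(list(
    accuracy_table = summary_table(stats$measures, "accuracy", digits = 0),
    inspection_table = summary_table(stats$measures, "inspection_time_s"),
    fixation_count_table = summary_table(stats$measures, "fixation_count"),
    fixation_duration_table = summary_table(stats$measures, "fixation_duration_ms"),
    confusion = confusion_long(records),
    confusion_by_gender = confusion_long(records, c("condition", "face_gender")),
    consensus = consensus_report(records),
    stats = stats), class = "gazewin_analysis")
}

#' Pipeline stage: report
#'
#' Writes the analysis outputs as delimited tables, a JSON statistics
#' report (full precision) and a short human-readable text summary.
#'
#' @param analysis Result of [pipeline_analyze()].
#' @param out_dir Output directory.
#' @return Character vector of the files written, invisibly.
#' @export
pipeline_report <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "gazewin_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_table(analysis$accuracy_table, file.path(out_dir, "accuracy.csv")),
    write_table(analysis$inspection_table, file.path(out_dir, "inspection_time.csv")),
    write_table(analysis$fixation_count_table, file.path(out_dir, "fixation_count.csv")),
    write_table(analysis$fixation_duration_table, file.path(out_dir, "fixation_duration.csv")),
    write_table(analysis$confusion, file.path(out_dir, "confusion.csv")),
    write_table(analysis$confusion_by_gender,
                file.path(out_dir, "confusion_by_gender.csv")),
    write_table(analysis$consensus, file.path(out_dir, "consensus.csv")))
  stats_path <- file.path(out_dir, "statistics.json")
  jsonlite::write_json(list(kruskal = analysis$stats$kruskal,
                            dunn = analysis$stats$dunn,
                            wilcoxon = analysis$stats$wilcoxon,
                            alpha = analysis$stats$alpha,
                            convention = analysis$stats$convention),
                       stats_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt_path <- file.path(out_dir, "summary.txt")
  kw <- analysis$stats$kruskal
  lines <- c("Condition comparison (Kruskal-Wallis on per-participant values)",
             sprintf("  %-22s %-12s H = %8.2f  p = %.4g  eta^2 = %.3f",
                     kw$measure, kw$scope, kw$H, kw$p_value, kw$eta_sq))
  writeLines(lines, txt_path)
  invisible(c(files, stats_path, txt_path))
}
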