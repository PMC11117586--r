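#' Fixation-detection parameters
#'
#' Spatiotemporal thresholds for the dispersion-based detector. The defaults
#' follow common eye-tracking practice for a 60 Hz desktop tracker viewed at
#' arm's length: a 40 px spatial tolerance (operationally one degree of
#' visual angle on the study hardware) and an 80 ms minimum duration.
#'
#' @param tolerance_px Spatial tolerance: maximum distance from a sample to
#'   the cluster reference point (running centroid by default) for the sample
#'   to join the cluster. Default 40 px.
#' @param min_duration_ms Minimum fixation duration (last minus first member
#'   timestamp). Clusters shorter than this are discarded. Default 80 ms.
#' @param max_gap_ms Longest tolerated gap between consecutive valid members
#'   of a cluster; a longer gap (e.g. a blink) closes the cluster.
#'   Default 100 ms.
#' @param secondary_tolerance_px Optional outlier-rejection radius applied
#'   once when a cluster closes: members farther than this from the final
#'   centroid are dropped and the centroid recomputed. `NULL` (default)
#'   disables it; when enabled it must be at least `tolerance_px`.
#' @param membership One of `"centroid"` (distance to the running centroid,
#'   default) or `"first"` (distance to the cluster's first sample).
#'
#' @return An object of class `fixation_params`.
#' @export
fixation_params <- function(tolerance_px = 40, min_duration_ms = 80,
                            max_gap_ms = 100, secondary_tolerance_px = NULL,
                            membership = c("centroid", "first")) {
  membership <- match.arg(membership)
  stopifnot(tolerance_px > 0, min_duration_ms > 0, max_gap_ms > 0)
  if (!is.null(secondary_tolerance_px)) {
    stopifnot(secondary_tolerance_px >= tolerance_px)
  }
  structure(list(tolerance_px = tolerance_px,
                 min_duration_ms = min_duration_ms,
                 max_gap_ms = max_gap_ms,
                 secondary_tolerance_px = secondary_tolerance_px,
                 membership = membership),
            class = "fixation_params")
}

#' Detect fixations by dispersion clustering
#'
#' Sequential spatiotemporal clustering of a time-ordered gaze stream: a
#' valid sample joins the current cluster iff its Euclidean distance to the
#' cluster's running centroid (recomputed after each accepted sample) is at
#' most `tolerance_px` and the time since the last valid member is at most
#' `max_gap_ms`; otherwise the cluster is closed and a new one starts at that
#' sample. Closed clusters lasting at least `min_duration_ms` are emitted as
#' fixations. Invalid samples are skipped. When `secondary_tolerance_px` is
#' set, members farther than it from the final centroid are dropped and the
#' centroid recomputed once.
#'
#' If `samples` carries the trial keys `participant_id`, `condition`,
#' `trial_index`, detection runs independently within each trial and the keys
#' are kept on the output.
#'
#' @param samples A tibble of gaze samples with columns `t_ms`, `x_px`,
#'   `y_px`, and optionally `validity` (logical or 0/1; missing or
#'   non-finite coordinates also mark a sample invalid).
#' @param params A [fixation_params()].
#' @return A tibble of fixations: `onset_ms`, `offset_ms`, `duration_ms`,
#'   `centroid_x_px`, `centroid_y_px`, `n_samples` (plus any trial keys).
#'   Streams with fewer than two valid samples yield zero rows.
#' @export
detect_fixations <- function(samples, params = fixation_params()) {
  stopifnot(inherits(params, "fixation_params"))
  keys <- intersect(c("participant_id", "condition", "trial_index"),
                    names(samples))
  if (length(keys) > 0) {
    return(samples |>
             dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
             dplyr::reframe(detect_fixations_one(dplyr::pick(dplyr::everything()),
                                                 params)))
  }
  detect_fixations_one(samples, params)
}

detect_fixations_one <- function(samples, params) {
  t <- as.numeric(samples$t_ms)
  if (is.unsorted(t, strictly = FALSE)) {
    stop("gaze samples must be time-ordered", call. = FALSE)
  }
  x <- as.numeric(samples$x_px)
  y <- as.numeric(samples$y_px)
  valid <- if ("validity" %in% names(samples)) {
    as.logical(samples$validity)
  } else {
    rep(TRUE, length(t))
  }
  valid <- valid & !is.na(valid) & is.finite(x) & is.finite(y) & is.finite(t)
  t2 <- if (is.null(params$secondary_tolerance_px)) NA_real_ else
    params$secondary_tolerance_px
  out <- .detect_fixations_cpp(t, x, y, valid,
                               params$tolerance_px, params$min_duration_ms,
                               params$max_gap_ms, t2,
                               params$membership == "first")
  tibble::as_tibble(out)
}

#' Segment a raw gaze log into per-trial streams
#'
#' Assigns each sample to the trial window containing its timestamp, using
#' the closed-open convention `[onset_ms, offset_ms)`. Samples outside every
#' window (inter-trial intervals, fixation-point screens, judgment screens)
#' are dropped and counted.
#'
#' @param raw_log A tibble of samples with at least `t_ms`; any other
#'   columns are carried through.
#' @param trial_windows A tibble with `trial_index`, `onset_ms`,
#'   `offset_ms`; windows must be ordered and non-overlapping.
#' @return The retained samples with a `trial_index` column, relative
#'   timestamps untouched. The number of dropped samples is attached as
#'   attribute `dropped_samples` and reported via a message.
#' @export
segment_trials <- function(raw_log, trial_windows) {
  w <- dplyr::arrange(trial_windows, .data$onset_ms)
  if (any(w$offset_ms < w$onset_ms)) {
    stop("trial windows must have offset_ms >= onset_ms", call. = FALSE)
  }
  if (nrow(w) > 1 && any(w$onset_ms[-1] < w$offset_ms[-nrow(w)])) {
    stop("trial windows overlap", call. = FALSE)
  }
  # closed-open: a sample at exactly an onset belongs to that window
  idx <- findInterval(raw_log$t_ms, w$onset_ms)
  inside <- idx >= 1 & raw_log$t_ms < w$offset_ms[pmax(idx, 1)]
  inside[is.na(inside)] <- FALSE
  out <- raw_log[inside, , drop = FALSE]
  out$trial_index <- w$trial_index[idx[inside]]
  dropped <- sum(!inside)
  if (dropped > 0) {
    message(sprintf("segment_trials: dropped %d of %d samples outside all trial windows",
                    dropped, nrow(raw_log)))
  }
  attr(out, "dropped_samples") <- dropped
  tibble::as_tibble(out)
}

#' Merge binocular gaze streams
#'
#' Combines simultaneously-sampled left- and right-eye streams into one
#' cyclopean stream: per timestamp, the mean of the valid eyes' coordinates;
#' a merged sample is invalid only when both eyes are invalid.
#'
#' @param left,right Tibbles with `t_ms`, `x_px`, `y_px`, `validity` sharing
#'   identical timestamps; other columns are taken from `left`.
#' @return A merged tibble with `eye = "merged"`.
#' @export
merge_binocular <- function(left, right) {
  if (nrow(left) != nrow(right) || !isTRUE(all(left$t_ms == right$t_ms))) {
    stop("binocular streams do not share timestamps", call. = FALSE)
  }
  lv <- as.logical(left$validity) & is.finite(left$x_px) & is.finite(left$y_px)
  rv <- as.logical(right$validity) & is.finite(right$x_px) & is.finite(right$y_px)
  lv[is.na(lv)] <- FALSE
  rv[is.na(rv)] <- FALSE
  wsum <- lv + rv
  x <- (ifelse(lv, left$x_px, 0) + ifelse(rv, right$x_px, 0)) / wsum
  y <- (ifelse(lv, left$y_px, 0) + ifelse(rv, right$y_px, 0)) / wsum
  out <- left
  out$x_px <- ifelse(wsum > 0, x, NA_real_)
  out$y_px <- ifelse(wsum > 0, y, NA_real_)
  out$validity <- wsum > 0
  if ("eye" %in% names(out)) out$eye <- "merged"
  tibble::as_tibble(out)
}

# merge a long-format log carrying an `eye` column, per trial
merge_binocular_log <- function(gaze) {
  if (!"eye" %in% names(gaze) || all(gaze$eye == "merged")) return(gaze)
  keys <- intersect(c("participant_id", "condition", "trial_index"),
                    names(gaze))
  gaze |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::reframe({
      s <- dplyr::pick(dplyr::everything())
      merge_binocular(s[s$eye == "left", , drop = FALSE],
                      s[s$eye == "right", , drop = FALSE])
    })
}

#' Visual inspection time of a trial
#'
#' Time from stimulus onset to the participant's keypress ending the
#' presentation, in seconds.
#'
#' @param onset_ms,offset_ms Trial window bounds in milliseconds
#'   (vectorized).
#' @return Inspection time in seconds.
#' @export
inspection_time <- function(onset_ms, offset_ms) {
  if (any(offset_ms < onset_ms)) {
    stop("negative presentation duration", call. = FALSE)
  }
  (offset_ms - onset_ms) / 1000
}
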