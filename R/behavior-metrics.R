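#' Session accuracy from a trial log
#'
#' Proportion of correct responses among first-attempt (non-correction)
#' trials, per subject and session. Correction trials replay the same
#' stimulus until the correct side is chosen, so first attempts carry
#' the unbiased performance signal; corrections are counted separately
#' (see [summarize_sessions()]).
#'
#' @param trials Trial log with columns `subject_id`, `session`,
#'   `is_correction`, `correct` (one row per attempt).
#' @return Tibble with columns `subject_id`, `session`, `accuracy`,
#'   `n_trials`.
#' @export
session_accuracy <- function(trials) {
  first <- dplyr::filter(trials, !.data$is_correction)
  if (nrow(first) == 0) stop("no non-correction trials", call. = FALSE)
  first |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(accuracy = mean(.data$correct),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Count perseverative errors
#'
#' A perseverative error is a repeated incorrect response after
#' negative feedback: within a correction loop (consecutive attempts at
#' the same stimulus), an attempt that presses the same report key as
#' the immediately preceding failed attempt. Counted per subject and
#' session; attempts are ordered by `session`, `trial`, `attempt`.
#'
#' @param trials Trial log with columns `subject_id`, `session`,
#'   `trial`, `attempt`, `is_correction`, `response`.
#' @return Tibble with columns `subject_id`, `session`,
#'   `n_perseverative`.
#' @export
count_perseverative_errors <- function(trials) {
  trials |>
    dplyr::group_by(.data$subject_id, .data$session, .data$trial) |>
    dplyr::arrange(.data$attempt, .by_group = TRUE) |>
    dplyr::mutate(
      persev = .data$is_correction &
        .data$response == dplyr::lag(.data$response)
    ) |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(n_perseverative = sum(.data$persev, na.rm = TRUE),
                     .groups = "drop")
}

#' Two-standard-deviation reaction-time filter
#'
#' Reaction times from incorrect trials are excluded first; then, in a
#' single pass, values deviating from the mean of the retained
#' correct-trial values by more than two standard deviations are
#' removed (mean and SD are computed once, not re-estimated after
#' removal). With fewer than three correct-trial values the input is
#' returned unfiltered with a warning flag; a zero SD (all values
#' equal) removes nothing.
#'
#' @param rts Numeric reaction times (seconds).
#' @param correct Logical correctness flags, same length.
#' @return Numeric vector of retained reaction times, with attribute
#'   `flagged = TRUE` when the minimum-count guard fired.
#' @export
#' @examples
#' filter_rt_outliers(c(rep(1, 19), 10), rep(TRUE, 20))
filter_rt_outliers <- function(rts, correct = rep(TRUE, length(rts))) {
  stopifnot(length(rts) == length(correct))
  x <- rts[correct]
  if (length(x) < 3) {
    out <- x
    attr(out, "flagged") <- TRUE
    return(out)
  }
  m <- mean(x)
  s <- sd(x)
  if (s == 0) return(x)
  x[abs(x - m) <= 2 * s]
}

#' Signed touch separation
#'
#' Touch separation compares each cue-phase touch x-coordinate to the
#' mean of the trial's three touches, signed so that positive values
#' indicate deviation toward the correct side (category A maps to the
#' left report key, B to the right). The third touch is the headline
#' measure: it immediately precedes the choice and carries the
#' anticipatory drift.
#'
#' @param touch_x1,touch_x2,touch_x3 Touch x-coordinates (pixels),
#'   vectorized over trials.
#' @param correct_side `"left"` or `"right"` per trial.
#' @return Tibble with columns `sep1`, `sep2`, `sep3` (pixels); the
#'   three separations of any trial sum to zero by construction.
#' @export
#' @examples
#' touch_separation(100, 110, 120, "right")
touch_separation <- function(touch_x1, touch_x2, touch_x3, correct_side) {
  stopifnot(all(correct_side %in% c("left", "right")))
  m <- (touch_x1 + touch_x2 + touch_x3) / 3
  sgn <- ifelse(correct_side == "right", 1, -1)
  tibble::tibble(
    sep1 = sgn * (touch_x1 - m),
    sep2 = sgn * (touch_x2 - m),
    sep3 = sgn * (touch_x3 - m)
  )
}

#' Per-session dependent measures from a trial log
#'
#' Computes the study's dependent measures for every subject-session:
#' first-attempt accuracy, correction-trial and perseverative-error
#' counts, mean cue- and choice-phase reaction times (incorrect trials
#' excluded, then a single-pass two-SD outlier filter per subject and
#' measure, training and testing filtered separately), and mean
#' third-touch separation over correct first-attempt trials. The
#' result is tidy (one row per subject-session), suitable for
#' downstream mixed-model tooling.
#'
#' @param trials Trial log from [generate_cohort()] or read from disk
#'   with the same columns.
#' @return Tibble with one row per subject-session: `subject_id`,
#'   `group`, `task_class`, `phase`, `session`, `accuracy`,
#'   `n_corrections`, `n_perseverative`, `mean_cue_rt`,
#'   `mean_choice_rt`, `mean_touch_sep3`.
#' @export
summarize_sessions <- function(trials) {
  first <- dplyr::filter(trials, !.data$is_correction)

  acc <- first |>
    dplyr::group_by(.data$subject_id, .data$group, .data$task_class,
                    .data$phase, .data$session) |>
    dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")

  corr <- trials |>
    dplyr::group_by(.data$subject_id, .data$phase, .data$session) |>
    dplyr::summarise(n_corrections = sum(.data$is_correction),
                     .groups = "drop")

  persev <- trials |>
    dplyr::group_by(.data$phase) |>
    dplyr::group_modify(~ count_perseverative_errors(.x)) |>
    dplyr::ungroup()

  # RT filter: per subject, per measure, per phase, across sessions
  rt <- first |>
    dplyr::group_by(.data$subject_id, .data$phase) |>
    dplyr::mutate(
      keep_cue = .rt_keep(.data$cue_rt, .data$correct),
      keep_choice = .rt_keep(.data$choice_rt, .data$correct)
    ) |>
    dplyr::group_by(.data$subject_id, .data$phase, .data$session) |>
    dplyr::summarise(
      mean_cue_rt = mean(.data$cue_rt[.data$keep_cue]),
      mean_choice_rt = mean(.data$choice_rt[.data$keep_choice]),
      .groups = "drop"
    )

  touch <- first |>
    dplyr::filter(.data$correct) |>
    dplyr::mutate(
      correct_side = ifelse(.data$category == "A", "left", "right"),
      sep3 = touch_separation(.data$touch_x1, .data$touch_x2,
                              .data$touch_x3, .data$correct_side)$sep3
    ) |>
    dplyr::group_by(.data$subject_id, .data$phase, .data$session) |>
    dplyr::summarise(mean_touch_sep3 = mean(.data$sep3), .groups = "drop")

  acc |>
    dplyr::left_join(corr, by = c("subject_id", "phase", "session")) |>
    dplyr::left_join(persev, by = c("subject_id", "phase", "session")) |>
    dplyr::left_join(rt, by = c("subject_id", "phase", "session")) |>
    dplyr::left_join(touch, by = c("subject_id", "phase", "session")) |>
    dplyr::mutate(n_perseverative = dplyr::coalesce(.data$n_perseverative, 0L))
}

# logical keep-mask version of the 2-SD filter (incorrect trials dropped)
.rt_keep <- function(rts, correct) {
  keep <- correct
  x <- rts[correct]
  if (length(x) >= 3) {
    m <- mean(x)
    s <- sd(x)
    if (s > 0) keep <- correct & abs(rts - m) <= 2 * s
  }
  keep
}
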