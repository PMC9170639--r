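# Sequence-role classification and trial-level filters.
#
# Role definitions, for a correct trial t with neighbours t-1, t+1:
#   post_correct: t-1 correct
#   pre_error:    t-1 correct and t+1 error (hence also post_correct)
#   post_error:   t-1 error and t+1 correct
#   ambiguous:    t-1 error and t+1 error (single correct trial between two
#                 errors; excluded from every role)
# A neighbour with no response cannot support any role that depends on it.
# Roles are a pure function of the accuracy sequence; filtering later only
# removes RTs from averages, never recomputes adjacency.

#' Classify trials by sequence role
#'
#' Assigns each trial its sequence role(s) — error, post-correct, pre-error,
#' post-error — from the participant's accuracy sequence, excluding single
#' correct trials sandwiched between two errors as ambiguous. Roles that
#' depend on a neighbouring trial are only assigned when that neighbour
#' exists and has a scored response; a no-response neighbour blocks the
#' roles that depend on it.
#'
#' @param trials a validated `pes_trials` tibble (any number of participants).
#' @return A tibble with one row per trial: `participant`, `trial_index`,
#'   logical role columns `is_error`, `post_correct`, `pre_error`,
#'   `post_error`, `ambiguous`, plus `measurement_eligible` (the trial's RT
#'   may enter averages: it is correct, carries at least one role, and has a
#'   known preceding RSI) and `exclusion_reason`
#'   (`"none"`, `"ambiguous_between_errors"`, or `"no_response_context"`;
#'   filter-based reasons are added by [apply_filters()]).
#' @export
#' @examples
#' trials <- pes_trials(
#'   participant = "p1", trial_index = 1:5,
#'   congruency = "congruent",
#'   preceding_rsi = c(NA, rep("short", 4)),
#'   rt_ms = c(400, 410, 395, 500, 430),
#'   accuracy = c("correct", "correct", "error", "correct", "correct")
#' )
#' classify_trials(trials)
classify_trials <- function(trials) {
  trials <- validate_trials(trials)
  unordered <- trials %>%
    group_by(.data$participant) %>%
    summarise(ok = !is.unsorted(.data$trial_index, strictly = TRUE),
              .groups = "drop")
  if (any(!unordered$ok)) {
    abort("Trials must be strictly ordered by trial_index within participant.",
          class = "pesbias_integrity_error")
  }

  trials %>%
    group_by(.data$participant) %>%
    arrange(.data$trial_index, .by_group = TRUE) %>%
    mutate(
      .prev = lag(.data$accuracy),
      .next = lead(.data$accuracy),
      is_error = .data$accuracy == "error",
      ambiguous = .data$accuracy == "correct" &
        !is.na(.data$.prev) & .data$.prev == "error" &
        !is.na(.data$.next) & .data$.next == "error",
      post_correct = .data$accuracy == "correct" &
        !is.na(.data$.prev) & .data$.prev == "correct",
      pre_error = .data$post_correct &
        !is.na(.data$.next) & .data$.next == "error",
      post_error = .data$accuracy == "correct" &
        !is.na(.data$.prev) & .data$.prev == "error" &
        !is.na(.data$.next) & .data$.next == "correct",
      .has_role = .data$post_correct | .data$pre_error | .data$post_error,
      exclusion_reason = case_when(
        ambiguous ~ "ambiguous_between_errors",
        .data$accuracy == "correct" & !.data$.has_role &
          ((!is.na(.data$.prev) & .data$.prev == "no_response") |
             (!is.na(.data$.next) & .data$.next == "no_response")) ~
          "no_response_context",
        TRUE ~ "none"
      ),
      measurement_eligible = .data$.has_role & !.data$ambiguous &
        !is.na(.data$preceding_rsi) & !is.na(.data$rt_ms)
    ) %>%
    ungroup() %>%
    select("participant", "trial_index", "is_error", "post_correct",
           "pre_error", "post_error", "ambiguous", "measurement_eligible",
           "exclusion_reason")
}

#' Filter settings for RT screening
#'
#' Bundles the reaction-time filters applied before averaging: removal of
#' trials immediately following breaks, an absolute RT window, and
#' median-absolute-deviation (MAD) outlier rejection on correct RTs.
#'
#' @param rt_min_ms,rt_max_ms absolute RT window in milliseconds
#'   (defaults 100 and 1500).
#' @param mad_scale consistency scale factor for the MAD (default 1.4826,
#'   the normal-consistency constant).
#' @param mad_threshold flag RTs whose absolute deviation from the cell
#'   median exceeds this multiple of the scaled MAD (default 2.5).
#' @param drop_post_break drop the first trial after each break
#'   (default `TRUE`).
#' @param mad_grouping `"participant_by_condition"` (default; MAD screening
#'   within participant x congruency x preceding-RSI cells, the
#'   within-condition screening recommended for RT data) or `"participant"`.
#' @return A list of class `pes_filter_config`.
#' @export
filter_config <- function(rt_min_ms = 100, rt_max_ms = 1500,
                          mad_scale = 1.4826, mad_threshold = 2.5,
                          drop_post_break = TRUE,
                          mad_grouping = c("participant_by_condition",
                                           "participant")) {
  mad_grouping <- match.arg(mad_grouping)
  stopifnot(rt_min_ms < rt_max_ms, mad_threshold > 0, mad_scale > 0)
  structure(
    list(rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms, mad_scale = mad_scale,
         mad_threshold = mad_threshold, drop_post_break = drop_post_break,
         mad_grouping = mad_grouping),
    class = "pes_filter_config"
  )
}

#' Apply RT filters to classified trials
#'
#' Marks trials whose RTs may not enter averages: post-break trials, RTs
#' outside the absolute window, and MAD outliers. Post-break and RT-window
#' screening are applied first; MAD statistics are then computed per
#' grouping cell over the surviving correct RTs as
#' \eqn{|x - \mathrm{med}| / (s \cdot \mathrm{med}(|x - \mathrm{med}|)) > k}
#' with scale \eqn{s} and threshold \eqn{k}. A cell whose raw MAD is zero
#' flags no trial (degenerate rule; identical RTs are never outliers).
#'
#' Sequence roles are deliberately not recomputed: a filtered trial keeps its
#' accuracy status for its neighbours' role assignment — only its own RT is
#' excluded from averaging.
#'
#' @param trials a validated `pes_trials` tibble.
#' @param labels output of [classify_trials()] for the same trials.
#' @param config a [filter_config()].
#' @return `labels` with `measurement_eligible` switched off (and
#'   `exclusion_reason` set to `"post_break"`, `"rt_out_of_range"` or
#'   `"mad_outlier"`) for filtered trials.
#' @export
apply_filters <- function(trials, labels, config = filter_config()) {
  stopifnot(inherits(config, "pes_filter_config"))
  trials <- validate_trials(trials)
  joined <- labels %>%
    left_join(
      trials %>%
        select("participant", "trial_index", "congruency", "preceding_rsi",
               "rt_ms", "accuracy", "first_after_break"),
      by = c("participant", "trial_index")
    ) %>%
    mutate(
      .post_break = config$drop_post_break & .data$first_after_break,
      .rt_bad = !is.na(.data$rt_ms) &
        (.data$rt_ms < config$rt_min_ms | .data$rt_ms > config$rt_max_ms)
    )

  mad_groups <- if (config$mad_grouping == "participant_by_condition") {
    c("participant", "congruency", "preceding_rsi")
  } else {
    "participant"
  }
  joined <- joined %>%
    mutate(.in_mad_pool = .data$accuracy == "correct" & !is.na(.data$rt_ms) &
             !.data$.rt_bad & !.data$.post_break)
  cell_stats <- joined %>%
    filter(.data$.in_mad_pool) %>%
    group_by(across(all_of(mad_groups))) %>%
    summarise(
      .cell_med = median(.data$rt_ms),
      .cell_mad = median(abs(.data$rt_ms - median(.data$rt_ms))),
      .groups = "drop"
    )
  joined <- joined %>%
    left_join(cell_stats, by = mad_groups) %>%
    mutate(
      .mad_out = .data$.in_mad_pool & !is.na(.data$.cell_mad) &
        .data$.cell_mad > 0 &
        abs(.data$rt_ms - .data$.cell_med) /
          (config$mad_scale * .data$.cell_mad) > config$mad_threshold
    )

  joined %>%
    mutate(
      exclusion_reason = case_when(
        exclusion_reason != "none" ~ exclusion_reason,
        .data$.post_break ~ "post_break",
        .data$.rt_bad ~ "rt_out_of_range",
        .data$.mad_out ~ "mad_outlier",
        TRUE ~ "none"
      ),
      measurement_eligible = .data$measurement_eligible &
        !.data$.post_break & !.data$.rt_bad & !.data$.mad_out
    ) %>%
    select("participant", "trial_index", "is_error", "post_correct",
           "pre_error", "post_error", "ambiguous", "measurement_eligible",
           "exclusion_reason")
}

#' Export classified trials
#'
#' Joins the original trial columns with role flags and exclusion reasons,
#' for writing alongside the raw log.
#'
#' @inheritParams apply_filters
#' @return A tibble with the trial columns plus the label columns.
#' @export
labeled_trials <- function(trials, labels) {
  validate_trials(trials) %>%
    left_join(labels, by = c("participant", "trial_index"))
}
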