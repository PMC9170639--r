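# Trial-level data model: a tidy tibble with one row per trial.

#' Canonical trial-log columns
#'
#' Column order and names used by [read_trial_log()] and [write_trial_log()].
#'
#' @format Character vector of column names.
#' @keywords internal
trial_columns <- function() {
  c("participant", "trial_index", "block_index", "congruency", "distance",
    "preceding_rsi", "rt_ms", "accuracy", "first_after_break")
}

congruency_levels <- function() c("congruent", "incongruent")
accuracy_levels <- function() c("correct", "error", "no_response")
rsi_levels <- function() c("short", "long")

#' Build a validated trial tibble
#'
#' Constructs the tidy trial-log representation used throughout the package:
#' one row per trial, ordered by `trial_index` within participant. Missing
#' optional columns are filled with defaults (`distance = "close"`,
#' `block_index` derived from `first_after_break`, `first_after_break = FALSE`).
#'
#' @param participant participant identifier (coerced to character).
#' @param trial_index 1-based trial position within the session.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param preceding_rsi `"short"` or `"long"`; the response-stimulus interval
#'   that preceded this trial's stimulus. `NA` is allowed only on a
#'   participant's first trial (no preceding interval exists).
#' @param rt_ms reaction time in milliseconds; `NA` iff `accuracy` is
#'   `"no_response"`.
#' @param accuracy `"correct"`, `"error"`, or `"no_response"`.
#' @param distance flanker-target distance, `"close"` (default) or `"far"`.
#' @param block_index 1-based break-delimited block number; derived from
#'   `first_after_break` when omitted.
#' @param first_after_break logical, `TRUE` for the first trial after a
#'   self-paced break.
#'
#' @return A tibble of class `pes_trials` passing [validate_trials()].
#' @export
#' @examples
#' pes_trials(
#'   participant = "p1", trial_index = 1:3,
#'   congruency = c("congruent", "incongruent", "congruent"),
#'   preceding_rsi = c(NA, "short", "long"),
#'   rt_ms = c(430, 510, 455),
#'   accuracy = c("correct", "error", "correct")
#' )
pes_trials <- function(participant, trial_index, congruency, preceding_rsi,
                       rt_ms, accuracy, distance = "close",
                       block_index = NULL, first_after_break = FALSE) {
  trials <- tibble(
    participant = as.character(participant),
    trial_index = as.integer(trial_index),
    congruency = as.character(congruency),
    distance = as.character(distance),
    preceding_rsi = as.character(preceding_rsi),
    rt_ms = as.numeric(rt_ms),
    accuracy = as.character(accuracy),
    first_after_break = as.logical(first_after_break)
  )
  if (is.null(block_index)) {
    trials <- trials %>%
      group_by(.data$participant) %>%
      arrange(.data$trial_index, .by_group = TRUE) %>%
      mutate(block_index = cumsum(.data$first_after_break) + 1L) %>%
      ungroup()
  } else {
    trials$block_index <- as.integer(block_index)
  }
  trials <- trials %>%
    select(all_of(trial_columns())) %>%
    arrange(.data$participant, .data$trial_index)
  validate_trials(trials)
}

#' Validate a trial tibble
#'
#' Checks the structural invariants of the trial-log data model:
#' required columns present; enum columns restricted to their levels;
#' `trial_index` unique and gapless within participant; `rt_ms` missing
#' exactly on `no_response` trials; `preceding_rsi` missing at most on a
#' participant's first trial.
#'
#' @param trials a data frame of trials.
#' @return The validated tibble (invisibly classed `pes_trials`), sorted by
#'   participant and trial order.
#' @export
validate_trials <- function(trials) {
  required <- c("participant", "trial_index", "congruency", "preceding_rsi",
                "rt_ms", "accuracy")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Trial log is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "pesbias_schema_error"
    )
  }
  trials <- as_tibble(trials)
  if (!"distance" %in% names(trials)) trials$distance <- "close"
  if (!"first_after_break" %in% names(trials)) trials$first_after_break <- FALSE
  if (!"block_index" %in% names(trials)) {
    trials <- trials %>%
      group_by(.data$participant) %>%
      arrange(.data$trial_index, .by_group = TRUE) %>%
      mutate(block_index = cumsum(.data$first_after_break) + 1L) %>%
      ungroup()
  }
  trials <- trials %>%
    mutate(
      participant = as.character(.data$participant),
      trial_index = as.integer(.data$trial_index),
      block_index = as.integer(.data$block_index),
      rt_ms = as.numeric(.data$rt_ms),
      first_after_break = as.logical(.data$first_after_break)
    ) %>%
    select(all_of(trial_columns())) %>%
    arrange(.data$participant, .data$trial_index)

  check_enum <- function(x, levels, col, na_ok = FALSE) {
    bad <- !(x %in% levels) & !(na_ok & is.na(x))
    if (any(bad)) {
      abort(
        paste0("Invalid value(s) in column '", col, "': ",
               paste(unique(x[bad]), collapse = ", "),
               " (rows ", paste(head(which(bad), 5L), collapse = ", "), ")"),
        class = "pesbias_validation_error"
      )
    }
  }
  check_enum(trials$congruency, congruency_levels(), "congruency")
  check_enum(trials$accuracy, accuracy_levels(), "accuracy")
  check_enum(trials$preceding_rsi, rsi_levels(), "preceding_rsi", na_ok = TRUE)
  check_enum(trials$distance, c("close", "far"), "distance")

  dup <- trials %>%
    dplyr::count(.data$participant, .data$trial_index) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    abort(
      paste0("Duplicate (participant, trial_index) pairs, e.g. participant ",
             dup$participant[1], " trial ", dup$trial_index[1]),
      class = "pesbias_integrity_error"
    )
  }
  gap <- trials %>%
    group_by(.data$participant) %>%
    summarise(
      gapless = all(.data$trial_index == seq_len(n()) + first(.data$trial_index) - 1L),
      .groups = "drop"
    ) %>%
    filter(!.data$gapless)
  if (nrow(gap) > 0) {
    abort(
      paste0("trial_index not gapless for participant(s): ",
             paste(gap$participant, collapse = ", ")),
      class = "pesbias_integrity_error"
    )
  }

  rt_mismatch <- xor(is.na(trials$rt_ms), trials$accuracy == "no_response")
  if (any(rt_mismatch)) {
    abort(
      paste0("rt_ms must be missing exactly on no_response trials; offending row(s): ",
             paste(head(which(rt_mismatch), 5L), collapse = ", ")),
      class = "pesbias_validation_error"
    )
  }

  rsi_na <- trials %>%
    group_by(.data$participant) %>%
    mutate(.first = row_number() == 1L) %>%
    ungroup() %>%
    filter(is.na(.data$preceding_rsi), !.data$.first)
  if (nrow(rsi_na) > 0) {
    abort(
      paste0("preceding_rsi may be missing only on a participant's first trial; ",
             "offending participant(s): ",
             paste(unique(rsi_na$participant), collapse = ", ")),
      class = "pesbias_validation_error"
    )
  }

  class(trials) <- unique(c("pes_trials", class(trials)))
  trials
}

#' Read a delimited trial log
#'
#' Reads a CSV/TSV trial log (one row per trial) into the validated tidy
#' representation. Column names default to the canonical lowercase
#' snake-case set (see [trial_columns()]); alternate headers can be mapped
#' via `col_map`. A numeric `preceding_rsi` column (milliseconds) is binned
#' into the two RSI classes at `rsi_split_ms`.
#'
#' @param path path to a delimited text file.
#' @param delim field delimiter; `","` (default) or `"\t"`.
#' @param col_map optional named character vector mapping canonical names to
#'   the file's headers, e.g. `c(participant = "subj_id")`.
#' @param rsi_split_ms threshold (ms) used to bin a numeric RSI column:
#'   values `< rsi_split_ms` become `"short"`, others `"long"`. Default 475,
#'   the midpoint of the 250/700 ms design.
#' @return A validated `pes_trials` tibble covering all participants in the
#'   file, sorted by participant and trial order.
#' @export
read_trial_log <- function(path, delim = ",", col_map = NULL,
                           rsi_split_ms = 475) {
  if (!file.exists(path)) {
    abort(paste0("Trial log not found: ", path), class = "pesbias_io_error")
  }
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    na = c("", "NA")
  )
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  if ("preceding_rsi" %in% names(raw) && is.numeric(raw$preceding_rsi)) {
    raw$preceding_rsi <- if_else(raw$preceding_rsi < rsi_split_ms,
                                 "short", "long")
  }
  if ("rt_ms" %in% names(raw) && !is.numeric(raw$rt_ms)) {
    parsed <- suppressWarnings(as.numeric(raw$rt_ms))
    bad <- !is.na(raw$rt_ms) & is.na(parsed)
    if (any(bad)) {
      abort(
        paste0("Non-numeric rt_ms on responded trial(s); row(s): ",
               paste(head(which(bad), 10L), collapse = ", ")),
        class = "pesbias_validation_error"
      )
    }
    raw$rt_ms <- parsed
  }
  validate_trials(raw)
}

#' Write a trial log
#'
#' Writes the tidy trial tibble as delimited text with the canonical column
#' order; the output round-trips losslessly through [read_trial_log()].
#'
#' @param trials a validated `pes_trials` tibble.
#' @param path output file path.
#' @param delim field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path, delim = ",") {
  if (nrow(trials) > 0) trials <- validate_trials(trials)
  out <- as_tibble(trials)[, intersect(trial_columns(), names(trials))]
  readr::write_delim(out, path, delim = delim, na = "NA")
  invisible(path)
}
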