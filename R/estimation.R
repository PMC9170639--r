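# Cell statistics, the four PES estimators, imbalance diagnostics,
# inclusion screening and group aggregation.
#
# The four estimators, per participant and preceding-RSI stratum:
#   traditional, uncorrected: pooled mean(post-error) - pooled mean(post-correct)
#   traditional, corrected:   unweighted congruency means of the same cells
#   robust, uncorrected:      pooled mean(post-error) - pooled mean(pre-error)
#   robust, corrected:        unweighted congruency means of the same cells
# "Pooled" concatenates congruent and incongruent RTs before averaging and is
# therefore a trial-count-weighted mixture; "corrected" averages the two
# congruency-specific central tendencies with equal weight, removing the bias
# introduced by congruency imbalance. Each estimator exists in a mean- and a
# median-based form.

trial_type_levels <- function() c("post_correct", "pre_error", "post_error")

central_fun <- function(central) {
  switch(central,
    mean = function(x) mean(x),
    median = function(x) stats::median(x),
    abort(paste0("Unknown central tendency: ", central),
          class = "pesbias_contract_error")
  )
}

#' Per-cell central tendencies of eligible RTs
#'
#' Computes, for every participant x trial-type x congruency x preceding-RSI
#' cell with at least one measurement-eligible trial, the chosen central
#' tendency of the RTs, alongside pooled (congruency-concatenated) cells used
#' by the uncorrected estimators. A trial that is both post-correct and
#' pre-error contributes to both trial types. Medians of an even number of
#' RTs use the midpoint of the two central order statistics.
#'
#' @param trials a validated `pes_trials` tibble.
#' @param labels labels from [classify_trials()], normally after
#'   [apply_filters()].
#' @param central `"mean"` or `"median"`.
#' @return A tibble with columns `participant`, `trial_type`, `congruency`
#'   (`"congruent"`, `"incongruent"` or `"pooled"`), `rsi`, `central`,
#'   `value_ms`, `n_trials`, and `sd_ms` (`NA` for median cells). Empty cells
#'   are absent, not zero.
#' @export
cell_statistics <- function(trials, labels, central = c("mean", "median")) {
  central <- match.arg(central)
  fun <- central_fun(central)
  eligible <- labeled_trials(trials, labels) %>%
    filter(.data$measurement_eligible)

  one_type <- function(type) {
    sub <- eligible[eligible[[type]], , drop = FALSE]
    if (nrow(sub) == 0) return(tibble())
    by_cong <- sub %>%
      group_by(.data$participant, .data$congruency, rsi = .data$preceding_rsi) %>%
      summarise(
        value_ms = fun(.data$rt_ms),
        n_trials = n(),
        sd_ms = if (central == "mean") sd(.data$rt_ms) else NA_real_,
        .groups = "drop"
      )
    pooled <- sub %>%
      group_by(.data$participant, rsi = .data$preceding_rsi) %>%
      summarise(
        value_ms = fun(.data$rt_ms),
        n_trials = n(),
        sd_ms = if (central == "mean") sd(.data$rt_ms) else NA_real_,
        .groups = "drop"
      ) %>%
      mutate(congruency = "pooled")
    bind_rows(by_cong, pooled) %>%
      mutate(trial_type = type)
  }

  bind_rows(lapply(trial_type_levels(), one_type)) %>%
    mutate(central = central) %>%
    select("participant", "trial_type", "congruency", "rsi", "central",
           "value_ms", "n_trials", "sd_ms") %>%
    arrange(.data$participant, .data$trial_type, .data$rsi, .data$congruency)
}

cell_value <- function(cells, participant, type, congruency, rsi) {
  hit <- cells %>%
    filter(.data$participant == !!participant, .data$trial_type == type,
           .data$congruency == !!congruency, .data$rsi == !!rsi)
  if (nrow(hit) == 0) {
    abort(
      paste0("Required cell missing for participant ", participant, ": ",
             type, " / ", congruency, " / ", rsi, " RSI"),
      class = "pesbias_estimation_error"
    )
  }
  hit$value_ms[[1]]
}

#' One PES estimate
#'
#' Computes a single participant's post-error slowing for one combination of
#' method, correction and RSI stratum from a table of cell statistics.
#' The baseline trial type is post-correct (traditional) or pre-error
#' (robust); the uncorrected variant differences pooled cells, the corrected
#' variant differences unweighted means of the two congruency-specific cells.
#' Baseline and post-error cells always share the same preceding-RSI class.
#'
#' @param cells output of [cell_statistics()].
#' @param method `"traditional"` or `"robust"`.
#' @param correction `"uncorrected"` or `"corrected"`.
#' @param rsi `"short"` or `"long"`.
#' @param participant participant identifier; may be omitted when `cells`
#'   contains a single participant.
#' @return A one-row tibble: `participant`, `method`, `correction`,
#'   `central`, `rsi`, `baseline_ms`, `post_error_ms`,
#'   `pes_ms = post_error_ms - baseline_ms`.
#' @export
pes_estimate <- function(cells, method = c("traditional", "robust"),
                         correction = c("uncorrected", "corrected"),
                         rsi = c("short", "long"), participant = NULL) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  rsi <- match.arg(rsi)
  if (is.null(participant)) {
    ids <- unique(cells$participant)
    if (length(ids) != 1) {
      abort("participant must be given when cells span several participants.",
            class = "pesbias_contract_error")
    }
    participant <- ids
  }
  baseline_type <- if (method == "traditional") "post_correct" else "pre_error"

  value_of <- function(type) {
    if (correction == "uncorrected") {
      cell_value(cells, participant, type, "pooled", rsi)
    } else {
      con <- cell_value(cells, participant, type, "congruent", rsi)
      incon <- cell_value(cells, participant, type, "incongruent", rsi)
      (con + incon) / 2
    }
  }
  baseline_ms <- value_of(baseline_type)
  post_error_ms <- value_of("post_error")
  tibble(
    participant = participant, method = method, correction = correction,
    central = unique(cells$central), rsi = rsi,
    baseline_ms = baseline_ms, post_error_ms = post_error_ms,
    pes_ms = post_error_ms - baseline_ms
  )
}

#' All PES estimates for a dataset
#'
#' Runs [pes_estimate()] for every participant, method, correction, central
#' tendency and RSI stratum for which the required cells exist; combinations
#' with missing cells are silently absent from the result.
#'
#' @inheritParams cell_statistics
#' @param centrals central tendencies to compute (default both).
#' @return A tidy tibble, one row per participant x method x correction x
#'   central x rsi.
#' @export
pes_table <- function(trials, labels, centrals = c("mean", "median")) {
  out <- list()
  for (central in centrals) {
    cells <- cell_statistics(trials, labels, central = central)
    if (nrow(cells) == 0) next
    for (id in unique(cells$participant)) {
      sub <- cells[cells$participant == id, , drop = FALSE]
      for (rsi in intersect(rsi_levels(), unique(sub$rsi))) {
        for (method in c("traditional", "robust")) {
          for (correction in c("uncorrected", "corrected")) {
            est <- tryCatch(
              pes_estimate(sub, method, correction, rsi, participant = id),
              pesbias_estimation_error = function(e) NULL
            )
            if (!is.null(est)) out[[length(out) + 1L]] <- est
          }
        }
      }
    }
  }
  if (length(out) == 0) return(tibble())
  bind_rows(out) %>%
    arrange(.data$participant, .data$central, .data$method, .data$correction,
            .data$rsi)
}

#' Uncorrected-minus-corrected PES bias
#'
#' The signed difference between a participant's uncorrected and corrected
#' PES estimate for the same method, central tendency and RSI stratum. Given
#' a full [pes_table()] as the only argument, computes the bias for every
#' matched pair in it.
#'
#' @param uncorrected either a one-row uncorrected estimate (then
#'   `corrected` is required and must agree on participant, method, central
#'   and rsi) or a full estimate table.
#' @param corrected optional one-row corrected estimate.
#' @return With a pair: a single signed value in ms. With a table: a tibble
#'   `participant`, `method`, `central`, `rsi`, `pes_uncorrected_ms`,
#'   `pes_corrected_ms`, `bias_ms`.
#' @export
pes_bias <- function(uncorrected, corrected = NULL) {
  if (is.null(corrected)) {
    wide <- uncorrected %>%
      select("participant", "method", "correction", "central", "rsi",
             "pes_ms") %>%
      tidyr::pivot_wider(names_from = "correction", values_from = "pes_ms")
    if (!all(c("uncorrected", "corrected") %in% names(wide))) {
      abort("Estimate table must contain both corrections.",
            class = "pesbias_contract_error")
    }
    return(
      wide %>%
        filter(!is.na(.data$uncorrected), !is.na(.data$corrected)) %>%
        mutate(
          pes_uncorrected_ms = .data$uncorrected,
          pes_corrected_ms = .data$corrected,
          bias_ms = .data$uncorrected - .data$corrected
        ) %>%
        select("participant", "method", "central", "rsi",
               "pes_uncorrected_ms", "pes_corrected_ms", "bias_ms")
    )
  }
  keys <- c("participant", "method", "central", "rsi")
  mism <- vapply(keys, function(k) !identical(uncorrected[[k]], corrected[[k]]),
                 logical(1))
  if (uncorrected$correction != "uncorrected" ||
      corrected$correction != "corrected" || any(mism)) {
    abort("pes_bias() requires a matched uncorrected/corrected pair.",
          class = "pesbias_contract_error")
  }
  uncorrected$pes_ms - corrected$pes_ms
}

#' Congruency imbalance per trial type and RSI
#'
#' The percentage of measurement-eligible trials of each trial type that are
#' congruent, stratified by the preceding RSI. Deviations from the designed
#' 50% are the source of the estimation bias the corrected estimators remove.
#'
#' @inheritParams cell_statistics
#' @param by_participant if `TRUE`, one row per participant x trial type x
#'   RSI; otherwise counts are pooled across participants (default).
#' @return A tibble with `trial_type`, `rsi`, `n_congruent`, `n_incongruent`
#'   and `percent_congruent`; strata with no eligible trials are absent.
#' @export
imbalance_summary <- function(trials, labels, by_participant = FALSE) {
  eligible <- labeled_trials(trials, labels) %>%
    filter(.data$measurement_eligible)
  keys <- if (by_participant) c("participant", "rsi") else "rsi"
  one_type <- function(type) {
    sub <- eligible[eligible[[type]], , drop = FALSE]
    if (nrow(sub) == 0) return(tibble())
    sub %>%
      mutate(rsi = .data$preceding_rsi) %>%
      group_by(across(all_of(keys))) %>%
      summarise(
        n_congruent = sum(.data$congruency == "congruent"),
        n_incongruent = sum(.data$congruency == "incongruent"),
        .groups = "drop"
      ) %>%
      mutate(trial_type = type)
  }
  bind_rows(lapply(trial_type_levels(), one_type)) %>%
    mutate(percent_congruent =
             100 * .data$n_congruent /
             (.data$n_congruent + .data$n_incongruent)) %>%
    select(all_of(c(if (by_participant) "participant", "trial_type", "rsi",
                    "n_congruent", "n_incongruent", "percent_congruent")))
}

#' Pre-error imbalance under relaxed adjacency constraints
#'
#' Recomputes the percentage of congruent trials immediately preceding an
#' error while successively dropping the adjacency constraints of the full
#' pre-error definition:
#' \describe{
#'   \item{`full`}{the pre-error trial and the trial before it (error-2)
#'     must both be correct,}
#'   \item{`pre_error_correct_only`}{only the pre-error trial must be
#'     correct,}
#'   \item{`error_minus2_correct_only`}{only the error-2 trial must be
#'     correct,}
#'   \item{`none`}{any trial preceding an error counts.}
#' }
#'
#' @param trials a validated `pes_trials` tibble.
#' @param mode constraint mode (see above); several may be given.
#' @return A tibble with `mode`, `rsi` (the RSI preceding the pre-error
#'   trial), counts and `percent_congruent`. Strata with no qualifying
#'   trials (e.g. an error-free dataset) are absent.
#' @export
constraint_relaxation_imbalance <- function(trials,
                                            mode = c("full",
                                                     "pre_error_correct_only",
                                                     "error_minus2_correct_only",
                                                     "none")) {
  mode <- match.arg(mode, several.ok = TRUE)
  trials <- validate_trials(trials)
  seq_tbl <- trials %>%
    group_by(.data$participant) %>%
    arrange(.data$trial_index, .by_group = TRUE) %>%
    mutate(
      .prev = lag(.data$accuracy),
      .next = lead(.data$accuracy)
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$.next), .data$.next == "error")

  one_mode <- function(m) {
    keep <- switch(m,
      full = seq_tbl$accuracy == "correct" &
        !is.na(seq_tbl$.prev) & seq_tbl$.prev == "correct",
      pre_error_correct_only = seq_tbl$accuracy == "correct",
      error_minus2_correct_only =
        !is.na(seq_tbl$.prev) & seq_tbl$.prev == "correct",
      none = rep(TRUE, nrow(seq_tbl))
    )
    sub <- seq_tbl[keep & !is.na(seq_tbl$preceding_rsi), , drop = FALSE]
    if (nrow(sub) == 0) return(tibble())
    sub %>%
      group_by(rsi = .data$preceding_rsi) %>%
      summarise(
        n_congruent = sum(.data$congruency == "congruent"),
        n_incongruent = sum(.data$congruency == "incongruent"),
        .groups = "drop"
      ) %>%
      mutate(
        mode = m,
        percent_congruent = 100 * .data$n_congruent /
          (.data$n_congruent + .data$n_incongruent)
      )
  }
  out <- bind_rows(lapply(mode, one_mode))
  if (nrow(out) == 0) {
    return(tibble(mode = character(), rsi = character(),
                  n_congruent = integer(), n_incongruent = integer(),
                  percent_congruent = numeric()))
  }
  out %>%
    select(all_of(c("mode", "rsi", "n_congruent", "n_incongruent",
                    "percent_congruent")))
}

#' Participant inclusion screening
#'
#' Applies the task-performance inclusion criteria: at least
#' `min_cell_trials` eligible trials in each of the eight pre-error /
#' post-error x congruency x RSI cells; minimum accuracy on congruent and
#' incongruent trials; and (optionally) a positive correct-trial
#' interference effect and a higher incongruent than congruent error rate.
#' Accuracies and error rates are computed over close trials surviving the
#' post-break and RT-window filters but before MAD outlier rejection (the
#' MAD screen targets correct-RT distributions, not accuracy); cell counts
#' use the fully filtered labels as passed.
#'
#' @inheritParams cell_statistics
#' @param min_cell_trials minimum eligible trials per screened cell
#'   (default 5); the boundary is inclusive.
#' @param min_congruent_accuracy,min_incongruent_accuracy minimum percent
#'   correct (defaults 80 and 60, inclusive).
#' @param require_interference require mean incongruent correct RT to exceed
#'   mean congruent correct RT (default `TRUE`).
#' @param require_error_rate_order require the incongruent error rate to
#'   exceed the congruent one (default `TRUE`).
#' @param config the [filter_config()] whose post-break/RT-window settings
#'   are used for the accuracy computation.
#' @return A tibble, one row per participant: `included`, `reasons`
#'   (comma-separated, empty iff included), cell-count and accuracy columns.
#' @export
screen_participants <- function(trials, labels, min_cell_trials = 5,
                                min_congruent_accuracy = 80,
                                min_incongruent_accuracy = 60,
                                require_interference = TRUE,
                                require_error_rate_order = TRUE,
                                config = filter_config()) {
  trials <- validate_trials(trials)
  close <- trials %>%
    filter(.data$distance == "close",
           !(config$drop_post_break & .data$first_after_break),
           is.na(.data$rt_ms) |
             (.data$rt_ms >= config$rt_min_ms & .data$rt_ms <= config$rt_max_ms))

  acc <- close %>%
    filter(.data$accuracy != "no_response") %>%
    group_by(.data$participant, .data$congruency) %>%
    summarise(
      n = n(),
      accuracy_pct = 100 * mean(.data$accuracy == "correct"),
      error_rate = mean(.data$accuracy == "error"),
      mean_correct_rt = mean(.data$rt_ms[.data$accuracy == "correct"]),
      .groups = "drop"
    )

  eligible <- labeled_trials(trials, labels) %>%
    filter(.data$measurement_eligible, .data$distance == "close")
  counts <- bind_rows(lapply(c("pre_error", "post_error"), function(type) {
    sub <- eligible[eligible[[type]], , drop = FALSE]
    if (nrow(sub) == 0) return(tibble())
    sub %>%
      group_by(.data$participant, .data$congruency,
               rsi = .data$preceding_rsi) %>%
      summarise(n_trials = n(), .groups = "drop") %>%
      mutate(trial_type = type)
  }))

  screen_one <- function(id) {
    reasons <- character(0)
    grid <- tidyr::expand_grid(
      trial_type = c("pre_error", "post_error"),
      congruency = congruency_levels(),
      rsi = rsi_levels()
    )
    cc <- grid %>%
      left_join(counts %>% filter(.data$participant == id),
                by = c("trial_type", "congruency", "rsi")) %>%
      mutate(n_trials = if_else(is.na(.data$n_trials), 0L, .data$n_trials))
    if (any(cc$n_trials < min_cell_trials)) {
      reasons <- c(reasons, "too_few_cell_trials")
    }
    a <- acc %>% filter(.data$participant == id)
    acc_con <- a$accuracy_pct[a$congruency == "congruent"]
    acc_incon <- a$accuracy_pct[a$congruency == "incongruent"]
    if (length(acc_con) == 0 || acc_con < min_congruent_accuracy) {
      reasons <- c(reasons, "low_congruent_accuracy")
    }
    if (length(acc_incon) == 0 || acc_incon < min_incongruent_accuracy) {
      reasons <- c(reasons, "low_incongruent_accuracy")
    }
    rt_con <- a$mean_correct_rt[a$congruency == "congruent"]
    rt_incon <- a$mean_correct_rt[a$congruency == "incongruent"]
    if (require_interference &&
        (length(rt_con) == 0 || length(rt_incon) == 0 ||
         !(rt_incon > rt_con))) {
      reasons <- c(reasons, "no_interference_effect")
    }
    er_con <- a$error_rate[a$congruency == "congruent"]
    er_incon <- a$error_rate[a$congruency == "incongruent"]
    if (require_error_rate_order &&
        (length(er_con) == 0 || length(er_incon) == 0 ||
         !(er_incon > er_con))) {
      reasons <- c(reasons, "inverted_error_rates")
    }
    tibble(
      participant = id,
      included = length(reasons) == 0,
      reasons = paste(reasons, collapse = ","),
      min_screened_cell_n = min(cc$n_trials),
      congruent_accuracy_pct = if (length(acc_con)) acc_con else NA_real_,
      incongruent_accuracy_pct = if (length(acc_incon)) acc_incon else NA_real_
    )
  }
  bind_rows(lapply(unique(trials$participant), screen_one))
}

#' Group-level PES summary
#'
#' Across-participant mean and SD of the individual PES estimates for each
#' method x correction x central x RSI combination.
#'
#' @param estimates a [pes_table()].
#' @return A tibble with `method`, `correction`, `central`, `rsi`,
#'   `n_participants`, `mean_pes_ms`, `sd_pes_ms`.
#' @export
group_summary <- function(estimates) {
  estimates %>%
    group_by(.data$method, .data$correction, .data$central, .data$rsi) %>%
    summarise(
      n_participants = n(),
      mean_pes_ms = mean(.data$pes_ms),
      sd_pes_ms = sd(.data$pes_ms),
      .groups = "drop"
    )
}

#' Group-level bias summary
#'
#' Pairs each participant's uncorrected and corrected estimates within
#' method, central tendency and RSI, and summarises the within-participant
#' bias: mean, SD, the paired effect size \eqn{d_Z = \bar{b} / SD(b)}
#' (reported as `NA` when the SD is zero), and the percent inflation of the
#' uncorrected estimate relative to the mean corrected estimate,
#' \eqn{100\,\bar{b}/\overline{PES}_{corr}}.
#'
#' @param estimates a [pes_table()] containing both corrections.
#' @return A tibble per method x central x rsi with `n_participants`,
#'   `mean_bias_ms`, `sd_bias_ms`, `d_z`, `pct_inflation`.
#' @export
bias_summary <- function(estimates) {
  pes_bias(estimates) %>%
    group_by(.data$method, .data$central, .data$rsi) %>%
    summarise(
      n_participants = n(),
      mean_bias_ms = mean(.data$bias_ms),
      sd_bias_ms = sd(.data$bias_ms),
      mean_corrected_ms = mean(.data$pes_corrected_ms),
      .groups = "drop"
    ) %>%
    mutate(
      d_z = if_else(!is.na(.data$sd_bias_ms) & .data$sd_bias_ms > 0,
                    .data$mean_bias_ms / .data$sd_bias_ms, NA_real_),
      pct_inflation = 100 * .data$mean_bias_ms / .data$mean_corrected_ms
    ) %>%
    select("method", "central", "rsi", "n_participants", "mean_bias_ms",
           "sd_bias_ms", "d_z", "pct_inflation")
}

#' Multilevel bootstrap percentile interval
#'
#' Two-stage nonparametric bootstrap for repeated-measures data: each
#' replicate first resamples participants with replacement, then resamples
#' observations within each sampled participant with replacement, and the
#' statistic is evaluated on the concatenated resampled observations. The
#' interval is the percentile interval of the replicate statistics.
#'
#' @param data a data frame with columns `participant` and `value`, or a
#'   named list of per-participant numeric vectors.
#' @param statistic function of a numeric vector (default [mean()]).
#' @param n_iter number of bootstrap replicates (default 1000).
#' @param level coverage level (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @return A one-row tibble: `estimate` (statistic on the original data),
#'   `lower`, `upper`, `level`, `n_iter`.
#' @export
multilevel_bootstrap_ci <- function(data, statistic = mean, n_iter = 1000,
                                    level = 0.95, seed = NULL) {
  if (is.data.frame(data)) {
    stopifnot(all(c("participant", "value") %in% names(data)))
    groups <- split(data$value, data$participant)
  } else if (is.list(data)) {
    groups <- data
  } else {
    abort("data must be a data frame or a list of numeric vectors.",
          class = "pesbias_contract_error")
  }
  groups <- groups[lengths(groups) > 0]
  if (length(groups) == 0 || n_iter < 1) {
    abort("Need at least one participant with one observation and n_iter >= 1.",
          class = "pesbias_contract_error")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(groups)
  reps <- vapply(seq_len(n_iter), function(i) {
    picked <- sample.int(k, k, replace = TRUE)
    obs <- unlist(lapply(groups[picked], function(v) {
      v[sample.int(length(v), length(v), replace = TRUE)]
    }), use.names = FALSE)
    statistic(obs)
  }, numeric(1))
  alpha <- (1 - level) / 2
  qs <- quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble(
    estimate = statistic(unlist(groups, use.names = FALSE)),
    lower = qs[1], upper = qs[2], level = level, n_iter = n_iter
  )
}

#' Expected post-correct trial counts under random trial order
#'
#' For a session of `n_trials` with a 50/50 congruent/incongruent design and
#' a given split of errors by congruency, the expected number of trials
#' available as post-correct baseline trials and their expected congruency
#' split, assuming post-error trials are on average equally often congruent
#' and incongruent: the total is `n_trials - (errors + post-error trials +
#' first trial)`, and each congruency loses its own errors plus half the
#' post-error trials from its `n_trials / 2` share (the first trial is
#' uncounted in the per-congruency shares).
#'
#' @param n_trials session length.
#' @param n_con_errors,n_incon_errors error counts on congruent and
#'   incongruent trials.
#' @return Named numeric vector `total`, `n_congruent`, `n_incongruent`.
#' @export
#' @examples
#' expected_post_correct_counts(101, 4, 16)
expected_post_correct_counts <- function(n_trials, n_con_errors,
                                         n_incon_errors) {
  n_errors <- n_con_errors + n_incon_errors
  total <- n_trials - (n_errors + n_errors + 1)
  half <- (n_trials - 1) / 2
  n_congruent <- half - (n_con_errors + n_errors / 2)
  n_incongruent <- half - (n_incon_errors + n_errors / 2)
  if (total < 0 || n_congruent < 0 || n_incongruent < 0) {
    abort("Error counts imply negative trial counts.",
          class = "pesbias_contract_error")
  }
  c(total = total, n_congruent = n_congruent, n_incongruent = n_incongruent)
}
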