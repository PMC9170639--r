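# Seeded synthetic flanker-task generator.
#
# Emulates a speeded arrow-flanker session: 1088 trials with a break every
# 200, 50% congruent with counterbalanced congruency transitions, preceding
# RSIs of 250/700 ms balanced within congruency, congruency- and
# RSI-dependent RT distributions, congruency-dependent error rates with
# conflict adaptation (errors are more likely after congruent trials),
# injected post-error slowing, and optional slow drifts in speed and
# accuracy. The congruency imbalances of pre-error, post-correct and
# post-error trials emerge from the error model alone; nothing conditions
# trial composition on sequence roles directly.

#' Simulation configuration
#'
#' Full parameterization of a synthetic flanker session.
#'
#' @param n_trials trials per session (default 1088).
#' @param break_every self-paced break after every this many trials
#'   (default 200); the following trial is flagged `first_after_break`.
#' @param p_congruent probability/proportion of congruent trials
#'   (default 0.5; must be 0.5 when transitions are counterbalanced).
#' @param counterbalance_transitions if `TRUE` (default) the four congruency
#'   transition types occur equally often (within one occurrence) and the
#'   congruent trial count is exactly balanced.
#' @param rt_model tibble with columns `congruency`, `rsi`, `mu_ms`,
#'   `sigma_ms` giving the per-condition RT distribution. Defaults: congruent
#'   400/450 ms mean at short/incongruent short, 360/410 at long (a 50-ms
#'   interference effect, short-RSI trials slower), SD 80 ms throughout.
#' @param rt_family `"normal"` (default) or `"ex_gaussian"`; the ex-Gaussian
#'   adds an exponential component with mean `rt_tau_ms`, giving the
#'   right-skew typical of empirical RTs.
#' @param rt_tau_ms exponential mean for the ex-Gaussian family (ms).
#' @param error_base named probabilities of an error on congruent and
#'   incongruent trials (defaults 0.05 and 0.299).
#' @param adaptation_delta conflict-adaptation contrast: the error
#'   probability is raised by `adaptation_delta / 2` when the previous trial
#'   was congruent and lowered by the same amount when it was incongruent
#'   (default 0.037, reproducing an after-congruent vs. after-incongruent
#'   error-rate gap of about 18.6% vs. 14.9% around the pooled base rate).
#' @param pes_ms additive slowing on any trial following an error; a scalar
#'   or a vector named `congruent`/`incongruent` (default 50).
#' @param rt_adaptation_ms optional congruency-sequence RT effect: RT is
#'   raised by half this amount after congruent and lowered after
#'   incongruent trials (default 0, off).
#' @param no_response_prob probability of a missed response deadline
#'   (default 0).
#' @param drift slow performance drift: `drift_none()` (default),
#'   `drift_linear_fatigue()`, or `drift_caution_phase()`.
#' @param seed integer seed used by [simulate_participant()] and as the
#'   default for [simulate_study()].
#' @return A list of class `pes_sim_config`.
#' @export
simulation_config <- function(n_trials = 1088,
                              break_every = 200,
                              p_congruent = 0.5,
                              counterbalance_transitions = TRUE,
                              rt_model = default_rt_model(),
                              rt_family = c("normal", "ex_gaussian"),
                              rt_tau_ms = 0,
                              error_base = c(congruent = 0.05,
                                             incongruent = 0.299),
                              adaptation_delta = 0.037,
                              pes_ms = 50,
                              rt_adaptation_ms = 0,
                              no_response_prob = 0,
                              drift = drift_none(),
                              seed = 1L) {
  rt_family <- match.arg(rt_family)
  stopifnot(
    n_trials >= 2, break_every >= 1,
    p_congruent >= 0, p_congruent <= 1,
    all(error_base >= 0), all(error_base <= 1),
    adaptation_delta >= 0, adaptation_delta <= 1,
    no_response_prob >= 0, no_response_prob <= 1,
    all(rt_model$sigma_ms > 0), rt_tau_ms >= 0
  )
  stopifnot(all(c("congruent", "incongruent") %in% names(error_base)))
  if (counterbalance_transitions && p_congruent != 0.5) {
    abort("Counterbalanced transitions require p_congruent = 0.5.",
          class = "pesbias_contract_error")
  }
  needed <- tidyr::expand_grid(congruency = congruency_levels(),
                               rsi = rsi_levels())
  have <- dplyr::anti_join(needed, rt_model, by = c("congruency", "rsi"))
  if (nrow(have) > 0) {
    abort("rt_model must cover all congruency x rsi conditions.",
          class = "pesbias_contract_error")
  }
  structure(
    list(n_trials = as.integer(n_trials), break_every = as.integer(break_every),
         p_congruent = p_congruent,
         counterbalance_transitions = counterbalance_transitions,
         rt_model = rt_model, rt_family = rt_family, rt_tau_ms = rt_tau_ms,
         error_base = error_base, adaptation_delta = adaptation_delta,
         pes_ms = pes_ms, rt_adaptation_ms = rt_adaptation_ms,
         no_response_prob = no_response_prob, drift = drift,
         seed = as.integer(seed)),
    class = "pes_sim_config"
  )
}

#' Default per-condition RT distributions
#' @return Tibble with `congruency`, `rsi`, `mu_ms`, `sigma_ms`.
#' @export
default_rt_model <- function() {
  tibble(
    congruency = rep(congruency_levels(), each = 2),
    rsi = rep(rsi_levels(), 2),
    mu_ms = c(400, 360, 450, 410),
    sigma_ms = 80
  )
}

#' Performance-drift specifications
#'
#' `drift_none()` disables drift. `drift_linear_fatigue()` adds
#' `rt_per_trial` ms to the RT mean and `logodds_per_trial` to the
#' error log-odds for every elapsed trial (tiredness: slower and more
#' error-prone late in the session). `drift_caution_phase()` models an
#' initial cautious phase of `phase_length` trials with `rt_delta_ms` added
#' to RT and `logodds_delta` added to the error log-odds (negative =
#' fewer errors), after which performance returns to baseline (speed-
#' accuracy shift: slow and accurate first, fast and sloppy later).
#'
#' @param rt_per_trial,logodds_per_trial linear slopes per elapsed trial.
#' @param phase_length,rt_delta_ms,logodds_delta cautious-phase parameters.
#' @return A list of class `pes_drift`.
#' @export
drift_none <- function() {
  structure(list(type = "none"), class = "pes_drift")
}

#' @rdname drift_none
#' @export
drift_linear_fatigue <- function(rt_per_trial = 0.09,
                                 logodds_per_trial = 8e-4) {
  structure(list(type = "linear_fatigue", rt_per_trial = rt_per_trial,
                 logodds_per_trial = logodds_per_trial),
            class = "pes_drift")
}

#' @rdname drift_none
#' @export
drift_caution_phase <- function(phase_length = 544, rt_delta_ms = 100,
                                logodds_delta = -1.5) {
  structure(list(type = "caution_phase", phase_length = as.integer(phase_length),
                 rt_delta_ms = rt_delta_ms, logodds_delta = logodds_delta),
            class = "pes_drift")
}

drift_terms <- function(drift, n) {
  t0 <- seq_len(n) - 1L
  switch(drift$type,
    none = list(rt = numeric(n), logodds = numeric(n)),
    linear_fatigue = list(rt = drift$rt_per_trial * t0,
                          logodds = drift$logodds_per_trial * t0),
    caution_phase = {
      phase <- as.numeric(seq_len(n) <= drift$phase_length)
      list(rt = drift$rt_delta_ms * phase,
           logodds = drift$logodds_delta * phase)
    },
    abort(paste0("Unknown drift type: ", drift$type),
          class = "pesbias_contract_error")
  )
}

#' Generate a condition sequence
#'
#' Emits the ordered trial conditions for one session: congruency (with
#' counterbalanced transition frequencies when requested, via a seeded
#' run-length construction), the preceding-RSI class balanced within each
#' congruency (the first trial has no preceding interval), and break
#' markers. Uses the current RNG state.
#'
#' @param config a [simulation_config()].
#' @return Tibble `trial_index`, `congruency`, `preceding_rsi`,
#'   `first_after_break`.
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "pes_sim_config"))
  n <- config$n_trials
  congruency <- if (config$counterbalance_transitions) {
    if (n < 8) {
      abort("Counterbalanced transitions need at least 8 trials.",
            class = "pesbias_contract_error")
    }
    counterbalanced_congruency(n, config$p_congruent)
  } else {
    if_else(runif(n) < config$p_congruent, "congruent", "incongruent")
  }

  rsi <- character(n)
  for (cong in congruency_levels()) {
    idx <- which(congruency == cong)
    k <- length(idx)
    n_short <- floor(k / 2) + rbinom(1, 1, 0.5) * (k %% 2)
    lab <- sample(c(rep("short", n_short), rep("long", k - n_short)))
    rsi[idx] <- lab
  }
  rsi[1] <- NA_character_

  trial_index <- seq_len(n)
  tibble(
    trial_index = trial_index,
    congruency = congruency,
    preceding_rsi = rsi,
    first_after_break = trial_index > 1L &
      (trial_index - 1L) %% config$break_every == 0L
  )
}

# Run-length construction of a binary sequence whose four transition counts
# are equal within one occurrence and whose congruent count is as close as
# possible to n * p (exact for the default 50% design with n divisible by 4).
counterbalanced_congruency <- function(n, p_congruent) {
  t_total <- n - 1L
  q <- t_total %/% 4L
  r <- t_total %% 4L
  types <- c("cc", "ci", "ic", "ii")

  extra_sets <- if (r == 0) {
    list(integer(0))
  } else {
    cmb <- utils::combn(4L, r)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  candidates <- list()
  for (extras in extra_sets) {
    m <- setNames(rep(q, 4L), types)
    m[extras] <- m[extras] + 1L
    for (start in c("congruent", "incongruent")) {
      feasible <- if (start == "congruent") {
        m["ci"] == m["ic"] || m["ci"] == m["ic"] + 1L
      } else {
        m["ci"] == m["ic"] || m["ic"] == m["ci"] + 1L
      }
      if (!feasible) next
      c_runs <- m[["ic"]] + (start == "congruent")
      i_runs <- m[["ci"]] + (start == "incongruent")
      if ((m[["cc"]] > 0 && c_runs == 0) || (m[["ii"]] > 0 && i_runs == 0)) next
      n_con <- m[["cc"]] + c_runs
      candidates[[length(candidates) + 1L]] <- list(
        m = m, start = start, c_runs = c_runs, i_runs = i_runs,
        dev = abs(n_con - n * p_congruent)
      )
    }
  }
  devs <- vapply(candidates, function(x) x$dev, numeric(1))
  best <- candidates[devs == min(devs)]
  pick <- best[[sample.int(length(best), 1L)]]

  run_lengths <- function(n_runs, extra) {
    if (n_runs == 0) return(integer(0))
    1L + as.integer(rmultinom(1, extra, rep(1, n_runs)))
  }
  c_len <- run_lengths(pick$c_runs, pick$m[["cc"]])
  i_len <- run_lengths(pick$i_runs, pick$m[["ii"]])
  out <- character(0)
  ci <- 1L; ii <- 1L
  cur <- pick$start
  while (ci <= length(c_len) || ii <= length(i_len)) {
    if (cur == "congruent") {
      out <- c(out, rep("congruent", c_len[ci])); ci <- ci + 1L
      cur <- "incongruent"
    } else {
      out <- c(out, rep("incongruent", i_len[ii])); ii <- ii + 1L
      cur <- "congruent"
    }
  }
  stopifnot(length(out) == n)
  out
}

#' Simulate one participant
#'
#' Draws one full session from the generative model: accuracy per trial from
#' the congruency-specific base error rate, shifted by conflict adaptation
#' (previous-trial congruency) and any drift term on the log-odds; RT from
#' the trial's condition distribution, plus the injected post-error slowing
#' whenever the previous trial was an error, plus any drift term.
#' Deterministic for a fixed seed and config.
#'
#' @param config a [simulation_config()].
#' @param participant participant identifier (default `"sim1"`).
#' @param seed integer seed; defaults to `config$seed`. Pass `NULL` to use
#'   the current RNG state (as [simulate_study()] does).
#' @return A validated `pes_trials` tibble.
#' @export
simulate_participant <- function(config, participant = "sim1",
                                 seed = config$seed) {
  stopifnot(inherits(config, "pes_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  seq_tbl <- generate_sequence(config)
  cong <- seq_tbl$congruency
  rsi <- seq_tbl$preceding_rsi
  drift <- drift_terms(config$drift, n)

  prev_cong <- c(NA_character_, cong[-n])
  p_err <- unname(config$error_base[cong])
  adj <- ifelse(is.na(prev_cong), 0,
                ifelse(prev_cong == "congruent",
                       config$adaptation_delta / 2,
                       -config$adaptation_delta / 2))
  p_err <- pmin(pmax(p_err + adj, 0), 1)
  if (any(drift$logodds != 0)) {
    p_err <- plogis(qlogis(pmin(pmax(p_err, 1e-8), 1 - 1e-8)) + drift$logodds)
  }

  u_nr <- runif(n)
  u_err <- runif(n)
  accuracy <- if_else(u_nr < config$no_response_prob, "no_response",
                      if_else(u_err < p_err, "error", "correct"))

  key <- paste(cong, rsi, sep = ".")
  model_key <- paste(config$rt_model$congruency, config$rt_model$rsi, sep = ".")
  mu <- config$rt_model$mu_ms[match(key, model_key)]
  sigma <- config$rt_model$sigma_ms[match(key, model_key)]
  # first trial: no preceding RSI; draw from the congruency's average condition
  first_na <- is.na(rsi)
  if (any(first_na)) {
    for (i in which(first_na)) {
      rows <- config$rt_model$congruency == cong[i]
      mu[i] <- mean(config$rt_model$mu_ms[rows])
      sigma[i] <- mean(config$rt_model$sigma_ms[rows])
    }
  }

  rt <- rnorm(n, mean = mu, sd = sigma)
  if (config$rt_family == "ex_gaussian" && config$rt_tau_ms > 0) {
    rt <- rt + rexp(n, rate = 1 / config$rt_tau_ms)
  }
  pes <- config$pes_ms
  pes_eff <- if (length(pes) == 1) rep(unname(pes), n) else unname(pes[cong])
  prev_err <- c(FALSE, accuracy[-n] == "error")
  rt <- rt + pes_eff * prev_err
  if (config$rt_adaptation_ms != 0) {
    rt <- rt + ifelse(is.na(prev_cong), 0,
                      ifelse(prev_cong == "congruent", 1, -1)) *
      config$rt_adaptation_ms / 2
  }
  rt <- rt + drift$rt
  rt[accuracy == "no_response"] <- NA_real_

  pes_trials(
    participant = participant,
    trial_index = seq_len(n),
    congruency = cong,
    preceding_rsi = rsi,
    rt_ms = rt,
    accuracy = accuracy,
    first_after_break = seq_tbl$first_after_break
  )
}

#' Simulate a multi-participant study
#'
#' Draws `n_participants` independent sessions from one configuration under
#' a single seeded RNG stream (bit-identical for identical seed and config).
#'
#' @inheritParams simulate_participant
#' @param n_participants number of participants.
#' @param id_prefix prefix for generated participant identifiers.
#' @return A validated `pes_trials` tibble covering all participants.
#' @export
simulate_study <- function(config, n_participants, seed = config$seed,
                           id_prefix = "sim") {
  stopifnot(n_participants >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("%s%03d", id_prefix, seq_len(n_participants))
  bind_rows(lapply(ids, function(id) {
    simulate_participant(config, participant = id, seed = NULL)
  }))
}

#' Named scenario presets
#'
#' Ready-made configurations exercising the estimators:
#' \describe{
#'   \item{`paper_like`}{the default generative model: 1088 trials,
#'     conflict adaptation on, 50-ms injected slowing, no drift.}
#'   \item{`null_pes`}{no injected slowing; corrected robust PES should be
#'     approximately zero.}
#'   \item{`fatigue_confound`}{linear fatigue drift (slower and more
#'     error-prone over the session); inflates traditional uncorrected PES
#'     because post-error trials cluster in the slow late phase, while the
#'     robust corrected estimator resists.}
#'   \item{`caution_confound`}{an initial slow-and-accurate phase followed
#'     by fast-and-sloppy responding; deflates traditional PES because
#'     post-error trials cluster in the fast phase.}
#'   \item{`strong_adaptation`}{conflict-adaptation contrast raised to 0.10,
#'     exaggerating the pre-error congruency imbalance.}
#' }
#'
#' @param seed seed stored in every preset (default 1).
#' @return Named list of [simulation_config()] objects.
#' @export
scenario_presets <- function(seed = 1L) {
  list(
    paper_like = simulation_config(seed = seed),
    null_pes = simulation_config(pes_ms = 0, seed = seed),
    fatigue_confound = simulation_config(drift = drift_linear_fatigue(),
                                         seed = seed),
    caution_confound = simulation_config(drift = drift_caution_phase(),
                                         seed = seed),
    strong_adaptation = simulation_config(adaptation_delta = 0.10, seed = seed)
  )
}
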