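# Shared builders and independent oracles for the test suite.

# Compact trial builder from an accuracy string like "CCECC" (C correct,
# E error, N no response). RTs default to 400 + 10 * index on responded
# trials; congruency alternates unless given.
acc_trials <- function(acc, congruency = NULL, rsi = NULL, rt = NULL,
                       participant = "t1", first_after_break = FALSE) {
  codes <- strsplit(acc, "")[[1]]
  accuracy <- c(C = "correct", E = "error", N = "no_response")[codes]
  n <- length(accuracy)
  if (is.null(congruency)) {
    congruency <- rep(c("congruent", "incongruent"), length.out = n)
  }
  if (is.null(rsi)) rsi <- c(NA, rep("short", n - 1))
  if (is.null(rt)) rt <- 400 + 10 * seq_len(n)
  rt[accuracy == "no_response"] <- NA
  pes_trials(
    participant = participant, trial_index = seq_len(n),
    congruency = congruency, preceding_rsi = rsi, rt_ms = rt,
    accuracy = accuracy, first_after_break = first_after_break
  )
}

# Independent brute-force role enumerator: checks each trial's neighbour
# triple with explicit conditionals, one trial at a time. Deliberately not
# vectorized and shares no code with classify_trials().
oracle_roles <- function(accuracy) {
  n <- length(accuracy)
  out <- data.frame(
    is_error = logical(n), post_correct = logical(n), pre_error = logical(n),
    post_error = logical(n), ambiguous = logical(n)
  )
  for (t in seq_len(n)) {
    a <- accuracy[t]
    prev <- if (t > 1) accuracy[t - 1] else NA
    nxt <- if (t < n) accuracy[t + 1] else NA
    if (a == "error") {
      out$is_error[t] <- TRUE
      next
    }
    if (a != "correct") next
    if (!is.na(prev) && prev == "error" && !is.na(nxt) && nxt == "error") {
      out$ambiguous[t] <- TRUE
      next
    }
    if (!is.na(prev) && prev == "correct") {
      out$post_correct[t] <- TRUE
      if (!is.na(nxt) && nxt == "error") out$pre_error[t] <- TRUE
    }
    if (!is.na(prev) && prev == "error" && !is.na(nxt) && nxt == "correct") {
      out$post_error[t] <- TRUE
    }
  }
  out
}

random_accuracy <- function(n, p_error = 0.25, p_no_response = 0.05) {
  sample(c("C", "E", "N"), n, replace = TRUE,
         prob = c(1 - p_error - p_no_response, p_error, p_no_response))
}

# Small simulated study shared by estimation-level tests (built once per
# test run; deterministic).
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 2024L)
      cache <<- simulate_study(cfg, n_participants = 8)
    }
    cache
  }
})
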