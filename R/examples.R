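# Hypothetical worked-example session used in documentation and checks.

#' Worked-example trial log for the imbalance bias
#'
#' Builds a small synthetic session for one participant who makes 20 errors,
#' so that 20 pre-error and 20 post-error trials exist, with fixed RTs:
#' congruent trials before errors take 1000 ms and incongruent 1200 ms, and
#' the participant slows by exactly 100 ms in each condition after an error
#' (post-error congruent 1100 ms, incongruent 1300 ms). In the `"balanced"`
#' variant both trial types are 10 congruent / 10 incongruent and pooled
#' averaging recovers the true 100-ms slowing. In the `"imbalanced"` variant
#' the pre-error trials are 15 congruent / 5 incongruent while the
#' post-error trials stay balanced: pooled (uncorrected) averaging then
#' overestimates robust PES (150 ms mean-based, 200 ms median-based), while
#' the corrected, unweighted estimator still returns 100 ms.
#'
#' Every error is embedded as correct, pre-error, error, post-error, with
#' correct filler trials (500 ms) bounding the session; all trials share the
#' short preceding-RSI class.
#'
#' @param variant `"balanced"` or `"imbalanced"`.
#' @param participant participant identifier.
#' @return A validated `pes_trials` tibble.
#' @export
#' @examples
#' trials <- worked_example_trials("imbalanced")
#' labels <- classify_trials(trials)
#' cells <- cell_statistics(trials, labels, central = "mean")
#' pes_estimate(cells, method = "robust", correction = "uncorrected",
#'              rsi = "short")$pes_ms  # 150
#' pes_estimate(cells, method = "robust", correction = "corrected",
#'              rsi = "short")$pes_ms  # 100
worked_example_trials <- function(variant = c("balanced", "imbalanced"),
                                  participant = "example") {
  variant <- match.arg(variant)
  n_pre_con <- if (variant == "balanced") 10L else 15L
  n_pre_incon <- 20L - n_pre_con

  pre_cong <- c(rep("congruent", n_pre_con), rep("incongruent", n_pre_incon))
  pre_cong <- pre_cong[order(rep_len(seq_len(5), 20))]  # interleave
  post_cong <- rep(c("congruent", "incongruent"), 10)

  cong <- character(0); rt <- numeric(0); acc <- character(0)
  add <- function(congruency, rt_ms, accuracy) {
    cong <<- c(cong, congruency); rt <<- c(rt, rt_ms); acc <<- c(acc, accuracy)
  }
  add("congruent", 500, "correct")  # leading filler
  for (i in seq_len(20)) {
    add(pre_cong[i], if (pre_cong[i] == "congruent") 1000 else 1200, "correct")
    add(if (i %% 2 == 0) "congruent" else "incongruent", 600, "error")
    add(post_cong[i], if (post_cong[i] == "congruent") 1100 else 1300, "correct")
  }
  add("congruent", 500, "correct")  # trailing filler closes the last triple

  n <- length(cong)
  pes_trials(
    participant = participant,
    trial_index = seq_len(n),
    congruency = cong,
    preceding_rsi = c(NA, rep("short", n - 1L)),
    rt_ms = rt,
    accuracy = acc
  )
}
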