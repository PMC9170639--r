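worked_cells <- function(variant, central) {
  trials <- worked_example_trials(variant)
  cell_statistics(trials, classify_trials(trials), central = central)
}

test_that("cell statistics reproduce the worked-example means and medians", {
  cells <- worked_cells("imbalanced", "mean")
  pre_pooled <- cells[cells$trial_type == "pre_error" &
                        cells$congruency == "pooled", ]
  expect_equal(pre_pooled$value_ms, 1050)
  expect_equal(pre_pooled$n_trials, 20L)

  cmed <- worked_cells("imbalanced", "median")
  pre_med <- cmed[cmed$trial_type == "pre_error" & cmed$congruency == "pooled", ]
  expect_equal(pre_med$value_ms, 1000)
  post_med <- cmed[cmed$trial_type == "post_error" & cmed$congruency == "pooled", ]
  expect_equal(post_med$value_ms, 1200)  # even count: midpoint rule

  const <- acc_trials("CCCCCCCCCCCE", rt = c(410, rep(1000, 10), 600),
                      congruency = "congruent")
  cc <- cell_statistics(const, classify_trials(const), "mean")
  pre <- cc[cc$trial_type == "pre_error" & cc$congruency == "congruent", ]
  expect_equal(pre$value_ms, 1000)
  expect_equal(pre$n_trials, 1L)
})

test_that("the four estimators reproduce the balanced and imbalanced examples", {
  bal <- worked_cells("balanced", "mean")
  imb <- worked_cells("imbalanced", "mean")
  expect_equal(pes_estimate(bal, "robust", "uncorrected", "short")$pes_ms, 100)
  expect_equal(pes_estimate(bal, "robust", "corrected", "short")$pes_ms, 100)
  expect_equal(pes_estimate(imb, "robust", "uncorrected", "short")$pes_ms, 150)
  expect_equal(pes_estimate(imb, "robust", "corrected", "short")$pes_ms, 100)

  est <- pes_estimate(imb, "robust", "corrected", "short")
  expect_equal(est$pes_ms, est$post_error_ms - est$baseline_ms)

  # identical baseline and post-error cells give exactly zero
  same <- bal
  same$value_ms[same$trial_type == "post_error"] <-
    same$value_ms[same$trial_type == "pre_error"]
  expect_equal(pes_estimate(same, "robust", "uncorrected", "short")$pes_ms, 0)

  # missing cells are a named estimation error
  expect_error(pes_estimate(imb, "robust", "uncorrected", "long"),
               class = "pesbias_estimation_error")
})

test_that("median-based uncorrected robust PES shows the stronger bias", {
  cmed <- worked_cells("imbalanced", "median")
  expect_equal(pes_estimate(cmed, "robust", "uncorrected", "short")$pes_ms, 200)
  expect_equal(pes_estimate(cmed, "robust", "corrected", "short")$pes_ms, 100)
})

test_that("pes_bias differences matched pairs and rejects mismatches", {
  imb <- worked_cells("imbalanced", "mean")
  unc <- pes_estimate(imb, "robust", "uncorrected", "short")
  cor <- pes_estimate(imb, "robust", "corrected", "short")
  expect_equal(pes_bias(unc, cor), 50)

  bal <- worked_cells("balanced", "mean")
  expect_equal(pes_bias(pes_estimate(bal, "robust", "uncorrected", "short"),
                        pes_estimate(bal, "robust", "corrected", "short")), 0)

  cmed <- worked_cells("imbalanced", "median")
  expect_equal(pes_bias(pes_estimate(cmed, "robust", "uncorrected", "short"),
                        pes_estimate(cmed, "robust", "corrected", "short")), 100)

  other <- pes_estimate(imb, "traditional", "corrected", "short")
  expect_error(pes_bias(unc, other), class = "pesbias_contract_error")
})

test_that("pooled-minus-unweighted equals the imbalance identity", {
  # pooled(cell) - unweighted(cell) = (p_con - 0.5) * (mean_con - mean_incon)
  set.seed(31)
  trials <- sim_small()
  labels <- apply_filters(trials, classify_trials(trials), filter_config())
  cells <- cell_statistics(trials, labels, "mean")
  wide <- tidyr::pivot_wider(
    cells[, c("participant", "trial_type", "congruency", "rsi", "value_ms",
              "n_trials")],
    names_from = "congruency", values_from = c("value_ms", "n_trials"))
  wide <- wide[stats::complete.cases(wide), ]
  expect_gt(nrow(wide), 20)
  p_con <- wide$n_trials_congruent /
    (wide$n_trials_congruent + wide$n_trials_incongruent)
  lhs <- wide$value_ms_pooled -
    (wide$value_ms_congruent + wide$value_ms_incongruent) / 2
  rhs <- (p_con - 0.5) * (wide$value_ms_congruent - wide$value_ms_incongruent)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("corrected PES ignores congruency composition at fixed cell values", {
  bal <- worked_cells("balanced", "mean")
  imb <- worked_cells("imbalanced", "mean")  # same condition RTs, new weights
  expect_equal(pes_estimate(bal, "robust", "corrected", "short")$pes_ms,
               pes_estimate(imb, "robust", "corrected", "short")$pes_ms)
  expect_false(isTRUE(all.equal(
    pes_estimate(bal, "robust", "uncorrected", "short")$pes_ms,
    pes_estimate(imb, "robust", "uncorrected", "short")$pes_ms)))
})

test_that("per-participant mean bias equals the analytic cell-wise prediction", {
  trials <- sim_small()
  labels <- apply_filters(trials, classify_trials(trials), filter_config())
  cells <- cell_statistics(trials, labels, "mean")
  tab <- pes_table(trials, labels, centrals = "mean")
  biases <- pes_bias(tab)
  biases <- biases[biases$method == "robust", ]
  expect_gt(nrow(biases), 4)
  for (i in seq_len(nrow(biases))) {
    cellbias <- function(type) {
      sub <- cells[cells$participant == biases$participant[i] &
                     cells$trial_type == type & cells$rsi == biases$rsi[i], ]
      con <- sub[sub$congruency == "congruent", ]
      incon <- sub[sub$congruency == "incongruent", ]
      p <- con$n_trials / (con$n_trials + incon$n_trials)
      mean_bias(incon$value_ms - con$value_ms, p)
    }
    expect_equal(biases$bias_ms[i], cellbias("post_error") - cellbias("pre_error"),
                 tolerance = 1e-10)
  }
})

test_that("imbalance summaries count congruent proportions per stratum", {
  trials <- worked_example_trials("imbalanced")
  labels <- classify_trials(trials)
  imb <- imbalance_summary(trials, labels)
  pre <- imb[imb$trial_type == "pre_error" & imb$rsi == "short", ]
  expect_equal(pre$n_congruent, 15)
  expect_equal(pre$n_incongruent, 5)
  expect_equal(pre$percent_congruent, 75)
  post <- imb[imb$trial_type == "post_error" & imb$rsi == "short", ]
  expect_equal(post$percent_congruent, 50)
})

test_that("constraint relaxation reproduces hand enumeration", {
  # 12 trials covering all four modes; all short RSI after the first.
  #  idx: 1  2  3  4  5  6  7  8  9 10 11 12
  #  acc: C  C  E  E  C  E  C  C  E  N  E  C
  # cong: c  i  c  i  c  c  i  c  i  c  i  c
  trials <- acc_trials("CCEECECCENEC",
                       congruency = c("congruent", "incongruent", "congruent",
                                      "incongruent", "congruent", "congruent",
                                      "incongruent", "congruent", "incongruent",
                                      "congruent", "incongruent", "congruent"))
  # trials preceding an error: 2(C,i), 3(E,c), 5(C,c), 8(C,c), 10(N,c)
  rel <- constraint_relaxation_imbalance(trials, "none")
  expect_equal(rel$n_congruent + rel$n_incongruent, 5)
  expect_equal(rel$percent_congruent, 100 * 4 / 5)
  # pre-error trial correct: 2, 5, 8 -> 2 congruent of 3
  rel <- constraint_relaxation_imbalance(trials, "pre_error_correct_only")
  expect_equal(rel$percent_congruent, 100 * 2 / 3)
  # error-2 trial correct: t-1 of {2,3,5,8,10} correct -> 2 (t1 C), 3 (t2 C),
  # 5 (t4 E -> no), 8 (t7 C), 10 (t9 E -> no) -> trials 2,3,8: 2 congruent of 3
  rel <- constraint_relaxation_imbalance(trials, "error_minus2_correct_only")
  expect_equal(rel$percent_congruent, 100 * 2 / 3)
  # both correct: trials 2, 8 -> 1 congruent of 2
  rel <- constraint_relaxation_imbalance(trials, "full")
  expect_equal(rel$percent_congruent, 50)
  # an error-free dataset has no pre-error strata
  expect_equal(nrow(constraint_relaxation_imbalance(acc_trials("CCCC"), "none")),
               0)
  # mode none on [C, E] with congruent first trial: 100% congruent
  ce <- acc_trials("CE", congruency = c("congruent", "incongruent"),
                   rsi = c("short", "short"))
  expect_equal(constraint_relaxation_imbalance(ce, "none")$percent_congruent, 100)
})

test_that("screening applies the inclusion criteria with inclusive boundaries", {
  build <- function(n_pre_con_short) {
    # blocks of F P E Q with controlled congruency/rsi of P cells
    cong <- character(0); rsi <- character(0); acc <- character(0); rt <- numeric(0)
    add <- function(cg, rs, ac, r) {
      cong <<- c(cong, cg); rsi <<- c(rsi, rs); acc <<- c(acc, ac); rt <<- c(rt, r)
    }
    add("congruent", "short", "correct", 450)
    combos <- expand.grid(cg = c("congruent", "incongruent"),
                          rs = c("short", "long"), rep = 1:5,
                          stringsAsFactors = FALSE)
    # drop pre-error congruent/short cells beyond the requested count
    keep <- !(combos$cg == "congruent" & combos$rs == "short" &
                combos$rep > n_pre_con_short)
    combos <- combos[keep, ]
    for (i in seq_len(nrow(combos))) {
      add(combos$cg[i], combos$rs[i], "correct",
          if (combos$cg[i] == "congruent") 400 else 460)       # pre-error
      add("incongruent", "short", "error", 350)                # error
      add(combos$cg[i], combos$rs[i], "correct",
          if (combos$cg[i] == "congruent") 430 else 480)       # post-error
      add("incongruent", "long", "correct", 480)               # filler
    }
    pes_trials(participant = "s", trial_index = seq_along(cong),
               congruency = cong, preceding_rsi = c(NA, rsi[-1]), rt_ms = rt,
               accuracy = acc)
  }
  ok <- build(5)
  lab <- apply_filters(ok, classify_trials(ok), filter_config())
  rep_ok <- screen_participants(ok, lab, require_interference = TRUE)
  expect_true(rep_ok$included)  # exactly 5 per cell is enough

  few <- build(4)
  labf <- apply_filters(few, classify_trials(few), filter_config())
  rep_few <- screen_participants(few, labf)
  expect_false(rep_few$included)
  expect_match(rep_few$reasons, "too_few_cell_trials")
})

test_that("accuracy thresholds are inclusive and reported per congruency", {
  mk <- function(n_con_err) {
    rows <- data.frame(
      congruency = c(rep("congruent", 100), rep("incongruent", 100)),
      accuracy = c(rep("correct", 100 - n_con_err), rep("error", n_con_err),
                   rep("correct", 70), rep("error", 30))
    )
    rows <- rows[sample(nrow(rows)), ]
    pes_trials(participant = "s", trial_index = 1:200,
               congruency = rows$congruency,
               preceding_rsi = c(NA, rep(c("short", "long"), length.out = 199)),
               rt_ms = ifelse(rows$congruency == "congruent", 400, 480),
               accuracy = rows$accuracy)
  }
  set.seed(5)
  t80 <- mk(20)  # exactly 80% congruent accuracy
  l80 <- apply_filters(t80, classify_trials(t80), filter_config())
  r80 <- screen_participants(t80, l80, min_cell_trials = 0)
  expect_false(grepl("low_congruent_accuracy", r80$reasons))

  t79 <- mk(21)
  l79 <- apply_filters(t79, classify_trials(t79), filter_config())
  r79 <- screen_participants(t79, l79, min_cell_trials = 0)
  expect_match(r79$reasons, "low_congruent_accuracy")
})

test_that("group summaries aggregate PES and bias with d_z conventions", {
  tab <- tibble::tibble(
    participant = rep(c("a", "b"), each = 2),
    method = "robust", central = "mean", rsi = "short",
    correction = rep(c("uncorrected", "corrected"), 2),
    baseline_ms = 0, post_error_ms = 0,
    pes_ms = c(60, 50, 30, 40)
  )
  g <- group_summary(tab)
  expect_equal(nrow(g), 2)
  expect_equal(g$mean_pes_ms[g$correction == "corrected"], 45)

  b <- bias_summary(tab)  # biases +10 and -10
  expect_equal(b$mean_bias_ms, 0)
  expect_equal(b$d_z, 0)

  tab3 <- tibble::tibble(
    participant = rep(c("a", "b", "c"), each = 2),
    method = "robust", central = "mean", rsi = "short",
    correction = rep(c("uncorrected", "corrected"), 3),
    baseline_ms = 0, post_error_ms = 0,
    pes_ms = c(45, 40, 55, 50, 35, 30)
  )
  b3 <- bias_summary(tab3)  # biases all exactly +5: zero SD
  expect_equal(b3$mean_bias_ms, 5)
  expect_true(is.na(b3$d_z))
  expect_equal(b3$pct_inflation, 100 * 5 / 40)
})

test_that("group mean recovers a known bias distribution", {
  set.seed(404)
  n <- 100
  bias <- rnorm(n, mean = 16, sd = 23)
  tab <- tibble::tibble(
    participant = rep(sprintf("p%03d", 1:n), each = 2),
    method = "robust", central = "mean", rsi = "long",
    correction = rep(c("uncorrected", "corrected"), n),
    baseline_ms = 0, post_error_ms = 0,
    pes_ms = as.vector(rbind(40 + bias, 40))
  )
  b <- bias_summary(tab)
  se <- 23 / sqrt(n)
  expect_lt(abs(b$mean_bias_ms - 16), 3 * se)
  expect_equal(b$mean_bias_ms, mean(bias))
})

test_that("expected post-correct counts follow the counting identity", {
  expect_equal(expected_post_correct_counts(101, 4, 16),
               c(total = 60, n_congruent = 36, n_incongruent = 24))
  expect_equal(expected_post_correct_counts(101, 10, 10),
               c(total = 60, n_congruent = 30, n_incongruent = 30))
  # hand arithmetic: 41 trials, 10 errors -> total 20; shares 20 each;
  # congruent 20 - (2 + 5) = 13, incongruent 20 - (8 + 5) = 7
  expect_equal(expected_post_correct_counts(41, 2, 8),
               c(total = 20, n_congruent = 13, n_incongruent = 7))
  expect_error(expected_post_correct_counts(10, 5, 5),
               class = "pesbias_contract_error")
})
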