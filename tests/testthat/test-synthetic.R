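test_that("trace generator: degenerate parameters give a constant trace", {
  p <- trace_gen_params(variability_amplitude_bpm = 0, accel_rate_per_h = 0,
                        decel_rate_per_h = 0, duration_s = 3000)
  tr <- generate_clean_trace(p, seed = 1)
  expect_equal(tr$fhr, rep(140, 3000 * 4))
  expect_equal(nrow(attr(tr, "events")), 0)
})

test_that("trace generator bookkeeping: event counts are exact", {
  # 6/h over 30 min -> exactly 3 accelerations
  p <- trace_gen_params(accel_rate_per_h = 6, duration_s = 3000,
                        variability_amplitude_bpm = 4)
  tr <- generate_clean_trace(p, seed = 2)
  ev <- attr(tr, "events")
  expect_equal(sum(ev$kind == "acceleration"), 5)  # 6/h * 3000 s = 5
  p2 <- trace_gen_params(accel_rate_per_h = 3.6, duration_s = 3000)
  ev2 <- attr(generate_clean_trace(p2, seed = 2), "events")
  expect_equal(nrow(ev2), 3)                        # 3.6/h * (5/6) h = 3
  # independent count: threshold runs in the noiseless signal
  p3 <- trace_gen_params(accel_rate_per_h = 4, variability_amplitude_bpm = 0)
  tr3 <- generate_clean_trace(p3, seed = 3)
  runs <- true_runs_df(tr3$fhr >= 140 + 15)
  expect_equal(nrow(runs), 4)
})

test_that("same seed reproduces the identical trace and cohort", {
  p <- trace_gen_params(decel_rate_per_h = 3)
  a <- generate_clean_trace(p, seed = 9)
  b <- generate_clean_trace(p, seed = 9)
  expect_identical(a$fhr, b$fhr)
  expect_identical(attr(a, "events"), attr(b, "events"))
  c1 <- generate_study_cohort(n = 60, n_pos = 8, seed = 5)
  c2 <- generate_study_cohort(n = 60, n_pos = 8, seed = 5)
  expect_identical(c1$cases, c2$cases)
  expect_identical(c1$ratings, c2$ratings)
})

test_that("corruption: zero rates are the identity; lengths follow the spec", {
  tr <- generate_clean_trace(trace_gen_params(), seed = 4)
  same <- corrupt_trace(tr, artifact_params(dropout_rate_per_h = 0,
                                            spike_rate_per_h = 0), seed = 1)
  expect_identical(same$fhr, tr$fhr)
  expect_equal(nrow(attr(same, "artifact_ledger")), 0)

  # one 8 s dropout -> 32 consecutive zeros
  ap <- artifact_params(dropout_rate_per_h = 1, dropout_len_s = c(8, 8),
                        spike_rate_per_h = 0)
  bad <- corrupt_trace(tr, ap, seed = 2)
  runs <- true_runs_df(bad$fhr == 0)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$end - runs$start + 1L, 32L)

  # long_dropout_prob = 1 -> at least one >= 60-sample zero run
  ap2 <- artifact_params(dropout_rate_per_h = 2, long_dropout_prob = 1,
                         spike_rate_per_h = 0)
  bad2 <- corrupt_trace(tr, ap2, seed = 3)
  runs2 <- true_runs_df(bad2$fhr == 0)
  expect_true(any(runs2$end - runs2$start + 1L >= 60L))
})

test_that("outcome sampling follows the logistic model at its limits", {
  feats <- data.frame(late_decel_count = rpois(200, 1),
                      variability_deficit = runif(200, 0, 0.5),
                      bradycardia_fraction = rbeta(200, 1, 30))
  allneg <- sample_outcome(feats, outcome_model_params(intercept = -30,
                             beta = c(late_decel_count = 0)), seed = 1)
  expect_false(any(allneg$label))
  allpos <- sample_outcome(feats, outcome_model_params(intercept = 30,
                             beta = c(late_decel_count = 0)), seed = 1)
  expect_true(all(allpos$label))
  # drawn fields reproduce the label through the labeling rule
  expect_equal(label_outcome(allpos$apgar_1min, allpos$apgar_5min,
                             allpos$ua_ph), allpos$label)
  expect_equal(label_outcome(allneg$apgar_1min, allneg$apgar_5min,
                             allneg$ua_ph), allneg$label)
})

test_that("calibrated prevalence lands within binomial bounds of 31/489", {
  set.seed(99)
  feats <- data.frame(late_decel_count = rpois(489, 1),
                      variability_deficit = pmax(0, 10 - runif(489, 5, 20)) / 10,
                      bradycardia_fraction = rbeta(489, 1, 30))
  out <- sample_outcome(feats, outcome_model_params(), seed = 123)
  n_pos <- sum(out$label)
  # binomial 95% interval around 31 at n = 489
  bounds <- qbinom(c(0.025, 0.975), 489, 31 / 489)
  expect_gte(n_pos, bounds[1])
  expect_lte(n_pos, bounds[2])
})

test_that("rater simulation: perfect raters echo the truth; quotas enforced", {
  truth <- c(rep(TRUE, 12), rep(FALSE, 50))
  names(truth) <- sprintf("c%02d", seq_along(truth))
  perfect <- simulate_raters(truth, rater_model_params(1, 1, n_raters = 5),
                             seed = 1)
  expect_equal(perfect$judgment, as.integer(truth[perfect$case_id]))
  expect_equal(nrow(perfect), 5 * 50)
  # each rater sees 10 positives and 40 negatives
  by_rater <- split(perfect, perfect$rater_id)
  for (b in by_rater) {
    expect_equal(sum(truth[b$case_id]), 10)
    expect_equal(nrow(b), 50)
    expect_false(anyDuplicated(b$case_id) > 0)
  }
  expect_error(simulate_raters(truth[1:15],
                               rater_model_params(n_raters = 2)),
               "quota", class = "ctgdx_invalid_params")
})

test_that("coin-flip raters are ~50% accurate (3 SE)", {
  truth <- c(rep(TRUE, 15), rep(FALSE, 60))
  names(truth) <- sprintf("c%02d", seq_along(truth))
  resp <- simulate_raters(truth, rater_model_params(0.5, 0.5, n_raters = 40),
                          seed = 21)
  acc <- mean(resp$judgment == as.integer(truth[resp$case_id]))
  se <- sqrt(0.25 / nrow(resp))
  expect_lt(abs(acc - 0.5), 3 * se)
  # 56 raters x 50 figures -> 2,800 responses when dropout is 0
  resp56 <- simulate_raters(truth, rater_model_params(n_raters = 56), seed = 1)
  expect_equal(nrow(resp56), 2800)
})

test_that("study cohort has the published shape and honest extremes", {
  coh <- generate_study_cohort(seed = 17)
  expect_equal(nrow(coh$cases), 489)
  expect_equal(sum(coh$cases$truth), 31)
  expect_equal(label_outcome(coh$cases$apgar_1min, coh$cases$apgar_5min,
                             coh$cases$ua_ph), coh$cases$truth)
  expect_true(all(coh$cases$dl_score >= 0 & coh$cases$dl_score <= 1))
  expect_true(all(coh$cases$ml_call %in% 0:1))
  allneg <- generate_study_cohort(n = 80, n_pos = 0, seed = 2,
                                  rater_params = rater_model_params(
                                    n_raters = 2, positives_per_rater = 0))
  expect_equal(sum(allneg$cases$truth), 0)
})

test_that("cohort traces reflect the per-case event plan", {
  coh <- generate_study_cohort(n = 4, n_pos = 2, seed = 31, traces = TRUE,
                               rater_params = rater_model_params(
                                 n_raters = 2, figures_per_rater = 3,
                                 positives_per_rater = 1))
  expect_length(coh$traces, 4)
  for (i in 1:4) {
    ev <- attr(coh$traces[[i]], "events")
    expect_equal(sum(ev$kind == "deceleration"),
                 coh$features$late_decel_count[i])
  }
})
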