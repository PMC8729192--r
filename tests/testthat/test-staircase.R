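# The 2-down/1-up adaptive engine, its threshold estimator and the
# constant-stimuli fallback.

test_that("level rule: two consecutive correct down, one incorrect up", {
  cfg <- staircase_config()
  expect_equal(as.numeric(next_delta_f(
    data.frame(delta_f = c(50, 50), correct = c(TRUE, TRUE)), cfg)), 48)
  up <- next_delta_f(data.frame(delta_f = 50, correct = FALSE), cfg)
  expect_equal(as.numeric(up), 50) # clamped at ceiling
  expect_true(attr(up, "exceeded"))
  expect_equal(as.numeric(next_delta_f(
    data.frame(delta_f = 48, correct = TRUE), cfg)), 48)
  # floor clamp
  dn <- next_delta_f(data.frame(delta_f = c(2, 2),
                                correct = c(TRUE, TRUE)), cfg)
  expect_equal(as.numeric(dn), 2)
  expect_false(attr(dn, "exceeded"))
  # empty history starts at the configured level
  expect_equal(as.numeric(next_delta_f(
    data.frame(delta_f = numeric(), correct = logical()), cfg)), 50)
})

test_that("deterministic threshold observer is bracketed within one step", {
  for (s in 1:25) {
    r <- run_staircase(threshold_observer(30), seed = s)
    expect_identical(r$outcome_type, "threshold")
    expect_gte(r$threshold, 28)
    expect_lte(r$threshold, 32)
  }
})

test_that("an always-correct observer descends to the floor", {
  r <- run_staircase(function(df) TRUE, seed = 1)
  # no incorrect responses means no reversals: the trial cap flags the
  # run invalid and the track sits at the floor
  expect_false(r$valid)
  expect_equal(min(r$trial_log$delta_f), staircase_config()$floor)
})

test_that("a guessing observer triggers the fallback and scores near 50%", {
  g <- tfs_observer(mu = 1e6, sigma = 10, lapse = 0)
  runs <- lapply(1:100, function(s) run_staircase(g, seed = s))
  types <- vapply(runs, `[[`, character(1), "outcome_type")
  expect_gt(mean(types == "fallback"), 0.9)
  fb <- vapply(runs[types == "fallback"], `[[`, numeric(1),
               "fallback_percent")
  # binomial: per-run sd = 100*sqrt(.25/40) ~ 7.9 points
  expect_equal(mean(fb), 50, tolerance = 3 / 50) # +-3 points on 50
  expect_equal(stats::sd(fb), 100 * sqrt(0.25 / 40), tolerance = 0.25)
})

test_that("fallback percent-correct is plain trial arithmetic", {
  expect_equal(run_fallback(function(df) TRUE, seed = 1)$percent_correct,
               100)
  # 29 of 40 correct -> 72.5%
  i <- 0
  obs29 <- function(df) { i <<- i + 1; i <= 29 }
  expect_equal(run_fallback(obs29, seed = 1)$percent_correct, 72.5)
})

test_that("reversal estimator equals the mean of the last six reversals", {
  cfg <- staircase_config()
  r <- run_staircase(tfs_observer(30, 8), cfg, seed = 4)
  expect_identical(r$outcome_type, "threshold")
  expect_length(r$reversal_values, 8)
  used <- tail(r$reversal_values, 6)
  expect_equal(r$threshold, mean(used))
  cfg_mean <- staircase_config(reversal_estimator = "mean")
  r2 <- run_staircase(tfs_observer(30, 8), cfg_mean, seed = 4)
  expect_equal(r2$threshold, r$threshold)
})

test_that("recorded runs replay to the identical outcome", {
  for (s in c(2, 4, 8, 16)) {
    r <- run_staircase(tfs_observer(28, 10), seed = s)
    if (r$outcome_type == "threshold")
      expect_identical(replay_staircase(r), r$threshold)
  }
})

test_that("threshold is invariant to trial seed for deterministic observers", {
  thr <- vapply(1:10, function(s)
    run_staircase(threshold_observer(24), seed = s)$threshold, numeric(1))
  expect_length(unique(thr), 1)
})

test_that("long tracks converge to the 70.7%-correct shift", {
  # asymptotic engine oracle: discard the descent transient by running
  # 20 reversals and keeping the protocol's last-six estimator
  obs <- tfs_observer(30, 8, lapse = 0)
  target <- 30 + 8 * stats::qnorm((0.707 - 0.5) / 0.5)
  cfg <- staircase_config(total_reversals = 20, max_trials = 500)
  est <- vapply(1:200, function(s)
    run_staircase(obs, cfg, seed = s)$threshold, numeric(1))
  expect_equal(mean(est, na.rm = TRUE), target, tolerance = 2 / target)
})
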