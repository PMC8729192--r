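# Transformed up-down (2-down/1-up) adaptive staircase over the
# inharmonicity shift delta_f, with reversal-based threshold estimation
# and a 40-trial constant-stimuli fallback when the track repeatedly
# demands shifts above the ceiling. The 2-down/1-up rule converges on
# the 70.7%-correct point of the psychometric function.

#' Staircase configuration
#'
#' Defaults follow the standard TFS1 protocol at F0 = 100 Hz: start at
#' delta_f = 50 Hz, fixed 2 Hz steps, eight reversals with the
#' threshold taken from the last six, and a 40-trial constant-stimuli
#' block at 50 Hz when the adaptive track exceeds the ceiling.
#'
#' @param start_delta_f starting shift, Hz.
#' @param step fixed step size, Hz (no initial-phase halving).
#' @param down_rule consecutive correct responses required to step down.
#' @param up_rule incorrect responses required to step up.
#' @param total_reversals reversals at which the track terminates.
#' @param reversals_used how many final reversals enter the estimate.
#' @param ceiling,floor bounds on delta_f, Hz.
#' @param fallback_trials trials in the constant-stimuli fallback block.
#' @param ceiling_exceedances how many times the track may demand a
#'   level above the ceiling before the fallback is triggered.
#' @param max_trials hard cap guarding against non-termination.
#' @param reversal_estimator `"midpoint"` averages the midpoints of the
#'   three non-overlapping consecutive pairs among the last
#'   `reversals_used` reversal values; `"mean"` averages the values
#'   directly. The two coincide for this pairing.
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(start_delta_f = 50, step = 2, down_rule = 2,
                             up_rule = 1, total_reversals = 8,
                             reversals_used = 6, ceiling = 50, floor = 2,
                             fallback_trials = 40,
                             ceiling_exceedances = 3, max_trials = 200,
                             reversal_estimator = c("midpoint", "mean")) {
  stopifnot(reversals_used <= total_reversals, floor >= step, step > 0,
            start_delta_f <= ceiling, floor <= start_delta_f)
  structure(list(start_delta_f = start_delta_f, step = step,
                 down_rule = down_rule, up_rule = up_rule,
                 total_reversals = total_reversals,
                 reversals_used = reversals_used, ceiling = ceiling,
                 floor = floor, fallback_trials = fallback_trials,
                 ceiling_exceedances = ceiling_exceedances,
                 max_trials = max_trials,
                 reversal_estimator = match.arg(reversal_estimator)),
            class = "staircase_config")
}

#' Next stimulus level under the 2-down/1-up rule
#'
#' Pure function of the trial history: after `down_rule` consecutive
#' correct responses since the last level change the level drops one
#' step; after any incorrect response it rises one step; otherwise it
#' stays. The result is clamped to `[floor, ceiling]`; a demand above
#' the ceiling is reported via the `exceeded` attribute so the caller
#' can count fallback triggers.
#'
#' @param state a `staircase_state` (see [run_staircase()]) or a data
#'   frame with columns `delta_f` and `correct`.
#' @param config a [staircase_config()].
#' @return next delta_f in Hz, with attribute `exceeded` (logical).
#' @export
next_delta_f <- function(state, config = staircase_config()) {
  log <- if (inherits(state, "staircase_state")) state$trial_log else state
  if (nrow(log) == 0) {
    out <- config$start_delta_f
    attr(out, "exceeded") <- FALSE
    return(out)
  }
  cur <- log$delta_f[nrow(log)]
  last <- log$correct[nrow(log)]
  if (!last) {
    raw <- cur + config$step
  } else {
    # count consecutive correct at the current level since it was last set
    run <- 0
    for (i in nrow(log):1) {
      if (log$correct[i] && log$delta_f[i] == cur) run <- run + 1 else break
    }
    raw <- if (run %% config$down_rule == 0) cur - config$step else cur
  }
  out <- min(max(raw, config$floor), config$ceiling)
  attr(out, "exceeded") <- raw > config$ceiling
  out
}

#' Run one adaptive staircase against an observer
#'
#' The observer is a function `function(delta_f) -> logical` judging
#' one 2IAFC trial (TRUE = correct), or a [tfs_observer()] whose
#' responses are drawn from its psychometric function. The track
#' terminates after `total_reversals` reversals, yielding a threshold
#' from the last `reversals_used` reversal values; if it demands a
#' level above the ceiling `ceiling_exceedances` times, the adaptive
#' phase aborts and the constant-stimuli fallback ([run_fallback()])
#' supplies a percent-correct score at the ceiling instead.
#'
#' @param observer function or [tfs_observer()].
#' @param config a [staircase_config()].
#' @param seed RNG seed for observer draws (fanned to sub-streams).
#' @return a `staircase_state`: `trial_log` (data frame: trial,
#'   delta_f, correct, reversal), `reversal_values`, `outcome_type`
#'   (`"threshold"` or `"fallback"`), `threshold` (Hz) or
#'   `fallback_percent` (%), `n_trials`, `valid`.
#' @export
run_staircase <- function(observer, config = staircase_config(), seed = 1) {
  obs <- as_observer_fun(observer, substream(seed, "adaptive"))
  level <- config$start_delta_f
  cap <- config$max_trials
  lv <- numeric(cap); cr <- logical(cap); rv <- logical(cap)
  n_log <- 0L
  reversal_values <- numeric()
  direction <- 0 # -1 down, +1 up, 0 none yet
  exceed_count <- 0
  run_correct <- 0
  valid <- TRUE
  make_log <- function() data.frame(trial = seq_len(n_log),
                                    delta_f = lv[seq_len(n_log)],
                                    correct = cr[seq_len(n_log)],
                                    reversal = rv[seq_len(n_log)])
  repeat {
    correct <- obs(level)
    # determine the move implied by this response
    if (!correct) {
      run_correct <- 0
      move <- +1
    } else {
      run_correct <- run_correct + 1
      move <- if (run_correct == config$down_rule) -1 else 0
      if (move == -1) run_correct <- 0
    }
    is_rev <- move != 0 && direction != 0 && move != direction
    n_log <- n_log + 1L
    lv[n_log] <- level; cr[n_log] <- correct; rv[n_log] <- is_rev
    if (is_rev) reversal_values <- c(reversal_values, level)
    if (move != 0) direction <- move
    if (length(reversal_values) >= config$total_reversals) break
    if (move != 0) {
      raw <- level + move * config$step
      if (raw > config$ceiling) {
        exceed_count <- exceed_count + 1
        if (exceed_count >= config$ceiling_exceedances) {
          fb <- run_fallback(observer, config, substream(seed, "fallback"))
          return(structure(list(trial_log = make_log(),
                                reversal_values = reversal_values,
                                outcome_type = "fallback",
                                fallback_percent = fb$percent_correct,
                                fallback_log = fb$trial_log,
                                n_trials = n_log + config$fallback_trials,
                                config = config, valid = TRUE),
                           class = "staircase_state"))
        }
      }
      level <- min(max(raw, config$floor), config$ceiling)
    }
    if (n_log >= config$max_trials) { valid <- FALSE; break }
  }
  thr <- if (valid) estimate_threshold(reversal_values, config) else NA_real_
  structure(list(trial_log = make_log(), reversal_values = reversal_values,
                 outcome_type = "threshold", threshold = thr,
                 n_trials = n_log, config = config, valid = valid),
            class = "staircase_state")
}

# Threshold from reversal values: mean of midpoints of the three
# non-overlapping consecutive pairs among the last `reversals_used`
# values (equal to their plain mean), or the plain mean directly.
estimate_threshold <- function(reversal_values, config) {
  used <- utils::tail(reversal_values, config$reversals_used)
  if (config$reversal_estimator == "mean" || length(used) %% 2 == 1)
    return(mean(used))
  idx <- seq(1, length(used), by = 2)
  mean((used[idx] + used[idx + 1]) / 2)
}

#' Constant-stimuli fallback block at the ceiling level
#'
#' Presents `fallback_trials` 2IAFC trials at delta_f equal to the
#' staircase ceiling (50 Hz by default, i.e. half of F0 = 100 Hz) and
#' returns the percentage of correct responses. This is the score the
#' protocol records for listeners whose adaptive track exceeds the
#' ceiling.
#'
#' @inheritParams run_staircase
#' @return list: `percent_correct` (0-100), `trial_log` (logical vector).
#' @export
run_fallback <- function(observer, config = staircase_config(), seed = 1) {
  obs <- as_observer_fun(observer, seed)
  res <- vapply(seq_len(config$fallback_trials),
                function(i) obs(config$ceiling), logical(1))
  list(percent_correct = 100 * sum(res) / length(res), trial_log = res)
}

#' Replay a recorded trial log through the staircase rules
#'
#' Feeds the recorded responses back through [run_staircase()]'s level
#' logic and recomputes the outcome; a faithfully recorded run replays
#' to the identical result.
#'
#' @param state a `staircase_state` with outcome_type `"threshold"`.
#' @return the recomputed threshold in Hz.
#' @export
replay_staircase <- function(state) {
  stopifnot(inherits(state, "staircase_state"),
            state$outcome_type == "threshold")
  responses <- state$trial_log$correct
  i <- 0
  obs <- function(delta_f) { i <<- i + 1; responses[i] }
  rerun <- run_staircase(obs, state$config, seed = 0)
  rerun$threshold
}

#' @export
print.staircase_state <- function(x, ...) {
  cat("2-down/1-up staircase run\n")
  cat(sprintf("  trials: %d, reversals: %d\n",
              nrow(x$trial_log), length(x$reversal_values)))
  if (x$outcome_type == "threshold") {
    cat(sprintf("  outcome: threshold = %.2f Hz%s\n", x$threshold,
                if (!x$valid) " (INVALID: trial cap reached)" else ""))
  } else {
    cat(sprintf("  outcome: fallback percent-correct = %.1f%% (%d trials at %g Hz)\n",
                x$fallback_percent, x$config$fallback_trials,
                x$config$ceiling))
  }
  invisible(x)
}

#' @export
summary.staircase_state <- function(object, ...) {
  out <- list(outcome_type = object$outcome_type,
              value = if (object$outcome_type == "threshold")
                object$threshold else object$fallback_percent,
              n_trials = object$n_trials,
              n_reversals = length(object$reversal_values),
              valid = object$valid)
  class(out) <- "summary.staircase_state"
  out
}

#' @export
print.summary.staircase_state <- function(x, ...) {
  cat(sprintf("staircase outcome: %s = %.2f (%d trials, %d reversals%s)\n",
              x$outcome_type, x$value, x$n_trials, x$n_reversals,
              if (!x$valid) ", INVALID" else ""))
  invisible(x)
}

#' Plot the adaptive track of a staircase run
#'
#' @param x a `staircase_state`.
#' @param ... passed to [plot()].
#' @export
plot.staircase_state <- function(x, ...) {
  log <- x$trial_log
  graphics::plot(log$trial, log$delta_f, type = "s",
                 xlab = "trial", ylab = expression(Delta * f ~ "(Hz)"),
                 ...)
  graphics::points(log$trial[log$correct], log$delta_f[log$correct],
                   pch = 16, col = "forestgreen")
  graphics::points(log$trial[!log$correct], log$delta_f[!log$correct],
                   pch = 4, col = "firebrick")
  if (x$outcome_type == "threshold")
    graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
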