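# Simulated listeners. A TFS observer answers 2IAFC inharmonicity
# trials through a cumulative-Gaussian psychometric function with a
# 0.5 guessing floor; a vowel observer produces single/double-correct
# CVI events with a per-condition F0-difference benefit. These stand
# in for child listeners so that every downstream stage is testable
# without human data.

#' Psychometric 2IAFC observer for the TFS task
#'
#' P(correct | delta_f) = guess + (1 - guess - lapse) *
#' Phi((delta_f - mu) / sigma): chance at small shifts, saturating at
#' 1 - lapse for large ones, monotone non-decreasing in delta_f.
#'
#' @param mu psychometric midpoint on delta_f, Hz.
#' @param sigma slope parameter, Hz.
#' @param lapse lapse probability in [0, 0.05].
#' @param guess guessing probability (0.5 for 2IAFC).
#' @return an object of class `tfs_observer`.
#' @export
tfs_observer <- function(mu, sigma, lapse = 0.02, guess = 0.5) {
  stopifnot(sigma > 0, lapse >= 0, lapse <= 0.05, guess >= 0, guess < 1)
  structure(list(mu = mu, sigma = sigma, lapse = lapse, guess = guess),
            class = "tfs_observer")
}

#' Probability of a correct response at a given shift
#'
#' @param obs a [tfs_observer()].
#' @param delta_f shift(s) in Hz.
#' @return probability vector.
#' @export
psychometric_p <- function(obs, delta_f) {
  stopifnot(inherits(obs, "tfs_observer"), all(delta_f >= 0))
  obs$guess + (1 - obs$guess - obs$lapse) *
    stats::pnorm((delta_f - obs$mu) / obs$sigma)
}

#' Draw one trial response from an observer
#'
#' @param obs a [tfs_observer()].
#' @param delta_f shift in Hz.
#' @param seed optional RNG seed for this draw.
#' @return logical: correct response.
#' @export
observer_response <- function(obs, delta_f, seed = NULL) {
  p <- psychometric_p(obs, delta_f)
  with_seed(seed, stats::runif(length(p)) < p)
}

# Normalize anything observer-like into function(delta_f) -> logical
# drawing from a private stream of pre-generated uniforms (one per
# trial, independent of the level sequence), keeping the staircase
# logic pure and the caller's RNG untouched.
as_observer_fun <- function(observer, seed, n_draws = 1024L) {
  if (is.function(observer)) return(observer)
  stopifnot(inherits(observer, "tfs_observer"))
  u <- with_seed(seed, stats::runif(n_draws))
  i <- 0L
  function(delta_f) {
    i <<- i + 1L
    if (i > n_draws) stop("observer draw budget exhausted")
    u[i] < psychometric_p(observer, delta_f)
  }
}

#' Event-level observer for the concurrent vowel task
#'
#' The probability of identifying at least one vowel of a pair is
#' `p_single_base + f0_benefit * step - group_deficit + child_offset`,
#' clipped to [0, 1], where `step` indexes the F0-difference condition
#' (0, 1, 2, 3 for 0, 1, 2, 4 semitones). Conditional on a single
#' identification, both vowels are identified with probability
#' `p_double_given_single`, so double-correct never exceeds
#' single-correct.
#'
#' @param p_single_base P(at least one correct) at 0 semitones for an
#'   unimpaired listener with zero offset.
#' @param f0_benefit added probability per condition step (>= 0).
#' @param group_deficit probability subtracted for reading-disability
#'   group members.
#' @param child_offset this listener's deviation from the group mean.
#' @param p_double_given_single conditional double-correct probability.
#' @return an object of class `vowel_observer`.
#' @export
vowel_observer <- function(p_single_base = 0.85, f0_benefit = 0.01,
                           group_deficit = 0, child_offset = 0,
                           p_double_given_single = 0.45) {
  stopifnot(f0_benefit >= 0, p_double_given_single >= 0,
            p_double_given_single <= 1)
  structure(list(p_single_base = p_single_base, f0_benefit = f0_benefit,
                 group_deficit = group_deficit,
                 child_offset = child_offset,
                 p_double_given_single = p_double_given_single),
            class = "vowel_observer")
}

# Per-condition probabilities: $single is the cumulative threshold
# used by the response sampler, $double the unconditional
# double-correct probability.
cvi_probabilities <- function(obs, semitone_diff,
                              conditions = c(0, 1, 2, 4)) {
  step <- match(semitone_diff, conditions) - 1
  if (any(is.na(step))) stop("unknown F0-difference condition: ",
                             semitone_diff)
  p_single <- pmin(pmax(obs$p_single_base + obs$f0_benefit * step -
                          obs$group_deficit + obs$child_offset, 0), 1)
  list(single = p_single, double = p_single * obs$p_double_given_single)
}
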