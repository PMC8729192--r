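# Presentation schedule and single/double-correct scoring of the
# concurrent vowel identification (CVI) task. Responses are unordered
# pairs of distinct identities from the five-vowel set; no feedback.

VOWELS <- c("a", "i", "e", "u", "o")

#' Score one concurrent-vowel response
#'
#' Double-correct when the responded pair equals the presented pair as
#' a set; single-correct when at least one responded identity was
#' presented. Double-correct implies single-correct.
#'
#' @param presented,responded character vectors of two distinct vowel
#'   identities each (order ignored).
#' @return list `double`, `single` (logicals).
#' @export
score_response <- function(presented, responded) {
  check_pair <- function(p, what) {
    if (length(p) != 2 || anyDuplicated(p) || !all(p %in% VOWELS))
      stop(what, " must be two distinct identities from {",
           paste(VOWELS, collapse = ", "), "}")
  }
  check_pair(presented, "presented")
  check_pair(responded, "responded")
  double <- setequal(presented, responded)
  single <- length(intersect(presented, responded)) > 0
  list(double = double, single = single)
}

#' Build the presentation schedule for a CVI session
#'
#' Every pair is presented `repetitions` times (20 in the standard
#' protocol) in a seeded random order.
#'
#' @param pairs output of [enumerate_pairs()].
#' @param repetitions presentations per pair.
#' @param order_seed RNG seed for the shuffle.
#' @return data frame: presentation index, pair_id, vowel_1, vowel_2,
#'   semitone_diff.
#' @export
presentation_plan <- function(pairs, repetitions = 20, order_seed = 1) {
  stopifnot(repetitions > 0)
  idx <- rep(seq_len(nrow(pairs)), each = repetitions)
  idx <- with_seed(order_seed, sample(idx))
  plan <- pairs[idx, c("pair_id", "vowel_1", "vowel_2", "semitone_diff")]
  plan$presentation <- seq_len(nrow(plan))
  rownames(plan) <- NULL
  plan[, c("presentation", "pair_id", "vowel_1", "vowel_2", "semitone_diff")]
}

#' Simulate one listener's CVI session at presentation level
#'
#' For each scheduled presentation the [vowel_observer()] emits a
#' responded pair: both vowels correct with its double-correct
#' probability; exactly one correct (the other drawn from the three
#' unpresented identities) with the residual single-correct
#' probability; otherwise both responses drawn from the unpresented
#' identities. Scoring then goes through [score_response()].
#'
#' @param observer a [vowel_observer()].
#' @param plan a [presentation_plan()].
#' @param seed RNG seed.
#' @return data frame: the plan columns plus resp_1, resp_2, single,
#'   double.
#' @export
simulate_cvi_session <- function(observer, plan, seed = 1) {
  stopifnot(inherits(observer, "vowel_observer"))
  with_seed(seed, {
    n <- nrow(plan)
    out <- plan
    out$resp_1 <- character(n); out$resp_2 <- character(n)
    out$single <- logical(n); out$double <- logical(n)
    for (i in seq_len(n)) {
      pres <- c(plan$vowel_1[i], plan$vowel_2[i])
      p <- cvi_probabilities(observer, plan$semitone_diff[i])
      u <- stats::runif(1)
      others <- setdiff(VOWELS, pres)
      resp <- if (u < p$double) {
        pres
      } else if (u < p$single) {
        c(sample(pres, 1), sample(others, 1))
      } else {
        sample(others, 2)
      }
      sc <- score_response(pres, resp)
      out$resp_1[i] <- resp[1]; out$resp_2[i] <- resp[2]
      out$single[i] <- sc$single; out$double[i] <- sc$double
    }
    out
  })
}

#' Aggregate CVI records into per-condition percent-correct scores
#'
#' @param records data frame with columns `semitone_diff`, `single`,
#'   `double` (one row per presentation), e.g. from
#'   [simulate_cvi_session()].
#' @param repetitions expected presentations per pair; when the
#'   schedule is incomplete a warning reports the partial denominator.
#' @param n_pairs expected number of distinct pairs per condition.
#' @return data frame: semitone_diff, n, single_percent, double_percent.
#' @export
aggregate_scores <- function(records, repetitions = 20, n_pairs = 10) {
  conds <- sort(unique(records$semitone_diff))
  out <- do.call(rbind, lapply(conds, function(d) {
    r <- records[records$semitone_diff == d, ]
    data.frame(semitone_diff = d, n = nrow(r),
               single_percent = 100 * sum(r$single) / nrow(r),
               double_percent = 100 * sum(r$double) / nrow(r))
  }))
  expected <- repetitions * n_pairs
  if (any(out$n != expected))
    warning("incomplete schedule: expected ", expected,
            " presentations per condition, got ",
            paste(out$n, collapse = "/"),
            "; percentages use the partial denominator")
  rownames(out) <- NULL
  out
}
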