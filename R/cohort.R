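# Simulated listener cohorts with the structure of the study design:
# 15 reading-disability (RD) and 15 typically developing (TD) children,
# one TFS percent-correct score per child from a full staircase run,
# and four concurrent-vowel single-correct scores (0/1/2/4 semitone
# F0-difference conditions).

CVI_CONDITIONS <- c(0, 1, 2, 4)
CVI_COLUMNS <- paste0("cvi_", CVI_CONDITIONS, "st")

#' Parameters of a simulated cohort
#'
#' Group-level means with between-child normal variation. The TFS side
#' parameterizes each child's psychometric midpoint `mu` (Hz); the CVI
#' side the single-correct base probability, F0 benefit and RD
#' deficit. Defaults produce the qualitative pattern of the study
#' population: most children's adaptive tracks exceed the 50 Hz
#' ceiling (so scores are fallback percent-correct), TD above RD on
#' both tasks, a modest monotone F0-difference benefit, and additive
#' (no-interaction) group and condition effects.
#'
#' @param n_per_group children per group.
#' @param tfs_mu_td,tfs_mu_rd group mean psychometric midpoints, Hz.
#' @param tfs_mu_sd between-child SD of the midpoint, Hz.
#' @param tfs_sigma psychometric slope, Hz.
#' @param lapse lapse rate.
#' @param p_single_base,f0_benefit,group_deficit,noise_sd CVI observer
#'   parameters; `noise_sd` is the SD of the per-child offset.
#' @param p_double_given_single conditional double-correct probability.
#' @param staircase a [staircase_config()].
#' @param cvi_repetitions presentations per vowel pair.
#' @param cvi_pairs_per_condition distinct identity pairs per condition.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = 15,
                          tfs_mu_td = 50, tfs_mu_rd = 75,
                          tfs_mu_sd = 12, tfs_sigma = 20, lapse = 0.02,
                          p_single_base = 0.85, f0_benefit = 0.0075,
                          group_deficit = 0.095, noise_sd = 0.08,
                          p_double_given_single = 0.45,
                          staircase = staircase_config(),
                          cvi_repetitions = 20,
                          cvi_pairs_per_condition = 10) {
  structure(as.list(environment()), class = "cohort_params")
}

#' Simulate a full cohort through the experimental pipeline
#'
#' Per child: a psychometric midpoint is drawn from the group
#' distribution, the 2-down/1-up staircase is run in full, and the TFS
#' score recorded is the percent correct over `fallback_trials` 2IAFC
#' trials at the 50 Hz ceiling — via the fallback when the track
#' exceeds the ceiling (the typical case under the defaults), or as a
#' constant-stimuli probe at the same level for children whose track
#' converges. CVI single-correct scores are binomial draws at each
#' condition's per-presentation probability over the full schedule
#' (`cvi_repetitions * cvi_pairs_per_condition` presentations);
#' [simulate_cvi_session()] provides the equivalent presentation-level
#' route.
#'
#' @param params a [cohort_params()].
#' @param seed master seed; every child and stage uses an independent
#'   sub-stream.
#' @return a `cohort_table` data frame: child_id, group ("RD"/"TD"),
#'   tfs_percent, cvi_0st, cvi_1st, cvi_2st, cvi_4st. Attribute
#'   `staircase_outcomes` records each child's adaptive outcome type.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_per_group
  groups <- rep(c("RD", "TD"), each = n)
  n_total <- 2 * n
  mu_mean <- ifelse(groups == "RD", params$tfs_mu_rd, params$tfs_mu_td)
  mus <- with_seed(substream(seed, "tfs_mu"),
                   stats::rnorm(n_total, mu_mean, params$tfs_mu_sd))
  mus <- pmax(mus, 1)
  offsets <- with_seed(substream(seed, "cvi_offset"),
                       stats::rnorm(n_total, 0, params$noise_sd))
  tfs <- numeric(n_total)
  outcome <- character(n_total)
  n_pres <- params$cvi_repetitions * params$cvi_pairs_per_condition
  cvi <- matrix(NA_real_, n_total, length(CVI_CONDITIONS),
                dimnames = list(NULL, CVI_COLUMNS))
  for (i in seq_len(n_total)) {
    obs <- tfs_observer(mus[i], params$tfs_sigma, params$lapse)
    run <- run_staircase(obs, params$staircase,
                         seed = substream(seed, i * 101))
    if (run$outcome_type == "fallback") {
      tfs[i] <- run$fallback_percent
    } else {
      probe <- run_fallback(obs, params$staircase,
                            seed = substream(seed, i * 101 + 1))
      tfs[i] <- probe$percent_correct
    }
    outcome[i] <- run$outcome_type
    vobs <- vowel_observer(params$p_single_base, params$f0_benefit,
                           group_deficit =
                             if (groups[i] == "RD") params$group_deficit else 0,
                           child_offset = offsets[i],
                           p_double_given_single =
                             params$p_double_given_single)
    p <- cvi_probabilities(vobs, CVI_CONDITIONS)$single
    cvi[i, ] <- with_seed(substream(seed, i * 101 + 2),
                          100 * stats::rbinom(length(p), n_pres, p) / n_pres)
  }
  out <- data.frame(child_id = sprintf("%s%02d", groups, c(1:n, 1:n)),
                    group = groups, tfs_percent = tfs,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cvi))
  attr(out, "staircase_outcomes") <- outcome
  class(out) <- c("cohort_table", "data.frame")
  validate_cohort(out, n_per_group = n)
}

#' Validate a cohort table against the study schema
#'
#' @param table data frame with columns child_id, group, tfs_percent
#'   and the four cvi columns.
#' @param n_per_group expected children per group (NULL to skip the
#'   row-count check).
#' @return the table, classed `cohort_table`, invisibly usable.
#' @export
validate_cohort <- function(table, n_per_group = 15) {
  needed <- c("child_id", "group", "tfs_percent", CVI_COLUMNS)
  missing <- setdiff(needed, names(table))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(table$group %in% c("RD", "TD")))
    stop("unknown group label(s): ",
         paste(setdiff(unique(table$group), c("RD", "TD")), collapse = ", "))
  if (!is.null(n_per_group)) {
    tab <- base::table(table$group)
    if (!all(tab == n_per_group) || length(tab) != 2)
      stop("expected ", n_per_group, " children per group, found ",
           paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  for (col in c("tfs_percent", CVI_COLUMNS)) {
    bad <- which(!is.finite(table[[col]]) | table[[col]] < 0 |
                   table[[col]] > 100)
    if (length(bad))
      stop("percentage out of [0, 100] in column ", col, ", row(s) ",
           paste(bad, collapse = ", "), " (child ",
           paste(table$child_id[bad], collapse = ", "), ")")
  }
  if (!inherits(table, "cohort_table"))
    class(table) <- c("cohort_table", "data.frame")
  table
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort of %d children (%s)\n", nrow(x),
              paste(names(table(x$group)), table(x$group),
                    sep = ": ", collapse = ", ")))
  agg <- stats::aggregate(x[, c("tfs_percent", CVI_COLUMNS)],
                          by = list(group = x$group), FUN = mean)
  cat("group means:\n")
  print(format(agg, digits = 3), row.names = FALSE)
  invisible(x)
}
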