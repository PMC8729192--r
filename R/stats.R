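# Statistical layer applied to any cohort table: Shapiro-Wilk
# normality checks, pooled independent t tests (RD minus TD sign
# convention), the mixed between-by-within repeated-measures ANOVA
# with sphericity-assumed degrees of freedom, and per-condition t
# tests with Bonferroni adjustment.

#' Pooled independent-samples t test, RD-first sign convention
#'
#' Student's pooled-variance t with df = n1 + n2 - 2 (a Welch option
#' exists behind `pooled = FALSE`). The first group is subtracted-from:
#' calling with RD scores first and TD second yields negative t when
#' RD performs worse.
#'
#' @param group_a,group_b numeric score vectors (conventionally RD, TD).
#' @param pooled logical; pooled-variance Student t (default) or Welch.
#' @return list of class `t_result`: t, df, p, mean_a, mean_b, sd_a,
#'   sd_b, pooled.
#' @export
independent_t <- function(group_a, group_b, pooled = TRUE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (pooled && stats::var(group_a) + stats::var(group_b) == 0)
    stop("zero pooled variance: groups are constant")
  ht <- stats::t.test(group_a, group_b, var.equal = pooled)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 sd_a = stats::sd(group_a), sd_b = stats::sd(group_b),
                 pooled = pooled),
            class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("t(%s) = %.3f, p = %.4g  (means %.2f vs %.2f)\n",
              format(x$df, digits = 4), x$t, x$p, x$mean_a, x$mean_b))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] returning W and p;
#' constant samples and n < 3 are errors.
#'
#' @param sample numeric vector, n >= 3.
#' @return list: W, p, n.
#' @export
shapiro_wilk <- function(sample) {
  if (length(sample) < 3) stop("Shapiro-Wilk requires n >= 3")
  if (stats::var(sample) == 0) stop("constant sample")
  ht <- stats::shapiro.test(sample)
  list(W = unname(ht$statistic), p = ht$p.value, n = length(sample))
}

#' Mixed between-by-within repeated-measures ANOVA
#'
#' Direct sums-of-squares partition for a design with one
#' between-subjects factor (group) and one within-subjects factor
#' (condition), complete and balanced: total SS splits into group,
#' subjects-within-group, condition, group-by-condition interaction,
#' and condition-by-subject error. F for the group effect uses the
#' subjects-within-group mean square; condition and interaction use
#' the within error. Degrees of freedom are sphericity-assumed
#' (uncorrected); the Greenhouse-Geisser epsilon is computed and
#' reported alongside for transparency, with epsilon-corrected p
#' values in `p_gg`.
#'
#' @param table a cohort table, or any data frame with a `group`
#'   column and the score columns named in `dv`.
#' @param dv character vector of within-condition column names
#'   (default the four CVI single-correct columns).
#' @param between name of the grouping column.
#' @return object of class `rm_anova`: per-effect F, df and p, the SS
#'   table, cell means, Greenhouse-Geisser epsilon, `degenerate` flag.
#' @export
rm_anova <- function(table, dv = CVI_COLUMNS, between = "group") {
  stopifnot(all(dv %in% names(table)), between %in% names(table))
  Y <- as.matrix(table[, dv])
  if (any(!is.finite(Y))) stop("missing cells: the design must be complete")
  g <- factor(table[[between]])
  k <- ncol(Y); N <- nrow(Y); n_g <- as.numeric(base::table(g))
  if (length(unique(n_g)) != 1)
    stop("unbalanced groups are not supported")
  gm <- mean(Y)
  ss_total <- sum((Y - gm)^2)
  subj_means <- rowMeans(Y)
  ss_bs <- k * sum((subj_means - gm)^2)
  grp_means <- tapply(subj_means, g, mean)
  ss_group <- k * sum(n_g * (grp_means - gm)^2)
  ss_subj <- ss_bs - ss_group
  cond_means <- colMeans(Y)
  ss_cond <- N * sum((cond_means - gm)^2)
  cell_means <- apply(Y, 2, function(col) tapply(col, g, mean))
  ss_cells <- sum(n_g * (cell_means - gm)^2)
  ss_inter <- ss_cells - ss_group - ss_cond
  ss_error <- ss_total - ss_bs - ss_cond - ss_inter
  df <- list(group = nlevels(g) - 1, subj = N - nlevels(g),
             cond = k - 1, inter = (nlevels(g) - 1) * (k - 1),
             error = (k - 1) * (N - nlevels(g)))
  degenerate <- ss_subj <= 0 || ss_error <= 0
  ms_subj <- ss_subj / df$subj
  ms_err <- ss_error / df$error
  F_between <- if (degenerate) NA_real_ else ss_group / df$group / ms_subj
  F_within <- if (degenerate) NA_real_ else ss_cond / df$cond / ms_err
  F_inter <- if (degenerate) NA_real_ else ss_inter / df$inter / ms_err
  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  eps <- if (degenerate) NA_real_ else {
    S <- Reduce(`+`, lapply(levels(g), function(lev) {
      Yg <- Y[g == lev, , drop = FALSE]
      stats::cov(Yg) * (nrow(Yg) - 1)
    })) / (N - nlevels(g))
    D <- S - outer(rowMeans(S), rep(1, k)) -
      outer(rep(1, k), colMeans(S)) + mean(S)
    sum(diag(D))^2 / ((k - 1) * sum(D^2))
  }
  p_val <- function(F, d1, d2, e = 1)
    if (is.na(F)) NA_real_ else stats::pf(F, e * d1, e * d2, lower.tail = FALSE)
  res <- list(
    F_between = F_between, df_between = c(df$group, df$subj),
    p_between = p_val(F_between, df$group, df$subj),
    F_within = F_within, df_within = c(df$cond, df$error),
    p_within = p_val(F_within, df$cond, df$error),
    F_interaction = F_inter, df_interaction = c(df$inter, df$error),
    p_interaction = p_val(F_inter, df$inter, df$error),
    gg_epsilon = eps,
    p_gg = list(within = p_val(F_within, df$cond, df$error, eps),
                interaction = p_val(F_inter, df$inter, df$error, eps)),
    ss = c(group = ss_group, subjects = ss_subj, condition = ss_cond,
           interaction = ss_inter, error = ss_error, total = ss_total),
    cell_means = cell_means, degenerate = degenerate)
  class(res) <- "rm_anova"
  res
}

#' @export
print.rm_anova <- function(x, ...) {
  if (x$degenerate) {
    cat("repeated-measures ANOVA: degenerate (zero error variance)\n")
    return(invisible(x))
  }
  cat("mixed repeated-measures ANOVA (sphericity-assumed df)\n")
  cat(sprintf("  group:       F(%d,%d) = %.3f, p = %.4g\n",
              x$df_between[1], x$df_between[2], x$F_between, x$p_between))
  cat(sprintf("  condition:   F(%d,%d) = %.3f, p = %.4g\n",
              x$df_within[1], x$df_within[2], x$F_within, x$p_within))
  cat(sprintf("  interaction: F(%d,%d) = %.3f, p = %.4g\n",
              x$df_interaction[1], x$df_interaction[2], x$F_interaction,
              x$p_interaction))
  cat(sprintf("  Greenhouse-Geisser epsilon = %.3f\n", x$gg_epsilon))
  invisible(x)
}

#' Per-condition group comparisons with Bonferroni adjustment
#'
#' One pooled independent t per F0-difference condition (RD minus TD),
#' with raw and Bonferroni-adjusted p values (adjusted p =
#' min(1, m * p) over the m conditions).
#'
#' @param table a cohort table.
#' @param dv condition column names.
#' @param between grouping column.
#' @return data frame: condition, t, df, p, p_bonferroni, mean_rd,
#'   mean_td.
#' @export
per_condition_t <- function(table, dv = CVI_COLUMNS, between = "group") {
  g <- table[[between]]
  rows <- lapply(dv, function(col) {
    tt <- independent_t(table[[col]][g == "RD"], table[[col]][g == "TD"])
    data.frame(condition = col, t = tt$t, df = tt$df, p = tt$p,
               mean_rd = tt$mean_a, mean_td = tt$mean_b)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  out
}

#' Full statistical analysis of a cohort table
#'
#' Reproduces the study's analysis plan: Shapiro-Wilk normality of the
#' TFS scores per group, pooled t on TFS percent-correct (RD vs TD),
#' mixed repeated-measures ANOVA on the four CVI single-correct
#' conditions, and per-condition pooled t tests with Bonferroni
#' adjustment.
#'
#' @param table a `cohort_table` (simulated or loaded).
#' @return object of class `cohort_analysis`.
#' @export
analyze_cohort <- function(table) {
  table <- validate_cohort(table, n_per_group = NULL)
  rd <- table$tfs_percent[table$group == "RD"]
  td <- table$tfs_percent[table$group == "TD"]
  res <- list(
    normality = list(RD = shapiro_wilk(rd), TD = shapiro_wilk(td)),
    tfs_t = independent_t(rd, td),
    cvi_anova = rm_anova(table),
    cvi_per_condition = per_condition_t(table),
    n = c(RD = sum(table$group == "RD"), TD = sum(table$group == "TD")))
  class(res) <- "cohort_analysis"
  res
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis (%d RD, %d TD)\n", x$n["RD"], x$n["TD"]))
  cat("\nTFS percent-correct at the ceiling shift\n")
  cat(sprintf("  normality: RD W = %.2f (p = %.2f), TD W = %.2f (p = %.2f)\n",
              x$normality$RD$W, x$normality$RD$p,
              x$normality$TD$W, x$normality$TD$p))
  cat(sprintf("  RD vs TD: t(%d) = %.2f, p = %.4g (means %.1f vs %.1f)\n",
              x$tfs_t$df, x$tfs_t$t, x$tfs_t$p, x$tfs_t$mean_a,
              x$tfs_t$mean_b))
  cat("\nConcurrent vowel identification (single-correct)\n")
  print(x$cvi_anova)
  cat("  per-condition RD vs TD:\n")
  pc <- x$cvi_per_condition
  for (i in seq_len(nrow(pc)))
    cat(sprintf("    %s: t(%d) = %.3f, p = %.3f (Bonferroni p = %.3f)\n",
                pc$condition[i], pc$df[i], pc$t[i], pc$p[i],
                pc$p_bonferroni[i]))
  invisible(x)
}
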