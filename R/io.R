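# Interchange formats and the end-to-end pipeline. Scores travel as
# UTF-8 CSV with a header row (the schema of the study's deposited
# per-child table), configuration as YAML or plain lists, reports as
# JSON. All outputs echo the seed for provenance.

COHORT_SCHEMA_VERSION <- 1L

#' Load a per-child cohort score CSV
#'
#' Reads a CSV in the deposited-table shape: one row per child, a
#' group column and five score columns (TFS percent-correct and the
#' four CVI single-correct conditions). Column names are mapped
#' through `mapping` when the file uses different headers; group
#' labels are mapped onto RD/TD case-insensitively. Extra columns are
#' kept but ignored by the analysis. Row count, group labels and
#' percentage ranges are validated with structured errors.
#'
#' @param path CSV file path.
#' @param mapping named character vector, `c(canonical = "file_column")`,
#'   for any of child_id, group, tfs_percent, cvi_0st, cvi_1st,
#'   cvi_2st, cvi_4st.
#' @param n_per_group expected group size (NULL disables the check).
#' @return a `cohort_table` with attributes `source_file` and
#'   `mapping`.
#' @export
load_cohort_csv <- function(path, mapping = NULL, n_per_group = 15) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df))
        stop("mapped column '", src, "' (for ", canon,
             ") not present in ", path)
      names(df)[names(df) == src] <- canon
    }
  }
  if (!"child_id" %in% names(df))
    df$child_id <- sprintf("C%02d", seq_len(nrow(df)))
  if ("group" %in% names(df)) {
    g <- toupper(trimws(as.character(df$group)))
    g[g %in% c("1", "GROUP 1", "GROUP1")] <- "RD"
    g[g %in% c("2", "GROUP 2", "GROUP2")] <- "TD"
    df$group <- g
  }
  validate_cohort(df, n_per_group = n_per_group)
}

#' Write a cohort table to CSV
#'
#' @param table a `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Experiment configuration
#'
#' Bundles the stage configurations with a global seed. `cohort`
#' covers the simulated-listener parameters; `stimuli` the TFS trial
#' settings (carried for stimulus export; the score-level simulation
#' is driven by the observer model); `cohort_csv` switches the
#' pipeline to analysis-only mode on an existing score file.
#'
#' @param seed global seed.
#' @param cohort a [cohort_params()].
#' @param stimuli a [trial_config()].
#' @param cohort_csv optional path to a score CSV; when set the
#'   simulation stage is skipped.
#' @param out_dir optional output directory for the cohort CSV and
#'   report JSON.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1, cohort = cohort_params(),
                              stimuli = trial_config(),
                              cohort_csv = NULL, out_dir = NULL) {
  structure(list(schema_version = COHORT_SCHEMA_VERSION, seed = seed,
                 cohort = cohort, stimuli = stimuli,
                 cohort_csv = cohort_csv, out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Unknown schema versions are rejected loudly; omitted blocks fall
#' back to the package defaults.
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ver <- y$schema_version %||% COHORT_SCHEMA_VERSION
  if (ver != COHORT_SCHEMA_VERSION)
    stop("unknown config schema version: ", ver)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$staircase) && !inherits(cohort_args$staircase,
                                                   "staircase_config"))
    cohort_args$staircase <- do.call(staircase_config,
                                     cohort_args$staircase)
  cohort <- do.call(cohort_params, cohort_args)
  stimuli <- do.call(trial_config, y$stimuli %||% list())
  experiment_config(seed = y$seed %||% 1, cohort = cohort,
                    stimuli = stimuli, cohort_csv = y$cohort_csv,
                    out_dir = y$out_dir)
}

#' Run the full pipeline: simulate or load, analyze, report
#'
#' Simulation mode generates a cohort from the configured observer
#' parameters ([generate_cohort()]); analysis-only mode loads an
#' existing score CSV. Either way the cohort goes through
#' [analyze_cohort()] and the statistics are returned (and written,
#' when `out_dir` is set) as a stable JSON-serializable report. The
#' whole run is a pure function of (config, seed).
#'
#' @param config an [experiment_config()] or path to a YAML file.
#' @return list of class `pipeline_report`: `cohort`, `analysis`,
#'   `report` (plain list as serialized), and file paths when written.
#' @export
run_pipeline <- function(config = experiment_config()) {
  if (is.character(config)) config <- read_config_yaml(config)
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(config$cohort_csv)) {
    cohort <- load_cohort_csv(config$cohort_csv)
    mode <- "analysis-only"
  } else {
    cohort <- generate_cohort(config$cohort, seed = config$seed)
    mode <- "simulation"
  }
  an <- analyze_cohort(cohort)
  report <- list(
    schema_version = COHORT_SCHEMA_VERSION,
    mode = mode, seed = config$seed,
    n = as.list(an$n),
    tfs = list(
      shapiro = list(RD = an$normality$RD[c("W", "p")],
                     TD = an$normality$TD[c("W", "p")]),
      t = an$tfs_t[c("t", "df", "p", "mean_a", "mean_b", "sd_a", "sd_b")]),
    cvi = list(
      anova = an$cvi_anova[c("F_between", "df_between", "p_between",
                             "F_within", "df_within", "p_within",
                             "F_interaction", "df_interaction",
                             "p_interaction", "gg_epsilon")],
      per_condition = an$cvi_per_condition,
      significant_group_effect_05 = isTRUE(an$cvi_anova$p_between < 0.05)),
    significant_tfs_group_effect_05 = isTRUE(an$tfs_t$p < 0.05))
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(config$out_dir, "cohort.csv")
    json <- file.path(config$out_dir, "report.json")
    write_cohort_csv(cohort, csv)
    jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- list(cohort_csv = csv, report_json = json)
  }
  structure(list(cohort = cohort, analysis = an, report = report,
                 paths = paths),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline run (%s, seed %s)\n", x$report$mode,
              x$report$seed))
  print(x$analysis)
  invisible(x)
}

#' Write the per-trial log of a staircase run to CSV
#'
#' @param state a `staircase_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_staircase_csv <- function(state, path) {
  stopifnot(inherits(state, "staircase_state"))
  utils::write.csv(state$trial_log, path, row.names = FALSE)
  invisible(path)
}
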