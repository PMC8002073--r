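#' Pipeline configuration
#'
#' Single configuration object for the end-to-end run: input mode
#' (`"synthetic"` generates a cohort from `cohort`; `"files"` reads the CSV
#' tables written by [write_cohort_csvs()]), processing options, and ML
#' options. All randomness flows from the named seeds recorded here; there
#' is no hidden global RNG state.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param paths Named list of file paths `telo`, `controls`, `ca`, `cbc`
#'   (files mode).
#' @param outcome ML outcome: `"mtl"`, `"n_short"` or `"n_long"`.
#' @param ml_config A [boosting_config()]; default chosen per outcome
#'   (depth 7 for MTL, depth 6 for the count outcomes).
#' @param train_fraction,cv_folds,leave_out ML evaluation settings;
#'   `leave_out = 0` skips the leave-patients-out pass.
#' @param split_seed,cv_seed Seeds for the split and fold assignment.
#' @param quantile_type Percentile convention for [baseline_cutoffs()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            cohort = cohort_config(),
                            paths = list(),
                            outcome = c("mtl", "n_short", "n_long"),
                            ml_config = NULL,
                            train_fraction = 0.8,
                            cv_folds = 5L,
                            leave_out = 0L,
                            split_seed = 1L,
                            cv_seed = 1L,
                            quantile_type = 7,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  outcome <- match.arg(outcome)
  if (is.null(ml_config)) {
    ml_config <- if (outcome == "mtl") boosting_config_mtl() else boosting_config_counts()
  }
  if (mode == "files") {
    need <- c("telo", "controls", "ca", "cbc")
    missing_paths <- setdiff(need, names(paths))
    if (length(missing_paths) > 0) {
      abort(paste0("invalid config: files mode needs path(s) ",
                   paste(missing_paths, collapse = ", ")),
            class = "teloRT_config_error")
    }
  }
  structure(
    list(mode = mode, cohort = cohort, paths = paths, outcome = outcome,
         ml_config = ml_config, train_fraction = train_fraction,
         cv_folds = as.integer(cv_folds), leave_out = as.integer(leave_out),
         split_seed = as.integer(split_seed), cv_seed = as.integer(cv_seed),
         quantile_type = quantile_type, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Write a cohort's tables as CSV files
#'
#' @param cohort A `synthetic_cohort` (or a list with the same tables).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    telo = file.path(dir, "telomeres.csv"),
    controls = file.path(dir, "controls.csv"),
    ca = file.path(dir, "aberration_cells.csv"),
    cbc = file.path(dir, "cbc.csv")
  )
  readr::write_csv(cohort$telo, paths[["telo"]])
  readr::write_csv(cohort$controls, paths[["controls"]])
  readr::write_csv(cohort$ca_cells, paths[["ca"]])
  readr::write_csv(cohort$cbc, paths[["cbc"]])
  invisible(paths)
}

#' Read cohort tables from CSV files
#'
#' @param paths Named list/vector with `telo`, `controls`, `ca`, `cbc`.
#' @return List with tables `telo`, `controls`, `ca_cells`, `cbc`.
#' @export
read_cohort_csvs <- function(paths) {
  for (p in unlist(paths[c("telo", "controls", "ca", "cbc")])) {
    if (!file.exists(p)) abort(paste0("missing file: ", p), class = "teloRT_io_error")
  }
  telo <- readr::read_csv(paths[["telo"]], show_col_types = FALSE)
  if (!all(c("patient_id", "timepoint", "telomere_rfi") %in% names(telo))) {
    abort("schema error: telomere table needs patient_id, timepoint, telomere_rfi",
          class = "teloRT_schema_error")
  }
  telo$timepoint <- timepoint_levels(telo$timepoint)
  list(
    telo = telo,
    controls = readr::read_csv(paths[["controls"]], show_col_types = FALSE),
    ca_cells = parse_score_sheet(paths[["ca"]]),
    cbc = readr::read_csv(paths[["cbc"]], show_col_types = FALSE)
  )
}

#' Run the end-to-end pipeline
#'
#' Executes the full analysis flow: inputs (synthetic or files) ->
#' standardization, outlier removal, imputation -> quartile feature
#' engineering -> cohort statistics (repeated-measures ANOVA with Tukey HSD
#' on MTL and on square-root transformed short/long counts; trajectory
#' clustering at k = 2) -> boosted-tree prediction of the chosen 3-month
#' outcome (stratified split, cross-validated MAE, test-set evaluation,
#' optional leave-patients-out) -> chromosome-aberration frequencies. Writes
#' tidy CSV outputs and a machine-readable JSON manifest recording the
#' configuration, seeds, and the row-count chain at every stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all result objects and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- if (config$mode == "synthetic") {
    generate_cohort(config$cohort)
  } else {
    read_cohort_csvs(config$paths)
  }
  theoretical_n <- if (config$mode == "synthetic") {
    config$cohort$n_cells_telo * config$cohort$telomeres_per_cell
  } else {
    4600L
  }

  processed <- process_telo_cohort(inputs$telo, inputs$controls,
                                   theoretical_n = theoretical_n,
                                   seed = config$split_seed)
  summaries <- summarize_telo_cohort(processed)
  features <- length_class_table(processed, type = config$quantile_type)
  summary_table <- left_join(summaries, features,
                             by = c("patient_id", "timepoint"))

  mat_mtl <- trajectory_matrix(summary_table, "mtl")
  stats_out <- list(
    anova_mtl = repeated_measures_anova(mat_mtl),
    anova_short = repeated_measures_anova(trajectory_matrix(summary_table, "n_short"),
                                          sqrt_transform = TRUE),
    anova_long = repeated_measures_anova(trajectory_matrix(summary_table, "n_long"),
                                         sqrt_transform = TRUE),
    clusters_mtl = cluster_patients(mat_mtl, k = 2)
  )

  outcome_col <- config$outcome
  targets <- summary_table %>%
    filter(.data$timepoint == "three_month_post") %>%
    select("patient_id", all_of(outcome_col)) %>%
    rename(target = all_of(outcome_col))
  ml_rows <- build_long_dataset(processed, targets)
  split <- stratified_shuffle_split(ml_rows, config$train_fraction,
                                    seed = config$split_seed)
  model <- fit_boosted_regressor(split$train, config$ml_config)
  cv <- cross_validate_mae(split$train, config$ml_config, k = config$cv_folds,
                           seed = config$cv_seed)
  evaluation <- evaluate_predictions(model, split$test)
  lpo <- if (config$leave_out > 0) {
    leave_patients_out(ml_rows, k_out = config$leave_out, config$ml_config,
                       train_fraction = config$train_fraction,
                       split_seed = config$split_seed)
  } else NULL

  ca_freq <- aberration_frequency_table(inputs$ca_cells)

  manifest <- list(
    mode = config$mode,
    outcome = config$outcome,
    seeds = list(
      cohort = if (config$mode == "synthetic") config$cohort$seed else NULL,
      split = config$split_seed, cv = config$cv_seed,
      model = config$ml_config$seed
    ),
    counts = list(
      telo_values_raw = nrow(inputs$telo),
      telo_values_processed = nrow(processed),
      telo_samples = nrow(summaries),
      values_per_sample = theoretical_n,
      patients_in_matrix = nrow(mat_mtl),
      ml_rows = nrow(ml_rows),
      ml_train = nrow(split$train),
      ml_test = nrow(split$test),
      ca_cells = nrow(inputs$ca_cells),
      ca_samples = nrow(ca_freq)
    ),
    metrics = list(
      anova_mtl_p = stats_out$anova_mtl$p_value,
      cv_mae_mean = cv$mean, cv_mae_sd = cv$sd,
      test_mae = evaluation$mae,
      r_squared_rows = evaluation$r_squared_rows,
      r_squared_patients = evaluation$r_squared_patients
    )
  )
  stopifnot(manifest$counts$ml_train + manifest$counts$ml_test == manifest$counts$ml_rows)

  results <- list(
    inputs = inputs, processed = processed, summary_table = summary_table,
    stats = stats_out, ml_rows = ml_rows, split = split, model = model,
    cv = cv, evaluation = evaluation, leave_patients_out = lpo,
    ca_frequencies = ca_freq, manifest = manifest
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(summary_table, file.path(config$out_dir, "sample_summaries.csv"))
    readr::write_csv(ca_freq, file.path(config$out_dir, "aberration_frequencies.csv"))
    readr::write_csv(evaluation$per_patient %>%
                       rename(y_pred_mean = "y_pred"),
                     file.path(config$out_dir, "ml_per_patient_predictions.csv"))
    if (!is.null(lpo)) {
      readr::write_csv(lpo, file.path(config$out_dir, "leave_patients_out.csv"))
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}
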