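#' Gradient-boosting configuration
#'
#' Contract for the boosted-tree regressors: squared-error objective,
#' `n_estimators` rounds of depth-`max_depth` trees at the given learning
#' rate, deterministic given `seed`. Presets mirror the study's tuned
#' settings: [boosting_config_mtl()] (200 trees, depth 7, eta 0.2, seed 1)
#' for mean-telomere-length outcomes, [boosting_config_counts()] (depth 6)
#' for short/long telomere counts, and [boosting_config_ca()] (200 trees,
#' depth 15, eta 0.1, seed 0) for the per-cell chromosome-aberration models.
#'
#' @param n_estimators Number of boosting rounds (>= 1).
#' @param max_depth Maximum tree depth (>= 1).
#' @param learning_rate Shrinkage (> 0).
#' @param seed Integer seed for the learner.
#' @return List of class `boosting_config`.
#' @export
boosting_config <- function(n_estimators = 200L, max_depth = 7L,
                            learning_rate = 0.2, seed = 1L) {
  if (n_estimators < 1 || max_depth < 1 || learning_rate <= 0) {
    abort("configuration error: n_estimators, max_depth >= 1 and learning_rate > 0 required")
  }
  structure(
    list(n_estimators = as.integer(n_estimators), max_depth = as.integer(max_depth),
         learning_rate = learning_rate, objective = "reg:squarederror",
         seed = as.integer(seed)),
    class = "boosting_config"
  )
}

#' @rdname boosting_config
#' @export
boosting_config_mtl <- function() boosting_config(200L, 7L, 0.2, 1L)

#' @rdname boosting_config
#' @export
boosting_config_counts <- function() boosting_config(200L, 6L, 0.2, 1L)

#' @rdname boosting_config
#' @export
boosting_config_ca <- function() boosting_config(200L, 15L, 0.1, 0L)

#' Reshape processed pre-therapy telomere samples into a long ML dataset
#'
#' One row per individual pre-therapy telomere measurement, with the
#' measurement's sample of origin encoded 0 (non-irradiated) / 1 (4 Gy in
#' vitro) and the patient's single 3-month outcome attached to every row.
#' With 14 complete patients at 4600 measurements per sample this yields
#' 14 x 2 x 4600 = 128,800 rows. Patients missing either pre-therapy sample
#' or the outcome are excluded with a warning.
#'
#' @param processed Long tibble from [process_telo_cohort()] (imputed to the
#'   theoretical count).
#' @param targets Tibble `patient_id`, `target` — one 3-month outcome per
#'   patient (MTL, n_short or n_long; one model per outcome).
#' @return Tibble: `patient_id`, `telomere_rfi`, `origin_label`, `target`.
#' @export
build_long_dataset <- function(processed, targets) {
  pre <- processed %>%
    filter(.data$timepoint %in% c("baseline_nonirr", "baseline_4gy"))
  have_both <- pre %>%
    distinct(.data$patient_id, .data$timepoint) %>%
    dplyr::count(.data$patient_id) %>%
    filter(.data$n == 2) %>%
    pull(.data$patient_id)
  eligible <- intersect(have_both, targets$patient_id[!is.na(targets$target)])
  dropped <- setdiff(unique(pre$patient_id), eligible)
  if (length(dropped) > 0) {
    warn(paste0("excluding patient(s) without both pre-therapy samples and a target: ",
                paste(dropped, collapse = ", ")))
  }
  pre %>%
    filter(.data$patient_id %in% eligible) %>%
    mutate(origin_label = as.integer(.data$timepoint == "baseline_4gy")) %>%
    left_join(targets, by = "patient_id") %>%
    select("patient_id", "telomere_rfi", "origin_label", "target")
}

#' Stratified shuffle split
#'
#' Rows are shuffled and split within each patient x origin stratum so the
#' training set holds `train_fraction` of every stratum (round half up,
#' residual rows to training), guaranteeing equivalent representation of
#' each patient's non-irradiated and irradiated measurements on both sides.
#' Both parts are then globally reshuffled. Deterministic given `seed`.
#'
#' @param rows Tibble with `patient_id` and `origin_label` columns.
#' @param train_fraction Fraction in (0, 1) (default 0.8).
#' @param seed Integer seed.
#' @return List of class `split_dataset`: `train`, `test`, and
#'   `stratification` (per-stratum train/test counts).
#' @export
stratified_shuffle_split <- function(rows, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("configuration error: train_fraction must lie in (0, 1)")
  }
  strata <- paste(rows$patient_id, rows$origin_label, sep = "|")
  tab <- table(strata)
  if (any(tab < 2)) abort("stratification error: every patient x origin stratum needs >= 2 rows")
  set.seed(seed)
  train_idx <- integer(0)
  for (s in names(tab)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    n_train <- round_half_up(train_fraction * length(idx))
    train_idx <- c(train_idx, idx[seq_len(n_train)])
  }
  is_train <- rep(FALSE, nrow(rows))
  is_train[train_idx] <- TRUE
  train <- rows[is_train, , drop = FALSE]
  test <- rows[!is_train, , drop = FALSE]
  train <- train[sample.int(nrow(train)), , drop = FALSE]
  test <- test[sample.int(nrow(test)), , drop = FALSE]
  strat <- tibble(
    stratum = names(tab),
    n_total = as.integer(tab),
    n_train = vapply(names(tab), function(s) sum(strata[is_train] == s), integer(1))
  ) %>% mutate(n_test = .data$n_total - .data$n_train)
  structure(list(train = train, test = test, stratification = strat),
            class = "split_dataset")
}

ml_feature_matrix <- function(rows, feature_cols) {
  m <- as.matrix(rows[, feature_cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Fit a gradient-boosted tree regressor
#'
#' Trains squared-error boosted trees on the feature columns only — patient
#' IDs are never presented to the learner. Training is single-threaded and
#' deterministic given `config$seed`.
#'
#' @param train_rows Tibble of training rows.
#' @param config A [boosting_config()].
#' @param feature_cols Feature column names (default the telomere value and
#'   origin label; per-cell aberration models pass their count columns).
#' @param target_col Target column name.
#' @return List of class `boosted_model`: the fitted booster, feature names
#'   and the config.
#' @export
fit_boosted_regressor <- function(train_rows, config,
                                  feature_cols = c("telomere_rfi", "origin_label"),
                                  target_col = "target") {
  if (nrow(train_rows) == 0) abort("empty training set")
  stopifnot(inherits(config, "boosting_config"))
  if ("patient_id" %in% feature_cols) abort("leakage guard: patient_id must not be a feature")
  dtrain <- xgboost::xgb.DMatrix(
    ml_feature_matrix(train_rows, feature_cols),
    label = train_rows[[target_col]], nthread = 1
  )
  booster <- xgboost::xgb.train(
    params = xgboost::xgb.params(
      max_depth = config$max_depth,
      learning_rate = config$learning_rate,
      objective = config$objective,
      seed = config$seed,
      nthread = 1
    ),
    data = dtrain, nrounds = config$n_estimators, verbose = 0
  )
  structure(list(booster = booster, feature_cols = feature_cols,
                 target_col = target_col, config = config),
            class = "boosted_model")
}

#' Predict from a fitted boosted model
#'
#' @param object A `boosted_model`.
#' @param newdata Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.boosted_model <- function(object, newdata, ...) {
  as.numeric(predict(object$booster, ml_feature_matrix(newdata, object$feature_cols)))
}

#' Evaluate predictions on a test set
#'
#' Reports mean absolute error and two coefficients of determination: over
#' individual rows, and over per-patient averaged predictions (each
#' patient's row predictions are averaged before comparison with the
#' patient's single true outcome — the study's headline metric).
#'
#' @param model A `boosted_model`.
#' @param test_rows Tibble with the feature columns, `patient_id`, and true
#'   targets.
#' @return List: `mae`, `r_squared_rows`, `r_squared_patients`,
#'   `per_patient` (tibble of averaged prediction and truth per patient).
#' @export
evaluate_predictions <- function(model, test_rows) {
  y <- test_rows[[model$target_col]]
  pred <- predict(model, test_rows)
  per_patient <- tibble(patient_id = test_rows$patient_id, y = y, pred = pred) %>%
    group_by(.data$patient_id) %>%
    summarise(y_true = .data$y[1], y_pred = mean(.data$pred), .groups = "drop")
  if (nrow(per_patient) < 2) {
    abort("per-patient r-squared undefined with a single patient in the test set")
  }
  list(
    mae = mean_abs_error(y, pred),
    r_squared_rows = r_squared(y, pred),
    r_squared_patients = r_squared(per_patient$y_true, per_patient$y_pred),
    per_patient = per_patient
  )
}

#' K-fold cross-validated mean absolute error
#'
#' Shuffles the training rows into `k` folds (simple partition; folds are
#' not patient-stratified) and reports each held-out fold's MAE with its
#' mean and SD — the study's check that the learner is not overfitting to
#' portions of the training data.
#'
#' @param train_rows Training rows.
#' @param config A [boosting_config()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param feature_cols,target_col As in [fit_boosted_regressor()].
#' @return List: `fold_maes` (length `k`), `mean`, `sd`.
#' @export
cross_validate_mae <- function(train_rows, config, k = 5L, seed = 1L,
                               feature_cols = c("telomere_rfi", "origin_label"),
                               target_col = "target") {
  n <- nrow(train_rows)
  if (k < 2) abort("configuration error: k must be >= 2")
  if (k > n) abort("configuration error: more folds than rows")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  maes <- vapply(seq_len(k), function(f) {
    fit <- fit_boosted_regressor(train_rows[fold != f, , drop = FALSE], config,
                                 feature_cols, target_col)
    held <- train_rows[fold == f, , drop = FALSE]
    mean_abs_error(held[[target_col]], predict(fit, held))
  }, numeric(1))
  list(fold_maes = maes, mean = mean(maes), sd = sd(maes))
}

#' Leave-patients-out generalizability evaluation
#'
#' Probes generalization to entirely new individuals: after one global
#' stratified 80/20 split, models are retrained with one (or `k_out`) whole
#' patient(s) removed from training; the held-out patients' rows are moved
#' into the evaluation set, which therefore contains every patient including
#' those the model never saw. With `k_out = 1` there is one iteration per
#' patient; with `k_out > 1` patients are shuffled (seeded) and partitioned
#' into disjoint groups of size `k_out`.
#'
#' @param rows Full long dataset from [build_long_dataset()].
#' @param k_out Number of patients held out per iteration (>= 1, < number of
#'   patients).
#' @param config A [boosting_config()].
#' @param train_fraction,split_seed Passed to [stratified_shuffle_split()].
#' @param feature_cols,target_col As in [fit_boosted_regressor()].
#' @return Tibble with one row per iteration: `iteration`, `held_out`
#'   (comma-joined patient IDs), `mae`, `r_squared_rows`,
#'   `r_squared_patients`, and `held_out_error` (absolute error of the
#'   held-out patients' averaged predictions).
#' @export
leave_patients_out <- function(rows, k_out = 1L, config,
                               train_fraction = 0.8, split_seed = 1L,
                               feature_cols = c("telomere_rfi", "origin_label"),
                               target_col = "target") {
  patients <- sort(unique(rows$patient_id))
  if (k_out < 1 || k_out >= length(patients)) {
    abort("configuration error: k_out must be >= 1 and < number of patients")
  }
  split <- stratified_shuffle_split(rows, train_fraction, seed = split_seed)
  if (k_out == 1) {
    groups <- as.list(patients)
  } else {
    set.seed(seed_stream(split_seed, k_out, 0, 7L))
    shuffled <- patients[sample.int(length(patients))]
    groups <- split(shuffled, ceiling(seq_along(shuffled) / k_out))
  }
  res <- lapply(seq_along(groups), function(i) {
    held <- groups[[i]]
    train <- split$train %>% filter(!.data$patient_id %in% held)
    test <- dplyr::bind_rows(
      split$test,
      split$train %>% filter(.data$patient_id %in% held)
    )
    stopifnot(length(intersect(unique(train$patient_id), held)) == 0)
    fit <- fit_boosted_regressor(train, config, feature_cols, target_col)
    ev <- evaluate_predictions(fit, test)
    held_pp <- ev$per_patient %>% filter(.data$patient_id %in% held)
    tibble(
      iteration = i,
      held_out = paste(held, collapse = ","),
      mae = ev$mae,
      r_squared_rows = ev$r_squared_rows,
      r_squared_patients = ev$r_squared_patients,
      held_out_error = mean(abs(held_pp$y_true - held_pp$y_pred))
    )
  })
  dplyr::bind_rows(res)
}

#' Randomized hyperparameter search
#'
#' Draws `n_draws` configurations uniformly from the supplied space and
#' returns the one with the best (lowest) cross-validated mean MAE.
#' Deterministic given `seed`.
#'
#' @param rows Training rows.
#' @param search_space Named list of candidate values for `n_estimators`,
#'   `max_depth` and `learning_rate`.
#' @param n_draws Number of random draws.
#' @param seed Integer seed (also used as the learner seed of each draw).
#' @param k CV folds per draw.
#' @param feature_cols,target_col As in [fit_boosted_regressor()].
#' @return The winning [boosting_config()], with the search trace attached
#'   as attribute `"trace"`.
#' @export
random_hyperparameter_search <- function(rows, search_space, n_draws = 10L,
                                         seed = 1L, k = 5L,
                                         feature_cols = c("telomere_rfi", "origin_label"),
                                         target_col = "target") {
  if (length(search_space) == 0) abort("configuration error: empty search space")
  space <- list(
    n_estimators = search_space$n_estimators %||% 200L,
    max_depth = search_space$max_depth %||% 7L,
    learning_rate = search_space$learning_rate %||% 0.2
  )
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(i) {
    boosting_config(
      n_estimators = space$n_estimators[sample.int(length(space$n_estimators), 1)],
      max_depth = space$max_depth[sample.int(length(space$max_depth), 1)],
      learning_rate = space$learning_rate[sample.int(length(space$learning_rate), 1)],
      seed = seed
    )
  })
  scores <- vapply(seq_along(draws), function(i) {
    cross_validate_mae(rows, draws[[i]], k = k,
                       seed = seed_stream(seed, i, 0, 8L),
                       feature_cols = feature_cols, target_col = target_col)$mean
  }, numeric(1))
  best <- draws[[which.min(scores)]]
  attr(best, "trace") <- tibble(
    draw = seq_along(draws),
    n_estimators = vapply(draws, `[[`, integer(1), "n_estimators"),
    max_depth = vapply(draws, `[[`, integer(1), "max_depth"),
    learning_rate = vapply(draws, `[[`, numeric(1), "learning_rate"),
    cv_mae = scores
  )
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
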