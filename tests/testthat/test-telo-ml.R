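test_that("the long dataset has one row per pre-therapy measurement", {
  coh <- generate_cohort(small_config(seed = 2))
  proc <- process_telo_cohort(coh$telo, coh$controls, theoretical_n = 100, seed = 2)
  summ <- summarize_telo_cohort(proc)
  targets <- dplyr::transmute(
    dplyr::filter(summ, timepoint == "three_month_post"), patient_id, target = mtl)
  expect_warning(rows <- build_long_dataset(proc, targets), "excluding patient")
  expect_equal(nrow(rows), 5 * 2 * 100)           # 5 complete patients
  expect_false(5 %in% rows$patient_id)            # the missing-sample patient
  # every row of a patient shares that patient's target; origin is 0/1 by sample
  per <- dplyr::summarise(dplyr::group_by(rows, patient_id),
                          one_target = dplyr::n_distinct(target),
                          n0 = sum(origin_label == 0), n1 = sum(origin_label == 1))
  expect_true(all(per$one_target == 1))
  expect_true(all(per$n0 == 100 & per$n1 == 100))

  # single patient, 5 telomeres per sample -> 10 rows, one shared target
  tiny_proc <- tibble::tibble(
    patient_id = 1,
    timepoint = rep(c("baseline_nonirr", "baseline_4gy"), each = 5),
    telomere_rfi = 1:10
  )
  tiny <- build_long_dataset(tiny_proc, tibble::tibble(patient_id = 1, target = 42))
  expect_equal(nrow(tiny), 10)
  expect_equal(unique(tiny$target), 42)
  expect_equal(tiny$origin_label, rep(0:1, each = 5))
})

test_that("stratified shuffle split balances every patient x origin stratum", {
  rows <- toy_rows(n_patients = 4, m = 30)
  sp <- stratified_shuffle_split(rows, 0.8, seed = 5)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(rows))
  expect_equal(nrow(sp$train), 0.8 * nrow(rows))
  expect_true(all(sp$stratification$n_train == 24))
  expect_true(all(sp$stratification$n_test == 6))

  # deterministic given seed; different seeds reshuffle but keep stratum counts
  sp2 <- stratified_shuffle_split(rows, 0.8, seed = 5)
  expect_identical(sp$train, sp2$train)
  sp3 <- stratified_shuffle_split(rows, 0.8, seed = 6)
  expect_false(identical(sp$train$telomere_rfi, sp3$train$telomere_rfi))
  expect_equal(sp$stratification$n_train, sp3$stratification$n_train)

  # rounding: a 5-row stratum at 0.5 rounds half up to 3 training rows
  odd <- tibble::tibble(patient_id = 1, origin_label = 0, telomere_rfi = 1:5,
                        target = 0)
  sp_odd <- stratified_shuffle_split(odd, 0.5, seed = 1)
  expect_equal(nrow(sp_odd$train), 3)
  expect_error(stratified_shuffle_split(rows, 0), "train_fraction")
  expect_error(stratified_shuffle_split(rows[1, ], 0.8), "stratification error")
})

test_that("boosted regressor honours its contract on degenerate targets", {
  rows <- toy_rows()
  rows$target <- 7
  fit <- fit_boosted_regressor(rows, boosting_config(50, 3, 0.3, seed = 1))
  expect_lt(max(abs(predict(fit, rows) - 7)), 1e-6)

  # determinism given the config seed
  rows2 <- toy_rows()
  f1 <- fit_boosted_regressor(rows2, boosting_config_mtl())
  f2 <- fit_boosted_regressor(rows2, boosting_config_mtl())
  expect_identical(predict(f1, rows2), predict(f2, rows2))

  expect_error(fit_boosted_regressor(rows[0, ], boosting_config_mtl()), "empty")
  expect_error(
    fit_boosted_regressor(rows, boosting_config_mtl(),
                          feature_cols = c("patient_id", "telomere_rfi")),
    "leakage"
  )
  # the study's tuned defaults
  expect_equal(unclass(boosting_config_mtl())[c("n_estimators", "max_depth", "learning_rate", "objective")],
               list(n_estimators = 200L, max_depth = 7L, learning_rate = 0.2,
                    objective = "reg:squarederror"))
  expect_equal(boosting_config_counts()$max_depth, 6L)
  expect_equal(unclass(boosting_config_ca())[c("n_estimators", "max_depth", "learning_rate", "seed")],
               list(n_estimators = 200L, max_depth = 15L, learning_rate = 0.1, seed = 0L))
})

test_that("cross-validated MAE behaves like its definition", {
  # target perfectly determined by the feature -> fold MAEs ~ 0
  rows <- toy_rows(m = 50)
  rows$target <- rows$telomere_rfi
  cv <- cross_validate_mae(rows, boosting_config(100, 4, 0.3, 1), k = 5, seed = 2)
  expect_length(cv$fold_maes, 5)
  expect_lt(cv$mean, 0.5)

  # the MAE metric itself, hand-checkable on 6 rows against a constant predictor:
  # a depth-limited model on a featureless problem predicts the fold-train mean
  y <- c(1, 2, 3, 10, 11, 12)
  expect_equal(mean(abs(y - mean(y))), 4.5)  # hand arithmetic for the oracle below
  hand <- tibble::tibble(patient_id = 1, telomere_rfi = 0, origin_label = 0, target = y)
  fit <- fit_boosted_regressor(hand, boosting_config(500, 1, 0.3, 1))
  expect_equal(mean(abs(y - predict(fit, hand))), 4.5, tolerance = 1e-3)

  expect_error(cross_validate_mae(rows, boosting_config_mtl(), k = 1), "k must be")
  expect_error(cross_validate_mae(rows[1:3, ], boosting_config_mtl(), k = 5), "more folds")
})

test_that("evaluation reports row-level and per-patient-averaged metrics", {
  rows <- toy_rows(m = 60)
  sp <- stratified_shuffle_split(rows, 0.8, seed = 1)
  fit <- fit_boosted_regressor(sp$train, boosting_config(100, 4, 0.3, 1))
  ev <- evaluate_predictions(fit, sp$test)
  pred <- predict(fit, sp$test)
  y <- sp$test$target
  # brute-force closed forms
  expect_equal(ev$mae, mean(abs(y - pred)), tolerance = 1e-12)
  expect_equal(ev$r_squared_rows,
               1 - sum((y - pred)^2) / sum((y - mean(y))^2), tolerance = 1e-12)
  pp <- ev$per_patient
  expect_equal(ev$r_squared_patients,
               1 - sum((pp$y_true - pp$y_pred)^2) /
                 sum((pp$y_true - mean(pp$y_true))^2), tolerance = 1e-12)
  # per-patient averaging: predictions {1,3} for one patient with truth 2
  # leave a zero residual
  expect_equal(mean(c(1, 3)) - 2, 0)
  one_patient <- sp$test[sp$test$patient_id == 1, ]
  expect_equal(pp$y_pred[pp$patient_id == 1], mean(pred[sp$test$patient_id == 1]))

  solo <- rows[rows$patient_id == 1, ]
  expect_error(evaluate_predictions(fit, solo), "single patient")
})

test_that("leave-patients-out never trains on held-out patients", {
  rows <- toy_rows(n_patients = 5, m = 40)
  lpo <- leave_patients_out(rows, 1, boosting_config(50, 4, 0.3, 1), split_seed = 2)
  expect_equal(nrow(lpo), 5)                      # one iteration per patient
  expect_equal(sort(lpo$held_out), as.character(1:5))
  expect_true(all(is.finite(lpo$r_squared_patients)))

  lpo2 <- leave_patients_out(rows, 2, boosting_config(50, 4, 0.3, 1), split_seed = 2)
  expect_equal(nrow(lpo2), 3)                     # ceiling(5 / 2) disjoint groups
  held <- unlist(strsplit(lpo2$held_out, ","))
  expect_equal(sort(as.integer(held)), 1:5)       # every patient held out once

  expect_error(leave_patients_out(rows, 5, boosting_config_mtl()), "k_out")
})

test_that("randomized hyperparameter search picks capacity that CV supports", {
  rows <- toy_rows(n_patients = 4, m = 40, seed = 3)
  # strongly nonlinear target: interaction of value-range and origin (XOR-like),
  # invisible to depth-1 stumps
  rows$target <- as.numeric(xor(rows$telomere_rfi > 110, rows$origin_label == 1)) * 10
  space <- list(n_estimators = 100L, max_depth = c(1L, 7L), learning_rate = 0.3)
  best <- random_hyperparameter_search(rows, space, n_draws = 6, seed = 4, k = 3)
  expect_equal(best$max_depth, 7L)

  single <- random_hyperparameter_search(rows, list(n_estimators = 77L,
                                                    max_depth = 3L,
                                                    learning_rate = 0.2),
                                         n_draws = 2, seed = 1, k = 3)
  expect_equal(single$n_estimators, 77L)
  best2 <- random_hyperparameter_search(rows, space, n_draws = 6, seed = 4, k = 3)
  expect_equal(unclass(best)[1:4], unclass(best2)[1:4])  # deterministic given seed
})
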