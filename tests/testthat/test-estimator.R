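test_that("class weights are inverse-frequency with unit mean", {
  # imbalance matching the published cohort: 10,982 low / 622 high windows
  y <- c(rep(10, 10982), rep(25, 622))
  w <- compute_class_weights(y)
  w_hi <- unique(w[y >= 20])
  w_lo <- unique(w[y < 20])
  expect_equal(w_hi / w_lo, 10982 / 622, tolerance = 1e-12)
  expect_equal(mean(w), 1, tolerance = 1e-12)

  # balanced classes: all weights 1
  expect_equal(compute_class_weights(c(10, 15, 22, 30)), rep(1, 4))

  # unit mean for arbitrary imbalance
  set.seed(2)
  y2 <- runif(501, 0, 40)
  expect_equal(mean(compute_class_weights(y2)), 1, tolerance = 1e-12)

  expect_warning(w1 <- compute_class_weights(c(5, 10, 15)), "one ICP class")
  expect_equal(w1, rep(1, 3))
  expect_error(compute_class_weights(numeric(0)), "empty")
})

test_that("patient splits are 80/20, disjoint, covering, reproducible", {
  pats <- sprintf("P%02d", 1:10)
  plan <- make_patient_splits(pats, n_splits = 10, seed = 4)
  expect_length(plan, 10)
  for (s in plan) {
    expect_length(s$train, 8)
    expect_length(s$test, 2)
    expect_length(intersect(s$train, s$test), 0)
  }
  # every patient appears in at least one test set
  tested <- unique(unlist(lapply(plan, `[[`, "test")))
  expect_setequal(tested, pats)

  plan2 <- make_patient_splits(pats, n_splits = 10, seed = 4)
  expect_identical(plan, plan2)

  expect_error(make_patient_splits(sprintf("P%d", 1:4)), "too few")
})

test_that("group k-fold mode partitions each patient into one test fold", {
  pats <- sprintf("P%02d", 1:20)
  plan <- make_patient_splits(pats, n_splits = 10, seed = 1,
                              method = "group_kfold")
  test_sets <- lapply(plan, `[[`, "test")
  expect_setequal(unlist(test_sets), pats)
  expect_equal(sum(lengths(test_sets)), 20)  # each patient tests exactly once
  for (s in plan) expect_length(intersect(s$train, s$test), 0)
})

test_that("median-of-folds prediction matches its definition", {
  ts <- toy_training_set(n_patients = 6, windows_per_patient = 40)
  cfg <- model_config(n_trees = 60, learning_rate = 0.1,
                      min_samples_leaf = 10, n_splits = 10, seed = 9,
                      n_landmarks = 120)
  bundle <- suppressWarnings(train_ensemble(ts$features, ts$pulses, cfg))
  expect_length(bundle$fold_models, 10)

  preds <- predict_eicp(bundle, ts$features, ts$pulses)
  fold_cols <- paste0("fold_", 1:10)
  fold_mat <- as.matrix(preds[, fold_cols])
  # median = mean of the two central order statistics for 10 folds
  manual <- apply(fold_mat, 1, function(v) mean(sort(v)[5:6]))
  expect_equal(preds$eicp_mmHg, manual, tolerance = 1e-12)
  expect_true(all(preds$eicp_mmHg >= apply(fold_mat, 1, min) - 1e-12))
  expect_true(all(preds$eicp_mmHg <= apply(fold_mat, 1, max) + 1e-12))

  # permuting the fold models leaves every median unchanged
  shuffled <- bundle
  perm <- c(7, 2, 9, 4, 10, 1, 3, 8, 5, 6)
  shuffled$fold_models <- bundle$fold_models[perm]
  shuffled$fold_features <- bundle$fold_features[perm]
  shuffled$fold_embeddings <- bundle$fold_embeddings[perm]
  preds_sh <- predict_eicp(shuffled, ts$features, ts$pulses)
  expect_equal(preds_sh$eicp_mmHg, preds$eicp_mmHg, tolerance = 1e-12)

  # signature mismatch is refused
  bad <- ts$features
  names(bad)[names(bad) == "p2p1"] <- "renamed"
  expect_error(predict_eicp(bundle, bad, ts$pulses), "signature")
})

test_that("train/test patients never overlap in any fitted bundle", {
  ts <- toy_training_set(n_patients = 7, windows_per_patient = 30, seed = 3)
  cfg <- model_config(n_trees = 40, learning_rate = 0.1,
                      min_samples_leaf = 10, seed = 2, n_landmarks = 100)
  bundle <- suppressWarnings(train_ensemble(ts$features, ts$pulses, cfg))
  for (s in bundle$splits) {
    expect_length(intersect(s$train, s$test), 0)
  }
  # held-out predictions only ever come from that split's test patients
  for (i in seq_along(bundle$splits)) {
    rows <- bundle$cv_predictions[bundle$cv_predictions$fold == i, ]
    expect_true(all(rows$patient_id %in% bundle$splits[[i]]$test))
  }
})

test_that("training validates its inputs", {
  ts <- toy_training_set(n_patients = 6, windows_per_patient = 40)
  cfg <- model_config(n_trees = 20, seed = 1)
  bad <- ts$features
  bad$p2p1[3] <- NA
  expect_error(train_ensemble(bad, ts$pulses, cfg), "p2p1")
  expect_error(train_ensemble(ts$features[1:50, ], ts$pulses[1:50, ], cfg),
               "200 windows")
})

test_that("noise-free targets are recovered on held-out patients", {
  # eps_sd = 0 and no patient offset: morphology determines ICP exactly,
  # so held-out rank correlation must be high
  ts <- toy_training_set(n_patients = 8, windows_per_patient = 40,
                         seed = 11, u_sd = 0, eps_sd = 0)
  cfg <- model_config(n_trees = 300, learning_rate = 0.1,
                      min_samples_leaf = 5, seed = 5, n_landmarks = 150)
  bundle <- suppressWarnings(train_ensemble(ts$features, ts$pulses, cfg))
  cv <- bundle$cv_predictions
  rho <- spearman_correlation(cv$reference_icp_mmHg, cv$eicp_mmHg)$rho
  expect_gte(rho, 0.9)
})

test_that("up-weighting the rare high class improves its accuracy", {
  # directional check: with weights, MAE restricted to >= 20 mmHg windows
  # is no worse than without
  ts <- toy_training_set(n_patients = 10, windows_per_patient = 60,
                         seed = 21, u_sd = 0, eps_sd = 1,
                         r_range = c(0.8, 2.2))
  cfg_w <- model_config(n_trees = 200, learning_rate = 0.1,
                        min_samples_leaf = 5, seed = 5, n_landmarks = 100)
  bundle_w <- suppressWarnings(train_ensemble(ts$features, ts$pulses, cfg_w))

  cfg_u <- cfg_w
  cfg_u$hi_threshold_mmHg <- Inf  # one class: unit weights
  bundle_u <- suppressWarnings(train_ensemble(ts$features, ts$pulses, cfg_u))

  hi_mae <- function(b) {
    cv <- b$cv_predictions
    hi <- cv$reference_icp_mmHg >= 20
    mean(abs(cv$eicp_mmHg[hi] - cv$reference_icp_mmHg[hi]))
  }
  expect_lte(hi_mae(bundle_w), hi_mae(bundle_u) * 1.05)
})

test_that("model bundles survive a save/load round trip", {
  ts <- toy_training_set(n_patients = 5, windows_per_patient = 40, seed = 8)
  cfg <- model_config(n_trees = 30, learning_rate = 0.1,
                      min_samples_leaf = 10, n_splits = 5, seed = 7,
                      n_landmarks = 100)
  bundle <- suppressWarnings(train_ensemble(ts$features, ts$pulses, cfg))
  dir <- file.path(tempdir(), "bundle_rt")
  save_model_bundle(bundle, dir)
  back <- load_model_bundle(dir)
  p1 <- predict_eicp(bundle, ts$features, ts$pulses)
  p2 <- predict_eicp(back, ts$features, ts$pulses)
  expect_equal(p2$eicp_mmHg, p1$eicp_mmHg, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
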