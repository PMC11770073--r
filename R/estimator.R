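#' Model configuration for the eICP regressor
#'
#' Defaults follow the published training recipe: a histogram-binned
#' gradient-boosted tree regressor with 4000 trees, maximum depth 15, L2
#' regularization 0.5, at most 50 leaf nodes, at least 80 samples per leaf,
#' learning rate 0.005 and 255 histogram bins; 10 patient-separated splits
#' with an 80/20 allocation; intracranial hypertension threshold 20 mmHg.
#'
#' @param n_trees Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param l2_regularization L2 penalty on leaf values.
#' @param max_leaf_nodes Maximum leaves per tree.
#' @param min_samples_leaf Minimum samples per leaf.
#' @param learning_rate Shrinkage in (0,1).
#' @param n_histogram_bins Histogram bins for split finding.
#' @param grid Named list of hyperparameter vectors searched when grid
#'   search is requested (`n_trees`, `max_depth`).
#' @param hi_threshold_mmHg Class boundary for the weighting scheme.
#' @param n_splits Number of cross-validation splits.
#' @param train_fraction Fraction of patients allocated to training.
#' @param split_method `"shuffle"` (default, seeded 80/20 group shuffles) or
#'   `"group_kfold"` (strict patient-level k-fold).
#' @param n_neighbors,n_components,n_landmarks Isomap embedding settings.
#' @param k_features,redundancy_threshold,min_target_rho Feature-selection
#'   settings.
#' @param seed Integer seed controlling splits and landmark choice.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_trees = 4000, max_depth = 15,
                         l2_regularization = 0.5, max_leaf_nodes = 50,
                         min_samples_leaf = 80, learning_rate = 0.005,
                         n_histogram_bins = 255,
                         grid = list(n_trees = c(1000, 2000, 4000),
                                     max_depth = c(5, 10, 15)),
                         hi_threshold_mmHg = 20, n_splits = 10,
                         train_fraction = 0.8,
                         split_method = c("shuffle", "group_kfold"),
                         n_neighbors = 10, n_components = 25,
                         n_landmarks = 500,
                         k_features = 15, redundancy_threshold = 0.9,
                         min_target_rho = 0.05, seed = 1) {
  split_method <- match.arg(split_method)
  stopifnot(n_trees > 0, max_depth > 0, max_leaf_nodes > 0,
            min_samples_leaf > 0, n_histogram_bins > 0, n_splits > 0)
  if (learning_rate <= 0 || learning_rate >= 1) {
    stop("learning_rate must lie in (0, 1)")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  structure(as.list(environment()), class = "model_config")
}

#' Inverse-frequency class weights for imbalanced ICP targets
#'
#' Two classes split at `hi_threshold`: below (normal) and at-or-above
#' (intracranial hypertension). Each sample in class `c` receives
#' `w_c = N / (2 * N_c)`, so rare high-ICP windows weigh more while the mean
#' sample weight stays exactly 1. With a single represented class all
#' weights are 1 and a warning is emitted.
#'
#' @param targets ICP values, mmHg.
#' @param hi_threshold Class boundary (default 20 mmHg).
#' @return Numeric vector of per-sample weights, mean 1.
#' @export
compute_class_weights <- function(targets, hi_threshold = 20) {
  if (length(targets) == 0) stop("empty input: no targets")
  hi <- targets >= hi_threshold
  n <- length(targets)
  n_hi <- sum(hi)
  n_lo <- n - n_hi
  if (n_hi == 0 || n_lo == 0) {
    warning("only one ICP class present; using unit weights")
    return(rep(1, n))
  }
  w <- ifelse(hi, n / (2 * n_hi), n / (2 * n_lo))
  w
}

#' Patient-separated cross-validation split plan
#'
#' `"shuffle"` produces `n_splits` seeded random patient-level shuffles, each
#' assigning `ceiling(train_fraction * P)` patients to training and the rest
#' to testing, followed by a deterministic repair pass guaranteeing every
#' patient appears in at least one test set. `"group_kfold"` partitions the
#' shuffled patients into `n_splits` folds, each fold testing once.
#' Windows from one patient never appear on both sides of a split.
#'
#' @param patient_ids Character vector of (unique) patient identifiers.
#' @param n_splits Number of splits (default 10).
#' @param train_fraction Training fraction of patients (default 0.8).
#' @param seed Integer seed.
#' @param method `"shuffle"` or `"group_kfold"`.
#' @return An object of class `split_plan`: list of `list(train=, test=)`.
#' @export
make_patient_splits <- function(patient_ids, n_splits = 10,
                                train_fraction = 0.8, seed = 1,
                                method = c("shuffle", "group_kfold")) {
  method <- match.arg(method)
  pats <- unique(as.character(patient_ids))
  P <- length(pats)
  if (P < 5) stop("too few groups: need at least 5 patients")
  set.seed(as.integer(seed))
  plan <- vector("list", n_splits)
  if (method == "group_kfold") {
    perm <- sample(pats)
    fold_of <- rep(seq_len(n_splits), length.out = P)
    for (s in seq_len(n_splits)) {
      test <- perm[fold_of == s]
      plan[[s]] <- list(train = setdiff(perm, test), test = test)
    }
  } else {
    n_tr <- ceiling(train_fraction * P)
    n_te <- P - n_tr
    if (n_te < 1) stop("train_fraction leaves no test patients")
    if (n_splits * n_te < P) {
      warning("only ", n_splits * n_te, " test slots for ", P,
              " patients; not every patient can appear in a test set")
    }
    # balanced dealing: each split tests the patients with the fewest test
    # appearances so far (random tie-breaks), so coverage is guaranteed
    # whenever n_splits * n_te >= P
    cnt <- stats::setNames(rep(0L, P), pats)
    for (s in seq_len(n_splits)) {
      priority <- cnt + stats::runif(P)
      test <- pats[order(priority)][seq_len(n_te)]
      cnt[test] <- cnt[test] + 1L
      plan[[s]] <- list(train = sort(setdiff(pats, test)), test = sort(test))
    }
  }
  for (s in seq_len(n_splits)) {
    if (length(intersect(plan[[s]]$train, plan[[s]]$test)) > 0) {
      stop("internal error: train/test patient overlap in split ", s)
    }
  }
  structure(plan, class = "split_plan")
}

fit_hgb <- function(x, y, w, cfg, n_trees = cfg$n_trees,
                    max_depth = cfg$max_depth) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, weight = w)
  params <- list(
    objective = "reg:squarederror",
    eta = cfg$learning_rate,
    max_depth = max_depth,
    lambda = cfg$l2_regularization,
    max_leaves = cfg$max_leaf_nodes,
    min_child_weight = cfg$min_samples_leaf,
    max_bin = cfg$n_histogram_bins,
    tree_method = "hist",
    grow_policy = "lossguide",
    nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = n_trees,
                     verbose = 0)
}

# Fit embedding with automatic neighbourhood enlargement on disconnection.
fit_embedding_safe <- function(pulses, cfg) {
  k <- cfg$n_neighbors
  for (attempt in 1:3) {
    model <- tryCatch(
      fit_embedding(pulses, n_neighbors = k,
                    n_components = cfg$n_components,
                    n_landmarks = cfg$n_landmarks),
      error = function(e) {
        if (grepl("disconnected", conditionMessage(e))) NULL else stop(e)
      })
    if (!is.null(model)) return(model)
    k <- k * 2
  }
  fit_embedding(pulses, n_neighbors = k, n_components = cfg$n_components,
                n_landmarks = cfg$n_landmarks)
}

#' Train the class-weighted, patient-separated ensemble
#'
#' For each split of the plan: the Isomap embedding is fitted on the training
#' patients' pulses only, embedding coordinates are appended to the feature
#' bank, features are selected by Spearman ranking with redundancy exclusion
#' on the training rows only, and a histogram gradient-boosted tree regressor
#' is fitted with inverse-frequency class weights. Held-out predictions and
#' per-split train/test MAE and MSE are recorded. With `do_grid_search`,
#' `(n_trees, max_depth)` combinations from `config$grid` are scored by mean
#' held-out MAE across splits and the best is refitted.
#'
#' @param features Data frame with `window_id`, `patient_id`,
#'   `reference_icp_mmHg` and the numeric feature columns.
#' @param pulses Numeric matrix of mean-pulse waveforms, rows aligned with
#'   `features`.
#' @param config A [model_config()].
#' @param do_grid_search Logical (default FALSE).
#' @return An object of class `icp_model_bundle`: `fold_models`,
#'   `fold_features`, `fold_embeddings`, `splits`, `config`, `cv` (per-fold
#'   error table) and `cv_predictions` (pooled held-out predictions).
#' @export
train_ensemble <- function(features, pulses, config = model_config(),
                           do_grid_search = FALSE) {
  stopifnot(inherits(config, "model_config"))
  req <- c("window_id", "patient_id", "reference_icp_mmHg")
  if (!all(req %in% names(features))) {
    stop("features must carry ", paste(req, collapse = ", "))
  }
  feat_cols <- setdiff(names(features), req)
  x_base <- as.matrix(features[, feat_cols, drop = FALSE])
  if (any(!is.finite(x_base))) {
    bad <- feat_cols[apply(x_base, 2, function(cc) any(!is.finite(cc)))]
    stop("non-finite features in columns: ", paste(bad, collapse = ", "))
  }
  y <- features$reference_icp_mmHg
  pid <- as.character(features$patient_id)
  if (nrow(features) < 200) stop("need at least 200 windows")
  if (length(unique(pid)) < 5) stop("need at least 5 patients")
  if (nrow(pulses) != nrow(features)) {
    stop("pulses and features must have matching rows")
  }

  splits <- make_patient_splits(unique(pid), n_splits = config$n_splits,
                                train_fraction = config$train_fraction,
                                seed = config$seed,
                                method = config$split_method)

  fit_all <- function(n_trees, max_depth) {
    folds <- vector("list", length(splits))
    for (s in seq_along(splits)) {
      tr <- pid %in% splits[[s]]$train
      te <- pid %in% splits[[s]]$test
      emb <- fit_embedding_safe(pulses[tr, , drop = FALSE], config)
      x_tr <- cbind(x_base[tr, , drop = FALSE], emb$training_coords)
      sel <- select_features(x_tr, y[tr], k = config$k_features,
                             redundancy_threshold = config$redundancy_threshold,
                             min_target_rho = config$min_target_rho)
      w_tr <- compute_class_weights(y[tr], config$hi_threshold_mmHg)
      model <- fit_hgb(x_tr[, sel$selected_names, drop = FALSE], y[tr], w_tr,
                       config, n_trees = n_trees, max_depth = max_depth)
      x_te <- cbind(x_base[te, , drop = FALSE],
                    apply_embedding(emb, pulses[te, , drop = FALSE]))
      pred_te <- predict(model, xgboost::xgb.DMatrix(
        x_te[, sel$selected_names, drop = FALSE]))
      pred_tr <- predict(model, xgboost::xgb.DMatrix(
        x_tr[, sel$selected_names, drop = FALSE]))
      folds[[s]] <- list(
        model = model, embedding = emb, selection = sel,
        train_mae = mean(abs(pred_tr - y[tr])),
        train_mse = mean((pred_tr - y[tr])^2),
        test_mae = mean(abs(pred_te - y[te])),
        test_mse = mean((pred_te - y[te])^2),
        held_out = data.frame(
          window_id = features$window_id[te], patient_id = pid[te],
          reference_icp_mmHg = y[te], eicp_mmHg = pred_te, fold = s,
          stringsAsFactors = FALSE))
    }
    folds
  }

  n_trees <- config$n_trees
  max_depth <- config$max_depth
  if (do_grid_search) {
    combos <- expand.grid(n_trees = config$grid$n_trees,
                          max_depth = config$grid$max_depth)
    scores <- numeric(nrow(combos))
    for (i in seq_len(nrow(combos))) {
      folds_i <- fit_all(combos$n_trees[i], combos$max_depth[i])
      scores[i] <- mean(vapply(folds_i, `[[`, numeric(1), "test_mae"))
    }
    best <- which.min(scores)
    n_trees <- combos$n_trees[best]
    max_depth <- combos$max_depth[best]
    config$n_trees <- n_trees
    config$max_depth <- max_depth
  }
  folds <- fit_all(n_trees, max_depth)

  cv <- data.frame(
    fold = seq_along(folds),
    train_mae = vapply(folds, `[[`, numeric(1), "train_mae"),
    test_mae = vapply(folds, `[[`, numeric(1), "test_mae"),
    train_mse = vapply(folds, `[[`, numeric(1), "train_mse"),
    test_mse = vapply(folds, `[[`, numeric(1), "test_mse"))
  structure(list(
    fold_models = lapply(folds, `[[`, "model"),
    fold_features = lapply(folds, function(f) f$selection$selected_names),
    fold_embeddings = lapply(folds, `[[`, "embedding"),
    fold_selections = lapply(folds, `[[`, "selection"),
    splits = splits, config = config,
    base_feature_names = feat_cols,
    cv = cv,
    cv_predictions = do.call(rbind, lapply(folds, `[[`, "held_out"))),
    class = "icp_model_bundle")
}

#' @export
print.icp_model_bundle <- function(x, ...) {
  cat(sprintf(
    "icp_model_bundle: %d fold models (%d trees, depth %d), %d base features\n",
    length(x$fold_models), x$config$n_trees, x$config$max_depth,
    length(x$base_feature_names)))
  cat(sprintf("cross-validation: test MAE %.2f +/- %.2f mmHg\n",
              mean(x$cv$test_mae), stats::sd(x$cv$test_mae)))
  invisible(x)
}

#' Median-of-folds eICP prediction
#'
#' Every fold model predicts each window (through its own embedding and
#' feature subset); the estimated ICP is the median across the fold
#' predictions (for an even fold count, the mean of the two central order
#' statistics), so it always lies within the range of the fold predictions.
#'
#' @param bundle An `icp_model_bundle`.
#' @param features Data frame with `window_id`, `patient_id` and the same
#'   base feature columns used in training.
#' @param pulses Mean-pulse matrix aligned with `features`.
#' @return Data frame: `window_id`, `patient_id`, `reference_icp_mmHg` (if
#'   present), `eicp_mmHg`, and `fold_1..fold_n` columns.
#' @export
predict_eicp <- function(bundle, features, pulses) {
  stopifnot(inherits(bundle, "icp_model_bundle"))
  if (!all(bundle$base_feature_names %in% names(features))) {
    stop("dimension error: feature signature does not match the bundle")
  }
  x_base <- as.matrix(features[, bundle$base_feature_names, drop = FALSE])
  pulses <- as.matrix(pulses)
  if (nrow(pulses) != nrow(features)) {
    stop("dimension error: pulses and features must have matching rows")
  }
  n_folds <- length(bundle$fold_models)
  preds <- matrix(NA_real_, nrow(features), n_folds)
  for (s in seq_len(n_folds)) {
    coords <- apply_embedding(bundle$fold_embeddings[[s]], pulses)
    x <- cbind(x_base, coords)[, bundle$fold_features[[s]], drop = FALSE]
    preds[, s] <- predict(bundle$fold_models[[s]], xgboost::xgb.DMatrix(x))
  }
  out <- data.frame(window_id = features$window_id,
                    patient_id = features$patient_id,
                    stringsAsFactors = FALSE)
  if ("reference_icp_mmHg" %in% names(features)) {
    out$reference_icp_mmHg <- features$reference_icp_mmHg
  }
  out$eicp_mmHg <- apply(preds, 1, stats::median)
  colnames(preds) <- paste0("fold_", seq_len(n_folds))
  cbind(out, as.data.frame(preds))
}
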