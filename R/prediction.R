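#' Default boosted-tree hyperparameters
#'
#' Fixed, recorded settings for every gradient-boosted model in the package
#' (classification and severity regression alike). Kept deliberately shallow
#' and unsubsampled so fits are deterministic for a given seed.
#'
#' @param nrounds Number of boosting rounds.
#' @param eta Learning rate.
#' @param max_depth Maximum tree depth.
#' @return List of parameters consumed by the fitting helpers.
#' @export
xgb_defaults <- function(nrounds = 50, eta = 0.3, max_depth = 3) {
  list(nrounds = nrounds, eta = eta, max_depth = max_depth,
       subsample = 1, colsample_bytree = 1, nthread = 1)
}

fit_boosted <- function(X, y, task, seed, params = xgb_defaults()) {
  objective <- if (task == "classify") "binary:logistic" else "reg:squarederror"
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = as.numeric(y))
  withr_seed(seed, {
    xgboost::xgb.train(
      params = list(objective = objective, eta = params$eta,
                    max_depth = params$max_depth,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    nthread = params$nthread),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
  })
}

#' Rank features by boosted-tree importance
#'
#' Fits one gradient-boosted ensemble on all provided rows and ranks
#' features by their share of total split gain (nonnegative, summing to 1;
#' features never used in a split score 0 and keep their column order).
#'
#' @param X Subjects-by-features numeric matrix or data frame.
#' @param y Binary labels (classification: 0/1, logical, or 2-level factor)
#'   or numeric scores (regression).
#' @param task `"classify"` or `"regress"`.
#' @param seed Integer seed.
#' @param params Hyperparameters from [xgb_defaults()].
#' @return Tibble with columns `rank`, `feature`, `importance`.
#' @export
rank_importance <- function(X, y, task = c("classify", "regress"), seed = 1L,
                            params = xgb_defaults()) {
  task <- match.arg(task)
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) abort("missing values in features or target")
  y <- normalize_target(y, task)
  if (length(unique(y)) < 2)
    abort("degenerate target: constant outcome")
  bst <- fit_boosted(X, y, task, seed, params)
  imp <- xgboost::xgb.importance(model = bst)
  scores <- setNames(rep(0, ncol(X)), colnames(X))
  scores[imp$Feature] <- imp$Gain
  if (sum(scores) > 0) scores <- scores / sum(scores)
  ord <- order(-scores)  # ties keep column order (stable)
  tibble::tibble(rank = seq_along(ord), feature = names(scores)[ord],
                 importance = unname(scores[ord]))
}

normalize_target <- function(y, task) {
  if (task == "classify") {
    if (is.factor(y)) y <- as.numeric(y) - 1
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1)))
      abort("classification target must be binary (0/1)")
  }
  as.numeric(y)
}

#' Classification metrics from labels and continuous scores
#'
#' AUC uses the rank-statistic (Mann-Whitney) formulation with ties
#' averaged; the positive class is coded 1 (ADHD).
#'
#' @param y True binary labels (0/1).
#' @param score Predicted scores or probabilities.
#' @param threshold Classification threshold on `score`.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
classification_metrics <- function(y, score, threshold = 0.5) {
  y <- as.numeric(y)
  pred <- as.numeric(score > threshold)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 > 0 && n0 > 0)
    (sum(rank(score)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  else NA_real_
  tibble::tibble(
    accuracy = mean(pred == y),
    sensitivity = if (n1 > 0) sum(pred == 1 & y == 1) / n1 else NA_real_,
    specificity = if (n0 > 0) sum(pred == 0 & y == 0) / n0 else NA_real_,
    auc = auc)
}

#' Coefficient of determination on held-out targets
#'
#' `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` around the held-out targets'
#' own mean; predicting that mean gives exactly 0.
#'
#' @param y Observed values.
#' @param pred Predicted values.
#' @return Scalar R-squared (can be negative for worse-than-mean models).
#' @export
r_squared <- function(y, pred) {
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

# fold assignment: stratified by class for classification, plain otherwise
make_folds <- function(y, task, n_folds, seed) {
  fold <- integer(length(y))
  withr_seed(seed, {
    if (task == "classify") {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        if (length(idx) < n_folds)
          abort(sprintf(
            "stratification error: class '%s' has %d subjects, fewer than n_folds = %d; reduce n_folds or add subjects",
            format(cls), length(idx), n_folds))
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      if (length(y) < n_folds)
        abort("stratification error: fewer subjects than folds")
      fold <- sample(rep_len(seq_len(n_folds), length(y)))
    }
  })
  fold
}

# one repeat of k-fold CV: returns out-of-fold predictions for all rows
cv_predictions <- function(X, y, task, n_folds, seed, params) {
  fold <- make_folds(y, task, n_folds, seed)
  pred <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    bst <- fit_boosted(X[tr, , drop = FALSE], y[tr], task,
                       seed = seed + f, params = params)
    pred[!tr] <- predict(bst, as.matrix(X[!tr, , drop = FALSE]))
  }
  pred
}

#' Ranked-importance top-N feature search under repeated cross-validation
#'
#' For each candidate prefix size N of the importance ranking, restricts the
#' model to the top-N features and runs `n_repeats` independent
#' `n_folds`-fold cross-validations (stratified for classification),
#' recording the mean metric (classification accuracy; regression R^2)
#' across repeats, each computed from that repeat's pooled out-of-fold
#' predictions. `best_n` is the curve maximum, ties resolved toward the
#' smallest N.
#'
#' With `nested = TRUE` the ranking is recomputed inside each training fold
#' (avoiding the selection bias of ranking on all labels, at k times the
#' cost); the default mirrors the reference procedure, which ranks once on
#' the full training cohort.
#'
#' @param X Subjects-by-features matrix or data frame.
#' @param y Labels (classification) or scores (regression).
#' @param task `"classify"` or `"regress"`.
#' @param ranking Optional precomputed [rank_importance()] tibble; computed
#'   from `X`, `y` when `NULL` (ignored when `nested = TRUE`).
#' @param n_folds,n_repeats Cross-validation shape (reference: 10 and 10).
#' @param n_grid Candidate N values (default `1:ncol(X)`).
#' @param nested Recompute the ranking within each training fold.
#' @param seed Integer seed; drives fold assignment and every fit.
#' @param params Hyperparameters from [xgb_defaults()].
#' @return A `topn_search` object: `curve` (tibble `n`, `metric`), `best_n`,
#'   `selected` (feature labels), `ranking`, `cv_metrics` (full metric set
#'   at `best_n`), `task`.
#' @export
top_n_search <- function(X, y, task = c("classify", "regress"),
                         ranking = NULL, n_folds = 10, n_repeats = 10,
                         n_grid = NULL, nested = FALSE, seed = 1L,
                         params = xgb_defaults()) {
  task <- match.arg(task)
  X <- as.matrix(X)
  y <- normalize_target(y, task)
  if (nrow(X) < n_folds) abort("stratification error: fewer subjects than folds")
  if (is.null(ranking) && !nested)
    ranking <- rank_importance(X, y, task, seed = seed, params = params)
  if (!nested && !all(colnames(X) %in% ranking$feature))
    abort("ranking must cover all features")
  if (is.null(n_grid)) n_grid <- seq_len(ncol(X))
  rep_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, n_repeats))

  metric_fun <- if (task == "classify") {
    function(y, p) mean((p > 0.5) == y)
  } else r_squared

  if (nested) {
    # per repeat/fold: rank on the training rows only, then sweep N
    per_rep <- vapply(rep_seeds, function(rs) {
      fold <- make_folds(y, task, n_folds, rs)
      preds <- matrix(NA_real_, length(y), length(n_grid))
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        rk <- rank_importance(X[tr, , drop = FALSE], y[tr], task,
                              seed = rs + f, params = params)
        for (gi in seq_along(n_grid)) {
          feats <- rk$feature[seq_len(n_grid[gi])]
          bst <- fit_boosted(X[tr, feats, drop = FALSE], y[tr], task,
                             seed = rs + f, params = params)
          preds[!tr, gi] <- predict(bst, X[!tr, feats, drop = FALSE])
        }
      }
      apply(preds, 2, function(p) metric_fun(y, p))
    }, numeric(length(n_grid)))
    curve_vals <- rowMeans(matrix(per_rep, nrow = length(n_grid)))
    ranking <- rank_importance(X, y, task, seed = seed, params = params)
  } else {
    curve_vals <- vapply(seq_along(n_grid), function(gi) {
      feats <- ranking$feature[seq_len(n_grid[gi])]
      mean(vapply(rep_seeds, function(rs) {
        p <- cv_predictions(X[, feats, drop = FALSE], y, task, n_folds, rs,
                            params)
        metric_fun(y, p)
      }, numeric(1)))
    }, numeric(1))
  }

  curve <- tibble::tibble(n = as.integer(n_grid), metric = curve_vals)
  best_n <- curve$n[which.max(curve$metric)]  # which.max takes the first tie
  selected <- ranking$feature[seq_len(best_n)]

  # full metric set at best_n, averaged over repeats
  cv_metrics <- purrr::map_dfr(rep_seeds, function(rs) {
    p <- cv_predictions(X[, selected, drop = FALSE], y, task, n_folds, rs,
                        params)
    if (task == "classify") classification_metrics(y, p)
    else tibble::tibble(r_squared = r_squared(y, p))
  }) |> dplyr::summarise(dplyr::across(dplyr::everything(), mean))

  structure(list(curve = curve, best_n = best_n, selected = selected,
                 ranking = ranking, cv_metrics = cv_metrics, task = task,
                 n_folds = n_folds, n_repeats = n_repeats,
                 seed = as.integer(seed), nested = nested, params = params),
            class = "topn_search")
}

#' @export
print.topn_search <- function(x, ...) {
  cat(sprintf("<topn_search> task '%s', best N = %d of %d candidates\n",
              x$task, x$best_n, nrow(x$curve)))
  print(x$cv_metrics)
  invisible(x)
}

#' @describeIn top_n_search The CV performance curve as a tibble.
#' @param x A `topn_search`.
#' @param ... Unused.
#' @export
tidy.topn_search <- function(x, ...) x$curve

#' @describeIn top_n_search One-row summary (`best_n` and CV metrics).
#' @export
glance.topn_search <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(task = x$task, best_n = x$best_n,
                                  n_folds = x$n_folds,
                                  n_repeats = x$n_repeats),
                   x$cv_metrics)
}

#' Fit on a training cohort and evaluate on an independent test cohort
#'
#' @param X_train,y_train Training features and targets.
#' @param X_test,y_test Independent test features and targets (disjoint
#'   subjects).
#' @param features Feature labels to use (e.g. `topn_search$selected`); must
#'   exist in both matrices.
#' @param task `"classify"` or `"regress"`.
#' @param seed Integer seed.
#' @param params Hyperparameters from [xgb_defaults()].
#' @return One-row tibble of test metrics (classification: `accuracy`,
#'   `sensitivity`, `specificity`, `auc`; regression: `r_squared`).
#' @export
evaluate_model <- function(X_train, y_train, X_test, y_test, features,
                           task = c("classify", "regress"), seed = 1L,
                           params = xgb_defaults()) {
  task <- match.arg(task)
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (!all(features %in% colnames(X_train)) ||
      !all(features %in% colnames(X_test)))
    abort("schema error: selected features missing from train or test matrix")
  y_train <- normalize_target(y_train, task)
  y_test <- normalize_target(y_test, task)
  bst <- fit_boosted(X_train[, features, drop = FALSE], y_train, task, seed,
                     params)
  pred <- predict(bst, X_test[, features, drop = FALSE])
  if (task == "classify") classification_metrics(y_test, pred)
  else tibble::tibble(r_squared = r_squared(y_test, pred))
}

#' Subjects-by-node flexibility feature matrix
#'
#' @param flex Stacked [flexibility_profile()] rows for several subjects.
#' @return Numeric matrix, one row per subject (rownames = subject ids), one
#'   column per node.
#' @export
flexibility_features <- function(flex) {
  wide <- flex |>
    dplyr::filter(.data$level == "node") |>
    dplyr::select("subject_id", "unit", "flexibility") |>
    tidyr::pivot_wider(names_from = "unit", values_from = "flexibility")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$subject_id
  m
}
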