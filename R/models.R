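# Model-search harness: three classifier families under stratified 10-fold
# cross-validation with pooled out-of-fold confusion metrics, the 3-feature
# baseline comparison, and bookkeeping over algorithm x task x combination.

# ---- classifier registry ---------------------------------------------------

#' Fit one classifier
#'
#' Families: `"lgr"` (ridge-regularized logistic regression),
#' `"rf"` (random forest), `"gb"` (depth-limited gradient-boosted trees),
#' plus two degenerate reference models: `"majority"` (constant
#' training-majority probability) and `"linear"` (unregularized linear
#' probability model). Hyperparameters are fixed, documented defaults
#' suited to cohorts of a few dozen subjects and are never tuned per
#' feature combination.
#'
#' @param algorithm one of the registry names above.
#' @param X numeric matrix (subjects x features).
#' @param y01 0/1 response (1 = positive/propensity class).
#' @param seed seed for the stochastic learners.
#' @return Model object of class `acti_model`.
#' @export
fit_classifier <- function(algorithm, X, y01, seed = 1L) {
  X <- as.matrix(X)
  fit <- switch(algorithm,
    lgr = {
      Xg <- if (ncol(X) == 1L) cbind(X, .pad = 0) else X
      # small-class warnings are expected at cohort scale (folds leave
      # a handful of subjects per class) and carry no information here
      suppressWarnings(
        glmnet::glmnet(Xg, factor(y01, levels = 0:1), family = "binomial",
                       alpha = 0, lambda = 0.05))
    },
    rf = with_seed(seed,
      randomForest::randomForest(X, factor(y01, levels = 0:1), ntree = 200)),
    gb = with_seed(seed,
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = 3, eta = 0.15,
                                       tree_method = "exact",
                                       nthread = 1),
                         data = xgboost::xgb.DMatrix(X, label = y01,
                                                     nthread = 1),
                         nrounds = 60, verbose = 0)),
    majority = list(p = mean(y01)),
    linear = {
      df <- data.frame(y = y01, X, check.names = FALSE)
      stats::lm(y ~ ., data = df)
    },
    stop("unknown algorithm: ", algorithm)
  )
  structure(list(algorithm = algorithm, fit = fit, features = colnames(X)),
            class = "acti_model")
}

#' Predict positive-class probability
#'
#' @param model an `acti_model` from [fit_classifier()].
#' @param X numeric matrix with the model's feature columns.
#' @return Numeric vector of probabilities (or linear scores for the
#'   `"linear"` reference model).
#' @export
predict_prob <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  switch(model$algorithm,
    lgr = {
      Xg <- if (ncol(X) == 1L) cbind(X, .pad = 0) else X
      as.numeric(stats::predict(model$fit, newx = Xg, type = "response"))
    },
    rf = as.numeric(stats::predict(model$fit, X, type = "prob")[, "1"]),
    gb = as.numeric(stats::predict(model$fit,
                                   xgboost::xgb.DMatrix(X, nthread = 1))),
    majority = rep(model$fit$p, nrow(X)),
    linear = as.numeric(stats::predict(model$fit,
      newdata = as.data.frame(X, check.names = FALSE))),
    # fixed-coefficient linear score, used as an analytic reference model
    fixed_linear = as.numeric(model$fit$intercept +
                                X %*% model$fit$coef),
    stop("unknown algorithm: ", model$algorithm)
  )
}

# ---- metrics ---------------------------------------------------------------

#' Classification metrics from pooled predictions
#'
#' Accuracy = (TP + TN) / total; precision = TP / (TP + FP); recall =
#' TP / (TP + FN), with the propensity class positive.
#'
#' @param predicted,truth 0/1 vectors (1 = positive class).
#' @return Named list `accuracy`, `precision`, `recall` and the four
#'   confusion counts.
#' @export
compute_metrics <- function(predicted, truth) {
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  list(accuracy = (tp + tn) / length(truth),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

# ---- cross-validation ------------------------------------------------------

# stratified fold assignment with seed-controlled shuffling
.stratified_folds <- function(y01, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y01))
    for (cls in unique(y01)) {
      idx <- sample(which(y01 == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validation of one model
#'
#' Folds are stratified by class with seed-controlled shuffling;
#' out-of-fold predictions are pooled into a single confusion matrix
#' (rather than averaging per-fold metrics), and a final model is fitted
#' on all rows for explanation.
#'
#' @param algorithm registry name (see [fit_classifier()]).
#' @param X numeric matrix (subjects x features).
#' @param y class labels (any two-level vector).
#' @param positive label of the propensity (positive) class.
#' @param folds number of folds (default 10).
#' @param seed seed for fold shuffling and the learners.
#' @return `model_result` list: metrics, pooled out-of-fold probabilities
#'   and classes, fold assignment, and the fitted full-data model.
#' @export
cross_validate <- function(algorithm, X, y, positive, folds = 10, seed = 1L) {
  X <- as.matrix(X)
  y01 <- as.integer(as.character(y) == as.character(positive))
  if (length(unique(y01)) < 2L) stop("response has a single class")
  if (min(table(y01)) < 2L) stop("each class needs at least two subjects")
  if (folds > length(y01)) stop("more folds than subjects")
  fold <- .stratified_folds(y01, folds, seed)
  prob <- numeric(length(y01))
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (!any(!tr)) next
    m <- fit_classifier(algorithm, X[tr, , drop = FALSE], y01[tr],
                        seed = child_seed(seed, k))
    prob[!tr] <- predict_prob(m, X[!tr, , drop = FALSE])
  }
  pred <- as.integer(prob >= 0.5)
  met <- compute_metrics(pred, y01)
  full <- fit_classifier(algorithm, X, y01, seed = child_seed(seed, 0L))
  structure(c(list(algorithm = algorithm, features = colnames(X),
                   prob = prob, predicted = pred, truth = y01, fold = fold,
                   model = full, positive = positive), met),
            class = "model_result")
}

# ---- search ----------------------------------------------------------------

#' Case--control tasks from a three-group label vector
#'
#' @param labels character vector with values in C/CTF/PSF.
#' @return Named list of tasks (`C_vs_CTF`, `C_vs_PSF`), each holding the
#'   row indices, labels and positive class; the control rows are shared.
#' @export
make_tasks <- function(labels) {
  labels <- as.character(labels)
  out <- list()
  for (g in intersect(c("CTF", "PSF"), unique(labels))) {
    rows <- which(labels %in% c("C", g))
    out[[paste0("C_vs_", g)]] <- list(rows = rows, labels = labels[rows],
                                      positive = g)
  }
  out
}

#' Cross-validate every algorithm x task x combination
#'
#' @param table a normalized `feature_table` covering all subjects.
#' @param tasks task list from [make_tasks()].
#' @param combinations list of feature-name vectors (combinations may be
#'   task-specific: a named list of lists keyed by task name, or one list
#'   shared by all tasks).
#' @param algorithms registry names (default the three families).
#' @param folds,seed cross-validation controls.
#' @param dry_run if TRUE, skip fitting and return the bookkeeping only.
#' @param verbose log progress per task.
#' @return list with `results` (one `model_result` per fit, with `task`
#'   and `combination` fields), and `n_planned` = algorithms x tasks x
#'   combinations.
#' @export
run_search <- function(table, tasks, combinations,
                       algorithms = c("lgr", "rf", "gb"),
                       folds = 10, seed = 1L, dry_run = FALSE,
                       verbose = FALSE) {
  per_task <- if (length(combinations) && is.list(combinations[[1]]) &&
                  !is.character(combinations[[1]]))
    combinations else stats::setNames(rep(list(combinations), length(tasks)),
                                      names(tasks))
  n_planned <- length(algorithms) *
    sum(vapply(names(tasks), function(t) length(per_task[[t]]), integer(1)))
  if (dry_run)
    return(list(results = list(), n_planned = n_planned))
  m <- feature_matrix(table)
  results <- vector("list", n_planned)
  i <- 0L
  for (task_name in names(tasks)) {
    task <- tasks[[task_name]]
    combos <- per_task[[task_name]]
    for (alg in algorithms) {
      for (ci in seq_along(combos)) {
        i <- i + 1L
        res <- cross_validate(alg,
                              m[task$rows, combos[[ci]], drop = FALSE],
                              task$labels, task$positive, folds = folds,
                              seed = child_seed(seed, i))
        res$task <- task_name
        res$combination <- ci
        results[[i]] <- res
      }
      if (verbose) message(task_name, " / ", alg, ": ",
                           length(combos), " combinations done")
    }
  }
  list(results = results[seq_len(i)], n_planned = n_planned)
}

#' Baseline metrics per algorithm x task
#'
#' @param baseline_matrix subjects x 3 matrix from [baseline_features()].
#' @param tasks task list from [make_tasks()].
#' @param algorithms,folds,seed as in [run_search()].
#' @return Named list `task.algorithm` -> `model_result`.
#' @export
baseline_results <- function(baseline_matrix, tasks,
                             algorithms = c("lgr", "rf", "gb"),
                             folds = 10, seed = 1L) {
  out <- list()
  i <- 0L
  for (task_name in names(tasks)) {
    task <- tasks[[task_name]]
    for (alg in algorithms) {
      i <- i + 1L
      res <- cross_validate(alg,
                            baseline_matrix[task$rows, , drop = FALSE],
                            task$labels, task$positive, folds = folds,
                            seed = child_seed(seed, 10000L + i))
      res$task <- task_name
      out[[paste(task_name, alg, sep = ".")]] <- res
    }
  }
  out
}

#' Retain models that outperform their baseline
#'
#' Keeps results whose pooled accuracy is strictly greater than the
#' baseline accuracy of the same algorithm and task.
#'
#' @param results `results` list from [run_search()].
#' @param baselines list from [baseline_results()].
#' @return Filtered list of `model_result`s.
#' @export
filter_above_baseline <- function(results, baselines) {
  keep <- vapply(results, function(r) {
    key <- paste(r$task, r$algorithm, sep = ".")
    if (is.null(baselines[[key]]))
      stop("missing baseline for ", key)
    r$accuracy > baselines[[key]]$accuracy
  }, logical(1))
  results[keep]
}
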