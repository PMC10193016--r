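# Classifier training and evaluation: stratified (optionally
# parent-grouped) splitting, grid-searched cross-validation over four model
# families, confusion-matrix metrics and the train-minus-test
# generalization gap that diagnoses overfitting on scarce seed sets.

#' Split specification
#'
#' @param test_fraction proportion held out (default 0.25).
#' @param rng_seed integer seed (constant random state).
#' @param group_by_parent keep a seed and all its augmented descendants on
#'   the same side of the split (leakage guard). Default TRUE.
#' @return list of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.25, rng_seed = 1L,
                       group_by_parent = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  structure(list(test_fraction = test_fraction,
                 rng_seed = as.integer(rng_seed),
                 group_by_parent = isTRUE(group_by_parent)),
            class = "split_spec")
}

#' Stratified train/test split
#'
#' Splits labeled molecule records preserving per-class proportions to
#' within one record. With `group_by_parent`, grouping units are the root
#' seeds: a parent and its augmented descendants always land on the same
#' side (class proportions then hold at the seed level).
#'
#' @param dataset labeled molecule records.
#' @param spec a [split_spec()].
#' @return list with elements `train` and `test`.
#' @export
stratified_split <- function(dataset, spec = split_spec()) {
  stopifnot(is.data.frame(dataset), !anyNA(dataset$label))
  root <- ifelse(is.na(dataset$parent_id) | dataset$parent_id == "",
                 dataset$id, dataset$parent_id)
  units <- if (spec$group_by_parent) root else dataset$id
  udf <- unique(data.frame(unit = units, label = dataset$label,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(udf$unit))
    stop("inconsistent labels within a parent group")
  if (any(table(udf$label) < 2))
    stop("cannot stratify: a class has fewer than 2 units")
  set.seed(spec$rng_seed)
  test_units <- character(0)
  for (cl in sort(unique(udf$label))) {
    u <- udf$unit[udf$label == cl]
    n_test <- round(spec$test_fraction * length(u))
    n_test <- min(max(n_test, 1L), length(u) - 1L)
    test_units <- c(test_units, sample(u, n_test))
  }
  in_test <- units %in% test_units
  list(train = dataset[!in_test, , drop = FALSE],
       test = dataset[in_test, , drop = FALSE])
}

#' Training configuration
#'
#' @param model_family one of `"random_forest"`, `"svm"`,
#'   `"logistic_regression"`, `"knn"`.
#' @param cv_folds cross-validation folds: 5 for a raw seed set, 10 for an
#'   augmented set (the study settings).
#' @param grid named list of hyperparameter candidate vectors; `NULL` uses
#'   the family's default grid (see [default_grid()]).
#' @param scoring CV model-selection score: `"recall"` (default),
#'   `"accuracy"`, `"f1"` or `"mcc"`.
#' @param class_weight `"balanced"` (default) weights classes inversely to
#'   frequency where the family supports it; `"none"` disables.
#' @return list of class `train_config`.
#' @export
train_config <- function(model_family = c("random_forest", "svm",
                                          "logistic_regression", "knn"),
                         cv_folds = 5L, grid = NULL,
                         scoring = c("recall", "accuracy", "f1", "mcc"),
                         class_weight = c("balanced", "none")) {
  model_family <- match.arg(model_family)
  scoring <- match.arg(scoring)
  class_weight <- match.arg(class_weight)
  stopifnot(cv_folds >= 2)
  if (is.null(grid)) grid <- default_grid(model_family)
  stopifnot(length(grid) >= 1, all(lengths(grid) >= 1))
  structure(list(model_family = model_family, cv_folds = as.integer(cv_folds),
                 grid = grid, scoring = scoring, class_weight = class_weight),
            class = "train_config")
}

#' Default hyperparameter grids
#'
#' Small grids ordered simplest-first per family, so the CV tie-break
#' (first maximum) prefers the least complex model.
#'
#' @param model_family family name as in [train_config()].
#' @return named list of candidate vectors.
#' @export
default_grid <- function(model_family) {
  switch(model_family,
    random_forest = list(ntree = c(100, 300, 500),
                         max_depth = c(NA, 10, 20),
                         min_leaf = c(1, 3)),
    svm = list(cost = c(0.1, 1, 10), gamma = c(NA, 1e-3, 1e-2)),
    logistic_regression = list(lambda = c(1, 0.1, 0.01, 0.001)),
    knn = list(k = c(9, 7, 5, 3)),
    stop("unknown model family: ", model_family))
}

# expand a named list grid into a data.frame of grid points (first column
# varies slowest so earlier = simpler under the documented ordering)
.expand_grid <- function(grid) {
  expand.grid(rev(grid), stringsAsFactors = FALSE)[, rev(seq_along(grid)),
                                                   drop = FALSE]
}

# stratified fold assignment (1..k) per row
.cv_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# fit one model of a family at one grid point; returns an opaque fit
.fit_one <- function(family, params, x, y, class_weight) {
  yf <- factor(y, levels = c(0, 1))
  if (family == "random_forest") {
    cw <- if (class_weight == "balanced")
      as.numeric(1 / (table(yf)[c("0", "1")] / length(yf)))
    else c(1, 1)
    ranger::ranger(
      x = x, y = yf, num.trees = params$ntree,
      max.depth = if (is.na(params$max_depth)) 0 else params$max_depth,
      min.node.size = params$min_leaf, probability = TRUE,
      class.weights = cw, num.threads = 1,
      seed = sample.int(1e9, 1))
  } else if (family == "svm") {
    cw <- if (class_weight == "balanced") "inverse" else NULL
    gamma <- if (is.na(params$gamma)) 1 / ncol(x) else params$gamma
    e1071::svm(x = x, y = yf, kernel = "radial", cost = params$cost,
               gamma = gamma, probability = TRUE,
               class.weights = cw)
  } else if (family == "logistic_regression") {
    w <- if (class_weight == "balanced")
      as.numeric(1 / (table(yf)[as.character(y)] / length(y))) else NULL
    glmnet::glmnet(x = x, y = yf, family = "binomial", alpha = 0,
                   lambda = params$lambda, weights = w)
  } else if (family == "knn") {
    list(x = x, y = yf, k = params$k)  # lazy learner: store training data
  } else stop("unknown model family")
}

# class-1 probabilities from a fit
.predict_one <- function(family, fit, x) {
  if (family == "random_forest") {
    unname(predict(fit, data = x, num.threads = 1)$predictions[, "1"])
  } else if (family == "svm") {
    pred <- predict(fit, x, probability = TRUE)
    p <- unname(attr(pred, "probabilities")[, "1"])
    # Platt scaling can invert on small weighted sets while the decision
    # labels stay correct; re-orient the probabilities if they disagree
    # with the predicted labels more often than not.
    lab1 <- pred == "1"
    if (length(p) > 1 && mean((p >= 0.5) == lab1) < 0.5) p <- 1 - p
    p
  } else if (family == "logistic_regression") {
    unname(predict(fit, newx = x, type = "response")[, 1])
  } else if (family == "knn") {
    pred <- class::knn(train = fit$x, test = x, cl = fit$y, k = fit$k,
                       prob = TRUE)
    p <- attr(pred, "prob")
    ifelse(pred == "1", p, 1 - p)
  } else stop("unknown model family")
}

.score_threshold <- function(score, y, prob) {
  pred <- as.integer(prob >= 0.5)
  cm <- .confusion(y, pred)
  switch(score,
         recall = if ((cm["TP"] + cm["FN"]) == 0) 0
                  else cm["TP"] / (cm["TP"] + cm["FN"]),
         accuracy = (cm["TP"] + cm["TN"]) / sum(cm),
         f1 = .metric_f1(cm),
         mcc = .metric_mcc(cm))
}

#' Train a classifier by grid-searched cross-validation
#'
#' Runs stratified `cv_folds`-fold cross-validation at every grid point,
#' selects the point maximizing the mean CV score under `cfg$scoring`
#' (ties broken toward the earlier = simpler grid point), and refits on the
#' full training set.
#'
#' @param x feature matrix from [featurize()] (rows = molecules).
#' @param y integer labels (0/1) aligned with `x`.
#' @param cfg a [train_config()].
#' @param rng_seed integer seed controlling fold assignment and any
#'   stochastic fitting.
#' @param scaler,feat_config featurization artifacts stored in the bundle
#'   so that held-out data can be featurized identically.
#' @return a `model_bundle`: fitted classifier, config, CV results table
#'   (one row per grid point x fold), selected grid point, scaler.
#' @export
train_model <- function(x, y, cfg = train_config(), rng_seed = 1L,
                        scaler = NULL, feat_config = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("degenerate training set: only one class present")
  pts <- .expand_grid(cfg$grid)
  set.seed(rng_seed)
  fold <- .cv_folds(y, cfg$cv_folds)
  cv <- vector("list", nrow(pts) * cfg$cv_folds)
  r <- 0L
  for (gi in seq_len(nrow(pts))) {
    params <- as.list(pts[gi, , drop = FALSE])
    for (f in seq_len(cfg$cv_folds)) {
      tr <- fold != f
      set.seed(rng_seed + 1000L * gi + f)
      fit <- .fit_one(cfg$model_family, params, x[tr, , drop = FALSE], y[tr],
                      cfg$class_weight)
      prob <- .predict_one(cfg$model_family, fit, x[!tr, , drop = FALSE])
      r <- r + 1L
      cv[[r]] <- cbind(pts[gi, , drop = FALSE],
                       data.frame(grid_point = gi, fold = f,
                                  score = .score_threshold(cfg$scoring,
                                                           y[!tr], prob),
                                  accuracy = .score_threshold("accuracy",
                                                              y[!tr], prob)))
    }
  }
  cv <- do.call(rbind, cv)
  rownames(cv) <- NULL
  mean_scores <- tapply(cv$score, cv$grid_point, mean)
  mean_acc <- tapply(cv$accuracy, cv$grid_point, mean)
  # Selection: best mean primary score; ties resolved first by mean
  # accuracy (a degenerate always-positive model maximizes recall but not
  # accuracy), then by grid order, which lists simpler models first.
  top <- mean_scores >= max(mean_scores) - 1e-12
  best <- as.integer(names(mean_scores)[top][which.max(mean_acc[top])])
  best_params <- as.list(pts[best, , drop = FALSE])
  set.seed(rng_seed)
  fit <- .fit_one(cfg$model_family, best_params, x, y, cfg$class_weight)
  structure(list(fit = fit, config = cfg, best_params = best_params,
                 cv_results = cv, rng_seed = as.integer(rng_seed),
                 scaler = scaler, feat_config = feat_config,
                 n_train = nrow(x)),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle: %s trained on %d molecules (%d-fold CV, %s scoring)\n",
              x$config$model_family, x$n_train, x$config$cv_folds,
              x$config$scoring))
  cat("  selected:", paste(names(x$best_params), unlist(x$best_params),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Class-1 probabilities from a trained bundle
#'
#' @param bundle a `model_bundle` from [train_model()].
#' @param x feature matrix featurized with the bundle's scaler.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(bundle, x) {
  stopifnot(inherits(bundle, "model_bundle"), is.matrix(x))
  .predict_one(bundle$config$model_family, bundle$fit, x)
}

# 2x2 confusion counts at a fixed prediction vector
.confusion <- function(y, pred) {
  c(TN = sum(y == 0 & pred == 0), FP = sum(y == 0 & pred == 1),
    FN = sum(y == 1 & pred == 0), TP = sum(y == 1 & pred == 1))
}

.metric_accuracy <- function(cm) (cm[["TP"]] + cm[["TN"]]) / sum(cm)

.metric_f1 <- function(cm) {
  denom <- 2 * cm[["TP"]] + cm[["FP"]] + cm[["FN"]]
  if (denom == 0) return(0)
  2 * cm[["TP"]] / denom
}

# Matthews correlation; 0 when any margin is empty (constant classifier)
.metric_mcc <- function(cm) {
  tp <- cm[["TP"]]; tn <- cm[["TN"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Metrics from a confusion matrix and probability ranking
#'
#' Accuracy, Matthews correlation coefficient, F1 and ROC-AUC for a labeled
#' set. The confusion matrix uses the 0.5 probability threshold; ROC-AUC
#' uses the full probability ranking.
#'
#' @param y integer labels (0/1).
#' @param prob class-1 probabilities.
#' @return object of class `metrics_report`: list with `accuracy`, `mcc`,
#'   `f1`, `roc_auc`, `confusion` (named TN/FP/FN/TP counts), `n`.
#' @export
classification_metrics <- function(y, prob) {
  stopifnot(length(y) == length(prob))
  y <- as.integer(y)
  cm <- .confusion(y, as.integer(prob >= 0.5))
  single <- length(unique(y)) < 2
  if (single)
    warning("single-class evaluation set: MCC and ROC-AUC undefined",
            call. = FALSE)
  auc <- if (single) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  structure(list(accuracy = .metric_accuracy(cm),
                 mcc = if (single) NA_real_ else .metric_mcc(cm),
                 f1 = .metric_f1(cm),
                 roc_auc = auc, confusion = cm, n = length(y)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | MCC %s | F1 %.3f | ROC-AUC %s  (n = %d)\n",
              x$accuracy,
              ifelse(is.na(x$mcc), "NA", sprintf("%.3f", x$mcc)), x$f1,
              ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc)),
              x$n))
  cat(sprintf("  confusion: TN %d FP %d FN %d TP %d\n", x$confusion["TN"],
              x$confusion["FP"], x$confusion["FN"], x$confusion["TP"]))
  invisible(x)
}

#' Evaluate a trained bundle on a labeled set
#'
#' @param bundle a `model_bundle`.
#' @param x feature matrix (featurized with the bundle's scaler).
#' @param y integer labels.
#' @return a `metrics_report`.
#' @export
evaluate <- function(bundle, x, y) {
  classification_metrics(y, predict_proba(bundle, x))
}

#' Generalization gap (training minus test)
#'
#' The overfitting diagnostic: element-wise difference of training-set and
#' test-set metrics. Large positive deltas flag a model that memorized the
#' training data.
#'
#' @param train_report,test_report `metrics_report` objects.
#' @return object of class `gap_report` with `delta_accuracy`, `delta_mcc`,
#'   `delta_f1`.
#' @export
generalization_gap <- function(train_report, test_report) {
  stopifnot(inherits(train_report, "metrics_report"),
            inherits(test_report, "metrics_report"))
  structure(list(delta_accuracy = train_report$accuracy - test_report$accuracy,
                 delta_mcc = train_report$mcc - test_report$mcc,
                 delta_f1 = train_report$f1 - test_report$f1),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("gap (train - test): accuracy %.3f | MCC %.3f | F1 %.3f\n",
              x$delta_accuracy, x$delta_mcc, x$delta_f1))
  invisible(x)
}
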