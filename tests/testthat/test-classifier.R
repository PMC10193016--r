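# helper: records table with given class sizes (structures irrelevant for
# split logic)
mk_records <- function(n1, n0) {
  data.frame(id = sprintf("m%03d", seq_len(n1 + n0)),
             smiles = "CCO", label = c(rep(1L, n1), rep(0L, n0)),
             provenance = "seed", parent_id = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("stratified split arithmetic is exact and deterministic", {
  d <- mk_records(60, 40)
  sp <- stratified_split(d, split_spec(0.25, rng_seed = 3,
                                       group_by_parent = FALSE))
  expect_equal(sum(sp$test$label == 1), 15)
  expect_equal(sum(sp$test$label == 0), 10)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- stratified_split(d, split_spec(0.25, rng_seed = 3,
                                        group_by_parent = FALSE))
  expect_identical(sp, sp2)
  expect_error(stratified_split(mk_records(5, 1), split_spec(0.25)),
               "fewer than 2")
})

test_that("parent grouping keeps every family on one side of the split", {
  seeds <- mk_records(8, 6)
  analogs <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i)
    data.frame(id = sprintf("%s_a%d", seeds$id[i], 1:5), smiles = "CCO",
               label = seeds$label[i], provenance = "augmented",
               parent_id = seeds$id[i], stringsAsFactors = FALSE)))
  d <- rbind(seeds, analogs)
  sp <- stratified_split(d, split_spec(0.25, rng_seed = 11))
  root <- function(x) ifelse(is.na(x$parent_id), x$id, x$parent_id)
  expect_length(intersect(root(sp$train), root(sp$test)), 0)
  # leakage guard: permuting the analog rows never changes the test parents
  test_parents <- sort(unique(root(sp$test)))
  for (perm_seed in 1:3) {
    set.seed(perm_seed)
    dp <- rbind(seeds, analogs[sample.int(nrow(analogs)), ])
    spp <- stratified_split(dp, split_spec(0.25, rng_seed = 11))
    expect_identical(sort(unique(root(spp$test))), test_parents)
  }
})

test_that("metrics match independent formula evaluation exactly", {
  # TP=3, TN=2, FP=1, FN=1
  y <- c(1, 1, 1, 1, 0, 0, 0)
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3, 0.6)
  m <- classification_metrics(y, prob)
  expect_identical(unname(m$confusion), c(2L, 1L, 1L, 3L))  # TN FP FN TP
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, 5 / 12)
  # brute-force recomputation from the stored confusion matrix
  cm <- m$confusion
  acc <- (cm[["TP"]] + cm[["TN"]]) / sum(cm)
  prec <- cm[["TP"]] / (cm[["TP"]] + cm[["FP"]])
  rec <- cm[["TP"]] / (cm[["TP"]] + cm[["FN"]])
  f1 <- 2 * prec * rec / (prec + rec)
  mcc <- (cm[["TP"]] * cm[["TN"]] - cm[["FP"]] * cm[["FN"]]) /
    sqrt(prod(c(cm[["TP"]] + cm[["FP"]], cm[["TP"]] + cm[["FN"]],
                cm[["TN"]] + cm[["FP"]], cm[["TN"]] + cm[["FN"]])))
  expect_equal(m$accuracy, acc)
  expect_equal(m$f1, f1)
  expect_equal(m$mcc, mcc)
})

test_that("a constant classifier has MCC 0 and single-class sets warn", {
  y <- c(1, 1, 0, 0)
  m <- classification_metrics(y, c(0.9, 0.9, 0.9, 0.9))
  expect_equal(m$mcc, 0)
  expect_warning(m1 <- classification_metrics(c(1, 1), c(0.8, 0.9)),
                 "single-class")
  expect_true(is.na(m1$mcc))
  expect_true(is.na(m1$roc_auc))
})

test_that("training on a separable toy set is perfect and deterministic", {
  set.seed(1)
  n <- 40
  x <- cbind(matrix(rnorm(n * 5), n), sig = c(rnorm(n / 2, -3),
                                              rnorm(n / 2, 3)))
  colnames(x) <- paste0("f", 1:6)
  y <- rep(c(0L, 1L), each = n / 2)
  cfg <- train_config("random_forest", cv_folds = 3,
                      grid = list(ntree = c(50, 100), max_depth = NA,
                                  min_leaf = 1))
  b1 <- train_model(x, y, cfg, rng_seed = 9)
  b2 <- train_model(x, y, cfg, rng_seed = 9)
  expect_identical(b1$best_params, b2$best_params)
  expect_equal(nrow(b1$cv_results), 2 * 3)  # grid points x folds
  m <- evaluate(b1, x, y)
  expect_equal(m$accuracy, 1.0)
  prob <- predict_proba(b1, x)
  expect_true(all(prob[y == 1] > 0.5) && all(prob[y == 0] < 0.5))
  # order equivariance
  perm <- sample(n)
  expect_equal(predict_proba(b1, x[perm, ]), prob[perm], tolerance = 1e-12)
  expect_error(train_model(x, rep(1L, n), cfg), "one class")
})

test_that("every model family trains and emits calibrated probabilities", {
  set.seed(2)
  n <- 30
  x <- cbind(matrix(rnorm(n * 3), n), sig = c(rnorm(n / 2, -2.5),
                                              rnorm(n / 2, 2.5)))
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c(0L, 1L), each = n / 2)
  for (fam in c("random_forest", "svm", "logistic_regression", "knn")) {
    cfg <- train_config(fam, cv_folds = 2, scoring = "accuracy")
    b <- suppressWarnings(train_model(x, y, cfg, rng_seed = 4))
    p <- predict_proba(b, x)
    expect_true(all(p >= 0 & p <= 1), info = fam)
    expect_gt(classification_metrics(y, p)$accuracy, 0.8)
  }
})

test_that("the generalization gap is an exact element-wise subtraction", {
  report <- function(acc, mcc, f1)
    structure(list(accuracy = acc, mcc = mcc, f1 = f1),
              class = "metrics_report")
  # seeds-only model: perfect training fit, weak test performance
  g1 <- generalization_gap(report(1.0, 1.0, 1.0), report(0.59, 0.11, 0.57))
  expect_equal(g1$delta_accuracy, 0.41)
  expect_equal(g1$delta_mcc, 0.89)
  expect_equal(g1$delta_f1, 0.43)
  # augmented model: the gap narrows
  g2 <- generalization_gap(report(0.87, 0.78, 0.90), report(0.84, 0.60, 0.84))
  expect_equal(g2$delta_accuracy, 0.03)
  expect_equal(g2$delta_mcc, 0.18)
  expect_equal(g2$delta_f1, 0.06, tolerance = 1e-12)
  # identical reports give zero deltas
  g0 <- generalization_gap(report(0.8, 0.5, 0.7), report(0.8, 0.5, 0.7))
  expect_equal(unlist(unclass(g0)), c(delta_accuracy = 0, delta_mcc = 0,
                                      delta_f1 = 0))
})
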