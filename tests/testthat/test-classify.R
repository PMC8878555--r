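# Stratified folds, the three classifier families, CV, metrics, ROC/AUC.

test_that("stratified folds respect the 262:38 imbalance", {
  labels <- c(rep("term", 262), rep("preterm", 38))
  folds <- stratified_folds(labels, k = 10, seed = 99)
  for (f in folds) {
    expect_true(sum(labels[f] == "preterm") %in% c(3, 4))
    expect_true(sum(labels[f] == "term") %in% c(26, 27))
  }
  expect_identical(sort(unlist(folds)), seq_along(labels))

  # exact division: one of each per fold
  f2 <- stratified_folds(rep(c("term", "preterm"), each = 10), k = 10, seed = 1)
  for (f in f2) expect_identical(length(f), 2L)

  expect_error(stratified_folds(c(rep("term", 50), rep("preterm", 5)),
                                k = 10, seed = 1),
               "stratification error")
})

test_that("folds partition indices for random label vectors, deterministically", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(40:120, 1)
    labels <- sample(c("term", "preterm"), n, replace = TRUE,
                     prob = c(0.8, 0.2))
    k <- 4
    if (min(table(labels)) < k) next
    f1 <- stratified_folds(labels, k = k, seed = i)
    expect_identical(sort(unlist(f1)), seq_len(n))
    expect_identical(length(unlist(f1)), n) # pairwise disjoint given the sort check
    expect_identical(f1, stratified_folds(labels, k = k, seed = i))
  }
})

test_that("all three classifiers separate a separable toy set", {
  fm <- normalize_features(make_toy_matrix(n_term = 40, n_preterm = 25))
  X <- as.matrix(as.data.frame(fm)[, c("RMS_IMF1", "RMS_IMF2", "SampEn_IMF1",
                                       "SampEn_IMF2", "MTKE_IMF1", "MTKE_IMF2")])
  y <- fm$label
  for (config in list(classifier_config("knn", knn_k = 4),
                      classifier_config("svm", svm_kernel = "linear"),
                      classifier_config("svm", svm_kernel = "rbf"),
                      classifier_config("svm", svm_kernel = "poly"),
                      classifier_config("dt", dt_min_leaf_size = 10))) {
    model <- train_classifier(config, X, y)
    pred <- predict(model, X)
    expect_identical(unname(pred), ifelse(y == "preterm", 1, -1),
                     info = config$kind)
  }
  expect_error(train_classifier(classifier_config("knn"), X,
                                rep("term", nrow(X))),
               "training error")
})

test_that("1-NN reproduces training labels; trees respect the split budget", {
  fm <- normalize_features(make_toy_matrix(gap = 0.5)) # overlapping classes
  X <- ehgemd:::feature_cols_matrix(fm)
  y <- fm$label
  m1 <- train_classifier(classifier_config("knn", knn_k = 1), X, y)
  expect_identical(unname(predict(m1, X)), ifelse(y == "preterm", 1, -1))

  for (mns in c(1, 3, 6)) {
    tr <- train_classifier(
      classifier_config("dt", dt_max_splits = mns, dt_min_leaf_size = 2), X, y)
    internal <- sum(!vapply(tr$nodes, `[[`, logical(1), "leaf"))
    expect_lte(internal, mns)
  }
})

test_that("confusion_metrics reproduces the definitions", {
  expect_equal(confusion_metrics(9, 1, 90, 10), c(Se = 90, Sp = 90, Acc = 90))
  expect_equal(confusion_metrics(5, 0, 20, 0), c(Se = 100, Sp = 100, Acc = 100))
  m <- confusion_metrics(3, 1, 25, 1)
  expect_equal(unname(m["Se"]), 75)
  expect_equal(unname(m["Sp"]), 2500 / 26)
  expect_equal(unname(m["Acc"]), 2800 / 30)
  expect_error(confusion_metrics(0, 0, 5, 5), "undefined-metric")
})

test_that("roc_auc equals the Mann-Whitney concordance oracle", {
  expect_equal(roc_auc(c(5, 4, 3, 2, 1),
                       c("preterm", "preterm", "term", "term", "term"))$auc, 1.0)
  set.seed(12)
  for (i in 1:40) {
    n <- sample(20:80, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    s <- round(rnorm(n), 1) # rounding forces ties
    r <- roc_auc(s, ifelse(pos, "preterm", "term"))
    expect_equal(r$auc, auc_oracle(s, pos), tolerance = 1e-12)
    expect_true(all(diff(r$roc_points[, "fpr"]) >= 0))
    expect_true(all(diff(r$roc_points[, "tpr"]) >= 0))
  }
  expect_error(roc_auc(1:5, rep("term", 5)), "both classes")
})

test_that("random scores give chance-level AUC", {
  set.seed(3)
  lab <- ifelse(runif(10000) < 0.5, "preterm", "term")
  expect_lt(abs(roc_auc(rnorm(10000), lab)$auc - 0.5), 0.02)
})

test_that("cross_validate conserves class totals, is deterministic, and aces separable data", {
  fm <- make_toy_matrix(n_term = 52, n_preterm = 13)
  cfg <- classifier_config("knn", knn_k = 4)
  res <- cross_validate(cfg, fm, k = 5, repetitions = 4, base_seed = 11)
  for (cm in res$per_repetition) {
    expect_identical(unname(cm["TP"] + cm["FN"]), 13L)
    expect_identical(unname(cm["TN"] + cm["FP"]), 52L)
  }
  expect_identical(res$acc_mean, 100)
  expect_identical(res$se_mean, 100)
  expect_identical(res$sp_mean, 100)
  expect_equal(res$auc, 1.0)

  res2 <- cross_validate(cfg, fm, k = 5, repetitions = 4, base_seed = 11)
  expect_identical(res, res2)
})

test_that("label permutation drives accuracy to the majority rate and AUC to 0.5", {
  set.seed(9)
  fm <- make_toy_matrix(n_term = 105, n_preterm = 15, gap = 6)
  fm$label <- sample(fm$label) # break the feature-label link
  res <- cross_validate(classifier_config("svm", svm_kernel = "linear"), fm,
                        k = 5, repetitions = 3, base_seed = 2)
  expect_gt(res$acc_mean, 70)   # near majority-class rate (87.5%)
  expect_lt(res$se_mean, 40)    # positives are unlearnable
  expect_lt(abs(res$auc - 0.5), 0.25)
})

test_that("train_only normalization never uses test-fold statistics", {
  fm <- make_toy_matrix(n_term = 40, n_preterm = 10)
  # shift one held-out-able block grossly; leakage would rescale training data
  res <- cross_validate(classifier_config("knn", knn_k = 3), fm, k = 5,
                        repetitions = 2, base_seed = 4,
                        normalize_mode = "train_only")
  expect_s3_class(res, "eval_result")
  expect_identical(res$normalization_mode, "train_only")
  # the separable structure survives leakage-safe normalization
  expect_gt(res$acc_mean, 95)
})

test_that("inner-search SVM tuning trains and predicts", {
  fm <- normalize_features(make_toy_matrix(n_term = 30, n_preterm = 10))
  X <- ehgemd:::feature_cols_matrix(fm)
  m <- train_classifier(classifier_config("svm", svm_kernel = "rbf",
                                          tuning = "inner_search"),
                        X, fm$label, seed = 5)
  expect_identical(unname(predict(m, X)), ifelse(fm$label == "preterm", 1, -1))
})
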