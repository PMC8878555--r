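#' Classifier configuration
#'
#' Bundles the hyperparameters for the three supported classifier families.
#' Only the fields relevant to `kind` are used. Defaults follow the common
#' sweep points for this problem: kNN neighbour counts {2,4,8,10,12} with
#' Euclidean distance; SVM kernels linear/RBF/poly (poly degree 3, box
#' constraint 1); decision tree with a 6-internal-node budget and minimum
#' leaf sizes swept over {10,20,30,40,50}.
#'
#' @param kind `"knn"`, `"svm"` or `"dt"`.
#' @param knn_k Number of neighbours (>= 1).
#' @param knn_metric Distance metric; only `"euclidean"` is implemented.
#' @param svm_kernel `"linear"`, `"rbf"` or `"poly"`.
#' @param svm_poly_degree Polynomial kernel degree.
#' @param svm_cost Box constraint C.
#' @param dt_max_splits Internal-node budget (maximum number of splits).
#' @param dt_min_leaf_size Minimum observations per leaf.
#' @param tuning `"default"` (fixed hyperparameters) or `"inner_search"`
#'   (SVM only: inner 5-fold grid over cost and kernel scale on training
#'   data).
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("knn", "svm", "dt"),
                              knn_k = 4L, knn_metric = "euclidean",
                              svm_kernel = "poly", svm_poly_degree = 3L,
                              svm_cost = 1,
                              dt_max_splits = 6L, dt_min_leaf_size = 20L,
                              tuning = c("default", "inner_search")) {
  kind <- match.arg(kind)
  tuning <- match.arg(tuning)
  if (knn_k < 1) stop("knn_k must be >= 1")
  if (dt_max_splits < 1) stop("dt_max_splits must be >= 1")
  if (knn_metric != "euclidean") stop("only the euclidean metric is implemented")
  structure(list(kind = kind, knn_k = as.integer(knn_k),
                 knn_metric = knn_metric, svm_kernel = svm_kernel,
                 svm_poly_degree = as.integer(svm_poly_degree),
                 svm_cost = svm_cost,
                 dt_max_splits = as.integer(dt_max_splits),
                 dt_min_leaf_size = as.integer(dt_min_leaf_size),
                 tuning = tuning),
            class = "classifier_config")
}

config_label <- function(config) {
  switch(config$kind,
         knn = sprintf("kNN (K=%d)", config$knn_k),
         svm = sprintf("SVM (%s)", config$svm_kernel),
         dt = sprintf("DT (MNS=%d, MLS=%d)",
                      config$dt_max_splits, config$dt_min_leaf_size))
}

#' Stratified k-fold partition
#'
#' Splits indices into `k` folds preserving class proportions: within each
#' class, a seeded shuffle is dealt round-robin, so per-class counts across
#' folds differ by at most one and every fold contains both classes.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param labels Character or factor label vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of `k` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, k = 10L, seed) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  labels <- as.character(labels)
  counts <- table(labels)
  if (min(counts) < k)
    stop(sprintf(
      "stratification error: minority class has %d members, fewer than k = %d folds",
      min(counts), k))
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  folds <- vector("list", k)
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    assign_to <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
  }
  lapply(folds, sort)
}

# Seed-scoped RNG helpers: set a local seed, restore the global state after.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

feature_cols_matrix <- function(fm) {
  as.matrix(as.data.frame(fm)[, feature_names(), drop = FALSE])
}

#' Train a classifier
#'
#' Dispatches on `config$kind`. Labels use `preterm` as the positive class
#' throughout. The returned model supports
#' `predict(model, X, type = "class")` (labels in {-1, +1}) and
#' `type = "score"` (higher = more preterm-like: kNN preterm vote fraction,
#' DT leaf preterm proportion, SVM signed decision value).
#'
#' @param config A [classifier_config()].
#' @param X Numeric feature matrix (normalized).
#' @param y Labels: `"preterm"`/`"term"` character vector or numeric
#'   {-1, +1}.
#' @param seed Seed for any internal tuning randomness.
#' @return An opaque trained model.
#' @export
train_classifier <- function(config, X, y, seed = 1L) {
  X <- as.matrix(X)
  yy <- if (is.numeric(y)) y else ifelse(y == "preterm", 1, -1)
  if (length(unique(yy)) < 2)
    stop("training error: single-class training set")
  switch(config$kind,
    knn = structure(list(X = X, y = yy, k = config$knn_k), class = "ehg_knn"),
    svm = {
      cost <- config$svm_cost; scale <- 1
      if (config$tuning == "inner_search") {
        tuned <- svm_tune(X, yy, config$svm_kernel, config$svm_poly_degree,
                          seed = seed)
        cost <- tuned$cost; scale <- tuned$scale
      }
      svm_fit(X, yy, kernel = config$svm_kernel, cost = cost,
              degree = config$svm_poly_degree, scale = scale)
    },
    dt = tree_fit(X, yy, max_splits = config$dt_max_splits,
                  min_leaf = config$dt_min_leaf_size))
}

#' @export
predict.ehg_knn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  k <- min(object$k, nrow(object$X))
  out <- vapply(seq_len(nrow(X)), function(r) {
    d2 <- colSums((t(object$X) - X[r, ])^2)
    nb <- order(d2)[seq_len(k)]
    votes <- object$y[nb]
    frac_pos <- mean(votes > 0)
    cls <- if (frac_pos > 0.5) 1
           else if (frac_pos < 0.5) -1
           else votes[1]            # tie: nearest neighbour decides
    c(cls, frac_pos)
  }, numeric(2))
  if (type == "score") out[2, ] else out[1, ]
}

#' Sensitivity, specificity, accuracy from confusion counts
#'
#' `Se = TP/(TP+FN) * 100`, `Sp = TN/(TN+FP) * 100`,
#' `Acc = (TP+TN)/(TP+TN+FP+FN) * 100`, with preterm the positive class.
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return Named numeric vector `c(Se, Sp, Acc)` in percent.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  if (tp + fn < 1 || tn + fp < 1)
    stop("undefined-metric error: a class is empty")
  c(Se = tp / (tp + fn) * 100,
    Sp = tn / (tn + fp) * 100,
    Acc = (tp + tn) / (tp + tn + fp + fn) * 100)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (equal scores form a
#' single threshold step), yielding the ROC as ordered (1-Sp, Se) points
#' from (0,0) to (1,1); the AUC is the trapezoidal integral, which equals
#' the Mann--Whitney pairwise concordance with ties counted one half.
#'
#' @param scores Numeric vector, higher = more preterm-like.
#' @param labels Labels (`"preterm"` positive, or numeric {-1,+1}).
#' @return List with `roc_points` (two-column matrix `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.numeric(labels)) labels > 0 else labels == "preterm"
  if (!any(pos) || all(pos)) stop("roc error: both classes must be present")
  if (!all(is.finite(scores))) stop("roc error: non-finite scores")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single threshold steps
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(p)[last_of_tie] / sum(pos)
  fpr <- cumsum(!p)[last_of_tie] / sum(!pos)
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc_points = cbind(fpr = fpr, tpr = tpr), auc = auc)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition (seed = `base_seed` + repetition index - 1): build
#' stratified folds, train on k-1 folds, predict the held-out fold, and pool
#' the confusion counts over the k folds (so sensitivity is never computed
#' on a lone fold holding only 3-4 preterm records). Summary means and SDs
#' are taken across repetitions. Out-of-fold decision scores of the first
#' repetition are retained for the ROC/AUC.
#'
#' With `normalize_mode = "global"` the matrix must already be normalized
#' (or is normalized here over all rows); with `"train_only"` each fold's
#' feature statistics come strictly from its training rows.
#'
#' @param config A [classifier_config()].
#' @param matrix A `feature_matrix`.
#' @param k Folds (default 10).
#' @param repetitions Repetitions (default 30).
#' @param base_seed Base seed; repetition r uses `base_seed + r - 1`.
#' @param normalize_mode `"global"` or `"train_only"`.
#' @return Object of class `eval_result`.
#' @export
cross_validate <- function(config, matrix, k = 10L, repetitions = 30L,
                           base_seed = 1L,
                           normalize_mode = c("global", "train_only")) {
  normalize_mode <- match.arg(normalize_mode)
  labels <- matrix$label
  n <- length(labels)
  if (normalize_mode == "global" && !isTRUE(attr(matrix, "normalized")))
    matrix <- normalize_features(matrix, mode = "global")
  raw <- feature_cols_matrix(matrix)

  per_rep <- vector("list", repetitions)
  seeds <- base_seed + seq_len(repetitions) - 1L
  roc_scores <- rep(NA_real_, n)
  for (r in seq_len(repetitions)) {
    folds <- stratified_folds(labels, k = k, seed = seeds[r])
    cm <- c(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
    for (f in folds) {
      tr <- setdiff(seq_len(n), f)
      if (normalize_mode == "train_only") {
        mu <- colMeans(raw[tr, , drop = FALSE])
        sds <- apply(raw[tr, , drop = FALSE], 2, stats::sd)
        if (any(sds == 0)) stop("degenerate-feature error in training fold")
        Xtr <- sweep(sweep(raw[tr, , drop = FALSE], 2, mu), 2, sds, "/")
        Xte <- sweep(sweep(raw[f, , drop = FALSE], 2, mu), 2, sds, "/")
      } else {
        Xtr <- raw[tr, , drop = FALSE]
        Xte <- raw[f, , drop = FALSE]
      }
      model <- train_classifier(config, Xtr, labels[tr], seed = seeds[r])
      pred <- predict(model, Xte, type = "class")
      truth <- ifelse(labels[f] == "preterm", 1, -1)
      cm["TP"] <- cm["TP"] + sum(pred == 1 & truth == 1)
      cm["FN"] <- cm["FN"] + sum(pred == -1 & truth == 1)
      cm["TN"] <- cm["TN"] + sum(pred == -1 & truth == -1)
      cm["FP"] <- cm["FP"] + sum(pred == 1 & truth == -1)
      if (r == 1L) roc_scores[f] <- predict(model, Xte, type = "score")
    }
    per_rep[[r]] <- cm
  }
  mets <- t(vapply(per_rep, function(cm)
    confusion_metrics(cm["TP"], cm["FN"], cm["TN"], cm["FP"]), numeric(3)))
  roc <- roc_auc(roc_scores, labels)
  structure(
    list(config = config,
         channel = if (!is.null(matrix$channel)) matrix$channel[1] else NA,
         normalization_mode = normalize_mode,
         per_repetition = per_rep,
         se_mean = mean(mets[, "Se"]), se_sd = stats::sd(mets[, "Se"]),
         sp_mean = mean(mets[, "Sp"]), sp_sd = stats::sd(mets[, "Sp"]),
         acc_mean = mean(mets[, "Acc"]), acc_sd = stats::sd(mets[, "Acc"]),
         roc_points = roc$roc_points, auc = roc$auc,
         roc_seed = seeds[1], seeds = seeds, k = k),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "%s  %s  [%s norm., %d-fold x %d reps]\n  Se %.1f%% (sd %.1f)  Sp %.1f%% (sd %.1f)  Acc %.1f%% (sd %.1f)  AUC %.3f\n",
    config_label(x$config), x$channel, x$normalization_mode,
    x$k, length(x$seeds),
    x$se_mean, x$se_sd, x$sp_mean, x$sp_sd, x$acc_mean, x$acc_sd, x$auc))
  invisible(x)
}

#' Serialize an evaluation result as structured text (JSON)
#'
#' @param result An `eval_result`.
#' @param path Output path.
#' @export
write_eval_result <- function(result, path) {
  obj <- list(
    config = unclass(result$config),
    channel = result$channel,
    normalization_mode = result$normalization_mode,
    k = result$k, seeds = result$seeds, roc_seed = result$roc_seed,
    per_repetition = lapply(result$per_repetition, as.list),
    summary = list(se_mean = result$se_mean, se_sd = result$se_sd,
                   sp_mean = result$sp_mean, sp_sd = result$sp_sd,
                   acc_mean = result$acc_mean, acc_sd = result$acc_sd,
                   auc = result$auc),
    roc_points = apply(result$roc_points, 1, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
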