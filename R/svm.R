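#' Soft-margin kernel SVM via the exact dual quadratic program
#'
#' C-classification SVM trained by solving the dual QP with
#' `quadprog::solve.QP` (problems here are a few hundred rows, so the exact
#' dense solve is both simple and fast). Kernels: `"linear"` (x.y), `"rbf"`
#' (`exp(-gamma ||x-y||^2)`), `"poly"` (`(1 + x.y)^degree`). A small ridge
#' is added to the (possibly semidefinite) kernel matrix for positive
#' definiteness and grown if the solver still complains.
#'
#' @param X Numeric matrix of training rows (already normalized).
#' @param y Labels coercible to {-1, +1}: `+1` = positive class.
#' @param kernel `"linear"`, `"rbf"` or `"poly"`.
#' @param cost Box constraint C (default 1, the common ecosystem default).
#' @param gamma RBF width; default `1 / ncol(X)`.
#' @param degree Polynomial degree (default 3).
#' @param scale Kernel scale: inputs are divided by `scale` before the
#'   kernel is applied (default 1).
#' @return Object of class `ehg_svm` with a `predict` method returning
#'   signed decision values (`type = "score"`) or labels.
#' @keywords internal
svm_fit <- function(X, y, kernel = c("linear", "rbf", "poly"),
                    cost = 1, gamma = NULL, degree = 3L, scale = 1) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X) / scale
  y <- as.numeric(y)
  stopifnot(all(y %in% c(-1, 1)))
  n <- nrow(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)

  K <- kernel_matrix(X, X, kernel, gamma, degree)
  D <- (y %o% y) * K
  ridge <- 1e-8 * mean(diag(D))
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  sol <- NULL
  for (tries in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(D + diag(ridge, n), rep(1, n), Amat, bvec, meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) stop("training error: SVM dual QP failed to solve")
  alpha <- pmin(pmax(sol$solution, 0), cost)
  eps <- 1e-6 * cost
  sv <- alpha > eps
  coef <- alpha[sv] * y[sv]
  f_raw <- as.numeric(K[, sv, drop = FALSE] %*% coef)
  free <- sv & alpha < cost - eps
  b <- if (any(free)) mean(y[free] - f_raw[free])
       else mean(y[sv] - f_raw[sv])
  structure(
    list(X_sv = X[sv, , drop = FALSE], coef = coef, b = b, kernel = kernel,
         gamma = gamma, degree = degree, scale = scale, cost = cost),
    class = "ehg_svm")
}

kernel_matrix <- function(A, B, kernel, gamma, degree) {
  G <- A %*% t(B)
  switch(kernel,
    linear = G,
    poly = (1 + G)^degree,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
      exp(-gamma * pmax(d2, 0))
    })
}

#' @export
predict.ehg_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  K <- kernel_matrix(as.matrix(newdata) / object$scale, object$X_sv,
                     object$kernel, object$gamma, object$degree)
  f <- as.numeric(K %*% object$coef) + object$b
  if (type == "score") f else ifelse(f >= 0, 1, -1)
}

# Inner 5-fold grid search over cost and kernel scale, training data only.
svm_tune <- function(X, y, kernel, degree, seed = 1L,
                     costs = c(0.1, 1, 10, 100),
                     scales = c(0.25, 0.5, 1, 2, 4)) {
  folds <- stratified_folds(ifelse(y > 0, "pos", "neg"),
                            k = min(5L, sum(y > 0), sum(y < 0)), seed = seed)
  best <- list(acc = -1, cost = 1, scale = 1)
  for (cost in costs) for (sc in scales) {
    correct <- 0L
    for (f in folds) {
      tr <- setdiff(seq_along(y), f)
      if (length(unique(y[tr])) < 2) next
      m <- svm_fit(X[tr, , drop = FALSE], y[tr], kernel = kernel,
                   cost = cost, degree = degree, scale = sc)
      correct <- correct + sum(predict(m, X[f, , drop = FALSE]) == y[f])
    }
    if (correct > best$acc) best <- list(acc = correct, cost = cost, scale = sc)
  }
  best
}
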