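# CART-style binary decision tree: Gini impurity, best-first growth under an
# internal-node budget (the "maximum number of splits"), minimum leaf size.
# Scores are leaf positive-class proportions.

gini_gain <- function(xcol, pos, min_leaf) {
  # best threshold for one feature; returns c(gain, threshold) or NULL
  ord <- order(xcol)
  xs <- xcol[ord]; ps <- pos[ord]
  n <- length(xs)
  npos <- sum(ps)
  cum_pos <- cumsum(ps)
  i <- seq_len(n - 1)
  valid <- which(xs[i] < xs[i + 1] & i >= min_leaf & (n - i) >= min_leaf)
  if (length(valid) == 0) return(NULL)
  nl <- valid
  pl <- cum_pos[valid]
  nr <- n - nl
  pr <- npos - pl
  gini <- function(p, m) { q <- p / m; 2 * q * (1 - q) }
  parent <- gini(npos, n)
  child <- (nl * gini(pl, nl) + nr * gini(pr, nr)) / n
  gains <- parent - child
  b <- which.max(gains)
  c(gain = gains[b] * n, threshold = (xs[valid[b]] + xs[valid[b] + 1]) / 2)
}

best_split <- function(X, pos, idx, min_leaf) {
  out <- NULL
  for (j in seq_len(ncol(X))) {
    g <- gini_gain(X[idx, j], pos[idx], min_leaf)
    if (!is.null(g) && g["gain"] > 1e-12 &&
        (is.null(out) || g["gain"] > out$gain))
      out <- list(feature = j, threshold = unname(g["threshold"]),
                  gain = unname(g["gain"]))
  }
  out
}

tree_fit <- function(X, y, max_splits = 6L, min_leaf = 20L) {
  X <- as.matrix(X)
  pos <- as.numeric(y) > 0
  nodes <- list(list(idx = seq_len(nrow(X)), leaf = TRUE,
                     p = mean(pos), n = nrow(X)))
  cand <- list(best_split(X, pos, nodes[[1]]$idx, min_leaf))
  n_splits <- 0L
  while (n_splits < max_splits) {
    gains <- vapply(seq_along(nodes), function(i) {
      if (nodes[[i]]$leaf && !is.null(cand[[i]])) cand[[i]]$gain else -Inf
    }, numeric(1))
    if (all(!is.finite(gains)) || max(gains) <= 0) break
    i <- which.max(gains)
    sp <- cand[[i]]
    idx <- nodes[[i]]$idx
    go_left <- X[idx, sp$feature] <= sp$threshold
    li <- idx[go_left]; ri <- idx[!go_left]
    nodes[[i]]$leaf <- FALSE
    nodes[[i]]$feature <- sp$feature
    nodes[[i]]$threshold <- sp$threshold
    for (child in list(li, ri)) {
      nodes[[length(nodes) + 1L]] <- list(idx = child, leaf = TRUE,
                                          p = mean(pos[child]),
                                          n = length(child))
      # single-bracket assignment: a NULL candidate must not shrink the list
      cand[length(nodes)] <- list(best_split(X, pos, child, min_leaf))
    }
    nodes[[i]]$left <- length(nodes) - 1L
    nodes[[i]]$right <- length(nodes)
    n_splits <- n_splits + 1L
  }
  nodes <- lapply(nodes, function(nd) { nd$idx <- NULL; nd })
  structure(list(nodes = nodes, n_splits = n_splits), class = "ehg_tree")
}

#' @export
predict.ehg_tree <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  p <- vapply(seq_len(nrow(X)), function(r) {
    i <- 1L
    while (!object$nodes[[i]]$leaf) {
      nd <- object$nodes[[i]]
      i <- if (X[r, nd$feature] <= nd$threshold) nd$left else nd$right
    }
    object$nodes[[i]]$p
  }, numeric(1))
  if (type == "score") p else ifelse(p >= 0.5, 1, -1)
}
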