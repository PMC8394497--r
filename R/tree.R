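# Minimal CART-style binary classification tree and a bagged ensemble.
# Written in-package because no recursive-partitioning or random-forest
# package is available in the supported environment; the data sizes here
# (tens of subjects, tens of features) keep the exhaustive split search
# cheap. Splits minimise weighted Gini impurity; leaves store the positive-
# class proportion.

gini <- function(y) {
  if (length(y) == 0) return(0)
  p <- mean(y)
  2 * p * (1 - p)
}

best_split <- function(X, y, feat_idx, min_leaf) {
  n <- length(y)
  best <- list(gain = 0, feature = NA, threshold = NA)
  g0 <- gini(y)
  for (j in feat_idx) {
    x <- X[, j]
    ux <- sort(unique(x))
    if (length(ux) < 2) next
    thr <- (ux[-1] + ux[-length(ux)]) / 2
    for (t in thr) {
      l <- x <= t
      nl <- sum(l)
      if (nl < min_leaf || n - nl < min_leaf) next
      gain <- g0 - (nl * gini(y[l]) + (n - nl) * gini(y[!l])) / n
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = j, threshold = t)
      }
    }
  }
  best
}

grow_tree <- function(X, y, depth, max_depth, min_split, min_leaf, mtry,
                      importance) {
  node <- list(prob = mean(y), n = length(y))
  if (depth >= max_depth || length(y) < min_split ||
      length(unique(y)) == 1L) {
    node$leaf <- TRUE
    return(list(node = node, importance = importance))
  }
  p <- ncol(X)
  feat_idx <- if (is.null(mtry) || mtry >= p) seq_len(p)
              else sort(sample.int(p, mtry))
  sp <- best_split(X, y, feat_idx, min_leaf)
  if (is.na(sp$feature) || sp$gain <= 0) {
    node$leaf <- TRUE
    return(list(node = node, importance = importance))
  }
  importance[sp$feature] <- importance[sp$feature] + sp$gain * length(y)
  l <- X[, sp$feature] <= sp$threshold
  left <- grow_tree(X[l, , drop = FALSE], y[l], depth + 1, max_depth,
                    min_split, min_leaf, mtry, importance)
  right <- grow_tree(X[!l, , drop = FALSE], y[!l], depth + 1, max_depth,
                     min_split, min_leaf, mtry, left$importance)
  node$leaf <- FALSE
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$left <- left$node
  node$right <- right$node
  list(node = node, importance = right$importance)
}

#' Fit a small CART-style classification tree
#'
#' @param X numeric matrix (subjects x features).
#' @param y 0/1 response (1 = positive class).
#' @param max_depth,min_split,min_leaf stopping rules.
#' @param mtry number of features tried per split (NULL = all; used by the
#'   bagged ensemble).
#' @return object of class \code{cart_tree} with per-feature split-gain
#'   importance.
#' @export
fit_cart <- function(X, y, max_depth = 3, min_split = 6, min_leaf = 3,
                     mtry = NULL) {
  X <- as.matrix(X)
  res <- grow_tree(X, y, 0, max_depth, min_split, min_leaf, mtry,
                   stats::setNames(numeric(ncol(X)), colnames(X)))
  structure(list(root = res$node, importance = res$importance,
                 features = colnames(X)), class = "cart_tree")
}

predict_node <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$prob
}

#' @export
predict.cart_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  apply(newdata, 1, function(x) predict_node(object$root, x))
}

#' Fit a bagged ensemble of randomised trees
#'
#' Bootstrap-aggregated CART trees with random feature subsets per split
#' (mtry = sqrt(p) by default): a compact random-forest analogue. Scores
#' are the mean leaf positive-class proportion across trees. Out-of-bag
#' permutation importance (mean accuracy drop when a feature is permuted in
#' the OOB samples) is computed when \code{importance = TRUE}.
#'
#' @inheritParams fit_cart
#' @param n_trees ensemble size.
#' @param importance compute OOB permutation importance.
#' @return object of class \code{bagged_trees}.
#' @export
fit_bagged_trees <- function(X, y, n_trees = 60, max_depth = 3,
                             min_split = 4, min_leaf = 2,
                             importance = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  mtry <- max(1L, floor(sqrt(p)))
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    bs <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- fit_cart(X[bs, , drop = FALSE], y[bs],
                           max_depth = max_depth, min_split = min_split,
                           min_leaf = min_leaf, mtry = mtry)
    oob[[b]] <- setdiff(seq_len(n), bs)
  }
  imp <- NULL
  if (importance) {
    imp <- stats::setNames(numeric(p), colnames(X))
    for (b in seq_len(n_trees)) {
      ob <- oob[[b]]
      if (length(ob) < 2) next
      base <- mean((predict(trees[[b]], X[ob, , drop = FALSE]) > 0.5) ==
                     (y[ob] == 1))
      for (j in seq_len(p)) {
        Xp <- X[ob, , drop = FALSE]
        Xp[, j] <- Xp[sample.int(length(ob)), j]
        perm <- mean((predict(trees[[b]], Xp) > 0.5) == (y[ob] == 1))
        imp[j] <- imp[j] + (base - perm)
      }
    }
    imp <- imp / n_trees
  }
  structure(list(trees = trees, importance = imp, features = colnames(X)),
            class = "bagged_trees")
}

#' @export
predict.bagged_trees <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  preds <- vapply(object$trees, function(tr) predict(tr, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}
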