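# Classifier registry for the repeated-holdout benchmark.
#
# Each entry is a list(fit = function(X, y) -> model,
#                      score = function(model, X) -> numeric in [0, 1])
# with X a standardized numeric matrix and y a 0/1 vector (1 = positive
# class, i.e. progression). Scores are comparable to a 0.5 threshold.
# Several learners (naive Bayes, nearest centroids, linear SVM, kNN
# scoring) are implemented in-package because no dedicated package is
# available in the supported environment; all operate on tiny panels
# (tens of subjects, ~10 features), where the simple implementations are
# exact enough and fast.

fit_knn <- function(X, y, k = 5) {
  k <- min(k, nrow(X))
  list(X = X, y = y, k = k)
}

score_knn <- function(model, X) {
  nn <- FNN::knnx.index(model$X, as.matrix(X), k = model$k)
  rowMeans(matrix(model$y[nn], nrow = nrow(X)))
}

fit_lasso <- function(X, y) {
  if (ncol(X) < 2) {
    # glmnet needs >= 2 columns; fall back to univariate logistic
    df <- data.frame(y = y, x = X[, 1])
    return(list(kind = "glm",
                fit = suppressWarnings(stats::glm(y ~ x, df,
                                                  family = stats::binomial))))
  }
  nf <- max(3, min(5, floor(length(y) / 4)))
  foldid <- rep_len(seq_len(nf), length(y))[order(order(y))]
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          nfolds = nf, foldid = foldid)
  list(kind = "glmnet", fit = cv)
}

score_lasso <- function(model, X) {
  if (model$kind == "glm") {
    as.numeric(stats::predict(model$fit,
                              data.frame(x = as.matrix(X)[, 1]),
                              type = "response"))
  } else {
    as.numeric(stats::predict(model$fit, as.matrix(X), s = "lambda.min",
                              type = "response"))
  }
}

fit_naive_bayes <- function(X, y) {
  eps <- 1e-6
  list(prior = mean(y),
       mu1 = colMeans(X[y == 1, , drop = FALSE]),
       mu0 = colMeans(X[y == 0, , drop = FALSE]),
       sd1 = pmax(apply(X[y == 1, , drop = FALSE], 2, stats::sd), eps),
       sd0 = pmax(apply(X[y == 0, , drop = FALSE], 2, stats::sd), eps))
}

score_naive_bayes <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  expand <- function(v) matrix(v, n, p, byrow = TRUE)
  ll1 <- rowSums(stats::dnorm(X, expand(model$mu1), expand(model$sd1),
                              log = TRUE))
  ll0 <- rowSums(stats::dnorm(X, expand(model$mu0), expand(model$sd0),
                              log = TRUE))
  stats::plogis(ll1 - ll0 + stats::qlogis(min(max(model$prior, 1e-6),
                                              1 - 1e-6)))
}

fit_centroid <- function(X, y, distance = c("euclidean", "spearman")) {
  distance <- match.arg(distance)
  list(c1 = colMeans(X[y == 1, , drop = FALSE]),
       c0 = colMeans(X[y == 0, , drop = FALSE]),
       distance = distance)
}

score_centroid <- function(model, X) {
  X <- as.matrix(X)
  dist_to <- function(cen) {
    if (model$distance == "euclidean") {
      sqrt(rowSums(sweep(X, 2, cen)^2))
    } else {
      # rank-correlation distance; degenerate (constant) profiles fall
      # back to zero correlation
      apply(X, 1, function(x) {
        r <- suppressWarnings(stats::cor(x, cen, method = "spearman"))
        1 - ifelse(is.na(r), 0, r)
      })
    }
  }
  d1 <- dist_to(model$c1); d0 <- dist_to(model$c0)
  d0 / pmax(d0 + d1, 1e-12)  # closer to positive centroid -> higher score
}

# L2-regularised squared-hinge linear SVM by BFGS; adequate for the tiny
# standardized panels used here.
fit_svm_linear <- function(X, y, lambda = 0.01) {
  ys <- ifelse(y == 1, 1, -1)
  p <- ncol(X)
  obj <- function(wb) {
    w <- wb[1:p]; b <- wb[p + 1]
    m <- pmax(0, 1 - ys * (X %*% w + b))
    lambda * sum(w^2) + mean(m^2)
  }
  grad <- function(wb) {
    w <- wb[1:p]; b <- wb[p + 1]
    m <- pmax(0, 1 - ys * (as.numeric(X %*% w) + b))
    gw <- 2 * lambda * w - 2 * colMeans(X * (m * ys))
    gb <- -2 * mean(m * ys)
    c(gw, gb)
  }
  fit <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(w = fit$par[1:p], b = fit$par[p + 1])
}

score_svm_linear <- function(model, X) {
  stats::plogis(as.numeric(as.matrix(X) %*% model$w + model$b))
}

fit_cart_clf <- function(X, y) fit_cart(X, y)

fit_forest_clf <- function(X, y) fit_bagged_trees(X, y)

#' Classifier registry
#'
#' Returns the named list of classifiers available to the benchmark:
#' k-nearest neighbours (\code{knn}), L1-regularised logistic regression
#' (\code{lasso}), a bagged randomised-tree ensemble (\code{rf}), a single
#' CART-style tree (\code{rpart}), a linear-kernel SVM (\code{svm}),
#' Gaussian naive Bayes (\code{naive_bayes}), nearest centroid with
#' Euclidean (\code{centroid_euclid}) and Spearman-correlation
#' (\code{centroid_spearman}) distances, and \code{ensemble} -- the
#' majority vote of all the others.
#'
#' @param names optional subset to return.
#' @return named list of \code{list(fit, score)} entries.
#' @export
classifier_registry <- function(names = NULL) {
  reg <- list(
    knn = list(fit = fit_knn, score = score_knn),
    lasso = list(fit = fit_lasso, score = score_lasso),
    rf = list(fit = fit_forest_clf,
              score = function(m, X) predict(m, X)),
    rpart = list(fit = fit_cart_clf,
                 score = function(m, X) predict(m, X)),
    svm = list(fit = fit_svm_linear, score = score_svm_linear),
    naive_bayes = list(fit = fit_naive_bayes, score = score_naive_bayes),
    centroid_euclid = list(
      fit = function(X, y) fit_centroid(X, y, "euclidean"),
      score = score_centroid),
    centroid_spearman = list(
      fit = function(X, y) fit_centroid(X, y, "spearman"),
      score = score_centroid))
  base_reg <- reg
  members <- names(base_reg)
  reg$ensemble <- list(
    fit = function(X, y) lapply(base_reg, function(cl) cl$fit(X, y)),
    score = function(m, X) {
      votes <- vapply(members,
                      function(nm) as.numeric(base_reg[[nm]]$score(m[[nm]], X) > 0.5),
                      numeric(nrow(as.matrix(X))))
      if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
      rowMeans(votes)
    })
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(reg))
    if (length(missing)) stop("unknown classifier(s): ",
                              paste(missing, collapse = ", "))
    reg <- reg[names]
  }
  reg
}
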