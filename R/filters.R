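# Feature-selection filter registry for the benchmark.
#
# Each filter is a function(X, y, k) returning up to k feature names,
# ranked most-informative first, computed on training data only. X is a
# standardized numeric matrix; y is 0/1. Constant features rank last.

rank_and_take <- function(score, k, decreasing = TRUE) {
  score[is.na(score)] <- if (decreasing) -Inf else Inf
  names(score)[order(score, decreasing = decreasing)][
    seq_len(min(k, length(score)))]
}

filter_wilcoxon <- function(X, y, k) {
  p <- apply(X, 2, function(v) {
    if (length(unique(v)) < 2) return(1)
    suppressWarnings(wilcoxon_rank_sum(v[y == 0], v[y == 1])$p_value)
  })
  rank_and_take(p, k, decreasing = FALSE)
}

filter_ttest <- function(X, y, k) {
  p <- apply(X, 2, function(v) {
    if (length(unique(v)) < 2) return(1)
    suppressWarnings(stats::t.test(v[y == 0], v[y == 1])$p.value)
  })
  rank_and_take(p, k, decreasing = FALSE)
}

filter_kendall <- function(X, y, k) {
  tau <- apply(X, 2, function(v) abs(kendall_tau_b(v, y)))
  rank_and_take(tau, k)
}

# greedy minimum-redundancy maximum-relevance: relevance = |tau_b with the
# class|, redundancy = mean |tau_b| with the already-selected set
filter_mrmr <- function(X, y, k) {
  rel <- apply(X, 2, function(v) abs(kendall_tau_b(v, y)))
  rel[is.na(rel)] <- 0
  feats <- colnames(X)
  sel <- character(0)
  k <- min(k, length(feats))
  tau_cache <- list()
  while (length(sel) < k) {
    rest <- setdiff(feats, sel)
    crit <- vapply(rest, function(f) {
      red <- if (length(sel) == 0) 0 else {
        mean(vapply(sel, function(s) {
          key <- paste(sort(c(f, s)), collapse = "|")
          if (is.null(tau_cache[[key]]))
            tau_cache[[key]] <<- abs(kendall_tau_b(X[, f], X[, s]))
          v <- tau_cache[[key]]
          if (is.na(v)) 0 else v
        }, numeric(1)))
      }
      rel[f] - red
    }, numeric(1))
    sel <- c(sel, rest[which.max(crit)])
  }
  sel
}

# order of first entry into the L1-regularised logistic path
filter_lasso <- function(X, y, k) {
  if (ncol(X) < 2) return(colnames(X)[seq_len(min(k, ncol(X)))])
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        nlambda = 100)
  beta <- as.matrix(fit$beta)
  entry <- apply(beta != 0, 1, function(r) if (any(r)) which(r)[1] else Inf)
  rank_and_take(-entry, k)
}

filter_rf <- function(X, y, k) {
  fit <- fit_bagged_trees(X, y, importance = TRUE)
  rank_and_take(fit$importance, k)
}

filter_rpart <- function(X, y, k) {
  fit <- fit_cart(X, y)
  imp <- fit$importance
  if (all(imp == 0)) return(filter_wilcoxon(X, y, k))
  rank_and_take(imp, k)
}

# univariate integrated discrimination improvement: the discrimination
# slope (mean fitted risk in events minus non-events) of the one-feature
# logistic model; the intercept-only reference has slope 0
filter_idi <- function(X, y, k) {
  idi <- apply(X, 2, function(v) {
    if (length(unique(v)) < 2) return(0)
    p <- stats::fitted(suppressWarnings(
      stats::glm(y ~ v, family = stats::binomial)))
    mean(p[y == 1]) - mean(p[y == 0])
  })
  rank_and_take(idi, k)
}

# univariate net reclassification improvement at threshold 0.5 against the
# constant-prevalence reference model
filter_nri <- function(X, y, k) {
  prev <- mean(y)
  nri <- apply(X, 2, function(v) {
    if (length(unique(v)) < 2) return(-Inf)
    p <- stats::fitted(suppressWarnings(
      stats::glm(y ~ v, family = stats::binomial)))
    up1 <- mean(p[y == 1] > 0.5) - mean(prev > 0.5)
    dn0 <- mean(p[y == 0] <= 0.5) - mean(prev <= 0.5)
    up1 + dn0
  })
  rank_and_take(nri, k)
}

#' Bootstrapped forward stepwise logistic selection
#'
#' A documented surrogate for bootstrapped stage-wise model selection:
#' on each of \code{n_boot} bootstrap resamples, features are added by
#' forward stepwise logistic regression (entry when the Wald p-value of
#' the candidate is below \code{p_enter}, up to \code{max_size} terms);
#' features selected in at least \code{min_freq} of the bootstraps form
#' the final set, ordered by selection frequency. Unlike the fixed-size
#' filters this returns a data-driven model size.
#'
#' @param X standardized numeric matrix.
#' @param y 0/1 response.
#' @param k upper bound on the returned set size.
#' @param n_boot bootstrap resamples.
#' @param p_enter entry p-value threshold.
#' @param min_freq minimum selection frequency across bootstraps.
#' @param max_size maximum model size per bootstrap.
#' @return Character vector of selected features (possibly length 1 when
#'   nothing is stable: the top univariate feature is the fallback).
#' @export
filter_stepwise_boot <- function(X, y, k, n_boot = 20, p_enter = 0.1,
                                 min_freq = 0.3, max_size = 6) {
  n <- nrow(X)
  counts <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (b in seq_len(n_boot)) {
    bs <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[bs])) < 2) next
    Xb <- X[bs, , drop = FALSE]; yb <- y[bs]
    sel <- character(0)
    repeat {
      rest <- setdiff(colnames(X), sel)
      if (length(rest) == 0 || length(sel) >= max_size) break
      base_dev <- suppressWarnings(stats::glm(
        yb ~ ., data.frame(yb = yb, Xb[, sel, drop = FALSE],
                           check.names = FALSE),
        family = stats::binomial))$deviance
      # likelihood-ratio entry test: Wald p-values collapse under the
      # separation this screen is meant to detect
      pv <- vapply(rest, function(f) {
        fit <- suppressWarnings(stats::glm(
          yb ~ ., data.frame(yb = yb, Xb[, c(sel, f), drop = FALSE],
                             check.names = FALSE),
          family = stats::binomial))
        stats::pchisq(base_dev - fit$deviance, df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (min(pv) >= p_enter) break
      sel <- c(sel, rest[which.min(pv)])
    }
    counts[sel] <- counts[sel] + 1
  }
  freq <- counts / n_boot
  keep <- names(freq)[freq >= min_freq]
  if (length(keep) == 0) return(filter_wilcoxon(X, y, 1))
  keep[order(freq[keep], decreasing = TRUE)][seq_len(min(k, length(keep)))]
}

#' Feature-filter registry
#'
#' Ranking functions used ahead of each classifier in the benchmark:
#' \code{wilcoxon} and \code{ttest} (univariate test p-values),
#' \code{kendall} (|tau-b| with the class), \code{mrmr} (greedy
#' minimum-redundancy maximum-relevance on tau-b), \code{lasso}
#' (L1-path entry order), \code{rf} (out-of-bag permutation importance of
#' a bagged-tree ensemble), \code{rpart} (split-gain importance of a
#' single tree), \code{idi} and \code{nri} (univariate reclassification
#' statistics of one-feature logistic models), and \code{bswims} (the
#' bootstrapped forward-stepwise surrogate,
#' \code{\link{filter_stepwise_boot}}).
#'
#' @param name a registered filter name (or NULL for the whole list).
#' @return A \code{function(X, y, k)} (or named list of them).
#' @export
filter_registry <- function(name = NULL) {
  reg <- list(wilcoxon = filter_wilcoxon,
              ttest = filter_ttest,
              kendall = filter_kendall,
              mrmr = filter_mrmr,
              lasso = filter_lasso,
              rf = filter_rf,
              rpart = filter_rpart,
              idi = filter_idi,
              nri = filter_nri,
              bswims = filter_stepwise_boot)
  if (is.null(name)) return(reg)
  if (!name %in% names(reg)) stop("unknown filter: ", name)
  reg[[name]]
}
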