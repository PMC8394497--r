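#' Configuration for the repeated stratified-holdout benchmark
#'
#' @param n_repeats number of random holdout repeats (default 100).
#' @param train_fraction fraction of subjects used for training (default
#'   0.8; splits are stratified by group, preserving group proportions to
#'   within one subject).
#' @param classifiers classifier names (see
#'   \code{\link{classifier_registry}}).
#' @param filters filter names (see \code{\link{filter_registry}}).
#' @param n_features number of features each fixed-size filter passes to
#'   its classifier.
#' @param seed RNG seed governing splits and every stochastic learner.
#' @param n_boot_ci bootstrap draws for the 95\% metric confidence
#'   intervals.
#' @return An object of class \code{benchmark_config}.
#' @export
benchmark_config <- function(n_repeats = 100, train_fraction = 0.8,
                             classifiers = c("knn", "lasso", "rf", "rpart",
                                             "svm", "naive_bayes",
                                             "centroid_euclid",
                                             "centroid_spearman",
                                             "ensemble"),
                             filters = c("wilcoxon", "ttest", "kendall",
                                         "mrmr", "lasso", "rf", "rpart",
                                         "idi", "nri"),
                             n_features = 10, seed = 1,
                             n_boot_ci = 2000) {
  stopifnot(n_repeats >= 1, train_fraction > 0, train_fraction < 1,
            n_features >= 1)
  structure(list(n_repeats = n_repeats, train_fraction = train_fraction,
                 classifiers = classifiers, filters = filters,
                 n_features = n_features, seed = seed,
                 n_boot_ci = n_boot_ci),
            class = "benchmark_config")
}

# stratified train/test splits: per group, round((1 - frac) * n_g) test
# subjects, so group proportions are preserved to within one subject
make_splits <- function(groups, n_repeats, train_fraction) {
  idx_by_group <- split(seq_along(groups), groups)
  lapply(seq_len(n_repeats), function(r) {
    test <- unlist(lapply(idx_by_group, function(ix) {
      nt <- max(1L, round((1 - train_fraction) * length(ix)))
      sample(ix, nt)
    }), use.names = FALSE)
    list(train = setdiff(seq_along(groups), test), test = sort(test))
  })
}

# train-fold-only preprocessing: drop columns mostly missing in training,
# impute the rest with the training median, standardize with training
# mean/sd. Returns the transformed train/test matrices.
preprocess_fold <- function(Xtr, Xte, max_missing = 0.2) {
  miss <- colMeans(is.na(Xtr))
  keep <- which(miss <= max_missing)
  Xtr <- Xtr[, keep, drop = FALSE]; Xte <- Xte[, keep, drop = FALSE]
  med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(Xtr))) {
    Xtr[is.na(Xtr[, j]), j] <- med[j]
    Xte[is.na(Xte[, j]), j] <- med[j]
  }
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, stats::sd)
  sg[sg == 0 | is.na(sg)] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sg, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sg, "/"))
}

#' Repeated stratified-holdout benchmark
#'
#' For each repeat, an 80/20 (by default) stratified split is drawn; for
#' each filter x classifier method the full pipeline -- median imputation,
#' standardization, feature filtering and model fitting -- is trained on
#' the training split only, and the held-out subjects' scores and class
#' predictions are recorded. Predictions are pooled over repeats for the
#' metric stage. Deterministic given \code{config$seed}.
#'
#' @param table a \code{\link{build_feature_table}} result.
#' @param config a \code{\link{benchmark_config}}.
#' @param pool feature columns available to the filters (e.g. the
#'   univariate selection pool); defaults to all feature columns.
#' @param splits optional precomputed split list (used to share identical
#'   splits across paired experiments).
#' @return An object of class \code{benchmark_report}: \code{predictions}
#'   (pooled out-of-sample rows), \code{selections} (features entering
#'   each trained model), \code{metrics} (per method, via
#'   \code{\link{compute_metrics}}), and \code{config}.
#' @export
repeated_holdout <- function(table, config = benchmark_config(),
                             pool = NULL, splits = NULL) {
  man <- table_manifest(table)
  if (is.null(pool)) pool <- man$column
  stopifnot(all(pool %in% colnames(table)))
  y <- as.integer(table$group == "MCIp")
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- as.matrix(table[, pool, drop = FALSE])
  set.seed(config$seed)
  if (is.null(splits))
    splits <- make_splits(table$group, config$n_repeats,
                          config$train_fraction)
  clf <- classifier_registry(config$classifiers)
  flt <- filter_registry()[config$filters]
  preds <- list(); sels <- list()
  for (r in seq_along(splits)) {
    tr <- splits[[r]]$train; te <- splits[[r]]$test
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2)
      stop("a split lost a class; stratification failed")
    pp <- preprocess_fold(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    for (fname in names(flt)) {
      feats <- flt[[fname]](pp$train, y[tr], config$n_features)
      for (cname in names(clf)) {
        model <- clf[[cname]]$fit(pp$train[, feats, drop = FALSE], y[tr])
        sc <- clf[[cname]]$score(model, pp$test[, feats, drop = FALSE])
        preds[[length(preds) + 1L]] <- data.frame(
          repeat_id = r, filter = fname, classifier = cname,
          subject = table$subject_id[te], truth = y[te],
          score = as.numeric(sc), pred = as.integer(sc > 0.5))
        sels[[length(sels) + 1L]] <- data.frame(
          repeat_id = r, filter = fname, classifier = cname,
          feature = feats)
      }
    }
  }
  predictions <- do.call(rbind, preds)
  selections <- do.call(rbind, sels)
  metrics <- compute_metrics(predictions, n_boot = config$n_boot_ci,
                             seed = config$seed)
  structure(list(predictions = predictions, selections = selections,
                 metrics = metrics, config = config, pool = pool),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d repeats, %d filter(s) x %d classifier(s), pool of %d features\n",
              x$config$n_repeats, length(unique(x$predictions$filter)),
              length(unique(x$predictions$classifier)), length(x$pool)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.benchmark_report <- function(object, ...) {
  m <- object$metrics
  data.frame(method = m$method,
             accuracy = sprintf("%.3f (%.3f-%.3f)", m$accuracy,
                                m$accuracy_lo, m$accuracy_hi),
             roc_auc = sprintf("%.3f (%.3f-%.3f)", m$roc_auc,
                               m$roc_auc_lo, m$roc_auc_hi),
             sensitivity = sprintf("%.3f", m$sensitivity),
             specificity = sprintf("%.3f", m$specificity),
             balanced_error = sprintf("%.3f", m$balanced_error))
}

# midrank (Mann-Whitney) AUC of scores against binary truth
auc_rank <- function(scores, truth) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class absent")
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metrics_from_pool <- function(df) {
  tp <- sum(df$pred == 1 & df$truth == 1)
  fn <- sum(df$pred == 0 & df$truth == 1)
  tn <- sum(df$pred == 0 & df$truth == 0)
  fp <- sum(df$pred == 1 & df$truth == 0)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  c(accuracy = (tp + tn) / nrow(df),
    sensitivity = sens, specificity = spec,
    balanced_error = 1 - (sens + spec) / 2,
    roc_auc = auc_rank(df$score, df$truth))
}

#' Pooled classification metrics with bootstrap confidence intervals
#'
#' From the pooled out-of-sample predictions of each method: accuracy,
#' sensitivity (positive class = progression, MCIp), specificity, balanced
#' error \eqn{1 - (sens + spec)/2} and the midrank ROC AUC, all at score
#' threshold 0.5. The 95\% CI is the percentile bootstrap over subjects
#' (clustered: all of a subject's pooled predictions move together).
#'
#' @param predictions the \code{predictions} data.frame of
#'   \code{\link{repeated_holdout}} (columns \code{filter},
#'   \code{classifier}, \code{subject}, \code{truth}, \code{score},
#'   \code{pred}).
#' @param n_boot bootstrap draws (0 disables CIs).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame, one row per filter x classifier method.
#' @export
compute_metrics <- function(predictions, n_boot = 2000, seed = 1) {
  stopifnot(all(c("truth", "score", "pred") %in% names(predictions)))
  if (length(unique(predictions$truth)) < 2)
    stop("metrics undefined: predictions contain a single class")
  if (is.null(predictions$filter)) predictions$filter <- "none"
  if (is.null(predictions$classifier)) predictions$classifier <- "model"
  key <- interaction(predictions$filter, predictions$classifier, drop = TRUE)
  out <- lapply(split(predictions, key), function(df) {
    m <- metrics_from_pool(df)
    row <- data.frame(filter = df$filter[1], classifier = df$classifier[1],
                      method = paste(df$filter[1], df$classifier[1],
                                     sep = "+"),
                      t(m))
    if (n_boot > 0) {
      subjects <- unique(df$subject)
      by_subj <- split(seq_len(nrow(df)), df$subject)
      set.seed(seed)
      bs <- replicate(n_boot, {
        take <- sample(subjects, length(subjects), replace = TRUE)
        d <- df[unlist(by_subj[take], use.names = FALSE), ]
        if (length(unique(d$truth)) < 2) return(rep(NA_real_, 5))
        metrics_from_pool(d)
      })
      ci <- apply(bs, 1, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE)
      for (nm in names(m)) {
        row[[paste0(nm, "_lo")]] <- ci[1, nm]
        row[[paste0(nm, "_hi")]] <- ci[2, nm]
      }
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Feature-selection frequencies across benchmark repeats
#'
#' Counts how often each feature entered a final trained model, per filter
#' (aggregated over classifiers) and per filter x classifier, and reports
#' the six most frequently selected features per filter.
#'
#' @param report a \code{\link{repeated_holdout}} result.
#' @param top_n length of the per-filter top list (default 6).
#' @return list with \code{by_filter} (data.frame filter/feature/count/
#'   frequency, frequency relative to the number of models fitted with
#'   that filter), \code{by_method}, and \code{top} (named list of
#'   character vectors).
#' @export
selection_frequency <- function(report, top_n = 6) {
  sel <- report$selections
  n_models <- stats::aggregate(
    repeat_id ~ filter,
    data = unique(sel[, c("repeat_id", "filter", "classifier")]),
    FUN = length)
  names(n_models)[2] <- "n_models"
  by_filter <- stats::aggregate(repeat_id ~ filter + feature, data = sel,
                                FUN = length)
  names(by_filter)[3] <- "count"
  by_filter <- merge(by_filter, n_models, by = "filter")
  by_filter$frequency <- by_filter$count / by_filter$n_models
  by_filter <- by_filter[order(by_filter$filter, -by_filter$count), ]
  by_method <- stats::aggregate(
    repeat_id ~ filter + classifier + feature, data = sel, FUN = length)
  names(by_method)[4] <- "count"
  top <- lapply(split(by_filter, by_filter$filter), function(df)
    utils::head(df$feature, top_n))
  rownames(by_filter) <- NULL
  list(by_filter = by_filter, by_method = by_method, top = top)
}

#' Run the paired neuropsych-only and neuropsych+imaging experiments
#'
#' Benchmarks the same filter x classifier grid twice: once on the eight
#' neuropsychological scores alone, and once on those scores plus the
#' imaging features retained by the univariate screen. Both experiments
#' use identical splits (same seed), so the imaging increment is a paired
#' comparison.
#'
#' @param table a \code{\link{build_feature_table}} result.
#' @param screen a \code{\link{screen_features}} result on the same table.
#' @param config a \code{\link{benchmark_config}}.
#' @return list with \code{np_only} and \code{np_imaging} benchmark
#'   reports and \code{comparison}, a per-method table of pooled accuracy
#'   and AUC in both experiments.
#' @export
run_experiments <- function(table, screen, config = benchmark_config()) {
  man <- table_manifest(table)
  np_cols <- man$column[man$family == "neuropsych"]
  stopifnot(length(np_cols) > 0)
  pool2 <- unique(c(np_cols, screen$pool))
  set.seed(config$seed)
  splits <- make_splits(table$group, config$n_repeats,
                        config$train_fraction)
  r1 <- repeated_holdout(table, config, pool = np_cols, splits = splits)
  r2 <- repeated_holdout(table, config, pool = pool2, splits = splits)
  comparison <- merge(
    r1$metrics[, c("method", "accuracy", "roc_auc", "balanced_error")],
    r2$metrics[, c("method", "accuracy", "roc_auc", "balanced_error")],
    by = "method", suffixes = c("_np", "_np_imaging"))
  list(np_only = r1, np_imaging = r2, comparison = comparison)
}
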