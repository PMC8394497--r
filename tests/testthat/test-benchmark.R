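# small synthetic feature tables built directly (fast), with a manifest so
# the benchmark surface sees the same object the pipeline produces
make_table <- function(n_mcis = 22, n_mcip = 18, p = 12, delta = 0,
                       seed = 1) {
  set.seed(seed)
  n <- n_mcis + n_mcip
  group <- c(rep("MCIs", n_mcis), rep("MCIp", n_mcip))
  y <- as.integer(group == "MCIp")
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("img", seq_len(p))))
  # a planted effect spans several imaging features (as a regional T2
  # shift moves many features of the same pair at once)
  for (j in seq_len(min(4, p))) X[, j] <- X[, j] + delta * y
  np <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("S1", "S2", "S3")))
  tab <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    group = group, X, np, check.names = FALSE)
  man <- data.frame(column = c(colnames(X), colnames(np)),
                    feature = c(colnames(X), colnames(np)),
                    family = c(rep("signal", p), rep("neuropsych", 3)),
                    region = NA,
                    mode = c(rep("mean", p), rep("score", 3)))
  structure(tab, manifest = man, class = c("feature_table", "data.frame"))
}

small_cfg <- function(...) {
  benchmark_config(n_repeats = 5, filters = "wilcoxon",
                   classifiers = c("knn", "naive_bayes"),
                   n_features = 4, n_boot_ci = 50, seed = 7, ...)
}

test_that("holdout bookkeeping: stratified splits and pooled predictions", {
  tab <- make_table()
  rep_ <- repeated_holdout(tab, small_cfg())
  pr <- rep_$predictions
  # 40 subjects at 80/20: round(0.2*22)=4 + round(0.2*18)=4 test subjects
  # per repeat, pooled over repeats and methods
  expect_equal(nrow(pr), 5 * 8 * 2)
  per <- table(pr$repeat_id, pr$classifier)
  expect_true(all(per == 8))
  # each test split preserves both classes
  expect_true(all(tapply(pr$truth, pr$repeat_id, function(t)
    length(unique(t))) == 2))
  # deterministic given the seed
  rep2 <- repeated_holdout(tab, small_cfg())
  expect_equal(pr$score, rep2$predictions$score)
})

test_that("a perfectly separable effect is classified almost perfectly", {
  tab <- make_table(delta = 8, seed = 2)
  rep_ <- repeated_holdout(tab, small_cfg())
  expect_true(all(rep_$metrics$accuracy > 0.95))
  expect_true(all(rep_$metrics$roc_auc > 0.95))
})

test_that("label permutation drives pooled AUC to chance", {
  # averaged over a few permutations: one 40-subject pool has AUC
  # sampling noise of about +/- 0.09 on its own
  aucs <- accs <- c()
  for (perm in 1:3) {
    tab <- make_table(delta = 6, seed = 3)
    set.seed(100 + perm)
    tab$group <- sample(tab$group)
    cfg <- benchmark_config(n_repeats = 10, filters = "wilcoxon",
                            classifiers = "naive_bayes", n_features = 4,
                            n_boot_ci = 0, seed = 8)
    rep_ <- repeated_holdout(tab, cfg)
    aucs <- c(aucs, rep_$metrics$roc_auc)
    accs <- c(accs, rep_$metrics$accuracy)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  # accuracy within noise of the majority-class rate
  maj <- max(table(tab$group)) / nrow(tab)
  expect_lt(abs(mean(accs) - maj), 0.15)
})

test_that("metric identities hold on hand-built prediction pools", {
  # sens 13/18 and spec 14/22 give accuracy 27/40 and bal. error 0.321
  pool <- data.frame(
    subject = sprintf("S%02d", 1:40),
    truth = c(rep(1, 18), rep(0, 22)),
    pred = c(rep(1, 13), rep(0, 5), rep(0, 14), rep(1, 8)),
    score = c(rep(0.9, 13), rep(0.1, 5), rep(0.2, 14), rep(0.8, 8)))
  m <- compute_metrics(pool, n_boot = 0)
  expect_equal(m$sensitivity, 13 / 18)
  expect_equal(m$specificity, 14 / 22)
  expect_equal(m$accuracy, 27 / 40)
  expect_equal(m$balanced_error, 1 - (13 / 18 + 14 / 22) / 2)
  expect_equal(round(m$balanced_error, 3), 0.321)
  # perfect predictions
  perfect <- data.frame(subject = 1:10, truth = rep(c(0, 1), 5),
                        pred = rep(c(0, 1), 5),
                        score = rep(c(0.1, 0.9), 5))
  mp <- compute_metrics(perfect, n_boot = 0)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$balanced_error, 0)
  expect_equal(mp$roc_auc, 1)
  # AUC is invariant to monotone score transforms
  pool2 <- pool; pool2$score <- exp(5 * pool2$score)
  expect_equal(compute_metrics(pool2, n_boot = 0)$roc_auc, m$roc_auc)
  # single-class pool is an error
  expect_error(compute_metrics(data.frame(subject = 1, truth = 1,
                                          pred = 1, score = 1),
                               n_boot = 0), "single class")
})

test_that("selection frequencies count model entries correctly", {
  tab <- make_table(delta = 6, seed = 4)
  cfg <- small_cfg()
  rep_ <- repeated_holdout(tab, cfg)
  sf <- selection_frequency(rep_)
  # fixed-size filter: counting identity, total = k x models
  n_models <- cfg$n_repeats * length(cfg$classifiers)
  expect_equal(sum(sf$by_filter$count), cfg$n_features * n_models)
  # the planted feature enters every model
  expect_equal(sf$by_filter$frequency[sf$by_filter$feature == "img1"], 1)
  expect_true("img1" %in% sf$top$wilcoxon)
  expect_lte(length(sf$top$wilcoxon), 6)
})

test_that("preprocessing statistics come from the training fold only", {
  Xtr <- matrix(c(1, 2, 3, 4, 5, 4, NA, 6, 8, 2), ncol = 2)
  Xte <- matrix(c(100, NA, 200, NA), ncol = 2)
  colnames(Xtr) <- colnames(Xte) <- c("a", "b")
  pp <- t2asym:::preprocess_fold(Xtr, Xte)
  # test NA imputed with the TRAIN median of b (median of 4,6,8,2 = 5)
  imp_b <- c(4, 5, 6, 8, 2)
  mu_b <- mean(imp_b); sd_b <- sd(imp_b)
  expect_equal(unname(pp$test[2, "b"]), (5 - mu_b) / sd_b)
  # test standardization uses train mean/sd, not test statistics
  mu_a <- mean(Xtr[, "a"]); sd_a <- sd(Xtr[, "a"])
  expect_equal(unname(pp$test[1, "a"]), (100 - mu_a) / sd_a)
  # columns mostly missing in training are dropped
  Xtr2 <- cbind(Xtr, c = c(NA, NA, 1, NA, 1))
  Xte2 <- cbind(Xte, c = c(1, 2))
  expect_false("c" %in% colnames(t2asym:::preprocess_fold(Xtr2, Xte2)$train))
})

test_that("paired experiments share splits and detect the imaging increment", {
  tab <- make_table(delta = 5, seed = 5)  # signal lives in imaging only
  scr <- screen_features(tab)
  cfg <- small_cfg()
  ex <- run_experiments(tab, scr, cfg)
  expect_equal(ex$np_only$config$seed, ex$np_imaging$config$seed)
  # identical subjects in the test folds of both experiments
  expect_equal(ex$np_only$predictions$subject,
               ex$np_imaging$predictions$subject)
  expect_true(all(ex$comparison$accuracy_np_imaging >
                    ex$comparison$accuracy_np))
  # identical feature sets give identical reports
  scr_np <- list(pool = character(0))
  ex2 <- run_experiments(tab, scr_np, cfg)
  expect_equal(ex2$np_only$metrics$accuracy,
               ex2$np_imaging$metrics$accuracy)
  # smoke: tiny config produces a well-formed report
  cfg2 <- benchmark_config(n_repeats = 2, filters = "kendall",
                           classifiers = "knn", n_features = 2,
                           n_boot_ci = 10)
  r <- repeated_holdout(tab, cfg2)
  expect_s3_class(r, "benchmark_report")
  expect_true(all(c("accuracy", "roc_auc", "balanced_error",
                    "accuracy_lo", "accuracy_hi") %in% names(r$metrics)))
})
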