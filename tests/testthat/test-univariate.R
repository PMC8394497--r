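test_that("rank-sum wrapper matches hand and enumeration results", {
  expect_warning(r <- wilcoxon_rank_sum(rep(2, 5), rep(2, 5)), "identical")
  expect_equal(r$p_value, 1)
  # fully separated 3 vs 3: the doubled extreme tail 2/20
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)
  expect_equal(oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical samples interleaved: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 3, 5), c(2, 4, 6))$p_value,
               oracle_wilcoxon_exact(c(1, 3, 5), c(2, 4, 6)))
  # exact mode agrees with full enumeration at n = 8 vs 8, and the normal
  # approximation tracks it closely (measured max deviation ~0.011 for
  # mid-range p-values)
  set.seed(60)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.4)
    ex <- wilcoxon_rank_sum(x, y)
    expect_equal(ex$method, "exact")
    expect_equal(ex$p_value, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
    approx <- wilcoxon_rank_sum(x, y, exact_max = 0)  # force normal mode
    expect_equal(approx$method, "normal")
    expect_lt(abs(approx$p_value - oracle_wilcoxon_exact(x, y)), 0.02)
  }
})

test_that("rank-sum exact p is invariant under monotone transforms", {
  set.seed(61)
  x <- rnorm(7); y <- rnorm(6, 1)
  p0 <- wilcoxon_rank_sum(x, y)$p_value
  for (f in list(function(v) exp(v), function(v) v^3,
                 function(v) atan(v) * 10)) {
    expect_equal(wilcoxon_rank_sum(f(x), f(y))$p_value, p0)
  }
})

test_that("BH q-values match the hand step-up and the brute-force oracle", {
  expect_equal(as.numeric(benjamini_hochberg(rep(0.03, 7))), rep(0.03, 7))
  expect_equal(as.numeric(benjamini_hochberg(0.2)), 0.2)
  expect_equal(as.numeric(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))),
               rep(0.04, 4))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(70)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- as.numeric(benjamini_hochberg(p))
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    # q monotone nondecreasing in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("BH controls the false-discovery fraction on null data", {
  set.seed(71)
  n_disc <- replicate(200, {
    p <- replicate(100, wilcoxon_rank_sum(rnorm(10), rnorm(10),
                                          exact_max = 0)$p_value)
    sum(attr(benjamini_hochberg(p), "significant"))
  })
  expect_lte(mean(n_disc / 100), 0.05 + 0.01)
})

test_that("kendall tau-b saturates on a class-identical feature", {
  y <- c(0, 0, 0, 1, 1, 1, 1)
  expect_equal(abs(kendall_tau_b(y, y)), 1)
  # a continuous perfectly separating feature: high but < 1 (tau-b tie
  # correction against a binary label caps it at sqrt(n0-ty)/sqrt(n0))
  expect_gt(abs(kendall_tau_b(c(1, 2, 3, 7, 8, 9, 10), y)), 0.7)
  expect_lt(abs(kendall_tau_b(c(1, 2, 3, 7, 8, 9, 10), y)), 1)
  expect_true(is.na(kendall_tau_b(rep(1, 7), y)))
  # agrees with the tie-corrected cor() implementation
  set.seed(80)
  for (i in 1:20) {
    x <- sample(1:5, 12, TRUE); z <- sample(1:4, 12, TRUE)
    expect_equal(kendall_tau_b(x, z),
                 cor(x, z, method = "kendall"), tolerance = 1e-12)
  }
})

test_that("demographic tests reproduce the worked sex-table example", {
  # 18/4 vs 14/8-4: males/females per group; Yates-corrected chi-squared
  cohort <- data.frame(
    group = c(rep("MCIs", 22), rep("MCIp", 18)),
    sex = c(rep("M", 18), rep("F", 4), rep("M", 14), rep("F", 4)),
    age = rnorm(40, 75), education = rnorm(40, 15))
  d <- demographics_tests(cohort)
  expect_equal(round(d$sex, 3), 1.000)
  expect_equal(as.vector(d$sex_table), c(18, 14, 4, 4))
  # perfectly balanced table -> p = 1
  cohort$sex <- rep(c("M", "F"), 20)[order(cohort$group)]
  b <- demographics_tests(data.frame(
    group = rep(c("MCIs", "MCIp"), each = 20),
    sex = rep(c("M", "F"), 20),
    age = rnorm(40), education = rnorm(40)))
  expect_equal(b$sex, 1)
  # total separation -> vanishing p
  s <- demographics_tests(data.frame(
    group = rep(c("MCIs", "MCIp"), each = 20),
    sex = c(rep("M", 20), rep("F", 20)),
    age = rnorm(40), education = rnorm(40)))
  expect_lt(s$sex, 1e-6)
})

test_that("screening ranks a strongly planted pair first and pools by family", {
  spec <- planted_spec(n_mcis = 10, n_mcip = 10)
  pipe <- t2asym_pipeline(spec, registration = "none")
  res <- pipe$screen$results
  st <- res[res$family == "signal_texture", ]
  top10 <- st$feature[order(st$p_value)][1:10]
  expect_true(all(grepl("^pair01\\.", top10)))
  # pool sizes follow the family fractions
  expect_equal(sum(pipe$screen$pool %in% st$feature),
               max(1, round(0.05 * 444)))
  expect_equal(sum(pipe$screen$pool %in%
                     res$feature[res$family == "volume"]),
               max(1, round(0.15 * 13)))
  expect_equal(sum(pipe$screen$pool %in%
                     res$feature[res$family == "neuropsych"]), 8)
})

test_that("prefilter on the full-atlas manifest selects 148 + 12 features", {
  # counts follow from the family fractions on 2960 + 83 columns
  expect_equal(round(0.05 * 2960), 148)
  spec83 <- phantom_spec(n_pairs = 40, n_midline = 3)
  at83 <- build_atlas_geometry(spec83)$atlas
  man83 <- build_manifest(at83, feature_registry())
  n_st <- sum(man83$family %in% c("signal", "texture"))
  n_vol <- sum(man83$family == "volume")
  expect_equal(max(1, round(0.05 * n_st)), 148)
  expect_equal(max(1, round(0.15 * n_vol)), 12)
})
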