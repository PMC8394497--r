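test_that("feature registry has the canonical 1 + 28 + 9 layout", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 38)
  expect_equal(sum(reg$family == "volume"), 1)
  expect_equal(sum(reg$family == "signal"), 28)
  expect_equal(sum(reg$family == "texture"), 9)
  expect_false(any(duplicated(reg$name)))
  expect_equal(nrow(feature_registry("signal")), 28)
  expect_equal(nrow(feature_registry("texture")), 9)
})

test_that("signal features handle degenerate and symmetric inputs", {
  v <- rep(7.5, 50)
  f <- signal_features(v)
  expect_equal(f[["sd"]], 0)
  expect_equal(f[["icv"]], 0)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["energy"]], 1)
  expect_equal(unname(f[grep("^p[0-9]", names(f))]), rep(7.5, 9))
  expect_equal(f[["p_below_2sd"]], 0)
  expect_equal(f[["p_above_3sd"]], 0)
  expect_equal(f[["skewness"]], 0)
  # symmetric sample: zero skewness
  v <- c(1, 2, 3, 4, 5, 5, 6, 7, 8, 9)
  v <- c(v, 10 - v)  # force exact symmetry about 5
  expect_lt(abs(signal_features(v)[["skewness"]]), 1e-12)
  # too few voxels -> all-NA sentinel
  expect_true(all(is.na(signal_features(1:5, min_voxels = 10))))
})

test_that("every signal feature matches the brute-force oracle", {
  cases <- list(as.numeric(1:100))
  set.seed(99)
  for (i in 1:25) cases[[i + 1]] <- rnorm(sample(12:300, 1), 100, 20)
  for (v in cases) {
    got <- signal_features(v)
    want <- oracle_signal_features(v)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
})

test_that("mass scatter matches point-mass, two-point and brute-force cases", {
  f <- texture_features(matrix(c(1, 2, 3), 1), 5, min_voxels = 1)
  expect_equal(unname(f[1:6]), rep(0, 6))
  # two unit-intensity voxels 4 mm apart along y: M_YY = (2 mm)^2 = 4
  f <- texture_features(rbind(c(0, 0, 0), c(0, 4, 0)), c(1, 1),
                        min_voxels = 1)
  expect_equal(f[["ms_yy"]], 4)
  expect_equal(unname(f[c("ms_xx", "ms_zz", "ms_xy", "ms_xz", "ms_yz")]),
               rep(0, 5))
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    coords <- matrix(runif(3 * n, -20, 20), ncol = 3)
    w <- runif(n, 0.5, 200)
    got <- texture_features(coords, w)
    want <- oracle_mass_scatter(coords, w)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
})

test_that("texture moments are translation invariant and intensity-scale free", {
  set.seed(31)
  coords <- matrix(runif(90, 0, 30), ncol = 3)
  w <- runif(30, 10, 100)
  f1 <- texture_features(coords, w)
  f2 <- texture_features(sweep(coords, 2, c(-12.3, 45.6, 7.8), "+"), w)
  expect_equal(f1[1:6], f2[1:6], tolerance = 1e-9)
  f3 <- texture_features(coords, w * 37.5)
  expect_equal(f1[1:6], f3[1:6], tolerance = 1e-9)
})

test_that("shape features are exact for a cube and near 1 for a ball", {
  # 4x4x4 voxel cube at 1 mm: V = 64, A = 6*16 = 96
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  f <- texture_features(idx, rep(1, 64), idx = idx)
  expect_equal(f[["surface_area"]], 96)
  expect_equal(f[["compactness"]], 36 * pi * 64^2 / 96^3)
  expect_equal(f[["sphericity"]], (36 * pi * 64^2 / 96^3)^(1 / 3))
  # rasterised ball: compactness below 1 (face counting overestimates A)
  g <- as.matrix(expand.grid(1:21, 1:21, 1:21))
  ball <- g[rowSums(sweep(g, 2, 11)^2) <= 8^2, ]
  fb <- texture_features(ball, rep(1, nrow(ball)), idx = ball)
  expect_lt(fb[["compactness"]], 1)
  expect_gt(fb[["compactness"]], 0.3)
})

test_that("region volume is voxel count times voxel volume", {
  arr <- array(0L, c(10, 10, 10))
  arr[1:4, 1:5, 1:5] <- 2L
  lab <- volume3d(arr, spacing_mm = c(2, 2, 2))
  expect_equal(region_volume(lab, 2), 100 * 8)
  expect_warning(v0 <- region_volume(lab, 9), "absent")
  expect_equal(v0, 0)
  # rasterised ellipsoid volume approximates the analytic one at 1 mm
  d <- c(24, 20, 20)
  idx <- t2asym:::grid_index_matrix(d)
  u <- sweep(idx, 2, c(12, 10, 10)) / rep(c(8, 6, 6), each = nrow(idx))
  arr <- array(0L, d)
  arr[idx[rowSums(u^2) <= 1, ]] <- 1L
  lab <- volume3d(arr, spacing_mm = c(1, 1, 1))
  expect_equal(region_volume(lab, 1), 4 / 3 * pi * 8 * 6 * 6,
               tolerance = 0.05)
})

test_that("extract_all returns 38 features per region and degrades to NA", {
  spec <- quiet_spec()
  g <- build_atlas_geometry(spec)
  s <- simulate_subject(spec, "MCIs", geometry = g, seed = 2)
  m <- compute_t2_map(s$echo_a, s$echo_b)
  feats <- extract_all(m, s$labels_true, g$atlas)
  expect_equal(dim(feats), c(13, 38))
  expect_false(any(is.na(feats)))
  # family-restricted registries
  fs <- extract_all(m, s$labels_true, g$atlas,
                    registry = feature_registry("signal"))
  expect_equal(ncol(fs), 28)
  ft <- extract_all(m, s$labels_true, g$atlas,
                    registry = feature_registry("texture"))
  expect_equal(ncol(ft), 9)
  # a label with too few valid voxels degrades to NA, not an error
  m2 <- m
  m2$valid_mask[s$labels_true$data == 1] <- FALSE
  f2 <- extract_all(m2, s$labels_true, g$atlas)
  expect_true(all(is.na(f2[1, setdiff(colnames(f2), "volume")])))
  expect_false(any(is.na(f2[-1, ])))
  expect_gt(f2[1, "volume"], 0)  # volume counts all labelled voxels
})
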