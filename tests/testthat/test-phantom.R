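test_that("atlas geometry places the requested mirrored regions", {
  spec <- quiet_spec()
  g <- build_atlas_geometry(spec)
  labs <- setdiff(sort(unique(as.vector(g$labels$data))), 0)
  expect_length(labs, 2 * 6 + 1)
  expect_equal(n_regions(g$atlas), 13)
  # mirrored pair voxel counts are equal before any misalignment
  counts <- table(g$labels$data[g$labels$data != 0])
  for (k in seq_len(nrow(g$atlas$pairs))) {
    expect_equal(counts[[as.character(g$atlas$pairs$left[k])]],
                 counts[[as.character(g$atlas$pairs$right[k])]])
  }
  # voxel-exact mirror across the mid-sagittal plane (x flip)
  flipped <- g$labels$data[dim(g$labels$data)[1]:1, , ]
  for (k in seq_len(nrow(g$atlas$pairs))) {
    expect_identical(which(flipped == g$atlas$pairs$left[k]),
                     which(g$labels$data == g$atlas$pairs$right[k]))
  }
  # midline regions are symmetric about the plane
  for (l in g$atlas$unpaired)
    expect_identical(which(flipped == l), which(g$labels$data == l))
})

test_that("the full-scale layout yields 83 distinct labels", {
  spec <- quiet_spec(n_pairs = 40, n_midline = 3)
  g <- build_atlas_geometry(spec)
  expect_length(setdiff(unique(as.vector(g$labels$data)), 0), 83)
  expect_equal(nrow(g$atlas$pairs), 40)
  expect_length(g$atlas$unpaired, 3)
})

test_that("noise-free echo signals follow the mono-exponential forward model", {
  spec <- quiet_spec()
  g <- build_atlas_geometry(spec)
  s <- simulate_subject(spec, "MCIs", geometry = g, seed = 11)
  lab1 <- which(s$labels_true$data == 1)
  t2 <- s$truth$t2_ms$t2_ms[1]
  s0 <- s$truth$s0
  expect_equal(unique(s$echo_a$data[lab1]), s0 * exp(-10 / t2),
               tolerance = 1e-12)
  expect_equal(unique(s$echo_b$data[lab1]), s0 * exp(-110 / t2),
               tolerance = 1e-12)
  expect_true(all(s$echo_a$data[s$labels_true$data == 0] == 0))
})

test_that("subject simulation is seed-deterministic and seed-sensitive", {
  spec <- null_spec(n_mcis = 2, n_mcip = 2)
  g <- build_atlas_geometry(spec)
  a <- simulate_subject(spec, "MCIp", geometry = g, seed = 99)
  b <- simulate_subject(spec, "MCIp", geometry = g, seed = 99)
  expect_identical(a$echo_a$data, b$echo_a$data)
  expect_identical(a$echo_b$data, b$echo_b$data)
  expect_identical(a$neuropsych, b$neuropsych)
  c <- simulate_subject(spec, "MCIp", geometry = g, seed = 100)
  expect_false(identical(a$echo_a$data, c$echo_a$data))
})

test_that("with no planted effect the groups share truth distribution", {
  # all between-subject variation off: MCIs and MCIp truth tables identical
  spec <- quiet_spec()
  g <- build_atlas_geometry(spec)
  s1 <- simulate_subject(spec, "MCIs", geometry = g, seed = 5)
  s2 <- simulate_subject(spec, "MCIp", geometry = g, seed = 5)
  expect_equal(s1$truth$t2_ms$t2_ms, s2$truth$t2_ms$t2_ms)
})

test_that("planted effects shift MCIp truth as configured", {
  spec <- quiet_spec()
  spec$effect_map <- data.frame(pair = 2, t2_shift_ms = 8,
                                asym_shift_ms = 5)
  g <- build_atlas_geometry(spec)
  s <- simulate_subject(spec, "MCIp", geometry = g, seed = 5)
  base <- spec$region_t2_ms[2]
  left <- s$truth$t2_ms$t2_ms[s$truth$t2_ms$label == 3]
  right <- s$truth$t2_ms$t2_ms[s$truth$t2_ms$label == 4]
  expect_equal(left, base + 8 + 2.5)
  expect_equal(right, base + 8 - 2.5)
})

test_that("cohort simulation has the configured size and reproducibility", {
  spec <- null_spec(n_mcis = 3, n_mcip = 2)
  co <- simulate_cohort(spec)
  expect_length(co$subjects, 5)
  expect_equal(as.vector(table(co$cohort$group)[c("MCIs", "MCIp")]),
               c(3, 2))
  co2 <- simulate_cohort(spec)
  expect_identical(co$subjects[[1]]$echo_a$data,
                   co2$subjects[[1]]$echo_a$data)
  spec2 <- null_spec(n_mcis = 3, n_mcip = 2, seed = spec$seed + 1)
  co3 <- simulate_cohort(spec2)
  expect_false(identical(co$subjects[[1]]$echo_a$data,
                         co3$subjects[[1]]$echo_a$data))
  # cohort table carries demographics and all 8 scores
  expect_true(all(c("subject_id", "group", "age", "sex", "education",
                    "MMSE", "ADAS11", "ADNI_MEM") %in% names(co$cohort)))
  d <- tempfile()
  simulate_cohort(null_spec(n_mcis = 2, n_mcip = 2), dir = d)
  expect_true(file.exists(file.path(d, "cohort.csv")))
  expect_length(list.files(d, pattern = "_truth\\.json$"), 4)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(te_a_ms = 110, te_b_ms = 10))
  expect_error(phantom_spec(n_mcis = 1))
  expect_error(phantom_spec(region_t2_ms = c(-5, rep(100, 6))))
  expect_error(build_atlas_geometry(quiet_spec(grid_shape = c(16, 16, 16),
                                               n_pairs = 30)),
               "slots")
})
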