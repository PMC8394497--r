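#' Specification of a synthetic dual-echo phantom cohort
#'
#' Describes everything needed to simulate a cohort of dual fast spin-echo
#' acquisitions with known ground truth: the grid, a mirrored ellipsoidal
#' multi-region atlas, echo times, the mono-exponential signal model with
#' additive noise, group-dependent regional T2 effects (including
#' left/right asymmetry shifts planted only in the progressor group), a
#' known rigid misalignment between echo space and anatomical space, and a
#' group-shifted neuropsychological score generator.
#'
#' Defaults describe a desk-scale phantom: a 64 x 64 x 48 grid at 2 mm
#' isotropic voxels with 6 mirrored pairs and 1 midline region. The
#' full-scale layout (40 pairs + 3 midline, matching an 83-region human
#' atlas) is available via \code{n_pairs = 40, n_midline = 3} and is used for
#' manifest-count checks, not for simulation-heavy tests.
#'
#' The mid-sagittal plane is fixed at the grid centre along the x axis;
#' left = lower x. Group sizes default to 22 stable (MCIs) and 18
#' progressors (MCIp), the cohort size of the motivating study.
#'
#' @param grid_shape integer(3) voxel counts per axis.
#' @param voxel_size_mm numeric(3) voxel spacing, mm.
#' @param n_pairs number of mirrored region pairs.
#' @param n_midline number of unpaired midline regions.
#' @param te_a_ms,te_b_ms echo times (ms) of the PD-weighted (short) and
#'   T2-weighted (long) echoes; \code{te_b_ms > te_a_ms > 0}.
#' @param s0_mean,s0_sd mean and between-subject sd of the baseline signal
#'   S0 (arbitrary units).
#' @param noise_sd additive noise sd on each echo (same units as S0);
#'   default 10 = 1\% of the default S0.
#' @param noise_model \code{"gaussian"} (additive on each echo) or
#'   \code{"rician"} (magnitude of a complex signal with Gaussian channels).
#' @param region_t2_ms baseline T2 (ms) per region, pairs first then midline
#'   regions; default evenly spans 70-130 ms.
#' @param t2_between_sd between-subject sd (ms) of a pair-level T2 deviation
#'   applied to both sides equally.
#' @param asym_sd between-subject sd (ms) of a natural left-right T2
#'   asymmetry (applied to the left side).
#' @param effect_map data.frame(pair, t2_shift_ms, asym_shift_ms): additive
#'   T2 shifts received only by MCIp subjects; \code{t2_shift_ms} moves both
#'   sides equally while \code{asym_shift_ms} is split antisymmetrically
#'   (+a/2 left, -a/2 right), so it widens the left-right difference
#'   without moving the pair mean. Default plants a bilateral +6 ms and a
#'   10 ms asymmetry in pair 1 (the "hippocampus analogue").
#' @param semi_axes_mm ellipsoid semi-axes (mm) of each region.
#' @param misalignment \code{rigid_transform} mapping anatomical-space world
#'   coordinates to echo-space world coordinates (the head movement between
#'   the spin-echo and anatomical acquisitions); default 2 mm in x and y and
#'   3 degrees about z.
#' @param n_mcis,n_mcip group sizes (>= 2).
#' @param seed RNG seed for \code{\link{simulate_cohort}}.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         voxel_size_mm = c(2, 2, 2),
                         n_pairs = 6, n_midline = 1,
                         te_a_ms = 10, te_b_ms = 110,
                         s0_mean = 1000, s0_sd = 50,
                         noise_sd = 10,
                         noise_model = c("gaussian", "rician"),
                         region_t2_ms = NULL,
                         t2_between_sd = 4,
                         asym_sd = 2,
                         effect_map = data.frame(pair = 1,
                                                 t2_shift_ms = 6,
                                                 asym_shift_ms = 10),
                         semi_axes_mm = c(8, 6, 6),
                         misalignment = rigid_transform(
                           angles_rad = c(0, 0, 3 * pi / 180),
                           translation_mm = c(2, 2, 0)),
                         n_mcis = 22, n_mcip = 18,
                         seed = 20210941) {
  noise_model <- match.arg(noise_model)
  n_regions <- 2 * n_pairs + n_midline
  if (is.null(region_t2_ms))
    region_t2_ms <- seq(70, 130, length.out = n_pairs + n_midline)
  stopifnot(te_b_ms > te_a_ms, te_a_ms > 0,
            all(region_t2_ms > 0),
            length(region_t2_ms) == n_pairs + n_midline,
            n_mcis >= 2, n_mcip >= 2,
            n_pairs >= 1, n_midline >= 0,
            all(grid_shape >= 8), all(voxel_size_mm > 0))
  if (nrow(effect_map) > 0)
    stopifnot(all(effect_map$pair >= 1 & effect_map$pair <= n_pairs))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 n_pairs = as.integer(n_pairs),
                 n_midline = as.integer(n_midline),
                 te_a_ms = te_a_ms, te_b_ms = te_b_ms,
                 s0_mean = s0_mean, s0_sd = s0_sd,
                 noise_sd = noise_sd, noise_model = noise_model,
                 region_t2_ms = region_t2_ms,
                 t2_between_sd = t2_between_sd, asym_sd = asym_sd,
                 effect_map = effect_map,
                 semi_axes_mm = semi_axes_mm,
                 misalignment = misalignment,
                 n_mcis = as.integer(n_mcis), n_mcip = as.integer(n_mcip),
                 neuropsych = default_neuropsych_model(),
                 seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s grid @ %s mm, %d pairs + %d midline, TE %g/%g ms, %d MCIs + %d MCIp\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              x$n_pairs, x$n_midline, x$te_a_ms, x$te_b_ms,
              x$n_mcis, x$n_mcip))
  invisible(x)
}

# Group-shifted Gaussian generators for the 8 neuropsychological totals.
# Only the memory composite and ADAS-11 separate the groups, emulating the
# pattern seen in MCI cohorts (memory and ADAS-11 discriminate; the rest
# overlap). ADAS-11 is a deficit score (higher = worse), hence MCIp higher.
default_neuropsych_model <- function() {
  data.frame(
    score = c("MMSE", "BNT", "GDS", "ADAS11",
              "ADNI_EF", "ADNI_VS", "ADNI_LAN", "ADNI_MEM"),
    mean_mcis = c(27.5, 26, 1.5, 9.0, 0.30, 0.10, 0.30, 0.30),
    mean_mcip = c(26.8, 25, 1.7, 12.5, 0.10, 0.05, 0.15, -0.40),
    sd = c(1.8, 3.0, 1.2, 3.2, 0.8, 0.7, 0.8, 0.6))
}

# midline x coordinate (fractional voxel index); mirror is i -> nx + 1 - i
mid_x_index <- function(nx) (nx + 1) / 2

#' Build the mirrored ellipsoidal atlas geometry
#'
#' Places \code{n_pairs} axis-aligned ellipsoids on a lattice in the left
#' hemisphere (x below the mid-sagittal plane at the grid centre), mirrors
#' them voxel-exactly into the right hemisphere, and places
#' \code{n_midline} ellipsoids symmetric about the mid-sagittal plane.
#' Labels are 2k-1 (left) and 2k (right) for pair k, then midline labels.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{labels} (a \code{volume3d} of integer labels) and
#'   \code{atlas} (a \code{\link{region_atlas}}).
#' @export
build_atlas_geometry <- function(spec) {
  d <- spec$grid_shape
  ax <- spec$semi_axes_mm / spec$voxel_size_mm  # semi-axes in voxels
  mid <- mid_x_index(d[1])
  step <- 2 * ceiling(ax) + 3
  # pair centres must stay clear of both the grid edge and the midline
  # region's extent so regions can never touch across the midline
  x_lo <- ceiling(ax[1]) + 2
  x_hi <- floor(mid - 2 * ax[1] - 2)
  y_lo <- ceiling(ax[2]) + 2; y_hi <- d[2] - ceiling(ax[2]) - 1
  z_lo <- ceiling(ax[3]) + 2; z_hi <- d[3] - ceiling(ax[3]) - 1
  if (x_hi < x_lo || y_hi < y_lo || z_hi < z_lo)
    stop(sprintf("grid too small: 0 pair slots available, %d requested",
                 spec$n_pairs))
  xs <- seq(x_lo, x_hi, by = step[1])
  ys <- seq(y_lo, y_hi, by = step[2])
  zs <- seq(z_lo, z_hi, by = step[3])
  centres <- expand.grid(x = xs, y = ys, z = zs)
  if (nrow(centres) < spec$n_pairs)
    stop(sprintf("grid too small: %d pair slots available, %d requested",
                 nrow(centres), spec$n_pairs))
  lab <- array(0L, dim = d)
  idx <- grid_index_matrix(d)
  ellipsoid_idx <- function(centre) {
    u <- sweep(idx, 2, centre) / rep(ax, each = nrow(idx))
    which(rowSums(u^2) <= 1)
  }
  assign_label <- function(vox, label, who) {
    if (any(lab[vox] != 0L))
      stop(sprintf("region overlap while placing %s (labels %s)", who,
                   paste(unique(lab[vox][lab[vox] != 0]), collapse = ",")))
    lab[vox] <<- label
  }
  for (k in seq_len(spec$n_pairs)) {
    c_k <- as.numeric(centres[k, ])
    left <- ellipsoid_idx(c_k)
    assign_label(left, 2L * k - 1L, sprintf("pair %d (left)", k))
    # voxel-exact mirror across the mid-sagittal plane
    mirrored <- idx[left, , drop = FALSE]
    mirrored[, 1] <- d[1] + 1L - mirrored[, 1]
    right <- mirrored[, 1] + (mirrored[, 2] - 1L) * d[1] +
      (mirrored[, 3] - 1L) * d[1] * d[2]
    assign_label(right, 2L * k, sprintf("pair %d (right)", k))
  }
  if (spec$n_midline > 0) {
    mcen <- expand.grid(y = ys, z = zs)
    if (nrow(mcen) < spec$n_midline)
      stop("grid too small for requested midline regions")
    for (m in seq_len(spec$n_midline)) {
      c_m <- c(mid, as.numeric(mcen[m, 1]), as.numeric(mcen[m, 2]))
      vox <- ellipsoid_idx(c_m)
      assign_label(vox, 2L * spec$n_pairs + m, sprintf("midline %d", m))
    }
  }
  pair_names <- sprintf("pair%02d", seq_len(spec$n_pairs))
  mid_names <- if (spec$n_midline > 0)
    sprintf("midline%d", seq_len(spec$n_midline)) else character(0)
  regions <- data.frame(
    label = seq_len(2L * spec$n_pairs + spec$n_midline),
    name = c(as.vector(rbind(paste0(pair_names, "_L"),
                             paste0(pair_names, "_R"))), mid_names),
    hemi = c(rep(c("L", "R"), spec$n_pairs), rep("M", spec$n_midline)))
  pairs <- data.frame(pair = seq_len(spec$n_pairs), name = pair_names,
                      left = 2L * seq_len(spec$n_pairs) - 1L,
                      right = 2L * seq_len(spec$n_pairs))
  unpaired <- if (spec$n_midline > 0)
    2L * spec$n_pairs + seq_len(spec$n_midline) else integer(0)
  list(labels = volume3d(lab, spec$voxel_size_mm),
       atlas = region_atlas(regions, pairs, unpaired))
}

# Per-region true T2 for one subject: pair-level between-subject deviation
# (both sides), natural left-right asymmetry (left side), and -- for MCIp
# only -- the planted bilateral and asymmetry shifts from effect_map.
subject_truth_t2 <- function(spec, group) {
  np <- spec$n_pairs; nm <- spec$n_midline
  base_pair <- spec$region_t2_ms[seq_len(np)]
  base_mid <- if (nm > 0) spec$region_t2_ms[np + seq_len(nm)] else numeric(0)
  dev <- stats::rnorm(np, 0, spec$t2_between_sd)
  asym <- stats::rnorm(np, 0, spec$asym_sd)
  left <- base_pair + dev + asym
  right <- base_pair + dev
  if (group == "MCIp" && nrow(spec$effect_map) > 0) {
    # t2_shift moves both sides; asym_shift is a pure asymmetry (split
    # antisymmetrically) so it moves |L - R| without moving the pair mean
    em <- spec$effect_map
    left[em$pair] <- left[em$pair] + em$t2_shift_ms + em$asym_shift_ms / 2
    right[em$pair] <- right[em$pair] + em$t2_shift_ms - em$asym_shift_ms / 2
  }
  mid <- if (nm > 0) base_mid + stats::rnorm(nm, 0, spec$t2_between_sd)
         else numeric(0)
  t2 <- numeric(2 * np + nm)
  t2[2 * seq_len(np) - 1] <- left
  t2[2 * seq_len(np)] <- right
  if (nm > 0) t2[2 * np + seq_len(nm)] <- mid
  pmax(t2, 1)  # T2 must stay positive even under extreme draws
}

add_noise <- function(signal, sd, model) {
  if (sd <= 0) return(signal)
  if (model == "gaussian") {
    signal + stats::rnorm(length(signal), 0, sd)
  } else {
    # magnitude image: real channel carries the signal, both channels noisy
    sqrt((signal + stats::rnorm(length(signal), 0, sd))^2 +
           stats::rnorm(length(signal), 0, sd)^2)
  }
}

#' Simulate one phantom subject
#'
#' Generates the dual-echo pair from the mono-exponential forward model
#' \eqn{S = S_0 e^{-TE/T2}} voxel-wise (plus noise), a structural
#' "anatomical" image and its label map resampled into the misaligned
#' anatomical space, per-region true T2 values, neuropsychological scores
#' and demographics. MCIp subjects receive the planted regional effects.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param group \code{"MCIs"} or \code{"MCIp"}.
#' @param subject_id identifier string.
#' @param geometry optional precomputed \code{\link{build_atlas_geometry}}
#'   result (built once per cohort).
#' @param seed optional integer; when given, the subject is generated from a
#'   private RNG state and is bit-reproducible.
#' @return An object of class \code{phantom_subject}: echo volumes
#'   \code{echo_a}/\code{echo_b}, \code{anatomical} image and \code{labels}
#'   in anatomical space, \code{labels_true} in echo space, a \code{truth}
#'   list (per-region T2 table and the correction transform that maps the
#'   echo grid into anatomical space), \code{neuropsych} scores and
#'   demographics.
#' @export
simulate_subject <- function(spec, group = c("MCIs", "MCIp"),
                             subject_id = "S000", geometry = NULL,
                             seed = NULL) {
  group <- match.arg(group)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(geometry)) geometry <- build_atlas_geometry(spec)
  lab <- geometry$labels
  t2_by_label <- subject_truth_t2(spec, group)
  t2vol <- array(NA_real_, dim = dim(lab$data))
  nz <- lab$data != 0L
  t2vol[nz] <- t2_by_label[lab$data[nz]]
  s0 <- stats::rnorm(1, spec$s0_mean, spec$s0_sd)
  sig_a <- array(0, dim = dim(lab$data))
  sig_b <- array(0, dim = dim(lab$data))
  sig_a[nz] <- s0 * exp(-spec$te_a_ms / t2vol[nz])
  sig_b[nz] <- s0 * exp(-spec$te_b_ms / t2vol[nz])
  sig_a <- array(add_noise(sig_a, spec$noise_sd, spec$noise_model),
                 dim = dim(lab$data))
  sig_b <- array(add_noise(sig_b, spec$noise_sd, spec$noise_model),
                 dim = dim(lab$data))
  echo_a <- echo_volume(sig_a, spec$te_a_ms, spec$voxel_size_mm)
  echo_b <- echo_volume(sig_b, spec$te_b_ms, spec$voxel_size_mm)
  # structural image: region-dependent contrast in echo space, then moved
  # into the anatomical frame by the known misalignment A (anat(p) =
  # structural(A(p))); the correction transform that realigns it is A^-1
  contrast <- c(stats::setNames(100 + 15 * seq_along(t2_by_label), NULL))
  struct <- array(0, dim = dim(lab$data))
  struct[nz] <- contrast[lab$data[nz]]
  struct_vol <- volume3d(struct, spec$voxel_size_mm)
  anat <- resample_image(struct_vol, spec$misalignment)
  labels_anat <- resample_labels(lab, spec$misalignment)
  np <- spec$neuropsych
  mu <- if (group == "MCIs") np$mean_mcis else np$mean_mcip
  scores <- stats::setNames(stats::rnorm(nrow(np), mu, np$sd), np$score)
  demo <- list(
    age = round(min(max(stats::rnorm(1, 75.3, 3.0), 70), 80), 1),
    sex = if (stats::runif(1) < (if (group == "MCIs") 18 / 22 else 14 / 18))
      "M" else "F",
    education = max(6, round(stats::rnorm(1, 15.7, 3.0))))
  truth <- list(
    t2_ms = data.frame(label = seq_along(t2_by_label),
                       region = geometry$atlas$regions$name,
                       side = geometry$atlas$regions$hemi,
                       t2_ms = t2_by_label),
    s0 = s0,
    misalignment = spec$misalignment,
    transform_to_anat = rt_invert(spec$misalignment))
  structure(list(subject_id = subject_id, group = group,
                 echo_a = echo_a, echo_b = echo_b,
                 anatomical = anat, labels = labels_anat,
                 labels_true = lab, atlas = geometry$atlas,
                 truth = truth, neuropsych = scores, demographics = demo),
            class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("phantom_subject %s (%s): %s grid, %d regions\n",
              x$subject_id, x$group,
              paste(dim(x$echo_a$data), collapse = "x"),
              nrow(x$truth$t2_ms)))
  invisible(x)
}

#' Simulate a full phantom cohort
#'
#' Generates \code{n_mcis + n_mcip} subjects reproducibly from
#' \code{spec$seed} and assembles the cohort table (id, group, age, sex,
#' education and the 8 neuropsychological totals).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param dir optional output directory; when given, writes
#'   \code{cohort.csv} and one JSON truth sidecar per subject.
#' @return An object of class \code{phantom_cohort}: list with
#'   \code{subjects} (list of \code{phantom_subject}), \code{cohort}
#'   (data.frame), \code{atlas} and \code{spec}.
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  geometry <- build_atlas_geometry(spec)
  groups <- c(rep("MCIs", spec$n_mcis), rep("MCIp", spec$n_mcip))
  ids <- sprintf("S%03d", seq_along(groups))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    subjects[[i]] <- simulate_subject(spec, groups[i], ids[i],
                                      geometry = geometry)
  }
  cohort <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               age = s$demographics$age, sex = s$demographics$sex,
               education = s$demographics$education,
               t(s$neuropsych), check.names = FALSE)
  }))
  rownames(cohort) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort, file.path(dir, "cohort.csv"),
                     row.names = FALSE)
    for (s in subjects) {
      jsonlite::write_json(
        list(subject_id = s$subject_id, group = s$group,
             t2_ms = s$truth$t2_ms, s0 = s$truth$s0,
             transform_to_anat = unclass(s$truth$transform_to_anat)),
        file.path(dir, paste0(s$subject_id, "_truth.json")),
        digits = NA, auto_unbox = TRUE)
    }
  }
  structure(list(subjects = subjects, cohort = cohort,
                 atlas = geometry$atlas, labels_true = geometry$labels,
                 spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d subjects (%d MCIs, %d MCIp), %d regions\n",
              length(x$subjects), sum(x$cohort$group == "MCIs"),
              sum(x$cohort$group == "MCIp"), n_regions(x$atlas)))
  invisible(x)
}
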