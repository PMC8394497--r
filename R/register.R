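#' Mutual information between a fixed image and a transformed moving image
#'
#' Mattes-style metric: intensities of both images are binned into
#' \code{n_bins} equal-width bins (bounds from each image's own sampled
#' range); the fixed sample uses hard assignment while the interpolated
#' moving sample is shared between its two nearest bins with linear (tent)
#' weights, which makes the metric vary smoothly with the transform. Only
#' sample points that land inside the moving grid contribute.
#'
#' @keywords internal
mi_metric <- function(fixed_vals, moving, pts_fixed, tf, n_bins = 32,
                      min_overlap = 0.25) {
  ci <- world_to_index(moving, rt_apply(tf, pts_fixed))
  d <- dim(moving$data)
  inside <- ci[, 1] >= 1 & ci[, 1] <= d[1] &
    ci[, 2] >= 1 & ci[, 2] <= d[2] &
    ci[, 3] >= 1 & ci[, 3] <= d[3]
  if (mean(inside) < min_overlap) return(NA_real_)
  fv <- fixed_vals[inside]
  mv <- sample_trilinear(moving, ci[inside, , drop = FALSE])
  fr <- range(fv); mr <- range(mv)
  if (diff(fr) == 0 || diff(mr) == 0) return(NA_real_)
  fb <- pmin(floor((fv - fr[1]) / diff(fr) * n_bins) + 1L, n_bins)
  # continuous bin coordinate for the moving sample, shared across two bins
  mc <- (mv - mr[1]) / diff(mr) * (n_bins - 1) + 1
  m0 <- pmin(floor(mc), n_bins - 1L)
  w1 <- mc - m0
  jh <- Matrix::sparseMatrix(i = c(fb, fb), j = c(m0, m0 + 1L),
                             x = c(1 - w1, w1), dims = c(n_bins, n_bins))
  jh <- as.matrix(jh) / length(fv)
  pf <- rowSums(jh); pm <- colSums(jh)
  nz <- jh > 0
  sum(jh[nz] * log(jh[nz] / (pf[row(jh)[nz]] * pm[col(jh)[nz]])))
}

#' Separable 1-2-1 smoothing of a volume
#'
#' One pass of the binomial [1,2,1]/4 kernel along each axis (replicated
#' borders): a light Gaussian-like blur used before registration to keep
#' acquisition noise from biasing the metric optimum.
#'
#' @param vol a \code{volume3d}.
#' @param passes number of smoothing passes.
#' @return A smoothed \code{volume3d}.
#' @export
smooth_volume <- function(vol, passes = 1) {
  a <- vol$data
  for (pass in seq_len(passes)) {
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      ap <- aperm(a, perm)
      d <- dim(ap)
      m <- matrix(ap, d[1])
      ms <- (rbind(m[1, , drop = FALSE], m[-d[1], ]) + 2 * m +
               rbind(m[-1, ], m[d[1], , drop = FALSE])) / 4
      a <- aperm(array(ms, d), order(perm))
    }
  }
  volume3d(a, vol$spacing_mm, vol$origin_mm)
}

#' Rigid registration by mutual-information maximisation
#'
#' Estimates the rigid transform that maps fixed-space world coordinates
#' into moving-space coordinates so that the resampled moving image aligns
#' with the fixed image (the transform to pass to
#' \code{\link{resample_image}} / \code{\link{resample_labels}}).
#' Mutual information between the images is maximised over the 6 rigid
#' parameters by a regular-step coordinate descent: each parameter is probed
#' in turn with +/- the current step, steps are halved whenever no probe
#' improves the metric, until \code{tol} is reached. Sampling is a
#' deterministic stride over the above-threshold fixed voxels, so the result
#' is reproducible without any RNG.
#'
#' @param fixed a \code{volume3d} (or \code{t2_map}; its values are used) in
#'   the target space. When the T2 map has large invalid areas, registering
#'   on the long-echo intensity image instead is often more stable.
#' @param moving a \code{volume3d} in the source (anatomical) space.
#' @param init optional initial \code{rigid_transform} (default identity
#'   centred at the fixed-image centre).
#' @param n_samples approximate number of fixed-image sample points.
#' @param n_bins histogram bins for the metric.
#' @param step_rot_rad,step_trans_mm initial optimisation steps.
#' @param tol stop when the rotation step falls below \code{tol} radians
#'   (the translation step shrinks in proportion).
#' @param max_iter maximum optimisation sweeps.
#' @param min_overlap minimum fraction of samples that must land inside the
#'   moving grid; below this the metric (and registration) fails.
#' @param smooth_passes passes of \code{\link{smooth_volume}} applied to
#'   both images before sampling (0 disables); light smoothing keeps voxel
#'   noise from displacing the metric optimum.
#' @return list with \code{transform} (a \code{rigid_transform}),
#'   \code{metric} (final MI), and \code{trace} (data.frame of metric per
#'   accepted step).
#' @export
register_rigid <- function(fixed, moving, init = NULL,
                           n_samples = 20000, n_bins = 32,
                           step_rot_rad = 2 * pi / 180, step_trans_mm = 2,
                           tol = 0.02 * pi / 180, max_iter = 200,
                           min_overlap = 0.25, smooth_passes = 1) {
  if (inherits(fixed, "t2_map")) fixed <- t2_as_volume(fixed)
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"))
  if (smooth_passes > 0) {
    fixed <- smooth_volume(fixed, smooth_passes)
    moving <- smooth_volume(moving, smooth_passes)
  }
  d <- dim(fixed$data)
  idx <- grid_index_matrix(d)
  # sample a margin-padded bounding box around the foreground (values above
  # 20% of the robust maximum): edges between foreground and background are
  # what localises the transform, while far-field noise-only voxels would
  # only flatten the metric
  thr <- 0.2 * stats::quantile(fixed$data, 0.999)
  fg <- which(fixed$data > thr)
  if (length(fg) < 100) fg <- seq_along(fixed$data)
  fg_idx <- idx[fg, , drop = FALSE]
  lo <- pmax(apply(fg_idx, 2, min) - 5L, 1L)
  hi <- pmin(apply(fg_idx, 2, max) + 5L, d)
  in_box <- idx[, 1] >= lo[1] & idx[, 1] <= hi[1] &
    idx[, 2] >= lo[2] & idx[, 2] <= hi[2] &
    idx[, 3] >= lo[3] & idx[, 3] <= hi[3]
  box <- which(in_box)
  stride <- max(1L, floor(length(box) / n_samples))
  sel <- box[seq(1L, length(box), by = stride)]
  pts <- index_to_world(fixed, idx[sel, , drop = FALSE])
  fv <- fixed$data[sel]
  centre <- index_to_world(fixed, matrix((d + 1) / 2, 1))
  if (is.null(init)) init <- rigid_transform(center_mm = as.numeric(centre))
  par <- c(init$angles_rad, init$translation_mm)
  cen <- init$center_mm
  eval_par <- function(p)
    mi_metric(fv, moving, pts, rigid_transform(p[1:3], p[4:6], cen),
              n_bins = n_bins, min_overlap = min_overlap)
  cur <- eval_par(par)
  if (!is.finite(cur))
    stop("registration failed: insufficient field-of-view overlap or ",
         "degenerate intensities at the initial transform")
  steps <- c(rep(step_rot_rad, 3), rep(step_trans_mm, 3))
  trace <- data.frame(iter = 0L, metric = cur)
  # stage 1: regular-step coordinate search to get inside the capture range
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (j in 1:6) {
      for (s in c(1, -1)) {
        cand <- par; cand[j] <- cand[j] + s * steps[j]
        m <- eval_par(cand)
        if (is.finite(m) && m > cur + 1e-12) {
          par <- cand; cur <- m; improved <- TRUE
          trace <- rbind(trace, data.frame(iter = it, metric = cur))
          break
        }
      }
    }
    if (!improved) {
      steps <- steps / 2
      if (steps[1] < 8 * tol) break
    }
  }
  # stage 2: simplex refinement of the smooth tent-kernel metric
  nm <- stats::optim(par, function(p) {
    m <- eval_par(p)
    if (!is.finite(m)) 1e6 else -m
  }, method = "Nelder-Mead",
  control = list(maxit = 400, reltol = 1e-8,
                 parscale = c(rep(step_rot_rad / 2, 3),
                              rep(step_trans_mm / 2, 3))))
  if (is.finite(nm$value) && -nm$value > cur) {
    par <- nm$par; cur <- -nm$value
    trace <- rbind(trace, data.frame(iter = max_iter + 1L, metric = cur))
  }
  if (!is.finite(cur))
    stop("registration diverged: non-finite metric")
  list(transform = rigid_transform(par[1:3], par[4:6], cen),
       metric = cur, trace = trace)
}

# Angular difference (radians) and translation difference (mm, at a set of
# probe points) between two transforms -- used to compare a recovered
# registration with a ground-truth transform without worrying about the
# rotation-centre parameterisation.
transform_discrepancy <- function(a, b, probe_pts) {
  Ra <- rotation_matrix(a$angles_rad); Rb <- rotation_matrix(b$angles_rad)
  Rd <- Ra %*% t(Rb)
  ang <- acos(pmin(pmax((sum(diag(Rd)) - 1) / 2, -1), 1))
  pa <- rt_apply(a, probe_pts); pb <- rt_apply(b, probe_pts)
  list(angle_rad = ang,
       max_point_mm = max(sqrt(rowSums((pa - pb)^2))))
}
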