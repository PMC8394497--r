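#' The canonical per-region feature registry
#'
#' One volume feature, 28 intensity-distribution ("signal") features and 9
#' texture features, 38 in all. The signal set contains every feature the
#' motivating study names explicitly (mean signal; sd, mean and intensity
#' coefficient of variation restricted to the central 90\% of values;
#' values at the 5/25/75/95/99.99th percentiles; precision range; entropy;
#' energy; skewness; kurtosis; tail probabilities below mean-2sd and above
#' mean+3sd) and fills the remainder with symmetric counterparts
#' (0.01/1/50/99th percentiles, min/max/range, median absolute deviation,
#' the below-3sd and above-2sd tails, and the unrestricted sd and ICV).
#' \code{paper_named} records which entries carry an explicitly published
#' name. Texture features are the six components of the intensity-weighted
#' mass-scatter tensor, a face-counted surface area, compactness
#' \eqn{36\pi V^2/A^3} and sphericity (its cube root).
#'
#' @param family optional filter: \code{"volume"}, \code{"signal"} or
#'   \code{"texture"}.
#' @return data.frame with columns \code{name}, \code{family},
#'   \code{paper_named}.
#' @export
feature_registry <- function(family = NULL) {
  named <- c("mean", "sd_central90", "mean_central90", "icv_central90",
             "p5", "p25", "p75", "p95", "p99.99",
             "precision_range", "entropy", "energy", "skewness", "kurtosis",
             "p_below_2sd", "p_above_3sd")
  signal <- c("mean", "sd", "icv", "skewness", "kurtosis",
              "entropy", "energy",
              "p0.01", "p1", "p5", "p25", "p50", "p75", "p95", "p99",
              "p99.99",
              "mean_central90", "sd_central90", "icv_central90",
              "precision_range",
              "min", "max", "range", "mad",
              "p_below_2sd", "p_below_3sd", "p_above_2sd", "p_above_3sd")
  texture <- c("ms_xx", "ms_yy", "ms_zz", "ms_xy", "ms_xz", "ms_yz",
               "surface_area", "compactness", "sphericity")
  reg <- data.frame(
    name = c("volume", signal, texture),
    family = c("volume", rep("signal", length(signal)),
               rep("texture", length(texture))))
  reg$paper_named <- reg$name %in% c("volume", named, "ms_yy")
  if (!is.null(family)) reg <- reg[reg$family %in% family, , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Intensity-distribution features of a set of voxel values
#'
#' Computes the 28 signal features of \code{\link{feature_registry}} from
#' the valid-voxel T2 values of one region. Percentiles use linear
#' interpolation between order statistics (R quantile type 7). Histogram
#' entropy (base 2) and energy (sum of squared bin probabilities) use
#' \code{n_bins} equal-width bins over the region's own value range; a
#' constant region is defined to have entropy 0 and energy 1. Skewness is
#' the third standardised central moment; kurtosis is excess (Fisher).
#' Central-90\% statistics are computed on values within [P5, P95]
#' (inclusive). Tail probabilities are one-sided and mean-centred, e.g.
#' \code{p_below_2sd} = P(v < mean - 2 sd), with sd the sample standard
#' deviation. The median absolute deviation is unscaled (no normal
#' consistency constant).
#'
#' @param values numeric vector of valid-voxel values (>= \code{min_voxels}).
#' @param n_bins histogram bin count for entropy/energy.
#' @param min_voxels minimum sample size; fewer values return all-NA.
#' @return Named numeric vector of length 28.
#' @export
signal_features <- function(values, n_bins = 64, min_voxels = 10) {
  nm <- feature_registry("signal")$name
  if (length(values) < min_voxels)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  v <- as.numeric(values)
  n <- length(v)
  mu <- mean(v)
  s <- stats::sd(v)
  qs <- stats::quantile(v, c(0.0001, 0.01, 0.05, 0.25, 0.50, 0.75, 0.95,
                             0.99, 0.9999), names = FALSE, type = 7)
  m2 <- mean((v - mu)^2)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 - 3 else 0
  rng <- range(v)
  if (diff(rng) > 0) {
    b <- pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
    p <- tabulate(b, n_bins) / n
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
    energy <- sum(p^2)
  } else {
    entropy <- 0; energy <- 1
  }
  central <- v[v >= qs[3] & v <= qs[7]]
  mu_c <- mean(central)
  s_c <- if (length(central) > 1) stats::sd(central) else 0
  icv <- if (mu != 0) s / mu else NA_real_
  icv_c <- if (mu_c != 0) s_c / mu_c else NA_real_
  stats::setNames(c(
    mu, s, icv, skew, kurt, entropy, energy,
    qs[1], qs[2], qs[3], qs[4], qs[5], qs[6], qs[7], qs[8], qs[9],
    mu_c, s_c, icv_c,
    qs[7] - qs[3],
    rng[1], rng[2], diff(rng),
    stats::median(abs(v - stats::median(v))),
    mean(v < mu - 2 * s), mean(v < mu - 3 * s),
    mean(v > mu + 2 * s), mean(v > mu + 3 * s)), nm)
}

#' Texture features: intensity-weighted mass scatter and mask shape
#'
#' The mass-scatter tensor is the intensity-weighted second central moment
#' of the region's voxel world coordinates: with weights \eqn{w_i = I_i}
#' and centroid \eqn{c = \sum w_i x_i / \sum w_i},
#' \deqn{M_{ab} = \sum_i w_i (a_i - c_a)(b_i - c_b) / \sum_i w_i}
#' for \eqn{ab \in \{XX, YY, ZZ, XY, XZ, YZ\}} (units mm^2); the Y axis is
#' the anterior-posterior world axis. Because weights enter as relative
#' weights, a global intensity rescaling leaves the tensor unchanged. The
#' three shape features are a face-counted surface area A of the voxel mask
#' (exposed faces times face area, mm^2), compactness
#' \eqn{36\pi V^2 / A^3} (1 for a perfect sphere, smaller for rougher
#' shapes) and sphericity, its cube root.
#'
#' @param coords_mm n x 3 matrix of voxel-centre world coordinates.
#' @param values intensity weights (nonnegative, e.g. T2 in ms).
#' @param idx optional n x 3 integer voxel indices of the same voxels (used
#'   for the face-counted surface); required for the 3 shape features.
#' @param spacing_mm voxel spacing, mm.
#' @param min_voxels minimum sample size; fewer voxels return all-NA.
#' @return Named numeric vector of length 9.
#' @export
texture_features <- function(coords_mm, values, idx = NULL,
                             spacing_mm = c(1, 1, 1), min_voxels = 10) {
  nm <- feature_registry("texture")$name
  coords_mm <- matrix(as.numeric(coords_mm), ncol = 3)
  n <- nrow(coords_mm)
  if (n < min_voxels)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  w <- as.numeric(values)
  W <- sum(w)
  cen <- colSums(coords_mm * w) / W
  dc <- sweep(coords_mm, 2, cen)
  ms <- c(xx = sum(w * dc[, 1]^2), yy = sum(w * dc[, 2]^2),
          zz = sum(w * dc[, 3]^2), xy = sum(w * dc[, 1] * dc[, 2]),
          xz = sum(w * dc[, 1] * dc[, 3]),
          yz = sum(w * dc[, 2] * dc[, 3])) / W
  if (is.null(idx)) {
    shape <- c(NA_real_, NA_real_, NA_real_)
  } else {
    idx <- matrix(as.integer(idx), ncol = 3)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    present <- new.env(hash = TRUE, size = n)
    for (k in key(idx)) assign(k, TRUE, envir = present)
    face_areas <- c(spacing_mm[2] * spacing_mm[3],
                    spacing_mm[1] * spacing_mm[3],
                    spacing_mm[1] * spacing_mm[2])
    area <- 0
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    for (o in seq_len(6)) {
      nb <- sweep(idx, 2, -offs[o, ])
      exposed <- !vapply(key(nb), exists, logical(1), envir = present,
                         inherits = FALSE)
      area <- area + sum(exposed) * face_areas[ceiling(o / 2)]
    }
    vol <- n * prod(spacing_mm)
    comp <- 36 * pi * vol^2 / area^3
    shape <- c(area, comp, comp^(1 / 3))
  }
  stats::setNames(c(ms, shape), nm)
}

#' Region volume in mm^3
#'
#' Voxel count of the label times the voxel volume; counts every labelled
#' voxel regardless of T2 validity (volume is an anatomical measure, not an
#' intensity one).
#'
#' @param labels a \code{volume3d} label image.
#' @param label the label to measure.
#' @param spacing_mm voxel spacing (default: from \code{labels}).
#' @return Volume in mm^3 (0, with a warning, for an absent label).
#' @export
region_volume <- function(labels, label, spacing_mm = labels$spacing_mm) {
  n <- sum(labels$data == label)
  if (n == 0) warning("label ", label, " absent from label image")
  n * prod(spacing_mm)
}

#' Extract the full 38-feature vector for every atlas region
#'
#' For each region: volume from all labelled voxels; signal and texture
#' features from the T2 values of labelled voxels that are valid in the T2
#' map. Regions with fewer than \code{min_voxels} valid voxels degrade to
#' an all-NA sentinel row (never an error), so one failed region cannot
#' abort a subject.
#'
#' @param t2map a \code{\link{compute_t2_map}} result.
#' @param labels a \code{volume3d} label image in T2-map space.
#' @param atlas a \code{\link{region_atlas}}.
#' @param registry feature registry (default \code{\link{feature_registry}()}).
#' @param min_voxels minimum valid-voxel count per region.
#' @param n_bins histogram bins for entropy/energy.
#' @return matrix (regions x features) with region names as rownames and an
#'   attribute \code{n_valid_voxels}.
#' @export
extract_all <- function(t2map, labels, atlas,
                        registry = feature_registry(),
                        min_voxels = 10, n_bins = 64) {
  stopifnot(identical(dim(t2map$t2_ms), dim(labels$data)))
  d <- dim(labels$data)
  want_sig <- registry$name[registry$family == "signal"]
  want_tex <- registry$name[registry$family == "texture"]
  want_vol <- "volume" %in% registry$name
  out <- matrix(NA_real_, nrow = n_regions(atlas), ncol = nrow(registry),
                dimnames = list(atlas$regions$name, registry$name))
  nvalid <- integer(n_regions(atlas))
  for (r in seq_len(n_regions(atlas))) {
    lab <- atlas$regions$label[r]
    in_region <- labels$data == lab
    if (want_vol)
      out[r, "volume"] <- sum(in_region) * prod(labels$spacing_mm)
    ok <- in_region & t2map$valid_mask
    nvalid[r] <- sum(ok)
    if (nvalid[r] < min_voxels) next
    vals <- t2map$t2_ms[ok]
    if (length(want_sig)) {
      sf <- signal_features(vals, n_bins = n_bins, min_voxels = min_voxels)
      out[r, want_sig] <- sf[want_sig]
    }
    if (length(want_tex)) {
      lin <- which(ok)
      k <- (lin - 1L) %/% (d[1] * d[2])
      j <- (lin - 1L - k * d[1] * d[2]) %/% d[1]
      i <- lin - 1L - k * d[1] * d[2] - j * d[1]
      idx <- cbind(i + 1L, j + 1L, k + 1L)
      coords <- index_to_world(labels, idx)
      tf <- texture_features(coords, vals, idx = idx,
                             spacing_mm = labels$spacing_mm,
                             min_voxels = min_voxels)
      out[r, want_tex] <- tf[want_tex]
    }
  }
  attr(out, "n_valid_voxels") <- stats::setNames(nvalid, atlas$regions$name)
  out
}
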