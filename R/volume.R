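#' 3D scalar volume with grid geometry
#'
#' Minimal image container used throughout the pipeline: a 3D array plus an
#' axis-aligned grid-to-world map (per-axis spacing in mm and a world origin
#' for voxel (1,1,1)). Rotational misalignment between spaces is carried by
#' \code{\link{rigid_transform}} objects, not by the affine, so the affine
#' stays diagonal.
#'
#' @param data 3D numeric array.
#' @param spacing_mm numeric(3) voxel size in mm.
#' @param origin_mm numeric(3) world position of voxel (1,1,1).
#' @return An object of class \code{volume3d}.
#' @export
volume3d <- function(data, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, length(spacing_mm) == 3,
            all(spacing_mm > 0), length(origin_mm) == 3)
  structure(list(data = data,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "volume3d")
}

#' Dual-echo volume: a 3D image with an acquisition echo time
#'
#' @inheritParams volume3d
#' @param te_ms echo time in ms (> 0).
#' @return An object of class \code{echo_volume} (inherits \code{volume3d}).
#' @export
echo_volume <- function(data, te_ms, spacing_mm = c(1, 1, 1),
                        origin_mm = c(0, 0, 0)) {
  stopifnot(is.numeric(te_ms), length(te_ms) == 1, te_ms > 0)
  v <- volume3d(data, spacing_mm, origin_mm)
  v$te_ms <- te_ms
  class(v) <- c("echo_volume", "volume3d")
  v
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 3), collapse = " x ")))
  if (!is.null(x$te_ms)) cat(sprintf(", TE = %g ms", x$te_ms))
  cat("\n")
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) return("dimensions")
  if (!isTRUE(all.equal(a$spacing_mm, b$spacing_mm))) return("spacing_mm")
  if (!isTRUE(all.equal(a$origin_mm, b$origin_mm))) return("origin_mm")
  NULL
}

stop_if_geometry_differs <- function(a, b) {
  bad <- same_geometry(a, b)
  if (!is.null(bad))
    stop("volumes differ in grid geometry: ", bad, call. = FALSE)
  invisible(NULL)
}

# world coordinates (n x 3, mm) of 1-based voxel indices (n x 3)
index_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx, 2, 1), 2, vol$spacing_mm, FUN = "*") |>
    sweep(2, vol$origin_mm, FUN = "+")
}

# continuous (possibly fractional) 1-based voxel coordinates of world points
world_to_index <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, vol$origin_mm), 2, vol$spacing_mm, FUN = "/") + 1
}

# all voxel index triples of a grid, x fastest (column-major order)
grid_index_matrix <- function(d) {
  cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
        rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

# Trilinear sample of vol$data at continuous index coords (n x 3).
# Points outside the grid return `outside`.
sample_trilinear <- function(vol, ci, outside = 0) {
  d <- dim(vol$data)
  x <- ci[, 1]; y <- ci[, 2]; z <- ci[, 3]
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(as.numeric(outside), length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  arr <- vol$data
  lin <- function(i, j, k) arr[cbind(i, j, k)]
  v <- lin(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    lin(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    lin(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    lin(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    lin(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    lin(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    lin(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    lin(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[inside] <- v
  out
}

# Nearest-neighbour sample (for label images); outside -> `outside`.
sample_nearest <- function(vol, ci, outside = 0) {
  d <- dim(vol$data)
  i <- round(ci[, 1]); j <- round(ci[, 2]); k <- round(ci[, 3])
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(as.numeric(outside), nrow(ci))
  out[inside] <- vol$data[cbind(i[inside], j[inside], k[inside])]
  out
}

#' Resample a volume through a rigid transform
#'
#' Produces an image on the grid of \code{reference}; each output voxel at
#' world position p takes the (trilinearly interpolated) value of
#' \code{moving} at \code{rt_apply(transform, p)}. Points falling outside the
#' moving grid get \code{outside}.
#'
#' @param moving a \code{volume3d}.
#' @param transform a \code{rigid_transform} mapping reference-space world
#'   coordinates into moving-space world coordinates.
#' @param reference a \code{volume3d} supplying the output grid (defaults to
#'   \code{moving}).
#' @param outside fill value for out-of-grid samples.
#' @return A \code{volume3d} on the reference grid.
#' @export
resample_image <- function(moving, transform, reference = moving,
                           outside = 0) {
  d <- dim(reference$data)
  pts <- index_to_world(reference, grid_index_matrix(d))
  ci <- world_to_index(moving, rt_apply(transform, pts))
  vals <- sample_trilinear(moving, ci, outside = outside)
  volume3d(array(vals, dim = d), reference$spacing_mm, reference$origin_mm)
}

#' Resample a label image through a rigid transform
#'
#' Labels are categorical, so only nearest-neighbour interpolation is used;
#' no label absent from the input can appear in the output, and voxels
#' mapping outside the source grid get label 0 (background).
#'
#' @inheritParams resample_image
#' @param labels a \code{volume3d} of integer labels.
#' @return A \code{volume3d} of labels on the reference grid.
#' @export
resample_labels <- function(labels, transform, reference = labels) {
  d <- dim(reference$data)
  pts <- index_to_world(reference, grid_index_matrix(d))
  ci <- world_to_index(labels, rt_apply(transform, pts))
  vals <- sample_nearest(labels, ci, outside = 0)
  out <- volume3d(array(vals, dim = d), reference$spacing_mm,
                  reference$origin_mm)
  stopifnot(all(unique(vals) %in% c(0, unique(as.vector(labels$data)))))
  out
}

#' Per-label Dice overlap between two label images
#'
#' @param a,b \code{volume3d} label images on the same grid.
#' @param labels labels to score (default: nonzero labels present in either).
#' @return Named numeric vector of Dice coefficients in [0, 1].
#' @export
dice_overlap <- function(a, b, labels = NULL) {
  stop_if_geometry_differs(a, b)
  if (is.null(labels))
    labels <- setdiff(sort(unique(c(a$data, b$data))), 0)
  vapply(labels, function(l) {
    ina <- a$data == l; inb <- b$data == l
    den <- sum(ina) + sum(inb)
    if (den == 0) return(NA_real_)
    2 * sum(ina & inb) / den
  }, numeric(1)) |> stats::setNames(labels)
}
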