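#' Rigid 3D transform
#'
#' A rigid-body transform parameterised by three rotation angles (radians,
#' applied as \eqn{R = R_z R_y R_x}, i.e. extrinsic rotations about the world
#' x, y and z axes in that order), a translation in mm, and a rotation centre
#' in mm. A point is mapped as \eqn{p' = R (p - c) + c + t}.
#'
#' The convention follows the resampling use of transforms in image
#' registration: the transform maps coordinates of the \emph{fixed} (output)
#' space into the \emph{moving} (input) space, so that an output voxel at
#' world position p samples the moving image at \code{rt_apply(tf, p)}.
#'
#' @param angles_rad numeric(3), rotations about x, y, z in radians.
#' @param translation_mm numeric(3), translation in mm.
#' @param center_mm numeric(3), centre of rotation in mm.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(angles_rad = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  stopifnot(length(angles_rad) == 3, length(translation_mm) == 3,
            length(center_mm) == 3)
  structure(list(angles_rad = as.numeric(angles_rad),
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  cat(sprintf("  rotation (deg about x,y,z): %s\n",
              paste(signif(x$angles_rad * 180 / pi, 4), collapse = ", ")))
  cat(sprintf("  translation (mm):           %s\n",
              paste(signif(x$translation_mm, 4), collapse = ", ")))
  cat(sprintf("  centre (mm):                %s\n",
              paste(signif(x$center_mm, 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(angles_rad) {
  a <- angles_rad[1]; b <- angles_rad[2]; g <- angles_rad[3]
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Recover x,y,z angles from a rotation matrix (inverse of rotation_matrix;
# valid away from the gimbal lock |beta| = pi/2, far beyond any misalignment
# handled here).
angles_from_matrix <- function(R) {
  b <- asin(-R[3, 1])
  a <- atan2(R[3, 2], R[3, 3])
  g <- atan2(R[2, 1], R[1, 1])
  c(a, b, g)
}

#' Apply a rigid transform to points
#'
#' @param tf a \code{rigid_transform}.
#' @param points n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
rt_apply <- function(tf, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  R <- rotation_matrix(tf$angles_rad)
  centred <- sweep(points, 2, tf$center_mm)
  out <- centred %*% t(R)
  sweep(out, 2, tf$center_mm + tf$translation_mm, FUN = "+")
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{b} first, then
#' \code{a}: \code{rt_apply(rt_compose(a, b), p) == rt_apply(a, rt_apply(b, p))}.
#'
#' @param a,b \code{rigid_transform} objects.
#' @return A \code{rigid_transform} with centre at the origin.
#' @export
rt_compose <- function(a, b) {
  Ra <- rotation_matrix(a$angles_rad)
  Rb <- rotation_matrix(b$angles_rad)
  R <- Ra %*% Rb
  # a(b(p)) = Ra(Rb(p - cb) + cb + tb - ca) + ca + ta
  off <- as.numeric(Ra %*% (-Rb %*% b$center_mm + b$center_mm +
                              b$translation_mm - a$center_mm)) +
    a$center_mm + a$translation_mm
  rigid_transform(angles_from_matrix(R), off, c(0, 0, 0))
}

#' Invert a rigid transform
#'
#' @param tf a \code{rigid_transform}.
#' @return The inverse transform; composing the two gives the identity to
#'   within floating tolerance.
#' @export
rt_invert <- function(tf) {
  R <- rotation_matrix(tf$angles_rad)
  Ri <- t(R)
  # p' = R(p - c) + c + t  =>  p = Ri(p' - c - t) + c
  off <- as.numeric(-Ri %*% (tf$center_mm + tf$translation_mm)) + tf$center_mm
  rigid_transform(angles_from_matrix(Ri), off, c(0, 0, 0))
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' The JSON records the three rotation angles (radians, x-y-z extrinsic
#' convention), the translation and the centre, plus a note fixing the
#' convention, so transforms survive a round trip through disk.
#'
#' @param tf a \code{rigid_transform}.
#' @param path file path.
#' @return \code{rt_read_json} returns a \code{rigid_transform}.
#' @export
rt_write_json <- function(tf, path) {
  jsonlite::write_json(list(
    type = "rigid_transform",
    convention = "p' = Rz*Ry*Rx (p - c) + c + t; fixed-to-moving resampling map",
    angles_rad = tf$angles_rad,
    translation_mm = tf$translation_mm,
    center_mm = tf$center_mm), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname rt_write_json
#' @export
rt_read_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$angles_rad, x$translation_mm, x$center_mm)
}
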