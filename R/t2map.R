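#' Two-point T2 map estimation
#'
#' Computes the voxel-wise transverse relaxation time from a dual fast
#' spin-echo pair by the closed-form two-point solution of the
#' mono-exponential decay model \eqn{S = S_0 e^{-TE/T2}}:
#' \deqn{T2(i) = (TE_b - TE_a) / (\ln S_a(i) - \ln S_b(i))}
#' where \eqn{S_a} is the short-echo (PD-weighted) and \eqn{S_b} the
#' long-echo (T2-weighted) signal.
#'
#' A voxel is marked invalid when the solution is undefined or nonphysical:
#' \eqn{S_a \le 0}, \eqn{S_b \le 0} (background or noise dominated), or
#' \eqn{S_a \le S_b} (no decay; the log-difference denominator is zero or
#' negative). Invalid voxels get \code{t2_ms = 0} and are excluded from all
#' downstream regional statistics. Valid values falling outside
#' \code{clip_range_ms} are clamped to the range bounds and stay valid, so
#' near-singular denominators cannot dominate regional histograms.
#'
#' @param echo_a,echo_b \code{\link{echo_volume}} objects on the same grid
#'   with \code{echo_a$te_ms < echo_b$te_ms}.
#' @param clip_range_ms numeric(2) lower/upper physical plausibility bounds
#'   (ms); default \code{c(1, 3000)}.
#' @return An object of class \code{t2_map}: fields \code{t2_ms} (3D array,
#'   ms), \code{valid_mask} (3D logical), \code{clip_range_ms},
#'   \code{spacing_mm}, \code{origin_mm}, \code{te_a_ms}, \code{te_b_ms}.
#' @export
compute_t2_map <- function(echo_a, echo_b, clip_range_ms = c(1, 3000)) {
  stopifnot(inherits(echo_a, "echo_volume"), inherits(echo_b, "echo_volume"))
  stop_if_geometry_differs(echo_a, echo_b)
  if (echo_a$te_ms >= echo_b$te_ms)
    stop("echo_a must be the shorter echo: TE_a < TE_b required")
  stopifnot(length(clip_range_ms) == 2, clip_range_ms[1] > 0,
            clip_range_ms[2] > clip_range_ms[1])
  sa <- echo_a$data; sb <- echo_b$data
  valid <- sa > 0 & sb > 0 & sa > sb
  t2 <- array(0, dim = dim(sa))
  dte <- echo_b$te_ms - echo_a$te_ms
  t2[valid] <- dte / (log(sa[valid]) - log(sb[valid]))
  t2[valid] <- pmin(pmax(t2[valid], clip_range_ms[1]), clip_range_ms[2])
  structure(list(t2_ms = t2, valid_mask = valid,
                 clip_range_ms = clip_range_ms,
                 spacing_mm = echo_a$spacing_mm,
                 origin_mm = echo_a$origin_mm,
                 te_a_ms = echo_a$te_ms, te_b_ms = echo_b$te_ms),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  v <- x$t2_ms[x$valid_mask]
  cat(sprintf("t2_map: %s voxels, %d valid (%.1f%%)",
              paste(dim(x$t2_ms), collapse = "x"), sum(x$valid_mask),
              100 * mean(x$valid_mask)))
  if (length(v))
    cat(sprintf(", valid T2 median %.1f ms [%.1f, %.1f]",
                stats::median(v), min(v), max(v)))
  cat("\n")
  invisible(x)
}

# view a t2_map as a plain volume3d (for registration / resampling)
t2_as_volume <- function(t2map) {
  volume3d(t2map$t2_ms, t2map$spacing_mm, t2map$origin_mm)
}

#' Residual of the mono-exponential refit
#'
#' Two echoes determine the two-parameter mono-exponential exactly, so the
#' refit residual is zero at every valid voxel unless clamping to
#' \code{clip_range_ms} altered the estimate; the residual therefore flags
#' exactly the clipped voxels. For each valid voxel, \eqn{S_0} is recovered
#' from the short echo and the (possibly clamped) T2, and the residual is
#' \eqn{|S_b^{pred} - S_b|} in signal units. Invalid voxels get 0.
#'
#' @inheritParams compute_t2_map
#' @param t2map the \code{t2_map} computed from the pair.
#' @return 3D numeric array of absolute residuals.
#' @export
t2_fit_quality <- function(echo_a, echo_b, t2map) {
  stop_if_geometry_differs(echo_a, echo_b)
  stopifnot(identical(dim(echo_a$data), dim(t2map$t2_ms)))
  res <- array(0, dim = dim(t2map$t2_ms))
  v <- t2map$valid_mask
  if (!any(v)) return(res)
  t2 <- t2map$t2_ms[v]
  s0_hat <- echo_a$data[v] * exp(echo_a$te_ms / t2)
  sb_pred <- s0_hat * exp(-echo_b$te_ms / t2)
  res[v] <- abs(sb_pred - echo_b$data[v])
  res
}
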