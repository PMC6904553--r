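# Pinhole camera model and pixel <-> millimetre error conversion.
#
# Camera convention (used everywhere in the package): +z forward along the
# optical axis, x right, y down, pixel origin at the image top-left.  The
# model is pure pinhole with zero lens distortion: the synthetic frames are
# generated distortion-free, so evaluation against them must use the same
# projection.

#' Pinhole camera intrinsics
#'
#' @param fx,fy focal lengths in pixels (positive).
#' @param cx,cy principal point in pixels, inside the image.
#' @param width,height image size in pixels.
#' @return an object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0,
            cx >= 0, cx < width, cy >= 0, cy < height)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = width, height = height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera intrinsics: fx=%g fy=%g cx=%g cy=%g, image %dx%d px\n",
              x$fx, x$fy, x$cx, x$cy, as.integer(x$width),
              as.integer(x$height)))
  invisible(x)
}

#' Intrinsics as a 3x3 calibration matrix
#'
#' @param x a `camera_intrinsics` object.
#' @param ... unused.
#' @return the 3x3 upper-triangular calibration matrix K.
#' @export
as.matrix.camera_intrinsics <- function(x, ...) {
  matrix(c(x$fx, 0, 0, 0, x$fy, 0, x$cx, x$cy, 1), 3, 3)
}

#' Project camera-frame 3D points to pixels
#'
#' Standard pinhole projection `u = fx x/z + cx`, `v = fy y/z + cy`.
#' All points must be strictly in front of the camera; projections may fall
#' outside the image (they are reported, not clamped).
#'
#' @param k `camera_intrinsics`.
#' @param pts n x 3 matrix (or 3-vector) of camera-frame points, mm.
#' @return data.frame with columns `u`, `v`, `depth` (camera z, mm) and
#'   `in_image` (logical, inside the pixel bounds).
#' @export
project_points <- function(k, pts) {
  stopifnot(inherits(k, "camera_intrinsics"))
  m <- points_matrix(pts)
  z <- m[, 3]
  if (any(z <= 0)) {
    stop("point behind camera: projection requires depth z > 0 ",
         "(got min z = ", format(min(z)), " mm)")
  }
  u <- k$fx * m[, 1] / z + k$cx
  v <- k$fy * m[, 2] / z + k$cy
  data.frame(u = u, v = v, depth = z,
             in_image = u >= 0 & u < k$width & v >= 0 & v < k$height)
}

#' Back-project pixels to 3D at a given depth
#'
#' Inverse of [project_points()]: returns the camera-frame point on the
#' viewing ray of `(u, v)` whose z equals `depth`.
#'
#' @param k `camera_intrinsics`.
#' @param u,v pixel coordinates (vectors of equal length).
#' @param depth camera-frame depth in mm (scalar or vector), > 0.
#' @return n x 3 matrix of camera-frame points, mm.
#' @export
unproject_pixels <- function(k, u, v, depth) {
  stopifnot(inherits(k, "camera_intrinsics"), all(depth > 0))
  cbind((u - k$cx) / k$fx * depth, (v - k$cy) / k$fy * depth, depth)
}

#' Convert a pixel discrepancy to millimetres at a known depth
#'
#' The AR error observed on screen is a pixel distance, which says nothing
#' about scale; to express it in millimetres both pixels are back-projected
#' through the inverse calibration matrix to rays, the rays are cut at the
#' supplied camera-frame depth, and the Euclidean distance of the two 3D
#' points is returned.  For in-plane offsets this equals
#' `depth * ||K^-1 (du, dv, 0)||`.  The depth used throughout the package is
#' the depth of the reprojected AR point, the only depth the navigation
#' system knows.
#'
#' @param k `camera_intrinsics`.
#' @param observed,reprojected pixel coordinates: data.frames with `u`,`v`
#'   columns, 2-column matrices, or length-2 vectors (vectorized).
#' @param depth camera-frame depth in mm, > 0 (scalar or vector).
#' @return distance(s) in mm.
#' @export
pixel_error_to_mm <- function(k, observed, reprojected, depth) {
  stopifnot(inherits(k, "camera_intrinsics"))
  if (any(depth <= 0)) stop("depth must be positive to convert pixels to mm")
  po <- pixel_uv(observed)
  pr <- pixel_uv(reprojected)
  a <- unproject_pixels(k, po[, 1], po[, 2], depth)
  b <- unproject_pixels(k, pr[, 1], pr[, 2], depth)
  sqrt(rowSums((a - b)^2))
}

pixel_uv <- function(p) {
  if (is.data.frame(p)) return(cbind(p$u, p$v))
  if (is.matrix(p)) { stopifnot(ncol(p) == 2L); return(p) }
  if (is.numeric(p) && length(p) == 2L) return(matrix(p, 1L, 2L))
  stop("pixels must be a data.frame with u/v, a 2-column matrix or a 2-vector")
}
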