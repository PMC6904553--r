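# Small numerical helpers shared across modules.

#' Round half away from zero
#'
#' Presentation rounding used in the summary tables: ties go away from zero
#' (so 29.35 -> 29.4), unlike [base::round()]'s round-half-even.  Raw results
#' are never rounded; this is applied only when tables are rendered.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Project a matrix to the nearest proper rotation
#'
#' Returns the rotation matrix closest (in Frobenius norm) to `m`, via SVD
#' with determinant correction so the result is in SO(3).
#'
#' @param m a 3x3 numeric matrix.
#' @return a 3x3 rotation matrix with determinant +1.
#' @export
nearest_rotation <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  s <- svd(m)
  d <- det(s$u %*% t(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Geodesic angle between two rotations
#'
#' @param r1,r2 3x3 rotation matrices.
#' @return angle in degrees, in `[0, 180]`.
#' @export
geodesic_angle <- function(r1, r2) {
  # 2 asin(||R1 - R2||_F / (2 sqrt(2))): equals the geodesic angle but,
  # unlike the acos-of-trace form, stays accurate for tiny angles
  s <- sqrt(sum((r1 - r2)^2)) / (2 * sqrt(2))
  2 * asin(min(1, s)) * 180 / pi
}

#' Rotation about an axis
#'
#' Rodrigues' formula.
#'
#' @param axis 3-vector (need not be normalized).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  kx <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

# Uniform random rotation via normalized quaternion; uses the current RNG
# stream so callers control reproducibility with set.seed / withr::with_seed.
random_rotation <- function(max_angle_deg = NULL) {
  if (!is.null(max_angle_deg)) {
    ax <- stats::rnorm(3)
    return(rotation_about_axis(ax, stats::runif(1, 0, max_angle_deg)))
  }
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# seed derivation for independent sub-streams; stays below 2^31 - 1
derive_seed <- function(seed, ...) {
  idx <- c(...)
  mix <- sum(as.numeric(idx) * (10007^(seq_along(idx) - 1)))
  as.integer((as.numeric(seed) + mix) %% 2147483629 + 1)
}

# coerce labeled points (data.frame with label,x,y,z) to a numeric matrix
points_matrix <- function(pts) {
  if (is.matrix(pts)) {
    stopifnot(ncol(pts) == 3L)
    return(pts)
  }
  if (is.data.frame(pts)) {
    stopifnot(all(c("x", "y", "z") %in% names(pts)))
    return(cbind(pts$x, pts$y, pts$z))
  }
  if (is.numeric(pts) && length(pts) == 3L) return(matrix(pts, 1L, 3L))
  stop("points must be an n x 3 matrix, a data.frame with x/y/z, or a 3-vector")
}

#' Build a labeled point set
#'
#' The package's exchange format for marks, annotations and fiducials: a
#' data.frame with columns `label`, `x`, `y`, `z` (millimetres).
#'
#' @param label character vector of unique mark labels.
#' @param xyz n x 3 numeric matrix of coordinates in mm.
#' @return data.frame with columns label, x, y, z.
#' @export
labeled_points <- function(label, xyz) {
  xyz <- points_matrix(xyz)
  stopifnot(length(label) == nrow(xyz), !anyDuplicated(label))
  data.frame(label = as.character(label), x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], stringsAsFactors = FALSE)
}
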