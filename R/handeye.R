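# Hand-eye calibration of the tracked laparoscope.
#
# The "hand" is the optical marker body M rigidly attached to the
# laparoscope shaft; the "eye" is the camera C.  The unknown is the fixed
# transform T_C^M.  Calibration data are multiple poses of a printed
# calibration plate whose own optical markers tie the plate to the tracker
# frame O: each pose yields the tracked body pose (R_O^M, t_O^M) and the
# plate pose observed by the camera (R_C^O, t_C^O).  Stacking, per pose,
#
#   [ I (x) (R_O^M)^-1   Z_{9,3}    ] [ vec(R_C^M) ]   [ vec(R_C^O)              ]
#   [ Z_{3,9}           (R_O^M)^-1 ] [   t_C^M    ] = [ t_C^O + (R_O^M)^-1 t_O^M ]
#
# ((x) the Kronecker product, vec() column-major vectorization, Z zero
# blocks) gives a 12N x 12 dense least-squares problem, solved jointly for
# rotation and translation by orthogonal (QR) factorization; the 9-vector
# rotation part is then reshaped column-wise and projected to the nearest
# proper rotation.

#' A tracked pose pair for hand-eye calibration
#'
#' @param tracker_to_marker pose of the tracker frame in the marker body,
#'   a `rigid_transform` with frames O -> M (houses `R_O^M`, `t_O^M`).
#' @param plate_to_camera plate pose observed by the camera, a
#'   `rigid_transform` with frames C -> O (houses `R_C^O`, `t_C^O`; the
#'   plate frame coincides with the tracker frame through its machined
#'   optical markers).
#' @return an object of class `pose_pair`.
#' @export
pose_pair <- function(tracker_to_marker, plate_to_camera) {
  stopifnot(inherits(tracker_to_marker, "rigid_transform"),
            inherits(plate_to_camera, "rigid_transform"))
  if (!identical(c(tracker_to_marker$from, tracker_to_marker$to), c("O", "M")))
    stop("tracker_to_marker must map O -> M")
  if (!identical(c(plate_to_camera$from, plate_to_camera$to), c("C", "O")))
    stop("plate_to_camera must map C -> O")
  structure(list(tracker_to_marker = tracker_to_marker,
                 plate_to_camera = plate_to_camera),
            class = "pose_pair")
}

#' Build the stacked hand-eye linear system
#'
#' Assembles the 12N x 12 coefficient matrix and right-hand side for the
#' stacked Kronecker-product formulation described above.  The unknown
#' vector is `c(vec(R_C^M), t_C^M)`.
#'
#' @param pairs list of [pose_pair()] objects, at least 3.
#' @return list with elements `A` (12N x 12 matrix), `b` (12N vector) and
#'   `n_poses`.
#' @export
build_handeye_system <- function(pairs) {
  check_pose_pairs(pairs)
  n <- length(pairs)
  A <- matrix(0, 12 * n, 12)
  b <- numeric(12 * n)
  for (i in seq_len(n)) {
    p <- pairs[[i]]
    rom_inv <- t(p$tracker_to_marker$rotation)  # (R_O^M)^-1
    rows <- (i - 1) * 12
    A[rows + (1:9), 1:9] <- diag(3) %x% rom_inv
    A[rows + (10:12), 10:12] <- rom_inv
    b[rows + (1:9)] <- as.numeric(p$plate_to_camera$rotation)
    b[rows + (10:12)] <- p$plate_to_camera$translation +
      as.numeric(rom_inv %*% p$tracker_to_marker$translation)
  }
  list(A = A, b = b, n_poses = n)
}

check_pose_pairs <- function(pairs) {
  if (!is.list(pairs) || !all(vapply(pairs, inherits, logical(1), "pose_pair")))
    stop("pairs must be a list of pose_pair objects")
  if (length(pairs) < 3L)
    stop("insufficient poses: hand-eye calibration needs at least 3 pose ",
         "pairs, got ", length(pairs))
  invisible(pairs)
}

#' Solve hand-eye calibration
#'
#' Least-squares solution of the stacked system via QR, followed by
#' projection of the reshaped rotation block to SO(3) (SVD with
#' determinant correction).  The reported residual is the root-mean-square
#' residual of the *pre-projection* linear solution, mixing dimensionless
#' rotation rows with millimetre translation rows as the stacked system
#' does.
#'
#' Pose sets whose tracked rotations are all (numerically) identical are
#' rejected: although the stacked system stays full rank, such motion
#' cannot expose a systematic error in the tracked rotation direction, so
#' the calibration would be untrustworthy.
#'
#' @param pairs list of [pose_pair()] objects, at least 3, with tracked
#'   rotations that actually differ.
#' @return an object of class `handeye_result`: `t_cm` (a
#'   `rigid_transform`, C -> M), `residual_rms`, `n_poses`.
#' @export
solve_handeye <- function(pairs) {
  check_pose_pairs(pairs)
  rots <- lapply(pairs, function(p) p$tracker_to_marker$rotation)
  spread <- max(vapply(rots[-1], geodesic_angle, numeric(1), r2 = rots[[1]]))
  if (spread < 1e-6) {
    stop("degenerate motion: all tracked rotations are identical; ",
         "rotate the laparoscope between calibration poses")
  }
  sys <- build_handeye_system(pairs)
  qrA <- qr(sys$A)
  if (qrA$rank < 12L) {
    stop("degenerate motion: stacked hand-eye system is rank deficient ",
         "(rank ", qrA$rank, " of 12)")
  }
  x <- qr.coef(qrA, sys$b)
  residual_rms <- sqrt(mean((sys$A %*% x - sys$b)^2))
  r_raw <- matrix(x[1:9], 3, 3)          # column-major, matching vec()
  r <- nearest_rotation(r_raw)
  structure(list(t_cm = rigid_transform(r, x[10:12], from = "C", to = "M"),
                 residual_rms = residual_rms, n_poses = sys$n_poses),
            class = "handeye_result")
}

#' @export
print.handeye_result <- function(x, ...) {
  cat(sprintf("hand-eye calibration from %d poses (linear residual RMS %.3g)\n",
              x$n_poses, x$residual_rms))
  print(x$t_cm)
  invisible(x)
}

#' Per-pose hand-eye residuals
#'
#' For each pose pair, predicts the plate-in-camera pose implied by the
#' calibration, `T_C^O = (T_O^M)^-1 . T_C^M`, and compares it with the
#' observed one: rotation error as geodesic angle (degrees), translation
#' error as Euclidean distance (mm).
#'
#' @param pairs list of [pose_pair()] objects.
#' @param result a `handeye_result` (or bare `rigid_transform` C -> M).
#' @return list with `per_pose` (data.frame: pose, rot_deg, trans_mm) and
#'   `summary` (mean/max of each).
#' @export
handeye_residual <- function(pairs, result) {
  check_pose_pairs(pairs)
  t_cm <- if (inherits(result, "handeye_result")) result$t_cm else result
  stopifnot(inherits(t_cm, "rigid_transform"))
  res <- t(vapply(pairs, function(p) {
    pred <- compose_transform(invert_transform(p$tracker_to_marker), t_cm)
    obs <- p$plate_to_camera
    c(geodesic_angle(pred$rotation, obs$rotation),
      sqrt(sum((pred$translation - obs$translation)^2)))
  }, numeric(2)))
  per_pose <- data.frame(pose = seq_along(pairs),
                         rot_deg = res[, 1], trans_mm = res[, 2])
  list(per_pose = per_pose,
       summary = c(mean_rot_deg = mean(res[, 1]), max_rot_deg = max(res[, 1]),
                   mean_trans_mm = mean(res[, 2]), max_trans_mm = max(res[, 2])))
}
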