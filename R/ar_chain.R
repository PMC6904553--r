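# The AR overlay chain: image (CT) space -> patient -> tracker -> marker
# body -> camera -> pixels.  The full operator is
#
#     T_I^C = M_I . (T_C^M)^-1 . (T_M^O)^-1 . T_P^O . (T_P^I)^-1
#
# where M_I is the intrinsics matrix, T_C^M the hand-eye calibration,
# T_M^O the tracked laparoscope pose, T_P^O the tracked patient pose, and
# T_P^I the image-to-patient registration (the chain consumes its inverse;
# equivalently, the I -> P transform T_I^P that the registration module
# returns directly -- both spellings denote the same estimate).

#' Build the AR projection operator
#'
#' Assembles the overlay chain from the four rigid transforms and the
#' camera intrinsics.  Frame labels are checked so that the chain runs
#' consistently from image space I to camera space C.
#'
#' @param k `camera_intrinsics`.
#' @param t_cm hand-eye calibration, frames C -> M.
#' @param t_mo tracked laparoscope marker pose, frames M -> O.
#' @param t_po tracked patient pose, frames P -> O.
#' @param t_ip image-to-patient registration, frames I -> P (the output of
#'   [rigid_register_svd()]).
#' @return an object of class `ar_chain` holding the intrinsics and the
#'   rigid part `t_ic` (frames I -> C).
#' @seealso [project_ar()]
#' @export
build_ar_chain <- function(k, t_cm, t_mo, t_po, t_ip) {
  stopifnot(inherits(k, "camera_intrinsics"))
  for (nm in c("t_cm", "t_mo", "t_po", "t_ip")) {
    if (!inherits(get(nm), "rigid_transform")) {
      stop(nm, " must be a rigid_transform")
    }
  }
  want <- list(t_cm = c("C", "M"), t_mo = c("M", "O"),
               t_po = c("P", "O"), t_ip = c("I", "P"))
  for (nm in names(want)) {
    t <- get(nm)
    if (!identical(c(t$from, t$to), want[[nm]])) {
      stop(sprintf("%s must map %s -> %s, got %s -> %s", nm,
                   want[[nm]][1], want[[nm]][2], t$from, t$to))
    }
  }
  t_ic <- compose_transform(
    invert_transform(t_cm),
    compose_transform(invert_transform(t_mo),
                      compose_transform(t_po, t_ip)))
  structure(list(intrinsics = k, t_ic = t_ic), class = "ar_chain")
}

#' @export
print.ar_chain <- function(x, ...) {
  cat("AR projection operator (image space -> pixels)\n")
  print(x$intrinsics)
  print(x$t_ic)
  invisible(x)
}

#' Project image-space points through the AR chain
#'
#' Applies the rigid part of the chain and then the pinhole projection.
#' Points that land behind the camera are flagged per point (`behind`),
#' not treated as fatal, since a navigation frame may legitimately look
#' away from part of the model.
#'
#' @param chain an `ar_chain` from [build_ar_chain()].
#' @param pts image-frame 3D points: n x 3 matrix, labeled point
#'   data.frame, or 3-vector (mm).
#' @return data.frame with columns `label` (if the input had labels), `u`,
#'   `v`, `depth` (camera-frame z in mm), `behind` and `visible` (inside
#'   the image and in front of the camera).  `u`,`v` are `NA` for points
#'   behind the camera.
#' @export
project_ar <- function(chain, pts) {
  stopifnot(inherits(chain, "ar_chain"))
  lab <- if (is.data.frame(pts)) pts$label else NULL
  pc <- transform_points(chain$t_ic, points_matrix(pts))
  k <- chain$intrinsics
  z <- pc[, 3]
  behind <- z <= 0
  u <- v <- rep(NA_real_, length(z))
  ok <- !behind
  u[ok] <- k$fx * pc[ok, 1] / z[ok] + k$cx
  v[ok] <- k$fy * pc[ok, 2] / z[ok] + k$cy
  visible <- ok & !is.na(u) & u >= 0 & u < k$width & v >= 0 & v < k$height
  out <- data.frame(u = u, v = v, depth = z, behind = behind,
                    visible = visible)
  if (!is.null(lab)) out <- cbind(data.frame(label = lab), out)
  out
}
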