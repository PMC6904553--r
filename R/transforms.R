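# Rigid transforms between the named coordinate frames of the navigation
# system.  Frame labels follow the field's convention for laparoscopic AR:
#   I  image (CT) space          P  patient (on-table) space
#   O  optical tracker space     M  laparoscope marker body
#   C  laparoscope camera
# A transform maps points expressed in `from` coordinates to `to`
# coordinates; composition therefore requires the inner frames to match,
# which is enforced rather than advised because sub/superscript conventions
# in this area are notoriously error-prone.

FRAME_LABELS <- c("I", "P", "O", "M", "C")

check_frame <- function(f) {
  if (!(is.character(f) && length(f) == 1L && f %in% FRAME_LABELS)) {
    stop("frame label must be one of {", paste(FRAME_LABELS, collapse = ", "),
         "}, got: ", deparse(f))
  }
  f
}

#' Create a rigid transform between two coordinate frames
#'
#' A rigid transform holds a proper rotation and a translation (mm) and is
#' labeled with the frame it maps *from* and the frame it maps *to*.
#' Points `p` (in `from` coordinates) map to `R p + t` (in `to` coordinates).
#' The rotation is validated (orthonormal, determinant +1) and snapped to
#' the nearest exact rotation to keep long composition chains from drifting.
#'
#' @param rotation 3x3 rotation matrix (dimensionless).
#' @param translation 3-vector, millimetres.
#' @param from,to frame labels, one of `"I","P","O","M","C"`.
#' @param tol maximum allowed deviation from orthonormality before the
#'   input is rejected as not a rotation.
#' @return an object of class `rigid_transform`.
#' @seealso [compose_transform()], [invert_transform()], [transform_points()]
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0),
                            from = "I", to = "P", tol = 1e-7) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            is.numeric(translation), length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  dev <- max(abs(crossprod(rotation) - diag(3)))
  if (dev > tol || abs(det(rotation) - 1) > tol) {
    stop("rotation is not orthonormal with determinant +1 (deviation ",
         format(dev), ")")
  }
  structure(
    list(rotation = nearest_rotation(rotation),
         translation = as.numeric(translation),
         from = check_frame(from), to = check_frame(to)),
    class = "rigid_transform")
}

#' Identity transform between two frames
#'
#' @param from,to frame labels (identical labels are allowed, e.g. a
#'   within-frame motion estimated by ICP).
#' @return a `rigid_transform` with identity rotation and zero translation.
#' @export
rt_identity <- function(from = "I", to = "I") {
  rigid_transform(diag(3), c(0, 0, 0), from, to)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform %s -> %s\n", x$from, x$to))
  m <- as.matrix(x)
  print(round(m, 6))
  invisible(x)
}

#' Homogeneous 4x4 form of a rigid transform
#'
#' @param x a `rigid_transform`.
#' @param ... unused.
#' @return 4x4 matrix with bottom row (0,0,0,1).
#' @export
as.matrix.rigid_transform <- function(x, ...) {
  m <- diag(4)
  m[1:3, 1:3] <- x$rotation
  m[1:3, 4] <- x$translation
  m
}

#' Build a rigid transform from a homogeneous 4x4 matrix
#'
#' @param m 4x4 homogeneous matrix, bottom row (0,0,0,1).
#' @param from,to frame labels.
#' @return a `rigid_transform`.
#' @export
rt_from_matrix <- function(m, from, to) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    stop("bottom row of a homogeneous rigid transform must be (0,0,0,1)")
  }
  rigid_transform(m[1:3, 1:3], m[1:3, 4], from, to)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`; it therefore
#' requires `a$from == b$to` and maps `b$from` to `a$to`, mirroring the
#' matrix product of the homogeneous forms.
#'
#' @param a,b `rigid_transform` objects with matching inner frames.
#' @return the composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  if (!identical(a$from, b$to)) {
    stop(sprintf(
      "frame mismatch in composition: outer transform maps %s -> %s but inner maps %s -> %s",
      a$from, a$to, b$from, b$to))
  }
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  from = b$from, to = a$to)
}

#' Invert a rigid transform
#'
#' Rotation is transposed, translation becomes `-R^T t`, and the frame
#' labels swap.
#'
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rt <- t(t$rotation)
  rigid_transform(rt, as.numeric(-rt %*% t$translation),
                  from = t$to, to = t$from)
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param pts an n x 3 matrix, a labeled point data.frame (columns
#'   `label,x,y,z`) or a single 3-vector, in `t$from` coordinates (mm).
#' @return points in `t$to` coordinates, same shape/class as the input.
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "rigid_transform"))
  m <- points_matrix(pts)
  out <- m %*% t(t$rotation) +
    matrix(t$translation, nrow(m), 3L, byrow = TRUE)
  if (is.data.frame(pts)) {
    pts$x <- out[, 1]; pts$y <- out[, 2]; pts$z <- out[, 3]
    return(pts)
  }
  if (is.numeric(pts) && !is.matrix(pts)) return(as.numeric(out))
  out
}
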