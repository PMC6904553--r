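# Image-to-patient registration.
#
# Point-based rigid registration by the classical centroid / cross-
# covariance SVD construction (Arun-style, with determinant correction so
# a reflection can never be returned), plus a small point-to-point rigid
# ICP used to compensate the model-to-model motion introduced when
# fiducials are inserted into the liver.

#' Paired correspondences between image and patient space
#'
#' Pairing is by mark label, never by position: the clinician annotates
#' mark "c" on the CT model and samples mark "c" with the tracked tool.
#'
#' @param image_points labeled points in image (CT) space, mm
#'   (data.frame `label,x,y,z`, see [labeled_points()]).
#' @param patient_points labeled points in patient space, mm.
#' @return an object of class `correspondence_set` with matrices `image`,
#'   `patient` (n x 3, same label order) and `labels`.
#' @export
correspondence_set <- function(image_points, patient_points) {
  stopifnot(is.data.frame(image_points), is.data.frame(patient_points))
  li <- as.character(image_points$label)
  lp <- as.character(patient_points$label)
  if (anyDuplicated(li) || anyDuplicated(lp))
    stop("labels must be unique within each point set")
  shared <- intersect(li, lp)
  if (length(shared) < 3L)
    stop("registration needs at least 3 shared labeled points, got ",
         length(shared))
  structure(list(
    image = points_matrix(image_points[match(shared, li), ]),
    patient = points_matrix(patient_points[match(shared, lp), ]),
    labels = shared), class = "correspondence_set")
}

#' Rigid image-to-patient registration by SVD
#'
#' Computes the least-squares rigid transform mapping the image-space
#' points onto the patient-space points: both sets are demeaned, the 3x3
#' cross-covariance is decomposed by SVD, and the rotation is
#' `V diag(1,1,det(VU')) U'` so the result is always a proper rotation even
#' when the correspondences would favour a reflection.  The fiducial
#' registration error (FRE) reported is the RMS residual over the points
#' used.
#'
#' @param c a [correspondence_set()] with at least 3 non-collinear points.
#' @return an object of class `registration_result`: `t_ip` (a
#'   `rigid_transform`, I -> P), `fre_rms` (mm), `n_markers`, `labels`.
#' @export
rigid_register_svd <- function(c) {
  stopifnot(inherits(c, "correspondence_set"))
  X <- c$image; Y <- c$patient
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  sv <- svd(Xc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate geometry: registration points are (near-)collinear")
  }
  H <- crossprod(Xc, Yc)             # sum over points of x_c y_c^T
  s <- svd(H)
  d <- det(s$v %*% t(s$u))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- my - as.numeric(R %*% mx)
  t_ip <- rigid_transform(R, t, from = "I", to = "P")
  res <- structure(list(t_ip = t_ip, fre_rms = NA_real_,
                        n_markers = length(c$labels), labels = c$labels),
                   class = "registration_result")
  res$fre_rms <- fre(res, c)
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("rigid image-to-patient registration: %d markers, FRE %.4g mm\n",
              x$n_markers, x$fre_rms))
  print(x$t_ip)
  invisible(x)
}

#' Fiducial registration error
#'
#' RMS of `||T p_image - p_patient||` over the correspondences: the
#' residual on the points *used* for the registration (distinct from TRE,
#' which is measured on held-out targets).
#'
#' @param result a `registration_result` or a bare `rigid_transform`
#'   mapping I -> P.
#' @param c a [correspondence_set()].
#' @return RMS residual in mm.
#' @export
fre <- function(result, c) {
  stopifnot(inherits(c, "correspondence_set"))
  t_ip <- if (inherits(result, "registration_result")) result$t_ip else result
  stopifnot(inherits(t_ip, "rigid_transform"))
  pred <- transform_points(t_ip, c$image)
  sqrt(mean(rowSums((pred - c$patient)^2)))
}

#' Rigid iterative closest point registration
#'
#' Point-to-point ICP: alternate nearest-neighbour matching (ties broken
#' by lowest index, for determinism) with the closed-form rigid fit of
#' [rigid_register_svd()] until the mean residual change falls below `tol`
#' or `max_iter` is reached.  The mean residual is non-increasing across
#' iterations.  Optionally a fraction of the worst matches can be trimmed
#' each iteration.
#'
#' ICP is a local method: with a grossly wrong initialization it can stop
#' in a local minimum.  Non-convergence, and convergence to a residual
#' that is large relative to the target cloud's extent, both raise a
#' warning and set the `converged` / `suspect_local_minimum` attributes;
#' the best transform found is still returned.
#'
#' @param source n x 3 matrix (or labeled points) to be moved, mm.
#' @param target m x 3 matrix (or labeled points) held fixed, mm.
#' @param init initial `rigid_transform` (frames copied to the result);
#'   defaults to the identity in the source cloud's frame.
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence threshold on the mean-residual change, mm
#'   (default 1e-4).
#' @param trim fraction in `[0, 0.5)` of worst correspondences discarded
#'   per iteration (default 0, no trimming).
#' @return a `rigid_transform` mapping source to target coordinates, with
#'   attributes `iterations`, `converged`, `residual` (final mean
#'   residual, mm), `residual_trace` and `suspect_local_minimum`.
#' @export
icp_register <- function(source, target, init = rt_identity("I", "I"),
                         max_iter = 100L, tol = 1e-4, trim = 0) {
  S <- points_matrix(source); T_ <- points_matrix(target)
  if (nrow(S) < 10L || nrow(T_) < 10L)
    stop("ICP needs at least 10 points in each cloud")
  stopifnot(inherits(init, "rigid_transform"), trim >= 0, trim < 0.5)
  cur <- init
  t2 <- rowSums(T_^2)
  prev_res <- Inf
  trace <- numeric(0)
  converged <- FALSE
  n_keep <- max(3L, floor(nrow(S) * (1 - trim)))
  for (it in seq_len(max_iter)) {
    Sm <- transform_points(cur, S)
    # nearest neighbour in target for every moved source point
    d2 <- outer(rowSums(Sm^2), t2, "+") - 2 * Sm %*% t(T_)
    nn <- max.col(-d2, ties.method = "first")
    dist <- sqrt(pmax(0, d2[cbind(seq_len(nrow(Sm)), nn)]))
    keep <- seq_len(nrow(Sm))
    if (n_keep < nrow(Sm)) keep <- order(dist)[seq_len(n_keep)]
    res <- mean(dist[keep])
    trace <- c(trace, res)
    if (res < tol || abs(prev_res - res) < tol) { converged <- TRUE; break }
    prev_res <- res
    lbl <- as.character(keep)
    cs <- correspondence_set(labeled_points(lbl, S[keep, , drop = FALSE]),
                             labeled_points(lbl, T_[nn[keep], , drop = FALSE]))
    fit <- rigid_register_svd(cs)
    cur <- rigid_transform(fit$t_ip$rotation, fit$t_ip$translation,
                           from = init$from, to = init$to)
  }
  scale <- max(sqrt(rowSums(sweep(T_, 2, colMeans(T_))^2)))
  suspect <- trace[length(trace)] > 0.05 * scale
  if (!converged)
    warning("ICP did not converge within ", max_iter, " iterations; ",
            "returning best transform found")
  else if (suspect)
    warning("ICP converged to a large residual (", format(trace[length(trace)]),
            " mm); possible local minimum, check the initialization")
  attr(cur, "iterations") <- length(trace)
  attr(cur, "converged") <- converged
  attr(cur, "residual") <- trace[length(trace)]
  attr(cur, "residual_trace") <- trace
  attr(cur, "suspect_local_minimum") <- isTRUE(suspect)
  cur
}
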