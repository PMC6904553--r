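# Synthetic liver phantom and trial generators.
#
# Every generator is a pure function of (configuration, seed): the same
# arguments always reproduce the same output, which is what makes the
# zero-noise world exactly self-consistent and the experiments
# reproducible.  The phantom is a flattened superellipsoid at porcine
# liver scale carrying 15 labeled cauterization marks on its anterior
# surface; deformation, annotation error, tool-sampling noise and camera
# trajectories are layered on top.

MARK_LABELS <- letters[1:15]

#' Phantom configuration
#'
#' The liver surrogate is the surface `|x/a|^p + |y/b|^p + |z/c|^p = 1`
#' with half-axes `half_axes` (mm) and exponent `p = 2.5` (boxier than an
#' ellipsoid, like a flattened liver lobe).  The default half-axes
#' 110 x 75 x 45 mm enclose about 1.88 litres, inside the porcine liver
#' volume range of roughly 1.6-2.8 litres.
#'
#' @param half_axes length-3 numeric, surface half-axes in mm.
#' @param exponent superellipsoid exponent (>= 1).
#' @param n_surface_points number of surface points sampled.
#' @param n_marks number of cauterization marks (default 15).
#' @param min_mark_spacing minimum pairwise mark distance in mm.
#' @param seed integer seed.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(half_axes = c(110, 75, 45), exponent = 2.5,
                           n_surface_points = 2000L, n_marks = 15L,
                           min_mark_spacing = 25, seed = 1L) {
  stopifnot(length(half_axes) == 3L, all(half_axes > 0), exponent >= 1,
            n_marks >= 1L, n_marks <= n_surface_points,
            min_mark_spacing >= 0)
  structure(list(half_axes = half_axes, exponent = exponent,
                 n_surface_points = as.integer(n_surface_points),
                 n_marks = as.integer(n_marks),
                 min_mark_spacing = min_mark_spacing,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Analytic volume of the phantom surface
#'
#' Closed form for the solid superellipsoid,
#' `8 a b c Gamma(1 + 1/p)^3 / Gamma(1 + 3/p)`.
#'
#' @param cfg a [phantom_config()] (or a `phantom`).
#' @return enclosed volume in cm^3.
#' @export
phantom_volume <- function(cfg) {
  if (inherits(cfg, "phantom")) cfg <- cfg$config
  p <- cfg$exponent
  v_mm3 <- 8 * prod(cfg$half_axes) * gamma(1 + 1 / p)^3 / gamma(1 + 3 / p)
  v_mm3 / 1000
}

# radial distance to the superellipsoid surface along unit direction u
superellipsoid_radius <- function(u, half_axes, p) {
  (rowSums(abs(sweep(u, 2, half_axes, "/"))^p))^(-1 / p)
}

#' Generate a synthetic liver phantom
#'
#' Samples a surface point cloud and places `n_marks` cauterization marks
#' (labels `a`..`o`) on the anterior surface (outward normal with a
#' positive z component) with a minimum pairwise spacing, by rejection
#' sampling with bounded retries.  Fiducial ground-truth positions are
#' coincident with the marks, emulating fiducials inserted exactly at the
#' cauterization sites.  All coordinates are image-frame (CT) mm.
#'
#' @param cfg a [phantom_config()].
#' @return an object of class `phantom`: `surface` (n x 3 matrix), `marks`
#'   and `fiducials` (labeled point data.frames), `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  withr::with_seed(cfg$seed, {
    dirs <- matrix(stats::rnorm(3 * cfg$n_surface_points), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    r <- superellipsoid_radius(dirs, cfg$half_axes, cfg$exponent)
    surface <- dirs * r
    marks <- matrix(NA_real_, cfg$n_marks, 3)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 400L * cfg$n_marks
    while (placed < cfg$n_marks) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not place ", cfg$n_marks, " marks with spacing >= ",
             cfg$min_mark_spacing, " mm after ", max_attempts,
             " attempts; reduce min_mark_spacing or enlarge the phantom")
      }
      d <- stats::rnorm(3)
      d[3] <- abs(d[3]) + 0.15 * sqrt(sum(d[1:2]^2))  # anterior bias
      d <- d / sqrt(sum(d^2))
      cand <- d * superellipsoid_radius(matrix(d, 1), cfg$half_axes,
                                        cfg$exponent)
      if (placed > 0L) {
        dmin <- min(sqrt(rowSums(sweep(marks[seq_len(placed), , drop = FALSE],
                                       2, cand)^2)))
        if (dmin < cfg$min_mark_spacing) next
      }
      placed <- placed + 1L
      marks[placed, ] <- cand
    }
  })
  lab <- MARK_LABELS[seq_len(cfg$n_marks)]
  structure(list(surface = surface,
                 marks = labeled_points(lab, marks),
                 fiducials = labeled_points(lab, marks),
                 config = cfg),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "synthetic liver phantom: %d surface points, %d marks, volume %.0f cm^3\n",
    nrow(x$surface), nrow(x$marks), phantom_volume(x)))
  invisible(x)
}

#' Pneumoperitoneum deformation model
#'
#' A smooth nonrigid pre/intra-operative shape difference: a small global
#' affine component (anisotropic scale and shear) plus a Gaussian
#' radial-basis displacement field, rescaled so the mean displacement of
#' the marks equals `magnitude` mm.  `magnitude = 0` is exactly the
#' identity.  Alternatively a constant `translation` field can be
#' requested (useful for analytic checks).
#'
#' The default magnitude of 25 mm is a synthetic default chosen so that
#' the preoperative/intraoperative error gap is comfortably detectable;
#' it is not an estimate of porcine tissue mechanics.
#'
#' @param magnitude target mean mark displacement, mm (>= 0).
#' @param n_control number of radial-basis control points.
#' @param kernel_width Gaussian kernel width, mm.
#' @param affine_scale magnitude of the random affine (scale/shear) part.
#' @param translation optional 3-vector: use a constant displacement field
#'   instead (overrides the smooth field).
#' @param seed integer seed for the field's random control points.
#' @return a list of class `deformation_model`.
#' @export
deformation_model <- function(magnitude = 25, n_control = 8L,
                              kernel_width = 80, affine_scale = 0.05,
                              translation = NULL, seed = 1L) {
  stopifnot(magnitude >= 0, n_control >= 1L, kernel_width > 0)
  structure(list(magnitude = magnitude, n_control = as.integer(n_control),
                 kernel_width = kernel_width, affine_scale = affine_scale,
                 translation = translation, seed = as.integer(seed)),
            class = "deformation_model")
}

# displacement field evaluated at an n x 3 matrix of points
deformation_field <- function(pts, centres, amplitudes, affine, centroid,
                              width) {
  disp <- sweep(pts, 2, centroid) %*% t(affine)
  for (j in seq_len(nrow(centres))) {
    w <- exp(-rowSums(sweep(pts, 2, centres[j, ])^2) / (2 * width^2))
    disp <- disp + outer(w, amplitudes[j, ])
  }
  disp
}

#' Apply a deformation model to a phantom
#'
#' Displaces the surface, marks and fiducials by the smooth field.  The
#' field is normalized so that the mean displacement of the marks equals
#' the model's `magnitude` (so the configured magnitude is realized
#' exactly at the marks, and approximately over the whole surface).
#'
#' @param phantom a [generate_phantom()] result.
#' @param d a [deformation_model()].
#' @return a deformed `phantom` (the preoperative-shape surrogate), with
#'   attribute `mean_mark_displacement_mm`.
#' @export
apply_deformation <- function(phantom, d) {
  stopifnot(inherits(phantom, "phantom"), inherits(d, "deformation_model"))
  out <- phantom
  if (!is.null(d$translation)) {
    tr <- matrix(as.numeric(d$translation), 1)
    out$surface <- sweep(phantom$surface, 2, -tr[1, ])
    out$marks[, c("x", "y", "z")] <-
      sweep(points_matrix(phantom$marks), 2, -tr[1, ])
    out$fiducials[, c("x", "y", "z")] <-
      sweep(points_matrix(phantom$fiducials), 2, -tr[1, ])
    attr(out, "mean_mark_displacement_mm") <- sqrt(sum(tr^2))
    return(out)
  }
  if (d$magnitude == 0) {
    attr(out, "mean_mark_displacement_mm") <- 0
    return(out)
  }
  box <- 1.2 * phantom$config$half_axes
  withr::with_seed(d$seed, {
    centres <- cbind(stats::runif(d$n_control, -box[1], box[1]),
                     stats::runif(d$n_control, -box[2], box[2]),
                     stats::runif(d$n_control, -box[3], box[3]))
    amplitudes <- matrix(stats::rnorm(3 * d$n_control), ncol = 3)
    affine <- matrix(stats::rnorm(9, sd = d$affine_scale), 3, 3)
  })
  centroid <- colMeans(phantom$surface)
  mk <- points_matrix(phantom$marks)
  raw_marks <- deformation_field(mk, centres, amplitudes, affine, centroid,
                                 d$kernel_width)
  scale <- d$magnitude / mean(sqrt(rowSums(raw_marks^2)))
  disp_surface <- scale * deformation_field(phantom$surface, centres,
                                            amplitudes, affine, centroid,
                                            d$kernel_width)
  out$surface <- phantom$surface + disp_surface
  out$marks[, c("x", "y", "z")] <- mk + scale * raw_marks
  out$fiducials[, c("x", "y", "z")] <-
    points_matrix(phantom$fiducials) +
    scale * deformation_field(points_matrix(phantom$fiducials), centres,
                              amplitudes, affine, centroid, d$kernel_width)
  attr(out, "mean_mark_displacement_mm") <-
    mean(sqrt(rowSums((scale * raw_marks)^2)))
  out
}

#' Clinician annotation model
#'
#' A clinician annotating mark positions on the 3D model commits a
#' systematic bias plus isotropic Gaussian error.  Preoperative models are
#' harder to read (the insufflated shape differs from the screen), so the
#' preoperative sigma is the intraoperative one times `preop_ratio`.
#'
#' With zero bias the expected localization error (mean 3D error norm) is
#' `sigma * 2 * sqrt(2/pi)` (the Maxwell mean), so a desired mean FLE of
#' 16.8 mm is targeted by `sigma_intraop ~ 10.5` mm — the package default.
#'
#' @param id user identifier.
#' @param bias systematic 3-vector offset, mm.
#' @param sigma_intraop isotropic annotation sigma on intraoperative
#'   models, mm.
#' @param preop_ratio multiplier for the preoperative sigma (default 1.45,
#'   reflecting the observed extra inter-clinician variability on
#'   preoperative images).
#' @return a list of class `user_model`.
#' @export
user_model <- function(id, bias = c(0, 0, 0), sigma_intraop = 10.5,
                       preop_ratio = 1.45) {
  stopifnot(sigma_intraop >= 0, preop_ratio >= 0, length(bias) == 3L)
  structure(list(id = as.character(id), bias = as.numeric(bias),
                 sigma_intraop = sigma_intraop,
                 sigma_preop = sigma_intraop * preop_ratio),
            class = "user_model")
}

#' Simulate clinician annotations of the marks
#'
#' @param phantom the model being annotated (intraoperative phantom, or
#'   the deformed preoperative phantom).
#' @param user a [user_model()].
#' @param variant `"intraop"` or `"preop"` — selects the noise sigma; pass
#'   the matching phantom.
#' @param seed integer seed.
#' @return labeled points (image frame, mm) with a `user` column.
#' @export
simulate_annotations <- function(phantom, user, variant = c("intraop", "preop"),
                                 seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), inherits(user, "user_model"))
  variant <- match.arg(variant)
  sigma <- if (variant == "intraop") user$sigma_intraop else user$sigma_preop
  mk <- points_matrix(phantom$marks)
  withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(length(mk), sd = sigma), ncol = 3)
  })
  if (sigma == 0) noise[] <- 0
  out <- labeled_points(phantom$marks$label,
                        sweep(mk + noise, 2, -user$bias))
  out$user <- user$id
  out
}

#' Tracked-tool sampling model
#'
#' The laparoscopic instrument tip is optically tracked while resting on a
#' mark; the liver moves with breathing (a sinusoid along a fixed
#' cranio-caudal direction) and each tracker sample carries isotropic
#' jitter.  Positions are averaged over the acquisition, which samples
#' `n_samples` instants equally spaced over `duration` seconds (default
#' two full breathing periods, so the sinusoid averages out exactly).
#'
#' @param breathing_amplitude_mm peak breathing displacement (default 5).
#' @param breathing_period_s breathing period in seconds (default 4).
#' @param jitter_sigma_mm per-sample isotropic tracker/hand jitter
#'   (default 2).
#' @param n_samples samples averaged per mark (default 50).
#' @param duration_s acquisition span per mark (default 8 = two periods).
#' @return a list of class `tracking_model`.
#' @export
tracking_model <- function(breathing_amplitude_mm = 5, breathing_period_s = 4,
                           jitter_sigma_mm = 2, n_samples = 50L,
                           duration_s = 8) {
  stopifnot(breathing_amplitude_mm >= 0, breathing_period_s > 0,
            jitter_sigma_mm >= 0, n_samples >= 1L, duration_s > 0)
  structure(list(breathing_amplitude_mm = breathing_amplitude_mm,
                 breathing_period_s = breathing_period_s,
                 jitter_sigma_mm = jitter_sigma_mm,
                 n_samples = as.integer(n_samples), duration_s = duration_s),
            class = "tracking_model")
}

#' Simulate tool sampling of the marks in patient space
#'
#' Applies a hidden true image-to-patient rigid transform to the phantom
#' marks, then corrupts each mark with breathing motion and per-sample
#' jitter and averages over the acquisition.  With all noise at zero the
#' hidden transform is exactly recoverable by [rigid_register_svd()].
#'
#' @param phantom a `phantom`.
#' @param t a [tracking_model()].
#' @param seed integer seed (also determines the hidden transform unless
#'   `t_ip` is supplied).
#' @param t_ip optional `rigid_transform` I -> P to use as the hidden
#'   truth; by default a random one is drawn from `seed`.
#' @return list: `points` (labeled patient-frame mark positions, mm),
#'   `t_ip` (the true image-to-patient transform used).
#' @export
simulate_tool_sampling <- function(phantom, t = tracking_model(), seed = 1L,
                                   t_ip = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(t, "tracking_model"))
  mk <- points_matrix(phantom$marks)
  n <- nrow(mk)
  withr::with_seed(seed, {
    if (is.null(t_ip)) {
      t_ip <- rigid_transform(random_rotation(),
                              stats::runif(3, -150, 150), "I", "P")
    }
    breath_dir <- random_unit_vector()
    phases <- stats::runif(n, 0, 2 * pi)
    true_p <- transform_points(t_ip, mk)
    times <- (seq_len(t$n_samples) - 1) / t$n_samples * t$duration_s
    sampled <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      breath <- t$breathing_amplitude_mm *
        sin(2 * pi * times / t$breathing_period_s + phases[i])
      jit <- matrix(stats::rnorm(3 * t$n_samples, sd = t$jitter_sigma_mm),
                    ncol = 3)
      if (t$jitter_sigma_mm == 0) jit[] <- 0
      samples <- matrix(true_p[i, ], t$n_samples, 3, byrow = TRUE) +
        outer(breath, breath_dir) + jit
      sampled[i, ] <- colMeans(samples)
    }
  })
  list(points = labeled_points(phantom$marks$label, sampled), t_ip = t_ip)
}

#' Simulate liver displacement caused by fiducial insertion
#'
#' Puncturing the parenchyma to insert fiducials moves the (mobile) liver:
#' the model acquired after insertion differs from the one before by a
#' small rigid motion plus a smooth residual.  This generator produces the
#' pair of surfaces that model-to-model registration ([icp_register()])
#' must align to compensate.
#'
#' @param phantom a `phantom`.
#' @param displacement overall displacement magnitude, mm (>= 0).
#' @param seed integer seed.
#' @param smooth_fraction fraction of the displacement realized as a
#'   smooth nonrigid residual (default 0.4; 0 gives a purely rigid
#'   motion).
#' @param rigid_angle_deg optional explicit rigid rotation angle; default
#'   scales with the displacement (0.5 deg per mm of rigid part).
#' @param rigid_translation optional explicit rigid translation 3-vector.
#' @return list: `original` (the input phantom), `displaced` (phantom
#'   after insertion, including displaced fiducials), `rigid` (the true
#'   rigid component, a `rigid_transform` I -> I), `smooth_magnitude_mm`.
#' @export
simulate_fiducial_insertion <- function(phantom, displacement, seed = 1L,
                                        smooth_fraction = 0.4,
                                        rigid_angle_deg = NULL,
                                        rigid_translation = NULL) {
  stopifnot(inherits(phantom, "phantom"), displacement >= 0,
            smooth_fraction >= 0, smooth_fraction <= 1)
  rigid_mag <- displacement * (1 - smooth_fraction)
  smooth_mag <- displacement * smooth_fraction
  withr::with_seed(seed, {
    if (is.null(rigid_translation)) {
      rigid_translation <- random_unit_vector() * rigid_mag
    }
    if (is.null(rigid_angle_deg)) rigid_angle_deg <- 0.5 * rigid_mag
    axis <- random_unit_vector()
  })
  rigid <- rigid_transform(rotation_about_axis(axis, rigid_angle_deg),
                           rigid_translation, "I", "I")
  displaced <- phantom
  displaced$surface <- transform_points(rigid, phantom$surface)
  displaced$marks[, c("x", "y", "z")] <-
    transform_points(rigid, points_matrix(phantom$marks))
  displaced$fiducials[, c("x", "y", "z")] <-
    transform_points(rigid, points_matrix(phantom$fiducials))
  if (smooth_mag > 0) {
    d <- deformation_model(magnitude = smooth_mag, n_control = 5L,
                           kernel_width = 90, affine_scale = 0.02,
                           seed = derive_seed(seed, 7L))
    displaced <- apply_deformation(displaced, d)
  }
  list(original = phantom, displaced = displaced, rigid = rigid,
       smooth_magnitude_mm = smooth_mag)
}

#' Generate a laparoscope camera trajectory over the phantom
#'
#' Camera poses orbit above the phantom's anterior surface looking at the
#' mark centroid; each frame's tracked marker-body pose `T_M^O` is derived
#' so that the *true* AR chain (true hand-eye, true patient pose, true
#' registration) reproduces the camera view exactly.  Per frame, all marks
#' are projected through that true chain; the default geometry keeps all
#' 15 marks visible in every frame (poses failing the visibility check are
#' re-drawn, with bounded retries).  Optional pixel noise models the
#' manual annotation of cauterization-mark centroids on the video.
#'
#' @param phantom a `phantom`.
#' @param n_frames number of frames (>= 1).
#' @param intrinsics `camera_intrinsics`.
#' @param world list with the true transforms: `t_cm` (C -> M), `t_po`
#'   (P -> O) and `t_ip` (I -> P).
#' @param seed integer seed.
#' @param centroid_noise_px isotropic pixel sigma added to the observed
#'   centroids (default 0).
#' @param distance_mm nominal camera distance from the mark centroid
#'   (default 350).
#' @param max_polar_deg maximum angle of the viewpoint from the anterior
#'   axis (default 35).
#' @return list of class `camera_trajectory`; each frame is a list with
#'   `t_mo` (the tracked pose, M -> O) and `centroids` (data.frame
#'   `label,u,v`).
#' @export
generate_camera_trajectory <- function(phantom, n_frames, intrinsics, world,
                                       seed = 1L, centroid_noise_px = 0,
                                       distance_mm = 350, max_polar_deg = 35) {
  stopifnot(inherits(phantom, "phantom"), n_frames >= 1,
            inherits(intrinsics, "camera_intrinsics"),
            all(c("t_cm", "t_po", "t_ip") %in% names(world)))
  target <- colMeans(points_matrix(phantom$marks))
  mk <- phantom$marks
  # rigid O -> M implied by a desired camera pose: from the chain,
  # (T_M^O)^-1 = T_C^M . T_I^C_rigid . (T_I^P)^-1 . (T_P^O)^-1
  k_po_ip <- compose_transform(world$t_po, world$t_ip)   # I -> O
  frames <- vector("list", n_frames)
  withr::with_seed(seed, {
    for (f in seq_len(n_frames)) {
      ok <- FALSE
      for (try in 1:100) {
        polar <- stats::runif(1, 0, max_polar_deg) * pi / 180
        azim <- stats::runif(1, 0, 2 * pi)
        dir <- c(sin(polar) * cos(azim), sin(polar) * sin(azim), cos(polar))
        eye <- target + dir * distance_mm * stats::runif(1, 0.9, 1.1)
        zax <- (target - eye); zax <- zax / sqrt(sum(zax^2))
        ref <- if (abs(zax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        xax <- ref - sum(ref * zax) * zax; xax <- xax / sqrt(sum(xax^2))
        yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
                 zax[3] * xax[1] - zax[1] * xax[3],
                 zax[1] * xax[2] - zax[2] * xax[1])
        r_ic <- rbind(xax, yax, zax)
        t_ic <- rigid_transform(r_ic, as.numeric(-r_ic %*% eye), "I", "C")
        t_mo <- invert_transform(compose_transform(
          world$t_cm, compose_transform(t_ic, invert_transform(k_po_ip))))
        chain <- build_ar_chain(intrinsics, world$t_cm, t_mo, world$t_po,
                                world$t_ip)
        proj <- project_ar(chain, mk)
        if (all(proj$visible)) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("could not find a camera pose with all marks visible after 100 ",
             "retries; widen the field of view (larger image or shorter ",
             "focal length) or increase distance_mm")
      }
      u <- proj$u; v <- proj$v
      if (centroid_noise_px > 0) {
        u <- u + stats::rnorm(length(u), sd = centroid_noise_px)
        v <- v + stats::rnorm(length(v), sd = centroid_noise_px)
      }
      frames[[f]] <- list(t_mo = t_mo,
                          centroids = data.frame(label = proj$label,
                                                 u = u, v = v))
    }
  })
  structure(frames, class = "camera_trajectory")
}

#' Generate synthetic hand-eye calibration data
#'
#' Draws random generic tracked poses of the laparoscope marker body and
#' derives the plate-in-camera observation consistent with a known true
#' hand-eye transform, `T_C^O = (T_O^M)^-1 . T_C^M`, optionally corrupted
#' by small pose noise on the observation.
#'
#' @param true_t_cm the true hand-eye `rigid_transform` (C -> M).
#' @param n_poses number of pose pairs (>= 3).
#' @param noise_rot_deg,noise_trans_mm observation noise magnitudes
#'   (default 0: exact closed loop).
#' @param seed integer seed.
#' @param degenerate if `TRUE`, all tracked rotations are identical
#'   (deliberately degenerate motion, for testing the solver's guard).
#' @return list of [pose_pair()] objects.
#' @export
generate_handeye_dataset <- function(true_t_cm, n_poses, noise_rot_deg = 0,
                                     noise_trans_mm = 0, seed = 1L,
                                     degenerate = FALSE) {
  stopifnot(inherits(true_t_cm, "rigid_transform"), n_poses >= 1)
  if (!identical(c(true_t_cm$from, true_t_cm$to), c("C", "M")))
    stop("true_t_cm must map C -> M")
  withr::with_seed(seed, {
    fixed_rot <- random_rotation()
    pairs <- lapply(seq_len(n_poses), function(i) {
      rot <- if (degenerate) fixed_rot else random_rotation()
      t_om <- rigid_transform(rot, stats::runif(3, -300, 300), "O", "M")
      t_co <- compose_transform(invert_transform(t_om), true_t_cm)
      if (noise_rot_deg > 0 || noise_trans_mm > 0) {
        dr <- rotation_about_axis(stats::rnorm(3),
                                  stats::rnorm(1, sd = noise_rot_deg))
        dt <- stats::rnorm(3, sd = noise_trans_mm)
        t_co <- rigid_transform(dr %*% t_co$rotation,
                                t_co$translation + dt, "C", "O")
      }
      pose_pair(t_om, t_co)
    })
  })
  pairs
}

#' Default laparoscope intrinsics for simulations
#'
#' A full-HD laparoscopic camera surrogate: 1920 x 1080 pixels, focal
#' length 1000 px, centred principal point.
#'
#' @return a `camera_intrinsics` object.
#' @export
default_intrinsics <- function() {
  camera_intrinsics(fx = 1000, fy = 1000, cx = 960, cy = 540,
                    width = 1920, height = 1080)
}

#' Generate one complete synthetic trial
#'
#' Assembles everything one animal trial contributes: the intraoperative
#' phantom, its deformed preoperative counterpart, annotations of the
#' marks by every user on both models, tool-sampled patient-frame mark
#' positions, fiducial ground truth, camera frames with observed 2D
#' centroids, the intrinsics and the true transforms.
#'
#' @param trial_id identifier stored in the results.
#' @param users list of [user_model()] objects.
#' @param phantom_cfg a [phantom_config()] (its seed is re-derived from
#'   `seed` so distinct trials get distinct phantoms).
#' @param deformation a [deformation_model()].
#' @param tracking a [tracking_model()].
#' @param intrinsics `camera_intrinsics`.
#' @param n_frames frames per trial (default 100).
#' @param centroid_noise_px 2D centroid annotation noise, pixels.
#' @param seed integer master seed for the trial.
#' @return an object of class `trial_data`.
#' @export
generate_trial <- function(trial_id = "trial1",
                           users = default_users(),
                           phantom_cfg = phantom_config(),
                           deformation = deformation_model(),
                           tracking = tracking_model(),
                           intrinsics = default_intrinsics(),
                           n_frames = 100L,
                           centroid_noise_px = 2,
                           seed = 1L) {
  stopifnot(is.list(users),
            all(vapply(users, inherits, logical(1), "user_model")))
  phantom_cfg$seed <- derive_seed(seed, 1L)
  phantom <- generate_phantom(phantom_cfg)
  deformation$seed <- derive_seed(seed, 2L)
  preop <- apply_deformation(phantom, deformation)
  annotations <- do.call(rbind, unlist(lapply(seq_along(users), function(ui) {
    lapply(c("intraop", "preop"), function(variant) {
      ph <- if (variant == "intraop") phantom else preop
      a <- simulate_annotations(ph, users[[ui]], variant,
                                seed = derive_seed(seed, 10L + ui,
                                                   match(variant,
                                                         c("intraop", "preop"))))
      a$variant <- variant
      a
    })
  }), recursive = FALSE))
  tool <- simulate_tool_sampling(phantom, tracking,
                                 seed = derive_seed(seed, 3L))
  withr::with_seed(derive_seed(seed, 4L), {
    t_po <- rigid_transform(random_rotation(), stats::runif(3, -200, 200),
                            "P", "O")
    t_cm <- rigid_transform(random_rotation(max_angle_deg = 60),
                            stats::runif(3, -100, 100), "C", "M")
  })
  world <- list(t_cm = t_cm, t_po = t_po, t_ip = tool$t_ip)
  frames <- generate_camera_trajectory(phantom, n_frames, intrinsics, world,
                                       seed = derive_seed(seed, 5L),
                                       centroid_noise_px = centroid_noise_px)
  structure(list(trial_id = trial_id, phantom = phantom, preop = preop,
                 users = users, annotations = annotations,
                 fiducials = phantom$fiducials, tool_points = tool$points,
                 frames = frames, intrinsics = intrinsics,
                 t_cm = t_cm, t_po = t_po, t_ip_true = tool$t_ip,
                 seed = as.integer(seed)),
            class = "trial_data")
}

#' Default panel of five clinicians
#'
#' @param n_users number of users (default 5).
#' @param sigma_intraop intraoperative annotation sigma, mm.
#' @param preop_ratio preoperative/intraoperative sigma ratio.
#' @return list of [user_model()] objects, ids `"A"`, `"B"`, ...
#' @export
default_users <- function(n_users = 5L, sigma_intraop = 10.5,
                          preop_ratio = 1.45) {
  lapply(seq_len(n_users), function(i)
    user_model(LETTERS[i], sigma_intraop = sigma_intraop,
               preop_ratio = preop_ratio))
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf(
    "synthetic trial '%s': %d users, %d frames, %d marks, seed %d\n",
    x$trial_id, length(x$users), length(x$frames), nrow(x$phantom$marks),
    x$seed))
  invisible(x)
}
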