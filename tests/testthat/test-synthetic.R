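test_that("phantom generation is deterministic and respects mark spacing", {
  cfg <- phantom_config(seed = 701)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$surface, p2$surface)
  expect_identical(p1$marks, p2$marks)
  d <- as.matrix(dist(points_matrix(p1$marks)))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_mark_spacing)
  expect_equal(p1$marks$label, letters[1:15])
  # fiducial truth coincides with the marks before insertion
  expect_equal(points_matrix(p1$fiducials), points_matrix(p1$marks))
  # every point and mark lies on the superellipsoid surface
  on_surf <- rowSums(abs(sweep(p1$surface, 2, cfg$half_axes, "/"))^cfg$exponent)
  expect_lt(max(abs(on_surf - 1)), 1e-9)
})

test_that("default phantom volume is porcine-liver sized (Monte-Carlo oracle)", {
  cfg <- phantom_config()
  v_analytic <- phantom_volume(cfg)
  set.seed(702)
  n <- 2e5
  box <- cfg$half_axes
  pts <- cbind(runif(n, -box[1], box[1]), runif(n, -box[2], box[2]),
               runif(n, -box[3], box[3]))
  inside <- rowSums(abs(sweep(pts, 2, box, "/"))^cfg$exponent) <= 1
  v_mc <- mean(inside) * prod(2 * box) / 1000
  expect_equal(v_analytic, v_mc, tolerance = 0.02)
  expect_gt(v_analytic, 1593)
  expect_lt(v_analytic, 2761)
})

test_that("infeasible mark spacing fails with a clear error", {
  cfg <- phantom_config(min_mark_spacing = 500, seed = 703)
  expect_error(generate_phantom(cfg), "could not place")
})

test_that("deformation honours magnitude, translation and identity cases", {
  ph <- generate_phantom(phantom_config(seed = 704))
  same <- apply_deformation(ph, deformation_model(magnitude = 0))
  expect_identical(same$surface, ph$surface)
  trans <- apply_deformation(ph, deformation_model(translation = c(10, 0, 0)))
  expect_equal(points_matrix(trans$marks) - points_matrix(ph$marks),
               matrix(rep(c(10, 0, 0), each = 15), 15, 3))
  def <- apply_deformation(ph, deformation_model(magnitude = 25, seed = 705))
  disp <- sqrt(rowSums((points_matrix(def$marks) -
                          points_matrix(ph$marks))^2))
  expect_equal(mean(disp), 25, tolerance = 0.2 * 25)
  # the field is smooth: nearby surface points move almost identically
  i <- which.min(rowSums((ph$surface - matrix(ph$surface[1, ], nrow(ph$surface),
                                              3, byrow = TRUE))^2)[-1]) + 1
  d1 <- def$surface[1, ] - ph$surface[1, ]
  d2 <- def$surface[i, ] - ph$surface[i, ]
  gap <- sqrt(sum((ph$surface[1, ] - ph$surface[i, ])^2))
  expect_lt(sqrt(sum((d1 - d2)^2)), 0.5 * gap + 1)
})

test_that("annotation noise has the Maxwell mean and bias the 3-4-5 norm", {
  ph <- generate_phantom(phantom_config(seed = 706))
  exact <- simulate_annotations(ph, user_model("A", sigma_intraop = 0),
                                "intraop", seed = 1)
  expect_equal(points_matrix(exact), points_matrix(ph$marks))
  biased <- simulate_annotations(
    ph, user_model("A", bias = c(3, 4, 0), sigma_intraop = 0), "intraop",
    seed = 1)
  expect_equal(compute_fle(biased, ph$marks)$fle_mm, rep(5, 15))
  # mean FLE over 10^4 draws ~ sigma * 2 * sqrt(2/pi)
  sigma <- 10.5
  u <- user_model("A", sigma_intraop = sigma)
  fles <- unlist(lapply(1:667, function(s) {
    compute_fle(simulate_annotations(ph, u, "intraop", seed = 7000 + s),
                ph$marks)$fle_mm
  }))
  expect_gt(length(fles), 1e4 - 15)
  expect_equal(mean(fles), sigma * 2 * sqrt(2 / pi), tolerance = 0.03)
  # preoperative noise is scaled by the configured ratio
  up <- user_model("A", sigma_intraop = 10, preop_ratio = 1.45)
  expect_equal(up$sigma_preop, 14.5)
})

test_that("tool sampling closes the loop and averaging shrinks jitter", {
  ph <- generate_phantom(phantom_config(seed = 707))
  clean <- simulate_tool_sampling(ph, tracking_model(0, 4, 0, 10), seed = 708)
  reg <- rigid_register_svd(correspondence_set(ph$marks, clean$points))
  expect_lt(geodesic_angle(reg$t_ip$rotation, clean$t_ip$rotation), 1e-9)
  expect_lt(trans_err(reg$t_ip, clean$t_ip), 1e-9)
  # breathing over whole periods averages out exactly
  breath <- simulate_tool_sampling(ph, tracking_model(5, 4, 0, 40, 8),
                                   seed = 709)
  truth <- transform_points(breath$t_ip, points_matrix(ph$marks))
  expect_lt(max(abs(points_matrix(breath$points) - truth)), 1e-9)
  # jitter of 2 mm averaged over 50 samples leaves ~2/sqrt(50) per axis
  errs <- unlist(lapply(1:40, function(s) {
    noisy <- simulate_tool_sampling(ph, tracking_model(0, 4, 2, 50),
                                    seed = 7100 + s)
    tr <- transform_points(noisy$t_ip, points_matrix(ph$marks))
    sqrt(rowSums((points_matrix(noisy$points) - tr)^2))
  }))
  expect_equal(mean(errs), (2 / sqrt(50)) * 2 * sqrt(2 / pi),
               tolerance = 0.05)
})

test_that("fiducial insertion produces an ICP-recoverable displacement", {
  ph <- generate_phantom(phantom_config(n_surface_points = 400L, seed = 710))
  still <- simulate_fiducial_insertion(ph, 0, seed = 711)
  expect_equal(still$displaced$surface, ph$surface, tolerance = 1e-12)
  fit0 <- icp_register(still$displaced$surface, ph$surface)
  expect_lt(max(abs(as.matrix(fit0) - diag(4))), 1e-9)
  # rigid-only displacement: 4 degrees, 6 mm
  rig <- simulate_fiducial_insertion(ph, 6, seed = 712, smooth_fraction = 0,
                                     rigid_angle_deg = 4)
  fit <- icp_register(rig$displaced$surface, ph$surface)
  undo <- compose_transform(fit, rig$rigid)
  probe <- transform_points(undo, ph$surface) - ph$surface
  expect_lt(max(sqrt(rowSums(probe^2))), 0.1)
  # smooth component leaves a bounded residual
  smooth <- simulate_fiducial_insertion(ph, 3, seed = 713,
                                        smooth_fraction = 1)
  fits <- icp_register(smooth$displaced$surface, ph$surface)
  expect_gt(attr(fits, "residual"), 0)
  expect_lt(attr(fits, "residual"), 3)
})

test_that("camera trajectories are deterministic and keep all marks visible", {
  ph <- generate_phantom(phantom_config(seed = 714))
  withr::with_seed(715, {
    world <- list(t_cm = random_rt("C", "M", 80),
                  t_po = random_rt("P", "O", 150),
                  t_ip = random_rt("I", "P", 150))
  })
  k <- default_intrinsics()
  tr1 <- generate_camera_trajectory(ph, 6, k, world, seed = 716)
  tr2 <- generate_camera_trajectory(ph, 6, k, world, seed = 716)
  expect_equal(tr1, tr2)
  expect_length(tr1, 6)
  for (f in tr1) {
    expect_setequal(f$centroids$label, letters[1:15])
    expect_true(all(f$centroids$u >= 0 & f$centroids$u < k$width))
    expect_true(all(f$centroids$v >= 0 & f$centroids$v < k$height))
  }
  # noiseless centroids agree with the true chain (closed loop)
  fr <- tr1[[1]]
  chain <- build_ar_chain(k, world$t_cm, fr$t_mo, world$t_po, world$t_ip)
  tre <- compute_tre_frame(chain, ph$marks, fr$centroids)
  expect_lt(max(tre$tre_mm), 1e-9)
})

test_that("centroid pixel noise sets the expected TRE floor", {
  ph <- generate_phantom(phantom_config(seed = 717))
  withr::with_seed(718, {
    world <- list(t_cm = random_rt("C", "M", 80),
                  t_po = random_rt("P", "O", 150),
                  t_ip = random_rt("I", "P", 150))
  })
  k <- default_intrinsics()
  noise_px <- 2
  tr <- generate_camera_trajectory(ph, 25, k, world, seed = 719,
                                   centroid_noise_px = noise_px)
  tres <- depths <- c()
  for (fr in tr) {
    chain <- build_ar_chain(k, world$t_cm, fr$t_mo, world$t_po, world$t_ip)
    res <- compute_tre_frame(chain, ph$marks, fr$centroids)
    prj <- project_ar(chain, ph$marks)
    tres <- c(tres, res$tre_mm)
    depths <- c(depths, prj$depth)
  }
  # 2D Gaussian pixel error of sigma px at depth z: mean TRE
  # = z * sigma/f * sqrt(pi/2)
  expected <- mean(depths) * (noise_px / k$fx) * sqrt(pi / 2)
  expect_equal(mean(tres), expected, tolerance = 0.1)
})

test_that("hand-eye datasets close the loop and honor the degenerate flag", {
  t_cm <- rigid_transform(rotation_about_axis(c(2, -1, 1), 35),
                          c(60, 30, -40), "C", "M")
  pairs <- generate_handeye_dataset(t_cm, 10, seed = 720)
  for (p in pairs) {
    closed <- compose_transform(p$tracker_to_marker, p$plate_to_camera)
    expect_lt(max(abs(as.matrix(closed) - as.matrix(t_cm))), 1e-9)
  }
  degen <- generate_handeye_dataset(t_cm, 5, seed = 721, degenerate = TRUE)
  rots <- vapply(degen, function(p) p$tracker_to_marker$rotation,
                 matrix(0, 3, 3))
  expect_lt(max(abs(rots[, , 1] - rots[, , 5])), 1e-12)
})
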