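make_cs <- function(image, patient, labels = NULL) {
  if (is.null(labels)) labels <- letters[seq_len(nrow(image))]
  correspondence_set(labeled_points(labels, image),
                     labeled_points(labels, patient))
}

test_that("identical point sets register to the identity with zero FRE", {
  set.seed(501)
  pts <- matrix(rnorm(18, sd = 60), 6, 3)
  reg <- rigid_register_svd(make_cs(pts, pts))
  expect_lt(geodesic_angle(reg$t_ip$rotation, diag(3)), 1e-9)
  expect_lt(sqrt(sum(reg$t_ip$translation^2)), 1e-9)
  expect_lt(reg$fre_rms, 1e-9)
  expect_identical(c(reg$t_ip$from, reg$t_ip$to), c("I", "P"))
})

test_that("a known rigid motion is recovered exactly from 6 points", {
  set.seed(502)
  for (rep in 1:20) {
    pts <- matrix(rnorm(18, sd = 80), 6, 3)
    truth <- random_rt("I", "P")
    reg <- rigid_register_svd(make_cs(pts, transform_points(truth, pts)))
    expect_lt(geodesic_angle(reg$t_ip$rotation, truth$rotation), 1e-9)
    expect_lt(trans_err(reg$t_ip, truth), 1e-9)
    expect_lt(reg$fre_rms, 1e-9)
  }
})

test_that("a reflected correspondence still yields a proper rotation", {
  set.seed(503)
  pts <- matrix(rnorm(24, sd = 50), 8, 3)
  mirrored <- pts %*% diag(c(-1, 1, 1))
  reg <- rigid_register_svd(make_cs(pts, mirrored))
  expect_equal(det(reg$t_ip$rotation), 1, tolerance = 1e-9)
  expect_gt(reg$fre_rms, 0)
})

test_that("pairing is by label, not by row order", {
  set.seed(504)
  pts <- matrix(rnorm(15, sd = 70), 5, 3)
  truth <- random_rt("I", "P")
  perm <- sample(5)
  cs <- correspondence_set(
    labeled_points(letters[1:5], pts),
    labeled_points(letters[perm], transform_points(truth, pts)[perm, ]))
  reg <- rigid_register_svd(cs)
  expect_lt(trans_err(reg$t_ip, truth), 1e-9)
})

test_that("degenerate inputs are refused", {
  pts <- matrix(rnorm(9), 3, 3)
  expect_error(correspondence_set(labeled_points(c("a", "b"), pts[1:2, ]),
                                  labeled_points(c("a", "b"), pts[1:2, ])),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))  # collinear
  expect_error(rigid_register_svd(make_cs(line, line)), "collinear")
  expect_error(correspondence_set(
    labeled_points(c("a", "b", "c"), pts),
    labeled_points(c("x", "y", "z"), pts)), "at least 3")
})

test_that("FRE matches its closed forms and the brute-force loop", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  shifted <- pts
  shifted[1, ] <- shifted[1, ] + c(3, 0, 0)
  cs <- make_cs(pts, shifted)
  expect_equal(fre(rt_identity("I", "P"), cs), sqrt(3), tolerance = 1e-12)
  set.seed(505)
  noisy <- pts + matrix(rnorm(9), 3, 3)
  cs2 <- make_cs(pts, noisy)
  t <- random_rt("I", "P", 10)
  loop <- sqrt(mean(vapply(1:3, function(i)
    sum((transform_points(t, pts[i, ]) - noisy[i, ])^2), numeric(1))))
  expect_equal(fre(t, cs2), loop, tolerance = 1e-12)
})

test_that("registration is invariant under a common rigid motion", {
  set.seed(506)
  pts <- matrix(rnorm(21, sd = 60), 7, 3)
  truth <- random_rt("I", "P")
  patient <- transform_points(truth, pts)
  reg0 <- rigid_register_svd(make_cs(pts, patient))
  for (rep in 1:5) {
    g <- random_rt("I", "I")
    regg <- rigid_register_svd(make_cs(transform_points(g, pts),
                                       transform_points(g, patient)))
    rel0 <- as.matrix(reg0$t_ip)
    relg <- solve(as.matrix(g)) %*% as.matrix(regg$t_ip) %*% as.matrix(g)
    expect_lt(max(abs(rel0 - relg)), 1e-8)
  }
})

test_that("the fitted transform beats 100 random rigid transforms on FRE", {
  set.seed(507)
  pts <- matrix(rnorm(30, sd = 50), 10, 3)
  noisy <- pts + matrix(rnorm(30, sd = 4), 10, 3)
  truth <- random_rt("I", "P")
  cs <- make_cs(pts, transform_points(truth, noisy))
  best <- rigid_register_svd(cs)
  for (rep in 1:100) {
    expect_gte(fre(random_rt("I", "P"), cs), best$fre_rms)
  }
})

test_that("ICP converges immediately on identical clouds", {
  set.seed(508)
  cloud <- matrix(rnorm(60, sd = 40), 20, 3)
  fit <- icp_register(cloud, cloud)
  expect_lt(max(abs(as.matrix(fit) - diag(4))), 1e-12)
  expect_equal(attr(fit, "iterations"), 1L)
  expect_true(attr(fit, "converged"))
})

test_that("ICP recovers a small rigid motion on a phantom surface", {
  ph <- generate_phantom(phantom_config(n_surface_points = 500L, seed = 509))
  motion <- rigid_transform(rotation_about_axis(c(0, 1, 1), 5), c(5, -4, 5),
                            "I", "I")
  moved <- transform_points(motion, ph$surface)
  fit <- icp_register(moved, ph$surface)
  # recovered transform should undo the motion
  round_trip <- compose_transform(fit, motion)
  probe <- transform_points(round_trip, ph$surface) - ph$surface
  expect_lt(max(sqrt(rowSums(probe^2))), 0.1)
  expect_true(attr(fit, "converged"))
})

test_that("ICP residuals never increase and bad starts are flagged", {
  set.seed(510)
  cloud <- matrix(rnorm(300, sd = 50), 100, 3)
  cloud[, 1] <- cloud[, 1] + 40  # asymmetric offset
  motion <- rigid_transform(rotation_about_axis(c(1, 0, 0), 6), c(8, 0, -6),
                            "I", "I")
  fit <- icp_register(transform_points(motion, cloud), cloud)
  trace <- attr(fit, "residual_trace")
  expect_true(all(diff(trace) <= 1e-9))
  flip <- rigid_transform(rotation_about_axis(c(0, 0, 1), 180), c(0, 0, 0),
                          "I", "I")
  expect_warning(icp_register(transform_points(motion, cloud), cloud,
                              init = flip, max_iter = 40),
                 "local minimum|did not converge")
})

test_that("ICP refuses clouds that are too small", {
  expect_error(icp_register(matrix(rnorm(9), 3, 3), matrix(rnorm(60), 20, 3)),
               "at least 10")
})
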