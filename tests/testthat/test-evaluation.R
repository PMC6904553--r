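test_that("FLE is the per-label Euclidean distance to ground truth", {
  set.seed(601)
  truth <- labeled_points(letters[1:5], matrix(rnorm(15, sd = 40), 5, 3))
  expect_equal(compute_fle(truth, truth)$fle_mm, rep(0, 5))
  bumped <- truth
  bumped[2, c("x", "y", "z")] <- bumped[2, c("x", "y", "z")] + c(3, 4, 0)
  f <- compute_fle(bumped, truth)
  expect_equal(f$fle_mm[f$label == "b"], 5)
  expect_equal(sum(f$fle_mm > 0), 1L)
  expect_error(compute_fle(labeled_points("q", c(0, 0, 0)), truth),
               "no shared labels")
})

test_that("reference per-marker FLE rows reproduce the published means", {
  ref <- fle_reference()
  expect_equal(nrow(ref), 45L)
  s <- summarize_fle(ref, group_by = "subject")
  expect_equal(round_half_up(s$mean_mm[s$subject == "A"], 1), 29.4)
  expect_equal(round_half_up(s$mean_mm[s$subject == "B"], 1), 31.6)
  expect_equal(round_half_up(s$mean_mm[s$subject == "C"], 1), 28.5)
})

test_that("FLE summaries flag undefined standard deviations", {
  one <- data.frame(user = "A", fle_mm = 7)
  s <- summarize_fle(one)
  expect_equal(s$mean_mm, 7)
  expect_equal(s$sd_mm, 0)
  expect_false(s$sd_defined)
})

test_that("inter-user variability matches the brute-force double loop", {
  set.seed(602)
  base <- labeled_points(letters[1:4], matrix(rnorm(12, sd = 30), 4, 3))
  same <- do.call(rbind, lapply(c("A", "B"), function(u) {
    b <- base; b$user <- u; b
  }))
  v <- inter_user_variability(same)
  expect_equal(v$mean_mm, 0)
  shifted <- base
  shifted[, c("x", "y", "z")] <- shifted[, c("x", "y", "z")] +
    matrix(c(10, 0, 0), 4, 3, byrow = TRUE)
  shifted$user <- "B"
  two <- rbind(cbind(base, user = "A"), shifted)
  v2 <- inter_user_variability(two)
  expect_equal(v2$mean_mm, 10)
  expect_equal(v2$sd_mm, 0)
  # three users with random offsets vs. an independent loop
  three <- do.call(rbind, lapply(c("A", "B", "C"), function(u) {
    b <- base
    b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] + matrix(rnorm(12), 4, 3)
    b$user <- u
    b
  }))
  v3 <- inter_user_variability(three)
  dists <- c()
  for (lab in letters[1:4]) {
    for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
      p1 <- three[three$label == lab & three$user == pair[1], c("x", "y", "z")]
      p2 <- three[three$label == lab & three$user == pair[2], c("x", "y", "z")]
      dists <- c(dists, sqrt(sum((p1 - p2)^2)))
    }
  }
  expect_equal(v3$mean_mm, mean(dists), tolerance = 1e-12)
  expect_equal(v3$n, 12L)
  expect_error(inter_user_variability(cbind(base, user = "A")), "2 users")
})

test_that("frame TRE honors the exclusion rule and the in-plane closed form", {
  k <- default_intrinsics()
  ch <- build_ar_chain(k, rt_identity("C", "M"), rt_identity("M", "O"),
                       rt_identity("P", "O"), rt_identity("I", "P"))
  set.seed(603)
  marks <- labeled_points(letters[1:6],
                          cbind(rnorm(6, sd = 30), rnorm(6, sd = 20),
                                runif(6, 140, 160)))
  obs <- project_ar(ch, marks)
  observed <- data.frame(label = obs$label, u = obs$u, v = obs$v)
  perfect <- compute_tre_frame(ch, marks, observed)
  expect_lt(max(perfect$tre_mm), 1e-9)
  # registration shifted 10 mm parallel to the image plane
  ch_off <- build_ar_chain(k, rt_identity("C", "M"), rt_identity("M", "O"),
                           rt_identity("P", "O"),
                           rigid_transform(diag(3), c(10, 0, 0), "I", "P"))
  off <- compute_tre_frame(ch_off, marks, observed)
  expect_equal(off$tre_mm, rep(10, 6), tolerance = 1e-9)
  # excluded labels never appear in the output
  part <- compute_tre_frame(ch, marks, observed, exclude = c("a", "d"))
  expect_false(any(c("a", "d") %in% part$label))
  expect_setequal(part$label, c("b", "c", "e", "f"))
})

test_that("the marker-subset experiment is reproducible and honors exclusion", {
  users <- default_users(2, sigma_intraop = 4)
  trial <- generate_trial("t1", users = users,
                          deformation = deformation_model(magnitude = 10),
                          tracking = tracking_model(2, 4, 1, 10),
                          n_frames = 4, centroid_noise_px = 1, seed = 604)
  cfg <- experiment_config(n_markers = c(3, 6), repeats = 2, seed = 605)
  tab1 <- run_marker_subset_experiment(trial, cfg)
  tab2 <- run_marker_subset_experiment(trial, cfg)
  expect_identical(tab1, tab2)
  expect_equal(audit_exclusion_rule(tab1), 0)
  expect_true(all(tab1$tre_mm >= 0, na.rm = TRUE))
  # every record's subset has the declared size
  sizes <- lengths(strsplit(tab1$registration_marks, ","))
  expect_equal(sizes, tab1$n_markers)
})

test_that("a zero-noise trial yields zero TRE end to end", {
  users <- default_users(1, sigma_intraop = 0)
  trial <- generate_trial("t0", users = users,
                          deformation = deformation_model(magnitude = 0),
                          tracking = tracking_model(0, 4, 0, 5),
                          n_frames = 3, centroid_noise_px = 0, seed = 606)
  cfg <- experiment_config(n_markers = c(3, 5, 10), repeats = 2, seed = 607)
  tab <- run_marker_subset_experiment(trial, cfg)
  expect_lt(max(tab$tre_mm), 1e-6)
})

test_that("TRE summaries reproduce hand-computed group means and deltas", {
  fix <- data.frame(
    trial = "t", condition = rep(c("intraop-user", "preop-user"), each = 4),
    user = "A", n_markers = rep(c(3L, 3L, 4L, 4L), 2), rep = 1L,
    frame = 1L, mark = "o",
    tre_mm = c(10, 14, 6, 8, 30, 34, 20, 24),
    registration_marks = "a,b,c")
  s <- summarize_tre(fix, "condition_n")
  expect_equal(s$summary$mean_mm, c(12, 7, 32, 22))
  expect_equal(s$summary$sd_mm,
               c(sd(c(10, 14)), sd(c(6, 8)), sd(c(30, 34)), sd(c(20, 24))))
  expect_equal(s$deltas$delta_mm, c(5, 10))
  expect_true(all(s$deltas$delta_mm >= 0))
  by_cond <- summarize_tre(fix, "condition")
  expect_equal(by_cond$mean_mm, c(9.5, 27))
})

test_that("condition comparison is antisymmetric and finds known effects", {
  set.seed(608)
  tab <- data.frame(
    condition = rep(c("intraop-user", "preop-user"), each = 500),
    tre_mm = c(rnorm(500, 20, 1), rnorm(500, 40, 1)))
  cmp <- compare_conditions(tab, "preop-user", "intraop-user")
  expect_equal(cmp$mean_difference, 20, tolerance = 0.2)
  swap <- compare_conditions(tab, "intraop-user", "preop-user")
  expect_equal(swap$mean_difference, -cmp$mean_difference)
  same <- compare_conditions(
    data.frame(condition = rep(c("a", "b"), each = 3),
               tre_mm = rep(c(1, 2, 3), 2)), "a", "b")
  expect_equal(same$mean_difference, 0)
  expect_error(compare_conditions(tab, "intraop-user", "fiducial"),
               "not present")
})
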