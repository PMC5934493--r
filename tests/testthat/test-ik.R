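test_that("virtual midpoint marker lies halfway between its parents", {
  t <- c(0, 0.01)
  traj <- marker_trajectory(t, list(Mk0 = rbind(c(0, 0, 0), c(1, 1, 1)),
                                    Mk1 = rbind(c(2, 0, 0), c(1, 1, 1))))
  out <- add_virtual_midpoint_marker(traj, "Mk0", "Mk1", "Mk14")
  expect_equal(out$markers$Mk14[1, ], c(x = 1, y = 0, z = 0))
  expect_equal(out$markers$Mk14[2, ], c(x = 1, y = 1, z = 1))  # a == b case
  expect_identical(out$markers$Mk0, traj$markers$Mk0)
  d_a <- sqrt(rowSums((out$markers$Mk14 - out$markers$Mk0)^2))
  d_b <- sqrt(rowSums((out$markers$Mk14 - out$markers$Mk1)^2))
  expect_equal(d_a, d_b)
  expect_error(add_virtual_midpoint_marker(traj, "Mk0", "MkX"), "missing")
})

test_that("marker IK recovers noiseless generating angles", {
  m <- two_link_leg()
  n <- 60
  t <- (seq_len(n) - 1) / 100
  qs <- cbind(hip = 20 * sin(2 * pi * t), knee = 25 + 20 * cos(2 * pi * t))
  mk <- list(A = matrix(0, n, 3), B = matrix(0, n, 3), C = matrix(0, n, 3))
  for (i in seq_len(n)) {
    pos <- marker_positions(m, qs[i, ], warn_limits = FALSE)
    for (l in rownames(pos)) mk[[l]][i, ] <- pos[l, ]
  }
  res <- marker_ik(m, marker_trajectory(t, mk))
  expect_true(all(res$converged))
  expect_lt(max(abs(do.call(cbind, res$trajectory$channels) - qs)), 0.1)
})

test_that("marker IK handles occlusion, noise, static input and degenerate frames", {
  m <- add_marker(two_link_leg(), "shank", "D", c(0.02, -0.2, 0.04))
  n <- 40
  t <- (seq_len(n) - 1) / 100
  qs <- cbind(hip = 15 * sin(2 * pi * t), knee = 30 + 15 * cos(2 * pi * t))
  mk <- list(A = matrix(0, n, 3), B = matrix(0, n, 3), C = matrix(0, n, 3),
             D = matrix(0, n, 3))
  for (i in seq_len(n)) {
    pos <- marker_positions(m, qs[i, ], warn_limits = FALSE)
    for (l in rownames(pos)) mk[[l]][i, ] <- pos[l, ]
  }
  # occluded sample: dropped from the cost, frame still solvable
  mk_occ <- mk; mk_occ$C[5, ] <- NaN
  res <- marker_ik(m, marker_trajectory(t, mk_occ))
  expect_lt(max(abs(do.call(cbind, res$trajectory$channels) - qs)), 0.5)
  # static markers give constant output
  mk_st <- lapply(mk, function(x) x[rep(1, n), ])
  res_st <- marker_ik(m, marker_trajectory(t, mk_st))
  expect_equal(stats::sd(res_st$trajectory$channels$hip), 0, tolerance = 1e-8)
  # fewer than 3 usable markers is underdetermined
  mk_bad <- mk; mk_bad$A[1, ] <- NaN; mk_bad$B[1, ] <- NaN
  expect_error(marker_ik(m, marker_trajectory(t, mk_bad)), "underdetermined")
  # weights: zero-weight markers are excluded
  expect_error(marker_ik(m, marker_trajectory(t, mk),
                         ik_settings(marker_weights = c(A = 0, B = 0, C = 0,
                                                        D = 0))),
               "at least one")
})

test_that("marker IK with 1 mm noise recovers a synthetic walk within 1 degree RMSE", {
  subj <- make_synthetic_subject(seed = 5, soft = soft_tissue_params(
    marker_noise_sd = 0.001, seed = 5), duration = 2,
    axis_offsets = c(hip = 0, knee = 0, ankle = 0), exo_motion = "affine")
  res <- process_subject(subj, gt_method = "marker_ik")
  err <- channel_rmse(res$v_H_gt, subj$truth$v_H)
  expect_lt(max(err), 1)
})

test_that("base free-6 coordinates are estimable jointly with angles on the coupled model", {
  subj <- ideal_subject(seed = 13, duration = 0.02)
  cp <- subj$truth$coupled
  truth_q <- coupled_q(cp, human = c(12, 25, -4), exo = c(12, 25, -4))
  tr <- paste0("base_t", c("x", "y", "z"))
  truth_q[tr] <- truth_q[tr] + c(0.04, -0.03, 0.02)
  pos <- marker_positions(cp$model, truth_q, warn_limits = FALSE)
  frame <- marker_trajectory(0, stats::setNames(
    lapply(rownames(pos), function(l) matrix(pos[l, ], 1)), rownames(pos)))
  free <- c(tr, cp$human_coords, "exo_hip_flexion", "exo_knee_flexion")
  fit <- marker_ik(cp$model, frame, free = free, fixed = cp$static_posture)
  sol <- vapply(fit$trajectory$channels, `[`, 0, 1L)
  expect_equal(unname(sol[tr]), unname(truth_q[tr]), tolerance = 1e-6)
  expect_equal(unname(sol[cp$human_coords]), c(12, 25, -4), tolerance = 1e-4)
})

test_that("the rigid baseline is the identity map on exoskeleton channels", {
  v <- generate_gait_profile(gait_profile_params(duration = 1))
  expect_identical(rigid_estimate(v), v)
  expect_equal(channel_rmse(rigid_estimate(v), v),
               c(hip_flexion = 0, knee_flexion = 0, ankle_flexion = 0))
  bad <- joint_trajectory(v$time, list(hip_flexion = v$channels$hip_flexion))
  expect_error(rigid_estimate(bad), "schema error")
})
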