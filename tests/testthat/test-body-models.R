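test_that("the generic human model carries the full 12-marker protocol", {
  m <- build_generic_human()
  labels <- unlist(lapply(m$segments, function(s) names(s$markers)))
  expect_setequal(labels, paste0("Mk", 0:11))
  # standing order at neutral: trochanter above knee above malleolus
  q0 <- stats::setNames(rep(0, length(m$coords)), m$coords)
  pos <- marker_positions(m, q0)
  expect_true(pos["Mk11", "y"] > pos["Mk7", "y"])
  expect_true(pos["Mk7", "y"] > pos["Mk3", "y"])
  expect_error(build_generic_human(markers = list(femur = list(Mk11 = c(0, 0, 0)))),
               "missing")
})

test_that("scale factors are marker-pair distance ratios", {
  m <- build_generic_human()
  q0 <- stats::setNames(rep(0, length(m$coords)), m$coords)
  pos <- marker_positions(m, q0)
  # a static frame identical to the model's neutral pose gives unit factors
  frame <- marker_trajectory(0, lapply(rownames(pos), function(l)
    matrix(pos[l, ], 1)) |> stats::setNames(rownames(pos)))
  f <- compute_scale_factors(frame, m)
  expect_equal(c(f$femur, f$tibia, f$foot), c(1, 1, 1), tolerance = 1e-12)
  # stretching the femur pair by 1.1 gives a femur factor of 1.1
  stretch <- frame
  d <- pos["Mk11", ] - pos["Mk7", ]
  stretch$markers$Mk11 <- matrix(pos["Mk7", ] + 1.1 * d, 1)
  f2 <- compute_scale_factors(stretch, m)
  expect_equal(f2$femur, 1.1, tolerance = 1e-12)
  expect_error(compute_scale_factors(select_markers(frame, "Mk0"), m),
               "missing marker")
})

test_that("known scale factors are recovered from a synthetic static capture", {
  subj <- make_synthetic_subject(seed = 3,
                                 factors = scale_factors(0.95, 1.05, 1.02),
                                 soft = soft_tissue_preset("none"),
                                 duration = 0.02,
                                 axis_offsets = c(hip = 0, knee = 0, ankle = 0))
  generic <- build_generic_human(
    markers = default_human_markers(axis_offsets = subj$axis_offsets))
  f <- compute_scale_factors(subj$static_no_exo, generic)
  expect_equal(c(f$femur, f$tibia, f$foot), c(0.95, 1.05, 1.02),
               tolerance = 1e-6)
})

test_that("apply_scaling scales lengths and longitudinal offsets only", {
  m <- build_generic_human()
  expect_identical(apply_scaling(m, scale_factors(1, 1, 1)), m)
  s <- apply_scaling(m, scale_factors(femur = 1.1))
  expect_equal(s$segments$femur$length, 0.44)
  expect_equal(s$segments$femur$markers$Mk8[2], 1.1 * m$segments$femur$markers$Mk8[2])
  expect_equal(s$segments$femur$markers$Mk8[c(1, 3)],
               m$segments$femur$markers$Mk8[c(1, 3)])
  # the knee joint moves distally with the femur
  knee <- Filter(function(j) j$name == "knee_flexion", s$joints)[[1]]
  expect_equal(knee$parent_xf$p[2], -0.44)
  # topology unchanged
  expect_identical(lapply(s$segments, function(x) names(x$markers)),
                   lapply(m$segments, function(x) names(x$markers)))
  expect_identical(s$coords, m$coords)
  # manual override takes precedence
  s2 <- apply_scaling(m, scale_factors(femur = 1.1,
                                       manual_overrides = list(femur = 1.2)))
  expect_equal(s2$segments$femur$length, 0.48)
  expect_error(apply_scaling(m, scale_factors(femur = 1e-9)), NA)
  expect_error(scale_factors(femur = -1), "> 0")
})

test_that("scaling then re-measuring the scaled model is a fixed point", {
  f <- scale_factors(0.93, 1.07, 1.01)
  m <- build_generic_human()
  s <- apply_scaling(m, f)
  q0 <- stats::setNames(rep(0, length(s$coords)), s$coords)
  pos <- marker_positions(s, q0)
  frame <- marker_trajectory(0, stats::setNames(
    lapply(rownames(pos), function(l) matrix(pos[l, ], 1)), rownames(pos)))
  f2 <- compute_scale_factors(frame, s)
  expect_equal(c(f2$femur, f2$tibia, f2$foot), c(1, 1, 1), tolerance = 1e-9)
})

test_that("the exoskeleton model is a parallel-axis sagittal device", {
  exo <- build_exo_model(c(thigh = 0.42, shank = 0.38, sole = 0.25))
  q0 <- stats::setNames(rep(0, length(exo$coords)), exo$coords)
  fk <- forward_kinematics(exo, q0)
  for (pose in fk) expect_equal(pose$R[, 3], c(0, 0, 1), tolerance = 1e-12)
  pos <- marker_positions(exo, q0)
  expect_true(pos["ExoHip", "y"] > pos["ExoKnee", "y"])
  expect_true(pos["ExoKnee", "y"] > pos["ExoAnkle", "y"])
  # motor markers sit at the joint centers with equal lateral offset
  expect_equal(sqrt(sum((pos["ExoKnee", ] - pos["ExoHip", ])^2)), 0.42,
               tolerance = 1e-12)
})

test_that("exoskeleton links adjust to marker heights in the worn static", {
  exo <- build_exo_model()
  frame <- marker_trajectory(0, list(Mk11 = matrix(c(0, 0.90, 0), 1),
                                     Mk7 = matrix(c(0, 0.48, 0), 1),
                                     Mk3 = matrix(c(0, 0.10, 0), 1)))
  adj <- adjust_exo_links(exo, frame)
  expect_equal(adj$meta$link_lengths[["thigh"]], 0.42)
  expect_equal(adj$meta$link_lengths[["shank"]], 0.38)
  same <- marker_trajectory(0, list(Mk11 = matrix(c(0, 0.5, 0), 1),
                                    Mk7 = matrix(c(0, 0.5, 0), 1),
                                    Mk3 = matrix(c(0, 0.5, 0), 1)))
  expect_error(adjust_exo_links(exo, same), "implausible")
  # round trip: links recovered from a subject generated with known links
  subj <- ideal_subject(seed = 11, duration = 0.02)
  adj2 <- adjust_exo_links(build_exo_model(), subj$static_with_exo)
  expect_equal(adj2$meta$link_lengths[["thigh"]],
               subj$truth$coupled$model$segments$exo_thigh$length,
               tolerance = 1e-9)
  expect_equal(adj2$meta$link_lengths[["shank"]],
               subj$truth$coupled$model$segments$exo_shank$length,
               tolerance = 1e-9)
})

test_that("assembly aligns hip centers, recovers the static posture, and is idempotent", {
  subj <- ideal_subject(seed = 11, duration = 0.02)
  cp <- pipeline_coupled(subj)
  # anterior-posterior hip-center alignment in the corset frame
  fk <- forward_kinematics(cp$model, cp$static_posture, warn_limits = FALSE)
  h_hip <- rt_apply(rt_invert(fk$corset),
                    rt_apply(fk$pelvis, c(0, -0.05, 0.09)))
  expect_equal(h_hip[1], c(0, -0.05, 0.12)[1], tolerance = 1e-9)
  # static angles recovered (truth is neutral standing)
  expect_equal(unname(cp$static_posture[cp$human_coords]), c(0, 0, 0),
               tolerance = 0.1)
  expect_equal(cp$hip_adduction, 0, tolerance = 0.1)
  expect_false(cp$poor_initialization)
  # idempotence: assembling twice gives an identical model
  cp2 <- pipeline_coupled(subj)
  expect_identical(cp$static_posture, cp2$static_posture)
  expect_identical(cp$model, cp2$model)
})
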