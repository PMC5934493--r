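test_that("the default fixation set has 11 residual dimensions, zero at the static posture", {
  subj <- ideal_subject(seed = 11, duration = 0.02)
  cp <- subj$truth$coupled
  cs <- make_default_constraint_set(cp)
  expect_equal(cs$residual_dim, 11L)
  kinds <- vapply(cs$specs, `[[`, "", "kind")
  expect_equal(sum(kinds == "weld6"), 1L)
  expect_equal(sum(kinds == "point_on_line2"), 1L)
  expect_equal(sum(kinds == "point_to_point3"), 3L)
  r0 <- constraint_residuals(cp, cs,
                             cp$static_posture[cp$human_coords],
                             cp$static_posture[cp$exo_coords])
  expect_lt(max(abs(r0)), 1e-9)
  # dropping the foot constraints leaves the 2-dimensional tibia residual
  reduced <- constraint_set(cs$specs[kinds != "point_to_point3"])
  expect_equal(reduced$residual_dim, 2L)
})

test_that("point-to-point residual is the world anchor difference", {
  pa <- rigid_transform(rot_z(30), c(0.1, 0.2, 0.3))
  pb <- rigid_transform(rot_y(40), c(-0.1, 0, 0.05))
  expect_equal(residual_point_to_point(pa, c(0, 0, 0), rt_identity(), pa$p),
               c(0, 0, 0))
  expect_equal(residual_point_to_point(rt_identity(), c(0, 0.01, 0),
                                       rt_identity(), c(0, 0, 0)),
               c(0, 0.01, 0))
  set.seed(9)
  for (i in 1:20) {
    la <- runif(3, -0.2, 0.2); lb <- runif(3, -0.2, 0.2)
    r <- residual_point_to_point(pa, la, pb, lb)
    # magnitude equals the Euclidean distance between the world anchors
    expect_equal(sqrt(sum(r^2)),
                 sqrt(sum((rt_apply(pa, la) - rt_apply(pb, lb))^2)))
  }
})

test_that("point-on-line residual measures off-axis offset and ignores sliding", {
  spec <- constraint_spec("point_on_line2", segment_a = "a", point_a = c(0, 0, 0),
                          segment_b = "b", point_b = c(0, 0, 0),
                          line_dir = c(0, 1, 0))
  line <- list(point = spec$point_b, dir = spec$line_dir, basis = spec$basis)
  expect_equal(residual_point_on_line(rt_identity(), c(0, 0.3, 0),
                                      rt_identity(), line), c(0, 0))
  r <- residual_point_on_line(rt_identity(), c(1, 0.3, 0), rt_identity(), line)
  expect_equal(sqrt(sum(r^2)), 1)
  # translating the point along the line leaves the residual unchanged
  r2 <- residual_point_on_line(rt_identity(), c(1, -5.7, 0), rt_identity(), line)
  expect_equal(r, r2)
  expect_error(constraint_spec("point_on_line2", line_dir = c(0, 2, 0)),
               "unit length")
})

test_that("residual norms are invariant to a common rigid motion", {
  subj <- ideal_subject(seed = 11, duration = 0.02)
  cp <- subj$truth$coupled
  cs <- make_default_constraint_set(cp)
  set.seed(21)
  for (i in 1:10) {
    qh <- runif(3, -20, 40); qr <- qh + runif(3, -3, 3)
    base1 <- cp$static_posture[cp$base_coords]
    base2 <- base1 + c(runif(3, -0.5, 0.5), runif(3, -40, 40))
    n1 <- sqrt(sum(constraint_residuals(cp, cs, qh, qr, base = base1)^2))
    n2 <- sqrt(sum(constraint_residuals(cp, cs, qh, qr, base = base2)^2))
    expect_equal(n1, n2, tolerance = 1e-9)
  }
})

test_that("closed-chain identity: equal geometry and equal angles give zero residual", {
  subj <- ideal_subject(seed = 11, duration = 0.5)
  cp <- subj$truth$coupled
  cs <- make_default_constraint_set(cp)
  h <- do.call(cbind, subj$truth$v_H$channels)
  for (i in seq(1, nrow(h), by = 10)) {
    r <- constraint_residuals(cp, cs, h[i, ], h[i, ])
    expect_lt(max(abs(r)), 1e-9)
  }
  # perturbing only the knee concentrates residual in tibia and foot rows
  r5 <- constraint_residuals(cp, cs, h[1, ] + c(0, 5, 0), h[1, ])
  expect_gt(sqrt(sum(r5^2)), 1e-3)
})

test_that("residuals are smooth: finite differences are consistent across step sizes", {
  subj <- ideal_subject(seed = 11, duration = 0.02)
  cp <- subj$truth$coupled
  cs <- make_default_constraint_set(cp)
  f <- function(q) constraint_residuals(cp, cs, q, c(5, 10, -2))
  q0 <- c(4, 11, -1)
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- 1
    g1 <- (f(q0 + 1e-4 * e) - f(q0 - 1e-4 * e)) / 2e-4
    g2 <- (f(q0 + 1e-6 * e) - f(q0 - 1e-6 * e)) / 2e-6
    expect_equal(g1, g2, tolerance = 1e-5)
  }
})
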