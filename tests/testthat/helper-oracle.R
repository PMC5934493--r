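# Independent closed-form oracle for the constraint-closure estimate.
#
# The whole device is sagittal: every joint rotates about Z and lateral
# (z) offsets are constants, so anchor positions follow from cumulative
# planar rotations — derived here with plain trigonometry, sharing no
# code with the package's forward-kinematics tree.

rotz2 <- function(v, phi_deg) {
  a <- phi_deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2], v[3])
}

# residual-norm^2 of the default constraint set, vectorized over a grid of
# human angle triples (h1, h2, h3 in degrees); exo angles fixed.
# Assumes zero base rotations and zero frozen hip angles.
oracle_resid2 <- function(cp, cs, H, qr) {
  model <- cp$model
  segs <- model$segments
  jts <- stats::setNames(model$joints, vapply(model$joints, `[[`, "", "name"))
  base <- cp$static_posture[cp$base_coords]
  stopifnot(all(abs(base[4:6]) < 1e-12))
  bt <- unname(base[1:3])
  weld <- jts[["pelvis_corset"]]$parent_xf
  tilt <- atan2(weld$R[2, 1], weld$R[1, 1]) * 180 / pi
  p_pelvis <- bt + weld$p
  p_hip <- p_pelvis + rotz2(jts[["hip_flexion"]]$parent_xf$p, tilt)
  lf <- -jts[["knee_flexion"]]$parent_xf$p[2]
  lt <- -jts[["ankle_flexion"]]$parent_xf$p[2]
  # exoskeleton chain (fixed this frame)
  p_eh <- bt + jts[["exo_hip_flexion"]]$parent_xf$p
  e1 <- qr[1]; e2 <- qr[1] + qr[2]; e3 <- e2 + qr[3]
  p_ek <- p_eh + rotz2(jts[["exo_knee_flexion"]]$parent_xf$p, e1)
  p_ea <- p_ek + rotz2(jts[["exo_ankle_flexion"]]$parent_xf$p, e2)

  d2r <- pi / 180
  f1 <- (tilt + H[, 1]) * d2r          # femur angle
  f2 <- f1 + H[, 2] * d2r              # tibia
  f3 <- f2 + H[, 3] * d2r              # foot
  kx <- p_hip[1] - lf * -sin(f1); ky <- p_hip[2] - lf * cos(f1)
  ax <- kx - lt * -sin(f2); ay <- ky - lt * cos(f2)
  rot_pt <- function(px, py, phi, v)
    list(x = px + cos(phi) * v[1] - sin(phi) * v[2],
         y = py + sin(phi) * v[1] + cos(phi) * v[2])
  total <- 0
  for (s in cs$specs) {
    if (s$kind == "point_on_line2") {
      w <- rot_pt(kx, ky, f2, s$point_a)
      wz <- p_hip[3] + s$point_a[3]
      # express in the exo-shank frame (rotation e2 about Z at p_ek)
      ce <- cos(e2 * d2r); se <- sin(e2 * d2r)
      lx <- ce * (w$x - p_ek[1]) + se * (w$y - p_ek[2])
      ly <- -se * (w$x - p_ek[1]) + ce * (w$y - p_ek[2])
      lz <- wz - p_ek[3] - s$point_b[3]
      off <- rbind(lx - s$point_b[1], ly - s$point_b[2], lz)
      r <- s$basis %*% off
      total <- total + colSums(r^2)
    } else if (s$kind == "point_to_point3") {
      w <- rot_pt(ax, ay, f3, s$point_a)
      wbx <- p_ea[1] + cos(e3 * d2r) * s$point_b[1] - sin(e3 * d2r) * s$point_b[2]
      wby <- p_ea[2] + sin(e3 * d2r) * s$point_b[1] + cos(e3 * d2r) * s$point_b[2]
      dz <- (p_hip[3] + s$point_a[3]) - (p_ea[3] + s$point_b[3])
      total <- total + (w$x - wbx)^2 + (w$y - wby)^2 + dz^2
    }
  }
  total
}

# zero the frozen out-of-plane hip angles so a coupled model satisfies
# the oracle's planarity assumption (the estimator uses the same model,
# so the comparison stays like-for-like)
planarize_coupled <- function(cp) {
  for (k in seq_along(cp$model$joints)) {
    if (cp$model$joints[[k]]$name == "hip_flexion") {
      cp$model$joints[[k]]$fixed_rx <- 0
      cp$model$joints[[k]]$fixed_ry <- 0
    }
  }
  cp$hip_adduction <- 0
  cp$hip_rotation <- 0
  cp
}

# dense grid search refined to a 0.01-degree grid
oracle_grid_search <- function(cp, cs, qr, center, half_width = 40) {
  best <- center
  width <- half_width
  repeat {
    step <- width / 10
    g <- expand.grid(h1 = best[1] + seq(-width, width, by = step),
                     h2 = best[2] + seq(-width, width, by = step),
                     h3 = best[3] + seq(-width, width, by = step))
    v <- oracle_resid2(cp, cs, as.matrix(g), qr)
    best <- as.numeric(g[which.min(v), ])
    if (step <= 0.01) return(best)
    width <- 2 * step
  }
}
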