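#' Estimate human joint angles from exoskeleton angles (EIKPE)
#'
#' The extended inverse-kinematics posture estimator: human limb and
#' exoskeleton form a single parallel kinematic chain closed by the
#' fixation constraints. For each frame the exoskeleton coordinates are
#' fixed to their known values and the human hip, knee and ankle flexion
#' angles are found by minimizing the squared norm of the stacked
#' constraint residuals (11 equations, 3 unknowns) with damped
#' least squares, warm-started from the previous frame (frame 1 from the
#' static posture). The base is pinned at the static pose: joint angles
#' are invariant to a common rigid motion of the whole chain. As a
#' safeguard, if the converged solution has a larger residual than the
#' rigid configuration (human angles equal to exoskeleton angles), the
#' solve is repeated from the rigid start and the better solution kept,
#' so the returned residual never exceeds the rigid baseline's.
#'
#' @param coupled a `coupled_model` from [assemble_coupled()].
#' @param v_R exoskeleton joint angles: a [joint_trajectory()] with
#'   `hip_flexion`, `knee_flexion`, `ankle_flexion` channels (degrees).
#' @param constraints a [constraint_set()]; defaults to
#'   [make_default_constraint_set()].
#' @param settings an [ik_settings()].
#' @param plausibility_bound residual RMS (meters) above which a frame is
#'   flagged with a warning (the closure is geometrically implausible).
#' @return An object of class `eikpe` with components `trajectory` (the
#'   estimated human angles), `per_frame_residual_rms`,
#'   `rigid_residual_rms`, `converged`, `v_R`, `constraints` and
#'   `settings`. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`.
#' @export
eikpe <- function(coupled, v_R, constraints = NULL,
                  settings = ik_settings(), plausibility_bound = 0.05) {
  stopifnot(inherits(coupled, "coupled_model"))
  v_R <- rigid_estimate(v_R)  # validates the channel schema
  if (is.null(constraints)) constraints <- make_default_constraint_set(coupled)
  model <- coupled$model
  jts <- stats::setNames(model$joints,
                         vapply(model$joints, `[[`, "", "name"))
  hipj <- jts[["hip_flexion"]]; kneej <- jts[["knee_flexion"]]
  anklej <- jts[["ankle_flexion"]]

  n <- n_frames(v_R)
  exo_mat <- cbind(v_R$channels$hip_flexion, v_R$channels$knee_flexion,
                   v_R$channels$ankle_flexion)
  sol <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, coupled$human_coords))
  rms <- numeric(n); rigid_rms <- numeric(n); conv <- logical(n)
  ctrl <- minpack.lm::nls.lm.control(maxiter = settings$max_iterations,
                                     ftol = 1e-15, ptol = 1e-13, gtol = 0)
  ndim <- constraints$residual_dim
  par <- as.numeric(coupled$static_posture[coupled$human_coords])

  q0 <- coupled$static_posture
  for (i in seq_len(n)) {
    q0[coupled$exo_coords] <- exo_mat[i, ]
    fk <- forward_kinematics(model, q0, warn_limits = FALSE)
    pelvis <- fk[["pelvis"]]
    hip_base <- rt_compose(pelvis, hipj$parent_xf)
    fixed_R <- NULL
    if (hipj$fixed_rx != 0 || hipj$fixed_ry != 0)
      fixed_R <- rot_x(hipj$fixed_rx) %*% rot_y(hipj$fixed_ry)
    knee_p <- kneej$parent_xf$p
    ankle_p <- anklej$parent_xf$p
    fn <- function(h) {
      Rz <- rot_z(h[1L])
      if (!is.null(fixed_R)) Rz <- Rz %*% fixed_R
      femur <- new_rt(hip_base$R %*% Rz, hip_base$p)
      tibia <- new_rt(femur$R %*% rot_z(h[2L]),
                      as.numeric(femur$R %*% knee_p) + femur$p)
      foot <- new_rt(tibia$R %*% rot_z(h[3L]),
                     as.numeric(tibia$R %*% ankle_p) + tibia$p)
      fk[["femur"]] <- femur; fk[["tibia"]] <- tibia; fk[["foot"]] <- foot
      eval_constraint_residuals(fk, constraints)
    }
    start <- if (settings$warm_start || i == 1L) par else exo_mat[i, ]
    start[abs(start) < 1e-9] <- 0  # keep lmdif's FD step resolvable
    fit <- minpack.lm::nls.lm(start, fn = fn, control = ctrl)
    dev_rigid <- sum(fn(exo_mat[i, ])^2)
    rigid_rms[i] <- sqrt(dev_rigid / ndim)
    if (fit$deviance > dev_rigid) {
      # LM is monotone from its start, so a solve started at the rigid
      # configuration can never end up above it
      fit2 <- minpack.lm::nls.lm(exo_mat[i, ], fn = fn, control = ctrl)
      if (fit2$deviance < fit$deviance) fit <- fit2
    }
    sol[i, ] <- fit$par
    rms[i] <- sqrt(fit$deviance / ndim)
    conv[i] <- (fit$info %in% 1:3) || rms[i] <= settings$tolerance
    par <- fit$par
  }
  if (any(rms > plausibility_bound))
    warning(sum(rms > plausibility_bound),
            " frame(s) with constraint residual RMS above the plausibility ",
            "bound (", plausibility_bound, " m)", call. = FALSE)
  structure(list(trajectory = joint_trajectory(v_R$time,
                                               as.list(as.data.frame(sol))),
                 per_frame_residual_rms = rms,
                 rigid_residual_rms = rigid_rms,
                 converged = conv,
                 v_R = v_R, coupled = coupled,
                 constraints = constraints, settings = settings,
                 call = match.call()),
            class = "eikpe")
}

#' @export
print.eikpe <- function(x, ...) {
  cat("EIKPE constraint-closure estimate\n")
  cat(n_frames(x$trajectory), "frames;",
      sum(x$converged), "converged;",
      sprintf("constraint residual RMS mean %.3g m (rigid baseline %.3g m)\n",
              mean(x$per_frame_residual_rms), mean(x$rigid_residual_rms)))
  invisible(x)
}

#' @export
summary.eikpe <- function(object, ...) {
  ch <- object$trajectory$channels
  tab <- t(vapply(names(ch), function(nm) {
    v <- ch[[nm]]
    e <- v - object$v_R$channels[[nm]]
    c(min = min(v), max = max(v), range = diff(range(v)),
      mean_shift_vs_exo = mean(e))
  }, numeric(4)))
  out <- list(angles = tab,
              residual_rms = summary(object$per_frame_residual_rms),
              n_converged = sum(object$converged),
              n = length(object$converged))
  class(out) <- "summary.eikpe"
  out
}

#' @export
print.summary.eikpe <- function(x, ...) {
  cat("EIKPE estimate summary\n\nEstimated angles (degrees):\n")
  print(round(x$angles, 3))
  cat("\nConstraint residual RMS (m):\n")
  print(x$residual_rms)
  cat("\n", x$n_converged, "of", x$n, "frames converged\n")
  invisible(x)
}

#' @export
coef.eikpe <- function(object, ...) {
  do.call(cbind, object$trajectory$channels)
}

#' @export
fitted.eikpe <- function(object, ...) object$trajectory

#' @export
residuals.eikpe <- function(object, type = c("constraint", "vs_rigid"), ...) {
  type <- match.arg(type)
  if (type == "constraint") return(object$per_frame_residual_rms)
  coef(object) - do.call(cbind, object$v_R$channels[colnames(coef(object))])
}

#' @export
predict.eikpe <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$trajectory)
  refit <- eikpe(object$coupled, newdata, constraints = object$constraints,
                 settings = object$settings)
  refit$trajectory
}

#' @export
plot.eikpe <- function(x, gt = NULL, ...) {
  chans <- c("hip_flexion", "knee_flexion", "ankle_flexion")
  old <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chans) {
    est <- x$trajectory$channels[[ch]]
    exo <- x$v_R$channels[[ch]]
    ylim <- range(est, exo, if (!is.null(gt)) gt$channels[[ch]])
    plot(x$trajectory$time, est, type = "l", col = "firebrick", lwd = 2,
         xlab = "time (s)", ylab = "angle (deg)", main = ch, ylim = ylim, ...)
    graphics::lines(x$trajectory$time, exo, col = "forestgreen", lty = 2)
    if (!is.null(gt))
      graphics::lines(gt$time, gt$channels[[ch]], col = "navy")
    graphics::legend("topright", bty = "n", lty = c(1, 2, 1), cex = 0.8,
                     col = c("firebrick", "forestgreen", "navy"),
                     legend = c("EIKPE", "exoskeleton (rigid)",
                                if (!is.null(gt)) "ground truth")[
                                  seq_len(2 + !is.null(gt))])
  }
  invisible(x)
}
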