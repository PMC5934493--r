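#' Inverse-kinematics solver settings
#'
#' @param tolerance residual-norm (RMS, meters) below which a frame is
#'   considered converged regardless of the optimizer's stop code.
#' @param max_iterations Levenberg-Marquardt iteration cap per frame.
#' @param marker_weights optional named non-negative weights per marker
#'   label; unlisted markers get weight 1, weight 0 removes a marker from
#'   the cost.
#' @param warm_start start each frame from the previous frame's solution.
#' @param restart_threshold residual RMS (meters) above which a frame's
#'   solution is treated as a wrong local minimum and the solve is retried
#'   from a deterministic coarse grid of candidate configurations (guards
#'   against branch flips when the first frame starts far from neutral).
#' @return An object of class `ik_settings`.
#' @export
ik_settings <- function(tolerance = 1e-10, max_iterations = 100,
                        marker_weights = NULL, warm_start = TRUE,
                        restart_threshold = 0.01) {
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  if (!is.null(marker_weights)) {
    if (is.null(names(marker_weights)) || any(marker_weights < 0))
      stop("marker_weights must be named and non-negative", call. = FALSE)
    if (!any(marker_weights > 0))
      stop("at least one marker weight must be positive", call. = FALSE)
  }
  structure(list(tolerance = tolerance, max_iterations = max_iterations,
                 marker_weights = marker_weights, warm_start = warm_start,
                 restart_threshold = restart_threshold),
            class = "ik_settings")
}

# deterministic candidate grid for basin rescue: quartile levels of each
# free revolute coordinate's limits, other coordinates held at `par`;
# NULL when the grid would be unreasonably large
ik_candidate_grid <- function(model, free, par, max_candidates = 4096L) {
  lims <- list()
  for (j in model$joints)
    if (j$kind %in% c("revolute_z", "ball_zxy"))
      for (cc in j$coords)
        lims[[cc]] <- j$limits
  rot_free <- intersect(free, names(lims))
  if (!length(rot_free) || 3^length(rot_free) > max_candidates) return(NULL)
  levels <- lapply(rot_free, function(cc) {
    l <- lims[[cc]]
    l[1] + c(0.25, 0.5, 0.75) * (l[2] - l[1])
  })
  grid <- as.matrix(expand.grid(levels))
  out <- matrix(rep(par, each = nrow(grid)), nrow(grid),
                dimnames = list(NULL, names(par)))
  out[, rot_free] <- grid
  out
}

# label -> (segment, local position) lookup for all model markers
model_marker_table <- function(model) {
  out <- list()
  for (s in model$segments)
    for (lab in names(s$markers))
      out[[lab]] <- list(segment = s$name, local = s$markers[[lab]])
  out
}

#' Attach a marker to a model segment
#'
#' @param model a `kinematic_model`.
#' @param segment segment name.
#' @param label marker label (must not already exist on the segment).
#' @param local local 3-vector position (meters).
#' @return The modified model.
#' @export
add_marker <- function(model, segment, label, local) {
  if (!segment %in% names(model$segments))
    stop("unknown segment `", segment, "`", call. = FALSE)
  if (label %in% names(model$segments[[segment]]$markers))
    stop("marker `", label, "` already exists on `", segment, "`", call. = FALSE)
  model$segments[[segment]]$markers[[label]] <- as.numeric(local)
  model
}

#' Add a virtual midpoint marker
#'
#' Creates a new marker channel located frame-by-frame at the midpoint of
#' two existing markers (used to construct the virtual ankle marker Mk14
#' midway between Mk0 and Mk1); the originals are untouched.
#'
#' @param traj a [marker_trajectory()].
#' @param a,b labels of the two parent markers.
#' @param name label of the new marker.
#' @return The augmented [marker_trajectory()].
#' @export
add_virtual_midpoint_marker <- function(traj, a, b, name = "Mk14") {
  missing <- setdiff(c(a, b), names(traj$markers))
  if (length(missing))
    stop("missing marker(s): ", paste(missing, collapse = ", "), call. = FALSE)
  mk <- traj$markers
  mk[[name]] <- (mk[[a]] + mk[[b]]) / 2
  marker_trajectory(traj$time, mk)
}

#' Marker-based inverse kinematics
#'
#' For each frame, finds the free coordinate values minimizing the weighted
#' sum of squared distances between model-attached markers and their
#' measured positions, by damped (Levenberg-Marquardt) least squares with
#' warm starting from the previous frame. Coordinates not listed in `free`
#' are held at their `fixed` values (e.g. a frozen base pose, or hip
#' ab-adduction/rotation held at static values). Markers with `NaN`
#' positions in a frame are dropped from that frame's cost.
#'
#' @param model a `kinematic_model`.
#' @param markers a [marker_trajectory()]; labels shared with the model
#'   (and with positive weight) enter the cost.
#' @param settings an [ik_settings()].
#' @param free character vector of coordinate names to solve for.
#' @param fixed named numeric of coordinate values for the full model
#'   (defaults to zeros); free entries are used as the first frame's start.
#' @return An object of class `ik_result`: `trajectory` (a
#'   [joint_trajectory()] of the free coordinates, degrees),
#'   `per_frame_residual_rms` (meters) and `converged` flags.
#' @export
marker_ik <- function(model, markers, settings = ik_settings(),
                      free = model$coords, fixed = NULL) {
  stopifnot(inherits(markers, "marker_trajectory"))
  if (!all(free %in% model$coords))
    stop("unknown coordinate(s): ",
         paste(setdiff(free, model$coords), collapse = ", "), call. = FALSE)
  q <- stats::setNames(rep(0, length(model$coords)), model$coords)
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), model$coords)
    if (length(unknown))
      stop("unknown coordinate(s) in fixed: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    q[names(fixed)] <- fixed
  }
  table <- model_marker_table(model)
  labels <- intersect(names(table), names(markers$markers))
  w <- stats::setNames(rep(1, length(labels)), labels)
  if (!is.null(settings$marker_weights)) {
    shared <- intersect(names(settings$marker_weights), labels)
    w[shared] <- settings$marker_weights[shared]
  }
  labels <- labels[w[labels] > 0]
  if (!length(labels))
    stop("no weighted markers shared between model and data", call. = FALSE)
  sw <- sqrt(w[labels])
  segs <- vapply(labels, function(l) table[[l]]$segment, "")
  locs <- lapply(labels, function(l) table[[l]]$local)

  n <- n_frames(markers)
  nf <- length(free)
  sol <- matrix(NA_real_, n, nf, dimnames = list(NULL, free))
  rms <- numeric(n)
  conv <- logical(n)
  ctrl <- minpack.lm::nls.lm.control(maxiter = settings$max_iterations,
                                     ftol = 1e-15, ptol = 1e-13, gtol = 0)
  par <- q[free]
  for (i in seq_len(n)) {
    targets <- lapply(markers$markers[labels], function(m) m[i, ])
    usable <- vapply(targets, function(t) all(is.finite(t)), TRUE)
    if (sum(usable) < 3L)
      stop("underdetermined frame ", i, ": fewer than 3 usable markers",
           call. = FALSE)
    ul <- which(usable)
    fn <- function(p) {
      q[free] <- p
      fk <- forward_kinematics(model, q, warn_limits = FALSE)
      res <- numeric(3L * length(ul))
      k <- 0L
      for (j in ul) {
        pose <- fk[[segs[[j]]]]
        res[(k + 1L):(k + 3L)] <-
          sw[[j]] * (as.numeric(pose$R %*% locs[[j]]) + pose$p - targets[[j]])
        k <- k + 3L
      }
      res
    }
    # lmdif's finite-difference step scales with |par|: snap near-zero
    # warm starts to exactly zero so their gradient stays resolvable
    par[abs(par) < 1e-9] <- 0
    fit <- minpack.lm::nls.lm(par, fn = fn, control = ctrl)
    if (sqrt(fit$deviance / (3L * length(ul))) > settings$restart_threshold) {
      # likely a wrong basin: rescue with a deterministic coarse grid of
      # candidate revolute configurations, then re-solve from the best few
      cands <- ik_candidate_grid(model, free, par)
      if (!is.null(cands)) {
        devs <- vapply(seq_len(nrow(cands)),
                       function(r) sum(fn(cands[r, ])^2), 0)
        for (r in order(devs)[seq_len(min(3L, nrow(cands)))]) {
          refit <- minpack.lm::nls.lm(cands[r, ], fn = fn, control = ctrl)
          if (refit$deviance < fit$deviance) fit <- refit
        }
      }
    }
    sol[i, ] <- fit$par
    rms[i] <- sqrt(fit$deviance / (3L * length(ul)))
    conv[i] <- (fit$info %in% 1:3) || rms[i] <= settings$tolerance
    if (settings$warm_start) par <- fit$par else par <- q[free]
  }
  rot <- free[!grepl("_t[xyz]$", free)]
  for (ch in rot) sol[, ch] <- wrap_angle_deg(sol[, ch])
  structure(list(trajectory = joint_trajectory(markers$time,
                                               as.list(as.data.frame(sol))),
                 per_frame_residual_rms = rms,
                 converged = conv,
                 free = free, settings = settings),
            class = "ik_result")
}

#' @export
print.ik_result <- function(x, ...) {
  cat("marker IK result:", n_frames(x$trajectory), "frames,",
      length(x$free), "free coordinates\n")
  cat(sprintf("residual RMS: mean %.3g m, max %.3g m; %d/%d frames converged\n",
              mean(x$per_frame_residual_rms), max(x$per_frame_residual_rms),
              sum(x$converged), length(x$converged)))
  invisible(x)
}

#' Exoskeleton ankle angle from the Mk3-Mk14 marker line
#'
#' The exoskeleton sole carries no marker, so its ankle angle cannot be
#' observed by position matching (the ankle motor marker sits at the joint
#' center). Instead, the ankle plantar-dorsiflexion is computed from the
#' direction of the line joining the malleolus marker Mk3 to the virtual
#' mid-foot marker Mk14 (the foot is strapped to the sole), expressed in
#' the exoskeleton shank frame: the ankle angle at frame t is the static
#' reference value plus the rotation of that line about the joint Z axis
#' since the static posture. The returned series is therefore referenced
#' to the static calibration, consistently with the constraint anchors.
#'
#' @param coupled a `coupled_model`.
#' @param markers walking [marker_trajectory()] containing Mk3 and Mk14
#'   (Mk14 is added from Mk0/Mk1 if absent).
#' @param gt_traj [joint_trajectory()] of already-estimated coordinates
#'   (human angles plus exoskeleton hip/knee) used to pose the shank.
#' @param static_markers one-frame worn-static [marker_trajectory()].
#' @return Numeric vector of exoskeleton ankle angles in degrees.
#' @export
exo_ankle_from_markers <- function(coupled, markers, gt_traj, static_markers) {
  if (!"Mk14" %in% names(markers$markers))
    markers <- add_virtual_midpoint_marker(markers, "Mk0", "Mk1", "Mk14")
  if (!"Mk14" %in% names(static_markers$markers))
    static_markers <- add_virtual_midpoint_marker(static_markers, "Mk0", "Mk1",
                                                  "Mk14")
  line_angle <- function(shank_pose, mk3, mk14) {
    ds <- as.numeric(t(shank_pose$R) %*% (mk14 - mk3))
    rad2deg(atan2(ds[1], -ds[2]))
  }
  fk0 <- forward_kinematics(coupled$model, coupled$static_posture,
                            warn_limits = FALSE)
  sf <- marker_frame(static_markers, 1L)
  psi0 <- line_angle(fk0[["exo_shank"]], sf$Mk3, sf$Mk14)
  alpha0 <- coupled$static_posture[["exo_ankle_flexion"]]
  n <- n_frames(markers)
  out <- numeric(n)
  q <- coupled$static_posture
  ch <- gt_traj$channels
  for (i in seq_len(n)) {
    for (nm in names(ch)) q[[nm]] <- ch[[nm]][i]
    fk <- forward_kinematics(coupled$model, q, warn_limits = FALSE)
    psi <- line_angle(fk[["exo_shank"]],
                      markers$markers$Mk3[i, ], markers$markers$Mk14[i, ])
    out[i] <- alpha0 + wrap_angle_deg(psi - psi0)
  }
  out
}

#' Rigid baseline estimate of human joint angles
#'
#' The traditional assumption of zero human-exoskeleton relative motion:
#' the human sagittal joint angles are taken channel-for-channel equal to
#' the exoskeleton joint angles.
#'
#' @param v_R a [joint_trajectory()] with `hip_flexion`, `knee_flexion`
#'   and `ankle_flexion` channels (exoskeleton angles, degrees).
#' @return The same [joint_trajectory()], unchanged.
#' @export
rigid_estimate <- function(v_R) {
  stopifnot(inherits(v_R, "joint_trajectory"))
  missing <- setdiff(c("hip_flexion", "knee_flexion", "ankle_flexion"),
                     names(v_R$channels))
  if (length(missing))
    stop("schema error: missing channel(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  v_R
}
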