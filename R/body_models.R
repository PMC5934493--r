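#' Default segment lengths and marker layout for the generic human model
#'
#' Round mid-range adult values, all overridable. Twelve markers are
#' attached to the right lower limb following a standard gait protocol:
#' three foot markers (Mk0 calcaneus, Mk1 fifth metatarsal, Mk2 first
#' metatarsal), the lateral malleolus (Mk3), a three-marker shank cluster
#' (Mk4-Mk6), the lateral knee (Mk7), a three-marker thigh cluster
#' (Mk8-Mk10) and the greater trochanter (Mk11). Mk11, Mk7 and Mk3 lie on
#' the segment axes with equal lateral offsets, so in the upright posture
#' the Mk11-Mk7 and Mk7-Mk3 distances are longitudinal spans of the femur
#' and tibia, and Mk2-Mk1 spans a fixed longitudinal fraction of the
#' foot — the marker pairs used for subject scaling.
#'
#' @return Named numeric vector of segment lengths in meters.
#' @export
default_human_lengths <- function() {
  c(pelvis = 0.20, femur = 0.40, tibia = 0.38, foot = 0.25)
}

#' @rdname default_human_lengths
#' @param lengths named lengths as from `default_human_lengths()`.
#' @param axis_offsets heights (meters) of the hip, knee and ankle
#'   landmark markers above their joint axes. Anatomical landmarks do not
#'   coincide with joint centers — the greater trochanter sits ~5.5 cm
#'   above the hip center, the lateral knee marker ~1 cm below the knee
#'   flexion axis, the malleolus at the ankle axis — and the exoskeleton's
#'   joint axes are aligned to marker heights, so these offsets define the
#'   human-device axis misalignment. Zero offsets give an idealized
#'   subject whose device axes coincide with the joints.
#' @return For `default_human_markers`, a list mapping segment name to a
#'   named list of local marker 3-vectors (meters).
#' @export
default_human_markers <- function(lengths = default_human_lengths(),
                                  axis_offsets = c(hip = 0.055, knee = -0.010,
                                                   ankle = 0.000)) {
  lf <- lengths[["femur"]]; lt <- lengths[["tibia"]]; lo <- lengths[["foot"]]
  list(
    femur = list(
      Mk11 = c(0, axis_offsets[["hip"]], 0.08),
      Mk8 = c(0.04, -0.15 * lf / 0.40, 0.07),
      Mk9 = c(0.02, -0.22 * lf / 0.40, 0.08),
      Mk10 = c(0.05, -0.28 * lf / 0.40, 0.06),
      Mk7 = c(0, -lf + axis_offsets[["knee"]], 0.08)),
    tibia = list(
      Mk4 = c(0.03, -0.12 * lt / 0.38, 0.06),
      Mk5 = c(0.01, -0.18 * lt / 0.38, 0.07),
      Mk6 = c(0.04, -0.24 * lt / 0.38, 0.05),
      Mk3 = c(0, -lt + axis_offsets[["ankle"]], 0.08)),
    foot = list(
      Mk0 = c(-0.05, -0.03 * lo / 0.25, 0.02),
      Mk2 = c(0, -0.40 * lo, 0.03),
      Mk1 = c(0, -lo, 0.03)))
}

HUMAN_MARKERS <- paste0("Mk", c(0:11))
HUMAN_COORDS <- c("hip_flexion", "knee_flexion", "ankle_flexion")
EXO_COORDS <- c("exo_hip_flexion", "exo_knee_flexion", "exo_ankle_flexion")
BASE_COORDS <- paste0("base_", c("tx", "ty", "tz", "rx", "ry", "rz"))

# hip joint center in the pelvis frame (right side)
hip_center_pelvis <- function() c(0, -0.05, 0.09)
# exoskeleton hip joint center in the corset frame
hip_center_corset <- function() c(0, -0.05, 0.12)

#' Build the generic human right-lower-limb model
#'
#' A kinematic tree: ground -> pelvis (free 6-DOF joint, coordinates
#' `base_tx` ... `base_rz`), then right hip, knee and ankle sagittal
#' revolute joints (`hip_flexion`, `knee_flexion`, `ankle_flexion`,
#' degrees). Hip ab-adduction and axial rotation enter forward kinematics
#' as frozen constants (`hip_adduction`, `hip_rotation` arguments), not as
#' coordinates; they are held at their static-posture values during
#' estimation.
#'
#' @param lengths named segment lengths (meters); see
#'   [default_human_lengths()].
#' @param markers marker layout as from [default_human_markers()].
#' @param hip_adduction,hip_rotation frozen hip angles in degrees.
#' @return A `kinematic_model` with attribute metadata; the twelve markers
#'   Mk0-Mk11 are attached in segment-local frames.
#' @export
build_generic_human <- function(lengths = default_human_lengths(),
                                markers = default_human_markers(lengths),
                                hip_adduction = 0, hip_rotation = 0) {
  if (any(lengths <= 0)) stop("segment lengths must be > 0", call. = FALSE)
  have <- unlist(lapply(markers, names), use.names = FALSE)
  missing <- setdiff(HUMAN_MARKERS, have)
  if (length(missing))
    stop("model definition error: marker layout is missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  segs <- list(
    segment("pelvis", lengths[["pelvis"]]),
    segment("femur", lengths[["femur"]], markers$femur),
    segment("tibia", lengths[["tibia"]], markers$tibia),
    segment("foot", lengths[["foot"]], markers$foot))
  jts <- list(
    joint("base", "free6", "ground", "pelvis"),
    joint("hip_flexion", "revolute_z", "pelvis", "femur",
          parent_xf = rt_translation(hip_center_pelvis()),
          limits = c(-30, 130),
          fixed_rx = hip_adduction, fixed_ry = hip_rotation),
    joint("knee_flexion", "revolute_z", "femur", "tibia",
          parent_xf = rt_translation(c(0, -lengths[["femur"]], 0)),
          limits = c(-10, 140)),
    joint("ankle_flexion", "revolute_z", "tibia", "foot",
          parent_xf = rt_translation(c(0, -lengths[["tibia"]], 0)),
          limits = c(-60, 60)))
  m <- kinematic_model(segs, jts)
  m$meta <- list(kind = "human", hip_adduction = hip_adduction,
                 hip_rotation = hip_rotation)
  m
}

#' Scale factors for subject-specific model personalization
#'
#' @param femur,tibia,foot dimensionless positive factors applied along
#'   each segment's longitudinal (Y) axis.
#' @param manual_overrides optional named list segment -> factor taking
#'   precedence over the computed factor for that segment (the config-file
#'   replacement for a visual-inspection correction step).
#' @return An object of class `scale_factors`.
#' @export
scale_factors <- function(femur = 1, tibia = 1, foot = 1,
                          manual_overrides = list()) {
  f <- c(femur = femur, tibia = tibia, foot = foot)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("scale factors must be finite and > 0", call. = FALSE)
  if (length(manual_overrides)) {
    ov <- unlist(manual_overrides)
    if (any(!is.finite(ov)) || any(ov <= 0))
      stop("manual overrides must be finite and > 0", call. = FALSE)
  }
  structure(list(femur = femur, tibia = tibia, foot = foot,
                 manual_overrides = manual_overrides),
            class = "scale_factors")
}

#' @export
print.scale_factors <- function(x, ...) {
  cat(sprintf("scale factors: femur %.4f, tibia %.4f, foot %.4f\n",
              x$femur, x$tibia, x$foot))
  if (length(x$manual_overrides))
    cat("manual overrides:",
        paste(names(x$manual_overrides), unlist(x$manual_overrides),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

scaling_pairs <- list(femur = c("Mk11", "Mk7"),
                      tibia = c("Mk7", "Mk3"),
                      foot = c("Mk2", "Mk1"))

#' Compute subject scale factors from a static capture
#'
#' Each factor is the measured marker-pair distance divided by the model's
#' marker-pair distance at the neutral pose: femur from Mk11-Mk7, tibia
#' from Mk7-Mk3, foot from Mk2-Mk1. The static trial is captured without
#' the exoskeleton.
#'
#' @param static_markers a one-frame (or first-frame) [marker_trajectory()]
#'   of the static upright trial without exoskeleton.
#' @param model the generic human model from [build_generic_human()].
#' @return A [scale_factors()] object.
#' @export
compute_scale_factors <- function(static_markers, model) {
  frame <- marker_frame(static_markers, 1L)
  needed <- unique(unlist(scaling_pairs))
  missing <- needed[!needed %in% names(frame)]
  if (length(missing))
    stop("missing marker(s) in static trial: ",
         paste(missing, collapse = ", "), call. = FALSE)
  q0 <- stats::setNames(rep(0, length(model$coords)), model$coords)
  pos <- marker_positions(model, q0, warn_limits = FALSE)
  f <- lapply(scaling_pairs, function(pair) {
    model_d <- sqrt(sum((pos[pair[1], ] - pos[pair[2], ])^2))
    if (model_d < 1e-12)
      stop("degenerate model: zero distance between ",
           pair[1], " and ", pair[2], call. = FALSE)
    meas_d <- sqrt(sum((frame[[pair[1]]] - frame[[pair[2]]])^2))
    meas_d / model_d
  })
  scale_factors(f$femur, f$tibia, f$foot)
}

#' Apply scale factors to the human model
#'
#' Segment lengths, local marker Y offsets and distal joint attachment
#' points are scaled along each segment's longitudinal axis; anterior and
#' lateral marker offsets are unchanged. Manual overrides take precedence
#' per segment.
#'
#' @param model a [build_generic_human()] model.
#' @param f a [scale_factors()] object.
#' @return The scaled model.
#' @export
apply_scaling <- function(model, f) {
  stopifnot(inherits(f, "scale_factors"))
  for (seg in c("femur", "tibia", "foot")) {
    fac <- if (!is.null(f$manual_overrides[[seg]])) f$manual_overrides[[seg]]
           else f[[seg]]
    if (!is.finite(fac) || fac <= 0)
      stop("scale factor for ", seg, " must be finite and > 0", call. = FALSE)
    if (fac == 1) next
    s <- model$segments[[seg]]
    s$length <- s$length * fac
    s$markers <- lapply(s$markers, function(m) { m[2] <- m[2] * fac; m })
    model$segments[[seg]] <- s
    for (k in seq_along(model$joints)) {
      if (model$joints[[k]]$parent == seg) {
        xf <- model$joints[[k]]$parent_xf
        xf$p[2] <- xf$p[2] * fac
        model$joints[[k]]$parent_xf <- xf
      }
    }
  }
  model
}

#' Build the exoskeleton kinematic model
#'
#' A sagittal-plane device for the right leg: corset (root), thigh link,
#' shank link and sole connected by hip, knee and ankle revolute joints
#' whose Z axes are all parallel. Link lengths are adjustable (the physical
#' device has extensible plates). Five markers sit on the centre-outside
#' surfaces of the hip, knee and ankle motors and at the midpoints of the
#' thigh and shank bars.
#'
#' @param link_lengths named vector `c(thigh=, shank=, sole=)` in meters.
#' @return A `kinematic_model` with coordinates `base_*` (corset pose) and
#'   `exo_hip_flexion`, `exo_knee_flexion`, `exo_ankle_flexion` (degrees).
#' @export
build_exo_model <- function(link_lengths = c(thigh = 0.40, shank = 0.38,
                                             sole = 0.25)) {
  if (any(link_lengths <= 0)) stop("link lengths must be > 0", call. = FALSE)
  lt <- link_lengths[["thigh"]]; ls <- link_lengths[["shank"]]
  lo <- link_lengths[["sole"]]
  segs <- list(
    segment("corset", 0.25, list(ExoHip = hip_center_corset() + c(0, 0, 0.03))),
    segment("exo_thigh", lt, list(ExoThighBar = c(0, -lt / 2, 0.02),
                                  ExoKnee = c(0, -lt, 0.03))),
    segment("exo_shank", ls, list(ExoShankBar = c(0, -ls / 2, 0.02),
                                  ExoAnkle = c(0, -ls, 0.03))),
    segment("exo_sole", lo))
  jts <- list(
    joint("base", "free6", "ground", "corset"),
    joint("exo_hip_flexion", "revolute_z", "corset", "exo_thigh",
          parent_xf = rt_translation(hip_center_corset()), limits = c(-40, 120)),
    joint("exo_knee_flexion", "revolute_z", "exo_thigh", "exo_shank",
          parent_xf = rt_translation(c(0, -lt, 0)), limits = c(-10, 120)),
    joint("exo_ankle_flexion", "revolute_z", "exo_shank", "exo_sole",
          parent_xf = rt_translation(c(0, -ls, 0)), limits = c(-45, 45)))
  m <- kinematic_model(segs, jts)
  m$meta <- list(kind = "exo", link_lengths = c(thigh = lt, shank = ls, sole = lo))
  m
}

#' Adjust exoskeleton link lengths from a worn static capture
#'
#' Sets the thigh and shank link lengths so that the hip, knee and ankle
#' joint axes sit at the heights (world Y in the static upright frame)
#' indicated by markers Mk11, Mk7 and Mk3; sole geometry is unchanged.
#'
#' @param exo a [build_exo_model()] model.
#' @param static_markers_with_exo one-frame [marker_trajectory()] of the
#'   static trial with the exoskeleton worn (Mk11/Mk7/Mk3 visible).
#' @return The adjusted exoskeleton model.
#' @export
adjust_exo_links <- function(exo, static_markers_with_exo) {
  frame <- marker_frame(static_markers_with_exo, 1L)
  need <- c("Mk11", "Mk7", "Mk3")
  missing <- need[!need %in% names(frame)]
  if (length(missing))
    stop("missing marker(s) in worn static trial: ",
         paste(missing, collapse = ", "), call. = FALSE)
  h <- vapply(frame[need], `[`, 0, 2L)
  if (!(h[["Mk11"]] > h[["Mk7"]] && h[["Mk7"]] > h[["Mk3"]]))
    stop("implausible static pose: marker heights must satisfy Mk11 > Mk7 > Mk3",
         call. = FALSE)
  build_exo_model(c(thigh = h[["Mk11"]] - h[["Mk7"]],
                    shank = h[["Mk7"]] - h[["Mk3"]],
                    sole = exo$meta$link_lengths[["sole"]]))
}

#' Standard base pose used for static captures
#'
#' World pose of the root body in the static upright trial: upright
#' orientation, hip level at about 1.05 m.
#'
#' @return Named coordinate vector for the 6 base coordinates.
#' @export
standard_base_pose <- function() {
  stats::setNames(c(0, 1.10, 0, 0, 0, 0), BASE_COORDS)
}

# weld translation placing the pelvis in the corset frame: hip joint
# centers aligned along the anterior-posterior (X) axis; vertically the
# exoskeleton hip axis sits at the trochanter marker (Mk11) height, i.e.
# `hip_drop` above the human hip center (the link-adjustment rule places
# all device axes at marker heights). The natural lateral (Z) clearance
# between the device and the leg is kept.
pelvis_corset_weld <- function(hip_drop = 0.040) {
  e <- hip_center_corset(); h <- hip_center_pelvis()
  rt_translation(c(e[1] - h[1], e[2] - h[2] - hip_drop, 0))
}

# Mk11 height above the hip center in a (possibly scaled) human model
mk11_hip_drop <- function(human) human$segments[["femur"]]$markers[["Mk11"]][2]

# merge a human and an exoskeleton model into one tree rooted at the
# corset, with the pelvis welded to the corset; static posture supplied
# directly (used by the synthetic generator, where the truth is known, and
# by assemble_coupled after solving it by IK).
couple_models <- function(human, exo, static_angles, static_exo_angles,
                          base_pose = standard_base_pose(),
                          weld_xf = NULL,
                          static_flag = FALSE, static_residual_rms = 0) {
  if (is.null(weld_xf)) weld_xf <- pelvis_corset_weld(mk11_hip_drop(human))
  segs <- c(unname(exo$segments), unname(human$segments))
  human_jts <- Filter(function(j) j$kind != "free6", human$joints)
  weld <- joint("pelvis_corset", "weld", "corset", "pelvis",
                parent_xf = weld_xf)
  jts <- c(exo$joints, list(weld), human_jts)
  model <- kinematic_model(segs, jts)
  if (!is.null(names(static_angles))) static_angles <- static_angles[HUMAN_COORDS]
  if (!is.null(names(static_exo_angles)) && all(EXO_COORDS %in% names(static_exo_angles)))
    static_exo_angles <- static_exo_angles[EXO_COORDS]
  static_q <- c(base_pose,
                stats::setNames(as.numeric(static_angles), HUMAN_COORDS),
                stats::setNames(as.numeric(static_exo_angles), EXO_COORDS))
  structure(list(model = model,
                 human_coords = HUMAN_COORDS,
                 exo_coords = EXO_COORDS,
                 base_coords = BASE_COORDS,
                 static_posture = static_q,
                 hip_adduction = human$meta$hip_adduction,
                 hip_rotation = human$meta$hip_rotation,
                 pelvis_corset_offset = weld$parent_xf,
                 poor_initialization = static_flag,
                 static_residual_rms = static_residual_rms),
            class = "coupled_model")
}

#' @export
print.coupled_model <- function(x, ...) {
  cat("coupled human-exoskeleton model\n")
  cat("static posture (deg):",
      paste(sprintf("%s=%.2f", x$human_coords,
                    x$static_posture[x$human_coords]), collapse = ", "), "\n")
  cat(sprintf("frozen hip adduction %.2f deg, rotation %.2f deg\n",
              x$hip_adduction, x$hip_rotation))
  if (x$poor_initialization)
    cat("NOTE: static calibration flagged as poor initialization (residual RMS ",
        format(x$static_residual_rms, digits = 3), " m)\n", sep = "")
  invisible(x)
}

#' Full coordinate vector for the coupled model
#'
#' @param coupled a `coupled_model`.
#' @param human named or positional human angles (hip, knee, ankle; degrees).
#' @param exo exoskeleton angles (hip, knee, ankle; degrees).
#' @param base base (corset) pose coordinates; defaults to the static pose.
#' @return Named coordinate vector for `coupled$model`.
#' @export
coupled_q <- function(coupled, human = NULL, exo = NULL, base = NULL) {
  q <- coupled$static_posture
  if (!is.null(human)) q[coupled$human_coords] <- as.numeric(human)
  if (!is.null(exo)) q[coupled$exo_coords] <- as.numeric(exo)
  if (!is.null(base)) q[coupled$base_coords] <- as.numeric(base)
  q
}

#' Assemble the coupled human-exoskeleton model
#'
#' Welds the (scaled) human pelvis to the exoskeleton corset so that the
#' hip joint rotation centers match along the anterior-posterior axis, then
#' solves the static posture by marker IK on the worn static frame: hip
#' flexion/ab-adduction/axial rotation, knee and ankle flexion of the
#' human, and the three exoskeleton angles. Ab-adduction and rotation are
#' then frozen at their static values for all subsequent estimation. If the
#' static IK residual RMS exceeds `residual_threshold` the model is flagged
#' (`poor_initialization = TRUE`) — the automated stand-in for a manual
#' revision step — and assembly proceeds.
#'
#' @param human scaled human model ([apply_scaling()]).
#' @param exo adjusted exoskeleton model ([adjust_exo_links()]).
#' @param static_markers_with_exo one-frame [marker_trajectory()], worn
#'   static trial.
#' @param base_pose known world pose of the corset in the static trial
#'   (the marker protocol has no pelvis/corset cluster, so the static base
#'   is registered externally; defaults to [standard_base_pose()]).
#' @param settings [ik_settings()] for the static solve.
#' @param residual_threshold static residual RMS (meters) above which the
#'   poor-initialization flag is set.
#' @return A `coupled_model`.
#' @export
assemble_coupled <- function(human, exo, static_markers_with_exo,
                             base_pose = standard_base_pose(),
                             settings = ik_settings(),
                             residual_threshold = 0.01) {
  # temporary coupled model in which the frozen hip angles are coordinates
  human_free <- human
  for (k in seq_along(human_free$joints)) {
    if (human_free$joints[[k]]$name == "hip_flexion") {
      human_free$joints[[k]]$fixed_rx <- 0
      human_free$joints[[k]]$fixed_ry <- 0
    }
  }
  tmp <- couple_models(human_free, exo,
                       static_angles = stats::setNames(rep(0, 3), HUMAN_COORDS),
                       static_exo_angles = rep(0, 3), base_pose = base_pose)
  # splice ball-joint hip coordinates for the static solve
  model <- tmp$model
  for (k in seq_along(model$joints)) {
    if (model$joints[[k]]$name == "hip_flexion") {
      model$joints[[k]]$kind <- "ball_zxy"
      model$joints[[k]]$coords <- c("hip_flexion", "hip_adduction", "hip_rotation")
    }
  }
  model$coords <- unlist(lapply(model$joints, `[[`, "coords"), use.names = FALSE)
  # free coordinates: the junction (base) translations plus the human and
  # exoskeleton angles. Base rotations stay at the registered capture
  # orientation: with no pelvis or corset marker cluster, a rotation about
  # the shared hip axis is exactly compensated by the hip and exo-hip
  # angles (a gauge freedom), so a worn-corset tilt is absorbed as a
  # common constant in both hip channels — consistently for calibration,
  # ground truth and estimation. The exoskeleton ankle is excluded: with
  # no marker on the sole it is unobservable in the static frame and is
  # referenced to zero, under the same consistency argument.
  angles <- c("hip_flexion", "hip_adduction", "hip_rotation",
              "knee_flexion", "ankle_flexion",
              "exo_hip_flexion", "exo_knee_flexion")
  free <- c(paste0("base_t", c("x", "y", "z")), angles)
  fixed <- c(base_pose, stats::setNames(rep(0, length(angles)), angles))
  fit <- marker_ik(model, static_markers_with_exo, settings = settings,
                   free = free, fixed = fixed)
  sol <- vapply(fit$trajectory$channels, `[`, 0, 1L)
  tr <- paste0("base_t", c("x", "y", "z"))
  base_pose[tr] <- sol[tr]
  rms <- fit$per_frame_residual_rms[1L]
  flag <- rms > residual_threshold
  if (flag)
    warning("static calibration residual RMS ", format(rms, digits = 3),
            " m exceeds threshold ", residual_threshold,
            " m; poor initialization flagged", call. = FALSE)
  human_frozen <- human
  for (k in seq_along(human_frozen$joints)) {
    if (human_frozen$joints[[k]]$name == "hip_flexion") {
      human_frozen$joints[[k]]$fixed_rx <- sol[["hip_adduction"]]
      human_frozen$joints[[k]]$fixed_ry <- sol[["hip_rotation"]]
    }
  }
  human_frozen$meta$hip_adduction <- sol[["hip_adduction"]]
  human_frozen$meta$hip_rotation <- sol[["hip_rotation"]]
  couple_models(human_frozen, exo,
                static_angles = sol[HUMAN_COORDS],
                static_exo_angles = c(sol[["exo_hip_flexion"]],
                                      sol[["exo_knee_flexion"]], 0),
                base_pose = base_pose,
                static_flag = flag, static_residual_rms = rms)
}
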