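# evaluate code with a local, restored RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Fourier coefficients of the default synthetic gait profile
#'
#' Smooth periodic sagittal joint-angle curves emulating slow treadmill
#' walking (about 1 km/h): each channel is
#' `mean + sum_k amp_k * cos(2*pi*k*cadence*t - phase_k)` in degrees.
#' Default amplitudes give ranges typical of slow gait: hip about -10 to
#' 25 degrees, knee about 0 to 60, ankle about -15 to 10.
#'
#' @return Named list of per-joint `list(mean, amp, phase)` coefficients
#'   (degrees; phases in radians).
#' @export
default_gait_coefficients <- function() {
  list(hip_flexion = list(mean = 7.5, amp = 17.5, phase = 0),
       knee_flexion = list(mean = 28, amp = c(25.07, 9.72),
                           phase = c(5.89, 0.44)),
       ankle_flexion = list(mean = -2.5, amp = c(8.61, 5.78),
                            phase = c(0.97, 0.37)))
}

#' Synthetic gait profile parameters
#'
#' @param duration trial length in seconds.
#' @param rate sampling rate in Hz.
#' @param cadence stride frequency in strides/s (0.5 matches slow
#'   treadmill walking at about 1 km/h).
#' @param coefficients per-joint Fourier coefficients; see
#'   [default_gait_coefficients()].
#' @param seed integer seed (the profile itself is deterministic; the seed
#'   is recorded for provenance).
#' @return An object of class `gait_profile_params`.
#' @export
gait_profile_params <- function(duration = 10, rate = 100, cadence = 0.5,
                                coefficients = default_gait_coefficients(),
                                seed = 1L) {
  if (duration <= 0 || rate <= 0 || cadence <= 0)
    stop("duration, rate and cadence must be > 0", call. = FALSE)
  structure(list(duration = duration, rate = rate, cadence = cadence,
                 coefficients = coefficients, seed = as.integer(seed)),
            class = "gait_profile_params")
}

#' Generate the ground-truth human gait profile
#'
#' @param p a [gait_profile_params()].
#' @return A [joint_trajectory()] with `hip_flexion`, `knee_flexion` and
#'   `ankle_flexion` channels (degrees); deterministic given `p`.
#' @export
generate_gait_profile <- function(p = gait_profile_params()) {
  stopifnot(inherits(p, "gait_profile_params"))
  n <- round(p$duration * p$rate)
  t <- (seq_len(n) - 1) / p$rate
  channels <- lapply(p$coefficients, function(co) {
    v <- rep(co$mean, n)
    for (k in seq_along(co$amp))
      v <- v + co$amp[k] * cos(2 * pi * k * p$cadence * t - co$phase[k])
    v
  })
  joint_trajectory(t, channels)
}

#' Soft-tissue / relative-motion surrogate parameters
#'
#' The exoskeleton never tracks the limb exactly: straps and soft tissue
#' introduce a per-joint affine distortion plus lag and slow random drift.
#' The surrogate maps each ground-truth human channel to the exoskeleton
#' channel as `gain * v_H(t - lag) + offset + smooth noise` (lag applied
#' as a periodic shift).
#'
#' @param offset per-joint additive offsets, degrees (`hip`, `knee`,
#'   `ankle`); used by the affine surrogate [derive_exo_motion()].
#' @param gain per-joint multiplicative gains (> 0); affine surrogate.
#' @param lag per-joint lags in seconds; affine surrogate.
#' @param corset_shift worn-geometry misalignment: anterior (x) and
#'   vertical (y) displacement, in meters, of the corset on the pelvis
#'   relative to ideal hip-center alignment.
#' @param corset_tilt sagittal tilt (degrees) of the worn corset.
#' @param thigh_link_delta,shank_link_delta physical device link lengths
#'   minus the subject's segment lengths (meters; extensible plates adjust
#'   in coarse steps, so an exact match is unlikely).
#' @param attachment_jitter_sd standard deviation (meters) of a constant
#'   per-trial perturbation of the exoskeleton marker attachments.
#' @param marker_noise_sd per-frame Gaussian marker noise, meters.
#' @param angle_noise_sd standard deviation (degrees) of the smooth
#'   band-limited compliance noise added to each exoskeleton channel.
#' @param seed integer seed driving every random draw.
#' @return An object of class `soft_tissue_params`.
#' @export
soft_tissue_params <- function(offset = c(hip = 0, knee = 0, ankle = 0),
                               gain = c(hip = 1, knee = 1, ankle = 1),
                               lag = c(hip = 0, knee = 0, ankle = 0),
                               corset_shift = c(x = 0, y = 0),
                               corset_tilt = 0,
                               thigh_link_delta = 0,
                               shank_link_delta = 0,
                               attachment_jitter_sd = 0,
                               marker_noise_sd = 0,
                               angle_noise_sd = 0,
                               seed = 1L) {
  full <- function(x, default) {
    out <- c(hip = default, knee = default, ankle = default)
    if (is.null(names(x))) out[] <- rep(as.numeric(x), length.out = 3)
    else out[names(x)] <- x
    out
  }
  offset <- full(offset, 0); gain <- full(gain, 1); lag <- full(lag, 0)
  if (any(gain <= 0)) stop("gains must be > 0", call. = FALSE)
  if (attachment_jitter_sd < 0 || marker_noise_sd < 0 || angle_noise_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  corset_shift <- stats::setNames(rep(as.numeric(corset_shift),
                                      length.out = 2), c("x", "y"))
  structure(list(offset = offset, gain = gain, lag = lag,
                 corset_shift = corset_shift, corset_tilt = corset_tilt,
                 thigh_link_delta = thigh_link_delta,
                 shank_link_delta = shank_link_delta,
                 attachment_jitter_sd = attachment_jitter_sd,
                 marker_noise_sd = marker_noise_sd,
                 angle_noise_sd = angle_noise_sd,
                 seed = as.integer(seed)),
            class = "soft_tissue_params")
}

# TRUE if the worn-device geometry deviates from ideal alignment
has_device_mismatch <- function(s) {
  any(s$corset_shift != 0) || s$corset_tilt != 0 ||
    s$thigh_link_delta != 0 || s$shank_link_delta != 0
}

#' Soft-tissue presets
#'
#' `"none"` disables all fitting error and noise (an ideally fitted,
#' ideally tracking device). `"misaligned"` is the default study
#' condition, adding worn-geometry imperfection on top of the anatomical
#' axis offsets: the belt-mounted corset sits 3 mm anterior and 2 mm low
#' with a 0.5-degree sagittal tilt, the device thigh and shank links are
#' 2 mm long and 1.5 mm short of their marker-height settings
#' (extensible-plate adjustment error), with 0.3 degrees of smooth
#' strap-compliance noise on each exoskeleton channel and 1 mm marker
#' noise. The exoskeleton motion is derived by closure of the worn-device
#' constraints; the rigid baseline then errs most at the knee, the joint
#' where human-device misalignment during gait is largest.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return A [soft_tissue_params()] object.
#' @export
soft_tissue_preset <- function(name = c("misaligned", "none"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    none = soft_tissue_params(seed = seed),
    misaligned = soft_tissue_params(
      corset_shift = c(x = 0.003, y = -0.002),
      corset_tilt = 0.5,
      thigh_link_delta = 0.002,
      shank_link_delta = -0.0015,
      marker_noise_sd = 0.001,
      angle_noise_sd = 0.3,
      seed = seed))
}

# circular shift: y[i] = x[i - k], indices mod n
circular_shift <- function(x, k) {
  n <- length(x)
  if (n == 0L || k %% n == 0L) return(x)
  k <- k %% n
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

# band-limited unit-variance noise: white noise smoothed by a circular
# Gaussian kernel (sd ~0.15 s), rescaled
smooth_noise <- function(n, rate, sd) {
  z <- stats::rnorm(n)
  if (n < 3L) return(z * sd)
  half <- max(1L, min(round(0.15 * rate), (n - 1L) %/% 6L))
  k <- stats::dnorm(seq(-3 * half, 3 * half), sd = half)
  sm <- as.numeric(stats::filter(z, k / sum(k), circular = TRUE))
  s <- stats::sd(sm)
  if (is.na(s) || s == 0) return(rep(0, n))
  sm * (sd / s)
}

#' Derive exoskeleton motion from human motion
#'
#' Applies the soft-tissue surrogate channel-by-channel:
#' `v_R_j(t) = gain_j * v_H_j(t - lag_j) + offset_j + smooth noise`.
#'
#' @param v_H ground-truth human [joint_trajectory()].
#' @param s a [soft_tissue_params()].
#' @return The exoskeleton [joint_trajectory()] (same channels and grid).
#' @export
derive_exo_motion <- function(v_H, s = soft_tissue_params()) {
  stopifnot(inherits(v_H, "joint_trajectory"), inherits(s, "soft_tissue_params"))
  rate <- v_H$rate
  n <- n_frames(v_H)
  with_seed(s$seed, {
    channels <- lapply(c(hip = "hip", knee = "knee", ankle = "ankle"),
                       function(j) {
      x <- v_H$channels[[paste0(j, "_flexion")]]
      k <- round(s$lag[[j]] * rate)
      y <- circular_shift(x, k)
      if (s$gain[[j]] != 1) y <- s$gain[[j]] * y
      if (s$offset[[j]] != 0) y <- y + s$offset[[j]]
      if (s$angle_noise_sd > 0) y <- y + smooth_noise(n, rate, s$angle_noise_sd)
      y
    })
    names(channels) <- paste0(c("hip", "knee", "ankle"), "_flexion")
    joint_trajectory(v_H$time, channels)
  })
}

EXO_MARKERS <- c("ExoHip", "ExoThighBar", "ExoKnee", "ExoShankBar", "ExoAnkle")

#' Marker labels of a with-exoskeleton walking trial
#'
#' The anatomical markers on the hip (Mk11) and knee (Mk7) are removed
#' before the exoskeleton is donned (its frame would occlude them); the
#' malleolus marker Mk3 is kept — it is needed, together with the virtual
#' mid-foot marker Mk14, to resolve the exoskeleton ankle angle. Walking
#' trials therefore record ten human markers plus the five exoskeleton
#' markers.
#' @export
walking_marker_labels <- function() {
  c(setdiff(HUMAN_MARKERS, c("Mk7", "Mk11")), EXO_MARKERS)
}

#' Synthesize a motion-capture record from a coupled model
#'
#' Forward kinematics of the human chain under `v_H` and the exoskeleton
#' chain under `v_R` (shared base), emitting every model marker with
#' optional seeded Gaussian noise. One-frame trajectories give static
#' trials.
#'
#' @param coupled a `coupled_model` (the generating truth).
#' @param v_H,v_R human and exoskeleton [joint_trajectory()] objects of
#'   equal length and rate.
#' @param s a [soft_tissue_params()] (only its noise fields and seed are
#'   used here).
#' @param labels optional subset of marker labels to emit.
#' @return A [marker_trajectory()].
#' @export
synthesize_marker_data <- function(coupled, v_H, v_R,
                                   s = soft_tissue_params(),
                                   labels = NULL) {
  stopifnot(inherits(coupled, "coupled_model"))
  if (n_frames(v_H) != n_frames(v_R) ||
      (!is.na(v_H$rate) && !is.na(v_R$rate) &&
       abs(v_H$rate - v_R$rate) > 1e-6))
    stop("schema error: v_H and v_R must share length and rate", call. = FALSE)
  model <- coupled$model
  with_seed(s$seed, {
    if (s$attachment_jitter_sd > 0) {
      for (seg in c("corset", "exo_thigh", "exo_shank", "exo_sole")) {
        mk <- model$segments[[seg]]$markers
        model$segments[[seg]]$markers <- lapply(mk, function(m)
          m + stats::rnorm(3, sd = s$attachment_jitter_sd))
      }
    }
    table <- model_marker_table(model)
    if (is.null(labels)) labels <- names(table)
    missing <- setdiff(labels, names(table))
    if (length(missing))
      stop("unknown marker label(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    n <- n_frames(v_H)
    h <- do.call(cbind, v_H$channels[HUMAN_COORDS])
    r <- do.call(cbind, v_R$channels[HUMAN_COORDS])
    mats <- stats::setNames(lapply(labels, function(l) matrix(0, n, 3)), labels)
    for (i in seq_len(n)) {
      q <- coupled_q(coupled, human = h[i, ], exo = r[i, ])
      fk <- forward_kinematics(model, q, warn_limits = FALSE)
      for (l in labels) {
        e <- table[[l]]
        mats[[l]][i, ] <- rt_apply(fk[[e$segment]], e$local)
      }
    }
    if (s$marker_noise_sd > 0)
      for (l in labels)
        mats[[l]] <- mats[[l]] + matrix(stats::rnorm(3 * n, sd = s$marker_noise_sd),
                                        n, 3)
    marker_trajectory(v_H$time, mats)
  })
}

# static configuration of the worn device: with the corset fixed on the
# pelvis, the exoskeleton angles settle where the straps hold the device
# -- shank bar along the tibia, sole flush under and aligned with the
# foot. These residuals define the donning fit in the sagittal plane.
align_device_static <- function(coupled) {
  model <- coupled$model
  lo_h <- model$segments[["foot"]]$length
  lo_e <- model$segments[["exo_sole"]]$length
  q <- coupled$static_posture
  fn <- function(e) {
    q[coupled$exo_coords] <- e
    fk <- forward_kinematics(model, q, warn_limits = FALSE)
    c(fk[["exo_shank"]]$R[1:2, 2] - fk[["tibia"]]$R[1:2, 2],
      fk[["exo_sole"]]$R[1:2, 2] - fk[["foot"]]$R[1:2, 2],
      rt_apply(fk[["exo_sole"]], c(0, -lo_e / 2, 0))[1:2] -
        rt_apply(fk[["foot"]], c(0, -lo_h / 2, 0))[1:2])
  }
  fit <- minpack.lm::nls.lm(rep(0, 3), fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  stats::setNames(fit$par, coupled$exo_coords)
}

# per-frame least-squares closure of the true worn-device constraints:
# given the human angles, solve the exoskeleton angles (the physical
# device follows the limb through its fixations)
solve_exo_closure <- function(coupled, cs, v_H) {
  model <- coupled$model
  jts <- stats::setNames(model$joints, vapply(model$joints, `[[`, "", "name"))
  hipj <- jts[["exo_hip_flexion"]]; kneej <- jts[["exo_knee_flexion"]]
  anklej <- jts[["exo_ankle_flexion"]]
  n <- n_frames(v_H)
  hmat <- do.call(cbind, v_H$channels[HUMAN_COORDS])
  sol <- matrix(NA_real_, n, 3, dimnames = list(NULL, coupled$exo_coords))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-15, ptol = 1e-13,
                                     gtol = 0)
  par <- as.numeric(coupled$static_posture[coupled$exo_coords])
  q0 <- coupled$static_posture
  for (i in seq_len(n)) {
    q0[coupled$human_coords] <- hmat[i, ]
    fk <- forward_kinematics(model, q0, warn_limits = FALSE)
    hip_base <- rt_compose(fk[["corset"]], hipj$parent_xf)
    knee_p <- kneej$parent_xf$p
    ankle_p <- anklej$parent_xf$p
    fn <- function(e) {
      thigh <- new_rt(hip_base$R %*% rot_z(e[1L]), hip_base$p)
      shank <- new_rt(thigh$R %*% rot_z(e[2L]),
                      as.numeric(thigh$R %*% knee_p) + thigh$p)
      sole <- new_rt(shank$R %*% rot_z(e[3L]),
                     as.numeric(shank$R %*% ankle_p) + shank$p)
      fk[["exo_thigh"]] <- thigh; fk[["exo_shank"]] <- shank
      fk[["exo_sole"]] <- sole
      eval_constraint_residuals(fk, cs)
    }
    par[abs(par) < 1e-9] <- 0  # keep lmdif's FD step resolvable
    fit <- minpack.lm::nls.lm(par, fn = fn, control = ctrl)
    if (i == 1L) {
      # guard the first frame (no warm start yet) against a flipped
      # branch: also try starting from the human angles
      alt <- minpack.lm::nls.lm(hmat[1L, ], fn = fn, control = ctrl)
      if (alt$deviance < fit$deviance) fit <- alt
    }
    sol[i, ] <- fit$par
    par <- fit$par
  }
  joint_trajectory(v_H$time, list(hip_flexion = sol[, 1L],
                                  knee_flexion = sol[, 2L],
                                  ankle_flexion = sol[, 3L]))
}

#' Build a complete synthetic test subject
#'
#' The study-condition generator: a subject with known segment scale
#' factors walks on a treadmill for `duration` seconds at `rate` Hz
#' wearing the exoskeleton. The worn device's geometry follows `soft`:
#' with worn-geometry misalignment (corset shift/tilt, link-length
#' mismatch) the exoskeleton angles are derived frame-by-frame by
#' least-squares closure of the true device fixation constraints (the
#' device physically follows the strapped limb), plus smooth compliance
#' noise; with purely affine soft-tissue parameters the
#' [derive_exo_motion()] surrogate is used instead. Produces the
#' ground-truth human and exoskeleton angle trajectories, the static
#' calibration trials (noiseless single frames, with and without the
#' exoskeleton) and the walking capture.
#'
#' @param seed integer seed controlling scale factors (when not supplied)
#'   and, through `soft`, all noise.
#' @param factors optional [scale_factors()]; by default drawn uniformly
#'   in 0.9-1.1 per segment.
#' @param soft a [soft_tissue_params()] (see [soft_tissue_preset()]).
#' @param duration,rate,cadence gait parameters.
#' @param static_angles human sagittal angles in the static upright trial
#'   (degrees; neutral by default).
#' @param axis_offsets marker heights above the joint axes (see
#'   [default_human_markers()]); zero offsets give an idealized subject
#'   whose device axes coincide with the joints.
#' @param exo_motion `"auto"` (closure when the device axes are offset or
#'   the worn geometry is mismatched, affine otherwise), `"closure"` or
#'   `"affine"`.
#' @return An object of class `synthetic_subject`: `truth` (scale factors,
#'   `v_H`, `v_R`, true coupled model), `static_no_exo`,
#'   `static_with_exo`, `walk_markers`.
#' @export
make_synthetic_subject <- function(seed = 1L,
                                   factors = NULL,
                                   soft = soft_tissue_preset("none", seed = seed),
                                   duration = 10, rate = 100, cadence = 0.5,
                                   static_angles = c(hip_flexion = 0,
                                                     knee_flexion = 0,
                                                     ankle_flexion = 0),
                                   axis_offsets = c(hip = 0.055, knee = -0.010,
                                                    ankle = 0.000),
                                   exo_motion = c("auto", "closure", "affine")) {
  exo_motion <- match.arg(exo_motion)
  if (exo_motion == "auto")
    exo_motion <- if (has_device_mismatch(soft) || any(axis_offsets != 0))
      "closure" else "affine"
  if (is.null(names(static_angles))) names(static_angles) <- HUMAN_COORDS
  if (is.null(factors)) {
    f <- with_seed(seed, stats::runif(3, 0.9, 1.1))
    factors <- scale_factors(f[1], f[2], f[3])
  }
  lengths <- default_human_lengths()
  human <- apply_scaling(
    build_generic_human(lengths, default_human_markers(lengths, axis_offsets)),
    factors)
  # the physical device's joint axes sit at the anatomical marker heights
  # (trochanter, lateral knee, malleolus), so the true link lengths are
  # marker-height differences in the neutral posture, plus any residual
  # extensible-plate quantization error
  q0 <- stats::setNames(rep(0, length(human$coords)), human$coords)
  mk <- marker_positions(human, q0, warn_limits = FALSE)
  exo <- build_exo_model(c(
    thigh = mk["Mk11", "y"] - mk["Mk7", "y"] + soft$thigh_link_delta,
    shank = mk["Mk7", "y"] - mk["Mk3", "y"] + soft$shank_link_delta,
    sole = 0.25))
  weld_true <- rt_compose(rigid_transform(rot_z(soft$corset_tilt),
                             c(soft$corset_shift[["x"]],
                               soft$corset_shift[["y"]], 0)),
                          pelvis_corset_weld(mk11_hip_drop(human)))

  if (exo_motion == "closure") {
    # fit the worn device to the subject at the static posture, lock the
    # strap anchors there, then let the device follow the limb
    pre <- couple_models(human, exo, static_angles, c(0, 0, 0),
                         weld_xf = weld_true)
    static_exo_angles <- align_device_static(pre)
    coupled <- couple_models(human, exo, static_angles, static_exo_angles,
                             weld_xf = weld_true)
    cs_true <- make_default_constraint_set(coupled)
  } else {
    static_exo_angles <- soft$gain * static_angles[HUMAN_COORDS] + soft$offset
    coupled <- couple_models(human, exo, static_angles, static_exo_angles,
                             weld_xf = weld_true)
  }
  one <- function(ang, exo_ang, labels) {
    vh <- joint_trajectory(0, as.list(stats::setNames(as.numeric(ang),
                                                      HUMAN_COORDS)))
    vr <- joint_trajectory(0, as.list(stats::setNames(as.numeric(exo_ang),
                                                      HUMAN_COORDS)))
    clean <- soft_tissue_params(seed = soft$seed)  # statics are noiseless
    synthesize_marker_data(coupled, vh, vr, clean, labels = labels)
  }
  static_no_exo <- one(static_angles, static_exo_angles, HUMAN_MARKERS)
  static_with_exo <- one(static_angles, static_exo_angles,
                         c(HUMAN_MARKERS, EXO_MARKERS))
  v_H <- generate_gait_profile(gait_profile_params(duration, rate, cadence,
                                                   seed = seed))
  if (exo_motion == "closure") {
    v_R <- solve_exo_closure(coupled, cs_true, v_H)
    if (soft$angle_noise_sd > 0) {
      v_R <- with_seed(soft$seed + 1L, {
        ch <- lapply(v_R$channels, function(x)
          x + smooth_noise(length(x), rate, soft$angle_noise_sd))
        joint_trajectory(v_R$time, ch)
      })
    }
  } else {
    v_R <- derive_exo_motion(v_H, soft)
  }
  walk_markers <- synthesize_marker_data(coupled, v_H, v_R, soft,
                                         labels = walking_marker_labels())
  structure(list(truth = list(factors = factors, v_H = v_H, v_R = v_R,
                              coupled = coupled),
                 static_no_exo = static_no_exo,
                 static_with_exo = static_with_exo,
                 walk_markers = walk_markers,
                 seed = as.integer(seed), soft = soft,
                 axis_offsets = axis_offsets,
                 exo_motion = exo_motion,
                 duration = duration, rate = rate, cadence = cadence),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat("synthetic subject (seed", x$seed, ")\n")
  print(x$truth$factors)
  cat(n_frames(x$truth$v_H), "walking frames at", x$rate, "Hz\n")
  invisible(x)
}

#' Write a complete synthetic fixture set to disk
#'
#' Writes the static trials and walking capture as TRC files and the
#' ground-truth human and exoskeleton angle trajectories as CSV.
#'
#' @param subject a [make_synthetic_subject()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_set <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    static_no_exo = file.path(dir, "static_no_exo.trc"),
    static_with_exo = file.path(dir, "static_with_exo.trc"),
    walk_with_exo = file.path(dir, "walk_with_exo.trc"),
    gt_human_angles = file.path(dir, "gt_human_angles.csv"),
    gt_exo_angles = file.path(dir, "gt_exo_angles.csv"))
  write_trc(subject$static_no_exo, paths[["static_no_exo"]])
  write_trc(subject$static_with_exo, paths[["static_with_exo"]])
  write_trc(subject$walk_markers, paths[["walk_with_exo"]])
  write_angles_csv(subject$truth$v_H, paths[["gt_human_angles"]])
  write_angles_csv(subject$truth$v_R, paths[["gt_exo_angles"]])
  invisible(paths)
}
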