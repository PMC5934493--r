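#' Pipeline configuration
#'
#' Settings for the end-to-end synthetic study: generate subjects, scale
#' and assemble the coupled model from their static captures, compute
#' ground-truth angles by marker IK, run the rigid and constraint-closure
#' estimators, and build the evaluation report.
#'
#' @param n_subjects number of synthetic subjects.
#' @param duration,rate,cadence gait parameters per trial (seconds, Hz,
#'   strides/s).
#' @param preset soft-tissue preset name (see [soft_tissue_preset()]) or a
#'   [soft_tissue_params()] object.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param gt_method `"marker_ik"` (ground truth recovered from the
#'   synthesized markers, the full pipeline) or `"truth"` (use the
#'   generator's angles directly; faster, for smoke tests).
#' @param settings [ik_settings()] used by every solve.
#' @param outdir optional directory; when given, fixtures, angle files and
#'   the report (CSV + JSON) are written there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 7, duration = 10, rate = 100,
                            cadence = 0.5, preset = "misaligned", seed = 1L,
                            gt_method = c("marker_ik", "truth"),
                            settings = ik_settings(), outdir = NULL) {
  structure(list(n_subjects = n_subjects, duration = duration, rate = rate,
                 cadence = cadence, preset = preset, seed = as.integer(seed),
                 gt_method = match.arg(gt_method), settings = settings,
                 outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  args <- doc[intersect(names(doc), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' Run pipeline stages 2-5 for one subject's captures
#'
#' Skeletal personalization from the static trial, exoskeleton link
#' adjustment and coupled-model assembly from the worn static, ground
#' truth joint angles (marker IK plus the Mk3-Mk14 exoskeleton ankle),
#' and the rigid and constraint-closure estimates.
#'
#' @param subject a [make_synthetic_subject()] result (or a list with the
#'   same `static_no_exo` / `static_with_exo` / `walk_markers` fields read
#'   from TRC files).
#' @param settings an [ik_settings()].
#' @param gt_method `"marker_ik"` for the full pipeline or `"truth"` to
#'   use the generator's angles directly.
#' @param generic optional generic human model (defaults to the protocol
#'   layout recorded in the subject).
#' @return A list with the assembled `coupled` model, recovered `factors`,
#'   ground-truth trajectories `v_H_gt` / `v_R_gt`, and the `rigid` and
#'   `eikpe` estimates.
#' @export
process_subject <- function(subject, settings = ik_settings(),
                            gt_method = "marker_ik", generic = NULL) {
  # 2. skeletal personalization from the static trial without exoskeleton.
  # The generic model's marker layout is protocol knowledge (where the
  # landmarks sit relative to the joints), shared with the capture.
  if (is.null(generic)) {
    lengths <- default_human_lengths()
    offs <- subject$axis_offsets
    if (is.null(offs)) offs <- c(hip = 0.040, knee = 0.015, ankle = 0.005)
    generic <- build_generic_human(lengths,
                                   default_human_markers(lengths, offs))
  }
  factors <- compute_scale_factors(subject$static_no_exo, generic)
  human <- apply_scaling(generic, factors)
  # 3. exoskeleton link adjustment + coupled model from the worn static
  exo <- adjust_exo_links(build_exo_model(), subject$static_with_exo)
  coupled <- assemble_coupled(human, exo, subject$static_with_exo,
                              settings = settings)

  # 4. ground-truth joint angles: human angles and exoskeleton hip/knee by
  # marker IK; the exoskeleton ankle from the Mk3-Mk14 line direction
  if (gt_method == "marker_ik") {
    walk <- add_virtual_midpoint_marker(subject$walk_markers, "Mk0", "Mk1", "Mk14")
    free <- c(coupled$human_coords, "exo_hip_flexion", "exo_knee_flexion")
    # the junction (base) translations are re-estimated on the first
    # walking frame (the static and walking marker sets differ) and held
    # for the trial: the treadmill capture volume is fixed, and base
    # orientation stays registered (see assemble_coupled)
    tr <- paste0("base_t", c("x", "y", "z"))
    first <- marker_trajectory(walk$time[1L],
                               lapply(walk$markers, function(m) m[1L, , drop = FALSE]))
    base_fit <- marker_ik(coupled$model, first, settings = settings,
                          free = c(tr, free),
                          fixed = coupled$static_posture)
    fixed <- coupled$static_posture
    fixed[tr] <- vapply(base_fit$trajectory$channels[tr], `[`, 0, 1L)
    gt_fit <- marker_ik(coupled$model, walk, settings = settings, free = free,
                        fixed = fixed)
    v_H_gt <- joint_trajectory(walk$time,
                               gt_fit$trajectory$channels[coupled$human_coords])
    pose_ch <- c(gt_fit$trajectory$channels,
                 lapply(fixed[coupled$base_coords],
                        rep, times = n_frames(walk)))
    exo_ankle <- exo_ankle_from_markers(coupled, walk,
                                        joint_trajectory(walk$time, pose_ch),
                                        subject$static_with_exo)
    v_R_gt <- joint_trajectory(walk$time, list(
      hip_flexion = gt_fit$trajectory$channels$exo_hip_flexion,
      knee_flexion = gt_fit$trajectory$channels$exo_knee_flexion,
      ankle_flexion = exo_ankle))
  } else {
    gt_fit <- NULL
    v_H_gt <- subject$truth$v_H
    v_R_gt <- subject$truth$v_R
  }

  # 5. estimates: rigid baseline and constraint closure
  rigid <- rigid_estimate(v_R_gt)
  fit <- eikpe(coupled, v_R_gt, settings = settings)
  list(coupled = coupled, factors = factors, gt_fit = gt_fit,
       v_H_gt = v_H_gt, v_R_gt = v_R_gt,
       rigid = rigid, eikpe_fit = fit, eikpe = fit$trajectory)
}

#' Run the full estimation study
#'
#' Executes the five pipeline stages for each synthetic subject — capture
#' generation, skeletal personalization, coupled-model assembly,
#' ground-truth angle computation, and human-angle estimation with both
#' the rigid baseline and the constraint-closure estimator — then
#' aggregates an evaluation report. Deterministic for a fixed
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `report` (an
#'   [build_report()] result), `subjects` (per-subject detail lists) and
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  soft0 <- if (inherits(config$preset, "soft_tissue_params")) config$preset
           else soft_tissue_preset(config$preset)
  subject_seeds <- with_seed(config$seed,
                             sample.int(.Machine$integer.max %/% 2,
                                        config$n_subjects))
  gt <- list(); rigid <- list(); est <- list(); subjects <- list()
  for (k in seq_len(config$n_subjects)) {
    soft <- soft0; soft$seed <- subject_seeds[k]
    subj <- make_synthetic_subject(seed = subject_seeds[k], soft = soft,
                                   duration = config$duration,
                                   rate = config$rate,
                                   cadence = config$cadence)
    res <- process_subject(subj, settings = config$settings,
                           gt_method = config$gt_method)
    key <- sprintf("S%02d", k)
    gt[[key]] <- res$v_H_gt
    rigid[[key]] <- res$rigid
    est[[key]] <- res$eikpe
    res$subject <- subj
    subjects[[key]] <- res
    if (!is.null(config$outdir)) {
      sdir <- file.path(config$outdir, key)
      write_fixture_set(subj, sdir)
      write_angles_csv(res$v_H_gt, file.path(sdir, "gt_ik_human_angles.csv"))
      write_angles_csv(res$eikpe, file.path(sdir, "eikpe_angles.csv"))
    }
  }
  report <- build_report(gt, rigid, est)
  if (!is.null(config$outdir)) {
    write_report(report, csv_path = file.path(config$outdir, "report.csv"),
                 json_path = file.path(config$outdir, "report.json"))
    jsonlite::write_json(list(seed = config$seed,
                              n_subjects = config$n_subjects,
                              duration = config$duration, rate = config$rate,
                              preset = if (is.character(config$preset))
                                config$preset else "custom",
                              package_version =
                                as.character(utils::packageVersion("exokin"))),
                         file.path(config$outdir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  structure(list(report = report, subjects = subjects, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run:", x$config$n_subjects, "synthetic subjects,",
      x$config$duration, "s at", x$config$rate, "Hz\n\n")
  print(x$report)
  invisible(x)
}
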