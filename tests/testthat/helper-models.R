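# shared fixtures, all built in code

# simple two-link planar leg used by the kinematics tests
two_link_leg <- function(lf = 0.4, lt = 0.38) {
  kinematic_model(
    list(segment("thigh", lf, list(A = c(0, -0.2, 0.05), B = c(0.03, -0.3, 0.02))),
         segment("shank", lt, list(C = c(0, -lt, 0.08)))),
    list(joint("hip", "revolute_z", "ground", "thigh"),
         joint("knee", "revolute_z", "thigh", "shank",
               parent_xf = rt_translation(c(0, -lf, 0)))))
}

# idealized subject: device axes coincide with the joints, no noise
ideal_subject <- function(seed = 7, duration = 1) {
  make_synthetic_subject(seed = seed, soft = soft_tissue_preset("none", seed = seed),
                         duration = duration,
                         axis_offsets = c(hip = 0, knee = 0, ankle = 0))
}

# study-condition subject (misaligned preset), short trial for unit tests
misaligned_subject <- function(seed = 42, duration = 2) {
  make_synthetic_subject(seed = seed,
                         soft = soft_tissue_preset("misaligned", seed = seed),
                         duration = duration)
}

# assembled coupled model reconstructed by the pipeline from a subject's
# static captures
pipeline_coupled <- function(subject) {
  lengths <- default_human_lengths()
  offs <- subject$axis_offsets
  generic <- build_generic_human(lengths, default_human_markers(lengths, offs))
  human <- apply_scaling(generic, compute_scale_factors(subject$static_no_exo,
                                                        generic))
  exo <- adjust_exo_links(build_exo_model(), subject$static_with_exo)
  suppressWarnings(assemble_coupled(human, exo, subject$static_with_exo))
}

channel_rmse <- function(a, b) {
  vapply(names(a$channels), function(ch) rmse(a$channels[[ch]], b$channels[[ch]]),
         0)
}
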