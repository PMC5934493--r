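Package: exokin
Title: Subject-Specific Kinematic Estimation of Human Joint Angles in
    Exoskeleton-Assisted Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict human lower-limb joint angles from the joint
    angles of a wearable exoskeleton. A scaled, subject-specific skeletal
    model of the right lower limb is coupled to a sagittal-plane kinematic
    model of the exoskeleton through a set of geometric fixation constraints
    (a rigid pelvis-corset junction, a point-on-line tibia brace, and three
    point-to-point foot-sole attachments). For each frame of a gait trial the
    human hip, knee and ankle flexion angles are estimated by damped
    least-squares closure of the coupled chain, and compared against a rigid
    baseline that assumes zero human-exoskeleton relative motion. The package
    also provides marker-based inverse kinematics for ground-truth angles,
    TRC/CSV motion-capture file handling, a seeded synthetic gait and
    soft-tissue-artifact generator, and evaluation reports (RMSE, range-of-
    motion error, improvement percentages, exact Wilcoxon-Mann-Whitney tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
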