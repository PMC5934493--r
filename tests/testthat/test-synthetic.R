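test_that("the gait profile matches the trial protocol and is deterministic", {
  v <- generate_gait_profile()
  expect_equal(n_frames(v), 1000L)           # 10 s at 100 Hz
  expect_equal(v$rate, 100)
  rng <- sapply(v$channels, range)  # row 1 = min, row 2 = max
  expect_true(rng[1, "hip_flexion"] > -15 && rng[2, "hip_flexion"] < 30)
  expect_true(rng[1, "knee_flexion"] > -5 && rng[2, "knee_flexion"] < 65)
  expect_true(rng[1, "ankle_flexion"] > -20 && rng[2, "ankle_flexion"] < 15)
  expect_identical(generate_gait_profile(), v)
  # zero amplitudes give constant channels at their means
  co <- default_gait_coefficients()
  for (nm in names(co)) co[[nm]]$amp <- co[[nm]]$amp * 0
  flat <- generate_gait_profile(gait_profile_params(coefficients = co))
  expect_equal(unique(flat$channels$knee_flexion), co$knee_flexion$mean)
  expect_error(gait_profile_params(duration = -1), "> 0")
})

test_that("the affine surrogate applies offsets, gains and lags exactly", {
  v <- generate_gait_profile(gait_profile_params(duration = 2))
  expect_identical(derive_exo_motion(v, soft_tissue_params()), v)
  off <- derive_exo_motion(v, soft_tissue_params(offset = c(hip = 3)))
  expect_identical(off$channels$hip_flexion, v$channels$hip_flexion + 3)
  expect_identical(off$channels$knee_flexion, v$channels$knee_flexion)
  g <- derive_exo_motion(v, soft_tissue_params(gain = c(knee = 0.9)))
  expect_equal(diff(range(g$channels$knee_flexion)),
               0.9 * diff(range(v$channels$knee_flexion)))
  # a lag shifts the channel circularly by lag*rate samples
  l <- derive_exo_motion(v, soft_tissue_params(lag = c(ankle = 0.05)))
  x <- v$channels$ankle_flexion
  expect_equal(l$channels$ankle_flexion, c(x[196:200], x[1:195]))
  expect_error(soft_tissue_params(gain = c(knee = 0)), "> 0")
})

test_that("synthesized markers are rigid per segment, seeded, and schema-checked", {
  subj <- ideal_subject(seed = 4, duration = 0.3)
  mk <- subj$walk_markers
  # same-segment inter-marker distances constant over time (no noise)
  d <- sqrt(rowSums((mk$markers$Mk8 - mk$markers$Mk9)^2))
  expect_lt(diff(range(d)), 1e-12)
  d2 <- sqrt(rowSums((mk$markers$ExoKnee - mk$markers$ExoThighBar)^2))
  expect_lt(diff(range(d2)), 1e-12)
  # fixed seed reproduces noisy output bitwise
  s <- soft_tissue_params(marker_noise_sd = 0.002, seed = 99)
  a <- synthesize_marker_data(subj$truth$coupled, subj$truth$v_H,
                              subj$truth$v_R, s)
  b <- synthesize_marker_data(subj$truth$coupled, subj$truth$v_H,
                              subj$truth$v_R, s)
  expect_identical(a, b)
  short <- joint_trajectory(0, lapply(subj$truth$v_H$channels[1:3], `[`, 1))
  expect_error(synthesize_marker_data(subj$truth$coupled, subj$truth$v_H, short,
                                      soft_tissue_params()),
               "schema error")
})

test_that("marker-IK angle error grows monotonically with marker noise", {
  errs <- sapply(c(0, 0.0005, 0.001, 0.002), function(sig) {
    subj <- make_synthetic_subject(seed = 6, soft = soft_tissue_params(
      marker_noise_sd = sig, seed = 6), duration = 1,
      axis_offsets = c(hip = 0, knee = 0, ankle = 0), exo_motion = "affine")
    res <- process_subject(subj, gt_method = "marker_ik")
    mean(channel_rmse(res$v_H_gt, subj$truth$v_H))
  })
  expect_true(all(diff(errs) > 0))
})

test_that("TRC files round-trip and reject malformed headers", {
  subj <- ideal_subject(seed = 4, duration = 0.1)
  path <- tempfile(fileext = ".trc")
  write_trc(subj$walk_markers, path)
  back <- read_trc(path)
  expect_equal(names(back$markers), names(subj$walk_markers$markers))
  for (l in names(back$markers))
    expect_lt(max(abs(back$markers[[l]] - subj$walk_markers$markers[[l]])),
              1e-6 / 1000)  # 1e-6 mm in meters
  # unit conversion: a marker at 100 mm reads back as 0.1 m
  one <- marker_trajectory(0, list(M = matrix(c(0.1, 0, 0), 1)))
  f <- tempfile(fileext = ".trc"); write_trc(one, f)
  expect_match(readLines(f)[4], "100.0000000")
  expect_equal(as.numeric(read_trc(f)$markers$M[1, 1]), 0.1)
  # occluded samples survive the round trip as NaN
  occ <- subj$walk_markers; occ$markers$Mk0[2, ] <- NaN
  f2 <- tempfile(fileext = ".trc"); write_trc(occ, f2)
  expect_true(all(is.nan(read_trc(f2)$markers$Mk0[2, ])))
  # header validation
  lines <- readLines(path)
  lines[2] <- sub("NumMarkers=[0-9]+", "NumMarkers=3", lines[2])
  f3 <- tempfile(fileext = ".trc"); writeLines(lines, f3)
  expect_error(read_trc(f3), "inconsistent")
  expect_error(suppressWarnings(read_trc(tempfile())), "cannot open",
               ignore.case = TRUE)
})

test_that("angle CSV files round-trip losslessly and validate their schema", {
  v <- generate_gait_profile(gait_profile_params(duration = 1))
  f <- tempfile(fileext = ".csv")
  write_angles_csv(v, f)
  back <- read_angles_csv(f)
  for (ch in names(v$channels))
    expect_lt(max(abs(back$channels[[ch]] - v$channels[[ch]])), 1e-9)
  expect_lt(max(abs(back$time - v$time)), 1e-9)
  # missing required column
  df <- utils::read.csv(f); df$hip_flexion <- NULL
  f2 <- tempfile(fileext = ".csv"); utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_angles_csv(f2), "schema error")
  # non-uniform time column
  df2 <- utils::read.csv(f); df2$time[3] <- df2$time[3] + 0.004
  f3 <- tempfile(fileext = ".csv"); utils::write.csv(df2, f3, row.names = FALSE)
  expect_error(read_angles_csv(f3), "uniform")
  # empty file
  f4 <- tempfile(fileext = ".csv"); file.create(f4)
  expect_error(read_angles_csv(f4), "schema error")
})

test_that("fixture sets are written as complete plain-text trial bundles", {
  subj <- ideal_subject(seed = 4, duration = 0.05)
  dir <- tempfile()
  paths <- write_fixture_set(subj, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(n_frames(read_trc(paths[["static_no_exo"]])), 1L)
  gt <- read_angles_csv(paths[["gt_human_angles"]])
  expect_equal(n_frames(gt), n_frames(subj$truth$v_H))
})
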