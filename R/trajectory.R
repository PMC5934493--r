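#' Joint-angle trajectories
#'
#' A set of named angle channels (degrees) sampled on a strictly
#' increasing, uniform time grid. The sagittal gait channels are
#' `hip_flexion`, `knee_flexion` and `ankle_flexion`; additional channels
#' (e.g. a pelvis 6-DOF pose) are allowed.
#'
#' @param time numeric vector of sample times in seconds, uniform within
#'   1e-9 s.
#' @param channels named list of numeric vectors, each the same length as
#'   `time`.
#' @return An object of class `joint_trajectory`.
#' @export
joint_trajectory <- function(time, channels) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 1L) stop("time must be non-empty", call. = FALSE)
  if (n > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-9)
      stop("time must be uniformly sampled within 1e-9 s", call. = FALSE)
  }
  if (!length(channels) || is.null(names(channels)) || anyDuplicated(names(channels)))
    stop("channels must be a uniquely named list", call. = FALSE)
  channels <- lapply(channels, as.numeric)
  if (any(vapply(channels, length, 0L) != n))
    stop("all channels must have the same length as time", call. = FALSE)
  rate <- if (n > 1L) 1 / mean(diff(time)) else NA_real_
  structure(list(time = time, channels = channels, rate = rate),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat("joint trajectory:", length(x$time), "samples",
      if (!is.na(x$rate)) paste0("at ", round(x$rate, 3), " Hz"),
      "\nchannels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.joint_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$channels, check.names = FALSE)
}

#' Number of frames in a trajectory
#' @param x a `joint_trajectory` or `marker_trajectory`.
#' @export
n_frames <- function(x) length(x$time)

#' Labelled 3D marker trajectories
#'
#' The motion-capture record: for each marker label, an n x 3 matrix of
#' world positions in meters (columns x/y/z). `NaN` rows mark occluded
#' frames; occluded markers are dropped from the inverse-kinematics cost
#' for that frame.
#'
#' @param time numeric vector of sample times (seconds), uniform.
#' @param markers named list of n x 3 numeric matrices (meters).
#' @return An object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(time, markers) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 1L) stop("time must be non-empty", call. = FALSE)
  if (n > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-9)
      stop("time must be uniformly sampled within 1e-9 s", call. = FALSE)
  }
  if (!length(markers) || is.null(names(markers)) || anyDuplicated(names(markers)))
    stop("markers must be a uniquely named list", call. = FALSE)
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (is.null(dim(m)) || ncol(m) != 3L || nrow(m) != n)
      stop("each marker must be an n x 3 matrix matching time", call. = FALSE)
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  rate <- if (n > 1L) 1 / mean(diff(time)) else NA_real_
  structure(list(time = time, markers = markers, rate = rate),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat("marker trajectory:", length(x$time), "frames,",
      length(x$markers), "markers",
      if (!is.na(x$rate)) paste0("at ", round(x$rate, 3), " Hz"), "\n")
  cat("labels:", paste(names(x$markers), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one frame of a marker trajectory
#'
#' @param traj a [marker_trajectory()].
#' @param i frame index.
#' @return Named list of 3-vectors (meters).
#' @export
marker_frame <- function(traj, i) {
  lapply(traj$markers, function(m) m[i, ])
}

#' Keep a subset of markers
#' @param traj a [marker_trajectory()].
#' @param labels marker labels to keep.
#' @export
select_markers <- function(traj, labels) {
  missing <- setdiff(labels, names(traj$markers))
  if (length(missing))
    stop("missing marker(s): ", paste(missing, collapse = ", "), call. = FALSE)
  marker_trajectory(traj$time, traj$markers[labels])
}
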