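#' Segments and joints of a kinematic chain
#'
#' A segment is a rigid body with a scalar length and a set of labelled
#' marker positions expressed in its local frame. The frame convention is:
#' origin at the proximal joint, +Y pointing from the distal end toward the
#' proximal end (so segments hang along -Y), +X anterior, +Z to the
#' subject's right. Positive revolute rotation follows the right-hand rule
#' about +Z, which makes hip/knee/ankle flexion positive for the right leg.
#'
#' @param name segment identifier.
#' @param length segment length in meters (> 0).
#' @param markers named list of local 3-vectors (meters), one per marker label.
#' @return An object of class `exo_segment`.
#' @export
segment <- function(name, length, markers = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(length) || length <= 0 || !is.finite(length))
    stop("segment `", name, "`: length must be a finite positive number", call. = FALSE)
  if (length(markers) && (is.null(names(markers)) || anyDuplicated(names(markers))))
    stop("segment `", name, "`: marker labels must be unique and named", call. = FALSE)
  markers <- lapply(markers, function(m) {
    m <- as.numeric(m)
    if (length(m) != 3L) stop("markers must be 3-vectors", call. = FALSE)
    m
  })
  structure(list(name = name, length = length, markers = markers),
            class = "exo_segment")
}

#' @param kind one of `"revolute_z"`, `"weld"`, `"free6"`.
#' @param parent,child names of the parent and child segments (`"ground"`
#'   allowed as parent of the root joint).
#' @param parent_xf,child_xf local attachment transforms: the joint frame
#'   expressed in the parent (resp. child) segment frame.
#' @param limits numeric `c(min, max)` in degrees, for `revolute_z` only;
#'   values outside produce a warning from [forward_kinematics()], not an error.
#' @param fixed_rx,fixed_ry frozen rotations (degrees) about the joint X and
#'   Y axes applied after the Z rotation; used for hip ab-adduction and
#'   axial rotation held at their static-posture values.
#' @rdname segment
#' @export
joint <- function(name, kind = c("revolute_z", "weld", "free6"),
                  parent, child,
                  parent_xf = rt_identity(), child_xf = rt_identity(),
                  limits = c(-180, 180), fixed_rx = 0, fixed_ry = 0) {
  kind <- match.arg(kind)
  check_rt(parent_xf, "parent_xf"); check_rt(child_xf, "child_xf")
  coords <- switch(kind,
    revolute_z = name,
    weld = character(0),
    free6 = paste0(name, c("_tx", "_ty", "_tz", "_rx", "_ry", "_rz")))
  structure(list(name = name, kind = kind, parent = parent, child = child,
                 parent_xf = parent_xf, child_xf = child_xf,
                 limits = as.numeric(limits),
                 fixed_rx = fixed_rx, fixed_ry = fixed_ry,
                 coords = coords),
            class = "exo_joint")
}

#' Assemble a kinematic model
#'
#' Joints must form a tree rooted at the implicit `"ground"` frame: every
#' segment is the child of exactly one joint and reachable from ground.
#' Generalized coordinates are ordered by joint declaration; revolute
#' coordinates are in degrees, free-6-DOF coordinates are
#' `(tx, ty, tz, rx, ry, rz)` in meters and degrees with intrinsic XYZ
#' Euler rotations.
#'
#' @param segments list of [segment()] objects.
#' @param joints list of [joint()] objects.
#' @return An object of class `kinematic_model`.
#' @export
kinematic_model <- function(segments, joints) {
  seg_names <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(seg_names)) stop("duplicate segment names", call. = FALSE)
  names(segments) <- seg_names
  jt_children <- vapply(joints, `[[`, "", "child")
  if (anyDuplicated(jt_children))
    stop("model is not a tree: a segment has two parent joints", call. = FALSE)
  if (!setequal(jt_children, seg_names))
    stop("every segment must be the child of exactly one joint", call. = FALSE)
  for (j in joints)
    if (!(j$parent %in% c("ground", seg_names)))
      stop("joint `", j$name, "`: unknown parent segment `", j$parent, "`",
           call. = FALSE)

  # topological order: parents before children (also detects disconnection)
  placed <- "ground"
  order <- integer(0)
  remaining <- seq_along(joints)
  while (length(remaining)) {
    ready <- remaining[vapply(joints[remaining],
                              function(j) j$parent %in% placed, TRUE)]
    if (!length(ready))
      stop("model is not connected to ground (cycle or orphan chain)", call. = FALSE)
    order <- c(order, ready)
    placed <- c(placed, jt_children[ready])
    remaining <- setdiff(remaining, ready)
  }

  coords <- unlist(lapply(joints, `[[`, "coords"), use.names = FALSE)
  if (anyDuplicated(coords)) stop("duplicate coordinate names", call. = FALSE)
  structure(list(segments = segments, joints = joints,
                 coords = coords, order = order),
            class = "kinematic_model")
}

#' @export
print.kinematic_model <- function(x, ...) {
  cat("kinematic model:", length(x$segments), "segments,",
      length(x$joints), "joints,", length(x$coords), "coordinates\n")
  cat("coordinates:", paste(x$coords, collapse = ", "), "\n")
  invisible(x)
}

#' Coordinate names of a model
#' @param model a `kinematic_model`.
#' @export
model_coords <- function(model) model$coords

# local joint transform for given coordinate values (degrees / meters)
joint_transform <- function(j, q) {
  switch(j$kind,
    weld = rt_identity(),
    revolute_z = {
      R <- rot_z(q[[j$coords]])
      if (j$fixed_rx != 0) R <- R %*% rot_x(j$fixed_rx)
      if (j$fixed_ry != 0) R <- R %*% rot_y(j$fixed_ry)
      new_rt(R, c(0, 0, 0))
    },
    free6 = {
      v <- q[j$coords]
      new_rt(rot_x(v[[4L]]) %*% rot_y(v[[5L]]) %*% rot_z(v[[6L]]),
             c(v[[1L]], v[[2L]], v[[3L]]))
    },
    ball_zxy = {
      # Z flexion with estimable X (ab-adduction) and Y (rotation) angles;
      # used transiently during static calibration
      v <- q[j$coords]
      new_rt(rot_z(v[[1L]]) %*% rot_x(v[[2L]]) %*% rot_y(v[[3L]]), c(0, 0, 0))
    })
}

#' Forward kinematics
#'
#' Computes the world pose of every segment for a configuration `q`. With
#' all coordinates zero, every segment's Y axis is parallel to the ground Y
#' axis (the neutral standing convention: adjacent segments' Y axes match).
#'
#' @param model a [kinematic_model()].
#' @param q named numeric vector of coordinate values covering exactly the
#'   model's coordinates (degrees for rotations, meters for translations).
#' @param warn_limits warn when a revolute coordinate is outside its limits.
#' @return Named list of `rigid_transform` world poses, one per segment.
#' @export
forward_kinematics <- function(model, q, warn_limits = TRUE) {
  qn <- names(q)
  if (is.null(qn) || !setequal(qn, model$coords) || length(q) != length(model$coords))
    stop("configuration error: q must name exactly the model coordinates (",
         paste(setdiff(model$coords, qn), collapse = ", "),
         if (length(setdiff(qn, model$coords)))
           paste0("; unknown: ", paste(setdiff(qn, model$coords), collapse = ", ")),
         ")", call. = FALSE)
  q <- as.list(q)
  poses <- vector("list", length(model$segments))
  names(poses) <- names(model$segments)
  ground <- rt_identity()
  for (k in model$order) {
    j <- model$joints[[k]]
    if (warn_limits && j$kind == "revolute_z") {
      th <- q[[j$coords]]
      if (th < j$limits[1] || th > j$limits[2])
        warning("coordinate `", j$coords, "` = ", format(th, digits = 4),
                " outside limits [", j$limits[1], ", ", j$limits[2], "]",
                call. = FALSE)
    }
    parent_pose <- if (j$parent == "ground") ground else poses[[j$parent]]
    pose <- rt_compose(rt_compose(parent_pose, j$parent_xf), joint_transform(j, q))
    if (!identical(j$child_xf$p, c(0, 0, 0)) ||
        !identical(j$child_xf$R, diag(3)))
      pose <- rt_compose(pose, rt_invert(j$child_xf))
    poses[[j$child]] <- pose
  }
  poses
}

#' Marker positions in world coordinates
#'
#' Maps every segment-local marker through its segment's world pose.
#'
#' @inheritParams forward_kinematics
#' @param fk optional precomputed [forward_kinematics()] result.
#' @return Numeric matrix, one row per marker (rownames = labels), columns
#'   x/y/z in meters.
#' @export
marker_positions <- function(model, q, fk = NULL, warn_limits = TRUE) {
  if (is.null(fk)) fk <- forward_kinematics(model, q, warn_limits = warn_limits)
  out <- list()
  for (s in model$segments) {
    if (!length(s$markers)) next
    pose <- fk[[s$name]]
    loc <- do.call(rbind, s$markers)
    out[[length(out) + 1L]] <- rt_apply(pose, loc)
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("x", "y", "z")
  res
}

# ---- model definition file (YAML) -------------------------------------------

rt_to_list <- function(x) list(rotation = lapply(seq_len(3), function(i) x$R[i, ]),
                               translation = x$p)
rt_from_list <- function(x) rigid_transform(do.call(rbind, x$rotation), x$translation)

#' Read and write model definition files
#'
#' Models are stored as YAML listing segments (name, length, local markers)
#' and joints (kind, parent/child, attachment transforms, limits, frozen
#' angles). A read -> write -> read cycle reproduces the model exactly.
#'
#' @param model a [kinematic_model()].
#' @param path file path.
#' @return `read_model_yaml` returns a [kinematic_model()];
#'   `write_model_yaml` returns `path` invisibly.
#' @export
write_model_yaml <- function(model, path) {
  doc <- list(
    segments = lapply(unname(model$segments), function(s)
      list(name = s$name, length = s$length, markers = s$markers)),
    joints = lapply(model$joints, function(j)
      list(name = j$name, kind = j$kind, parent = j$parent, child = j$child,
           parent_xf = rt_to_list(j$parent_xf), child_xf = rt_to_list(j$child_xf),
           limits = j$limits, fixed_rx = j$fixed_rx, fixed_ry = j$fixed_ry)))
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  segs <- lapply(doc$segments, function(s) {
    mk <- s$markers
    if (is.null(mk)) mk <- list()
    segment(s$name, s$length, lapply(mk, as.numeric))
  })
  jts <- lapply(doc$joints, function(j)
    joint(j$name, j$kind, j$parent, j$child,
          parent_xf = rt_from_list(j$parent_xf),
          child_xf = rt_from_list(j$child_xf),
          limits = as.numeric(j$limits),
          fixed_rx = j$fixed_rx, fixed_ry = j$fixed_ry))
  kinematic_model(segs, jts)
}
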