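#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation plus a translation, mapping points
#' from a child frame into a parent frame: `x_parent = R %*% x_child + p`.
#' Rotations are 3x3 orthonormal matrices with determinant +1; translations
#' are 3-vectors in meters. All user-facing angles in this package are in
#' degrees; radians appear only at trigonometric call sites.
#'
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation numeric 3-vector (meters).
#' @param validate if `TRUE`, check orthonormality and determinant.
#' @return An object of class `rigid_transform` with elements `R` and `p`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0), validate = TRUE) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (validate) {
    if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
      stop("invalid transform: rotation must be 3x3 and translation length 3",
           call. = FALSE)
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
      stop("invalid transform: rotation is not orthonormal within 1e-9",
           call. = FALSE)
    if (abs(det(rotation) - 1) > 1e-9)
      stop("invalid transform: rotation determinant is not +1 within 1e-9",
           call. = FALSE)
  }
  structure(list(R = rotation, p = translation), class = "rigid_transform")
}

# unchecked constructor for hot paths (forward kinematics)
new_rt <- function(R, p) {
  structure(list(R = R, p = p), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() new_rt(diag(3), c(0, 0, 0))

#' @rdname rigid_transform
#' @export
rt_translation <- function(translation) rigid_transform(diag(3), translation, validate = FALSE)

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform\n")
  m <- cbind(x$R, x$p)
  dimnames(m) <- list(c("x", "y", "z"), c("R.x", "R.y", "R.z", "p"))
  print(round(m, 6))
  invisible(x)
}

#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angle in degrees.
#'
#' @param deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

check_rt <- function(x, arg) {
  if (!inherits(x, "rigid_transform"))
    stop("invalid transform: `", arg, "` is not a rigid_transform; build it with rigid_transform()",
         call. = FALSE)
  x
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` applies `b` first, then `a`: the result maps
#' grandchild-frame coordinates through `b`'s frame into `a`'s parent frame.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  check_rt(a, "a"); check_rt(b, "b")
  new_rt(a$R %*% b$R, as.numeric(a$R %*% b$p) + a$p)
}

#' Invert a rigid transform
#'
#' @param x a `rigid_transform`.
#' @return The inverse transform, satisfying
#'   `rt_compose(x, rt_invert(x)) == rt_identity()` to machine precision.
#' @export
rt_invert <- function(x) {
  check_rt(x, "x")
  Rt <- t(x$R)
  new_rt(Rt, as.numeric(-Rt %*% x$p))
}

#' Apply a rigid transform to points
#'
#' @param x a `rigid_transform`.
#' @param pts a numeric 3-vector or an n x 3 matrix of points (meters).
#' @return Transformed points in the same shape as `pts`.
#' @export
rt_apply <- function(x, pts) {
  if (is.matrix(pts)) {
    t(x$R %*% t(pts) + x$p)
  } else {
    as.numeric(x$R %*% pts) + x$p
  }
}

#' Wrap an angle into (-180, 180] degrees
#'
#' Ties at +/-180 resolve to +180.
#'
#' @param deg angle(s) in degrees.
#' @export
wrap_angle_deg <- function(deg) {
  out <- deg - 360 * floor((deg + 180) / 360)
  out[out == -180] <- 180
  out
}

#' Signed Z-rotation angle between two frames
#'
#' Returns the signed rotation about the common Z axis taking the parent
#' frame's Y axis onto the child frame's Y axis, in degrees within
#' (-180, 180]. The relative rotation must be a pure Z rotation: any
#' out-of-plane component beyond `tol` raises a geometry-violation error.
#' This is the convention in which a joint is neutral (0 degrees) when the
#' Y axes of the two adjacent segments are parallel.
#'
#' @param parent,child world poses (`rigid_transform`) of the two frames.
#' @param tol permissible out-of-plane rotation component (default 1e-6).
#' @return Signed angle in degrees.
#' @export
joint_angle_between_frames <- function(parent, child, tol = 1e-6) {
  check_rt(parent, "parent"); check_rt(child, "child")
  Rel <- t(parent$R) %*% child$R
  off <- max(abs(c(Rel[1, 3], Rel[2, 3], Rel[3, 1], Rel[3, 2], Rel[3, 3] - 1)))
  if (off > tol)
    stop("geometry violation: relative rotation is not about the Z axis (off-axis ",
         format(off, digits = 3), " > tol ", format(tol), ")", call. = FALSE)
  wrap_angle_deg(rad2deg(atan2(Rel[2, 1], Rel[1, 1])))
}
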