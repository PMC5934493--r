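#' Human-exoskeleton fixation constraints
#'
#' The fixations connecting the exoskeleton to the limb are expressed as
#' geometric constraints between points fixed on one body and points or
#' lines fixed on another:
#' \itemize{
#'   \item `weld6` — rigid 6-DOF junction. Implemented structurally (the
#'     pelvis is merged into the corset tree), so it contributes no
#'     residual rows.
#'   \item `point_on_line2` — a point of one body constrained to a line of
#'     another (the tibia brace): 2 residual components.
#'   \item `point_to_point3` — coincident anchor points (the foot-sole
#'     straps): 3 residual components.
#' }
#'
#' @param kind constraint kind.
#' @param segment_a segment carrying the anchor point.
#' @param point_a local anchor 3-vector on `segment_a` (meters).
#' @param segment_b segment carrying the mating point or line.
#' @param point_b local anchor (for `point_to_point3`) or a point on the
#'   line (for `point_on_line2`).
#' @param line_dir unit direction of the line in `segment_b`'s frame
#'   (`point_on_line2` only).
#' @return An object of class `constraint_spec` with a `residual_dim`
#'   field (2 or 3; 0 for `weld6`).
#' @export
constraint_spec <- function(kind = c("point_to_point3", "point_on_line2", "weld6"),
                            segment_a = NULL, point_a = NULL,
                            segment_b = NULL, point_b = NULL,
                            line_dir = NULL) {
  kind <- match.arg(kind)
  basis <- NULL
  if (kind == "point_on_line2") {
    line_dir <- as.numeric(line_dir)
    if (abs(sqrt(sum(line_dir^2)) - 1) > 1e-12)
      stop("line direction must be unit length within 1e-12", call. = FALSE)
    # fixed orthonormal completion, chosen once for residual continuity
    seed <- if (abs(line_dir[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    e1 <- seed - sum(seed * line_dir) * line_dir
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(line_dir[2] * e1[3] - line_dir[3] * e1[2],
            line_dir[3] * e1[1] - line_dir[1] * e1[3],
            line_dir[1] * e1[2] - line_dir[2] * e1[1])
    basis <- rbind(e1, e2)
  }
  dim <- switch(kind, weld6 = 0L, point_on_line2 = 2L, point_to_point3 = 3L)
  structure(list(kind = kind, segment_a = segment_a,
                 point_a = as.numeric(point_a),
                 segment_b = segment_b,
                 point_b = if (!is.null(point_b)) as.numeric(point_b),
                 line_dir = line_dir, basis = basis,
                 residual_dim = dim),
            class = "constraint_spec")
}

#' Bundle constraints into an ordered set
#'
#' @param specs list of [constraint_spec()] objects; residuals are stacked
#'   in this order.
#' @return An object of class `constraint_set` with a `residual_dim` total.
#' @export
constraint_set <- function(specs) {
  stopifnot(all(vapply(specs, inherits, TRUE, "constraint_spec")))
  structure(list(specs = specs,
                 residual_dim = sum(vapply(specs, `[[`, 0L, "residual_dim"))),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("constraint set:", length(x$specs), "constraints, residual dimension",
      x$residual_dim, "\n")
  for (s in x$specs)
    cat(sprintf("  %-16s %s -> %s\n", s$kind, s$segment_a, s$segment_b))
  invisible(x)
}

#' Point-to-point constraint residual
#'
#' World-frame difference between an anchor fixed on body a and an anchor
#' fixed on body b.
#'
#' @param pose_a,pose_b world poses (`rigid_transform`) of the two bodies.
#' @param local_a,local_b local anchor 3-vectors (meters).
#' @return Numeric 3-vector (meters), zero when the anchors coincide.
#' @export
residual_point_to_point <- function(pose_a, local_a, pose_b, local_b) {
  rt_apply(pose_a, local_a) - rt_apply(pose_b, local_b)
}

#' Point-on-line constraint residual
#'
#' Offset of a point (fixed on one body) from a line (fixed on another),
#' projected on the two fixed unit vectors that complete an orthonormal
#' basis with the line direction. Sliding along the line leaves the
#' residual unchanged.
#'
#' @param pose_point_body world pose of the body carrying the point.
#' @param local_point local point 3-vector (meters).
#' @param pose_line_body world pose of the body carrying the line.
#' @param line list with `point` (local 3-vector), `dir` (local unit
#'   3-vector) and `basis` (2 x 3 matrix of completion vectors); as stored
#'   in a `point_on_line2` [constraint_spec()].
#' @return Numeric 2-vector (meters).
#' @export
residual_point_on_line <- function(pose_point_body, local_point,
                                   pose_line_body, line) {
  world_pt <- rt_apply(pose_point_body, local_point)
  local_in_b <- rt_apply(rt_invert(pose_line_body), world_pt)
  as.numeric(line$basis %*% (local_in_b - line$point))
}

#' Default human-exoskeleton constraint set
#'
#' The fixation set used for estimation: the structural pelvis-corset weld
#' (no residual rows), one point-on-line constraint between a mid-shank
#' point on the tibia and the exoskeleton shank bar axis, and three
#' point-to-point constraints between heel / first-metatarsal /
#' fifth-metatarsal sole points of the foot and the exoskeleton sole —
#' 11 residual components in total. Exoskeleton-side anchors are
#' calibrated so that every residual is exactly zero at the static
#' posture.
#'
#' @param coupled a `coupled_model` from [assemble_coupled()].
#' @param tibia_point local tibia anchor override (3-vector, meters).
#' @param foot_points optional list of three local foot anchors.
#' @return A [constraint_set()].
#' @export
make_default_constraint_set <- function(coupled, tibia_point = NULL,
                                        foot_points = NULL) {
  stopifnot(inherits(coupled, "coupled_model"))
  model <- coupled$model
  lt <- model$segments[["tibia"]]$length
  lo <- model$segments[["foot"]]$length
  if (is.null(tibia_point)) tibia_point <- c(0.01, -lt / 2, 0.05)
  if (is.null(foot_points))
    foot_points <- list(heel = c(-0.05, -0.12 * lo, 0.01),
                        first_met = c(0, -0.40 * lo, -0.02),
                        fifth_met = c(0, -0.88 * lo, 0.03))
  fk <- forward_kinematics(model, coupled$static_posture, warn_limits = FALSE)
  # exo-side anchors: images of the static human anchor positions
  tib_world <- rt_apply(fk[["tibia"]], tibia_point)
  line_point <- rt_apply(rt_invert(fk[["exo_shank"]]), tib_world)
  specs <- list(
    constraint_spec("weld6", segment_a = "pelvis", point_a = c(0, 0, 0),
                    segment_b = "corset", point_b = c(0, 0, 0)),
    constraint_spec("point_on_line2", segment_a = "tibia",
                    point_a = tibia_point, segment_b = "exo_shank",
                    point_b = line_point, line_dir = c(0, 1, 0)))
  sole_inv <- rt_invert(fk[["exo_sole"]])
  for (nm in names(foot_points)) {
    p <- foot_points[[nm]]
    sole_anchor <- rt_apply(sole_inv, rt_apply(fk[["foot"]], p))
    specs[[length(specs) + 1L]] <-
      constraint_spec("point_to_point3", segment_a = "foot", point_a = p,
                      segment_b = "exo_sole", point_b = sole_anchor)
  }
  constraint_set(specs)
}

#' Stacked constraint residuals of the coupled model
#'
#' Evaluates every non-structural constraint at the configuration given by
#' the human and exoskeleton coordinates (tibia point-on-line first, then
#' the three foot point-to-point constraints).
#'
#' @param coupled a `coupled_model`.
#' @param cs a [constraint_set()].
#' @param q_H human angles (hip, knee, ankle; degrees).
#' @param q_R exoskeleton angles (hip, knee, ankle; degrees).
#' @param base optional base pose coordinates (defaults to the static pose;
#'   residuals are invariant to it).
#' @return Numeric vector of length `cs$residual_dim` (meters).
#' @export
constraint_residuals <- function(coupled, cs, q_H, q_R, base = NULL) {
  q <- coupled_q(coupled, human = q_H, exo = q_R, base = base)
  fk <- forward_kinematics(coupled$model, q, warn_limits = FALSE)
  eval_constraint_residuals(fk, cs)
}

# residuals from a precomputed FK pose list (hot path)
eval_constraint_residuals <- function(fk, cs) {
  out <- numeric(cs$residual_dim)
  i <- 0L
  for (s in cs$specs) {
    if (s$kind == "weld6") next
    if (s$kind == "point_on_line2") {
      r <- residual_point_on_line(fk[[s$segment_a]], s$point_a,
                                  fk[[s$segment_b]],
                                  list(point = s$point_b, dir = s$line_dir,
                                       basis = s$basis))
    } else {
      r <- residual_point_to_point(fk[[s$segment_a]], s$point_a,
                                   fk[[s$segment_b]], s$point_b)
    }
    out[(i + 1L):(i + length(r))] <- r
    i <- i + length(r)
  }
  out
}
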