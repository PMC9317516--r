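# 3D primitives shared by all stages: trajectories, rigid transforms,
# angles, and cylinder containment. World coordinates are millimetres
# throughout; directions are unit vectors oriented "into bone".

#' Screw or drill trajectory
#'
#' A trajectory is a directed cylinder axis in world coordinates: the entry
#' point on (or near) the bone surface, a unit direction pointing into the
#' bone, and the screw length and radius.
#'
#' @param entry Numeric length-3, entry point in world mm.
#' @param direction Numeric length-3; normalized internally. Must be non-zero.
#' @param length Cylinder length in mm, positive.
#' @param radius Cylinder radius in mm, positive.
#' @param id Optional identifier carried through tables.
#' @return An object of class `trajectory`.
#' @examples
#' trajectory(c(0, 0, 0), c(0, 0, 1), length = 30, radius = 1.75)
#' @export
trajectory <- function(entry, direction, length, radius, id = NULL) {
  entry <- as.numeric(entry)
  direction <- as.numeric(direction)
  if (length(entry) != 3L || length(direction) != 3L)
    stop("entry and direction must be length-3 numeric vectors", call. = FALSE)
  if (!all(is.finite(entry)) || !all(is.finite(direction)))
    stop("trajectory coordinates must be finite", call. = FALSE)
  if (vnorm(direction) < 1e-12)
    stop("trajectory direction must be non-zero", call. = FALSE)
  if (!is.numeric(length) || length <= 0 || !is.numeric(radius) || radius <= 0)
    stop("trajectory length and radius must be positive", call. = FALSE)
  structure(list(entry = entry, direction = unit(direction),
                 length = as.numeric(length), radius = as.numeric(radius),
                 id = id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory%s: entry (%.2f, %.2f, %.2f) mm, direction (%.3f, %.3f, %.3f), L=%.1f mm, r=%.2f mm\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$entry[1], x$entry[2], x$entry[3],
              x$direction[1], x$direction[2], x$direction[3],
              x$length, x$radius))
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' Represents a proper rigid motion `p -> R p + t` mapping one frame onto
#' another (e.g. the post-operative scan frame onto the planning frame).
#'
#' @param rotation 3x3 rotation matrix; must be orthonormal with
#'   determinant +1 (checked to 1e-9).
#' @param translation Numeric length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @seealso [rt_compose()], [rt_invert()], [apply_transform()]
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  translation <- as.numeric(translation)
  if (length(translation) != 3L)
    stop("translation must have length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: %.3f deg about (%.3f, %.3f, %.3f), translation (%.2f, %.2f, %.2f) mm\n",
              rt_angle(x), rt_axis(x)[1], rt_axis(x)[2], rt_axis(x)[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity rigid transform
#' @return A `rigid_transform` leaving every point fixed.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Rigid transform from axis and angle
#'
#' @param axis Rotation axis (any non-zero 3-vector, normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @param center Point the rotation pivots about (default origin).
#' @param translation Extra translation applied after the rotation.
#' @return A `rigid_transform`.
#' @export
rt_from_axis_angle <- function(axis, angle_deg, center = c(0, 0, 0),
                               translation = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  center <- as.numeric(center)
  t <- as.numeric(center) - as.vector(R %*% center) + as.numeric(translation)
  rigid_transform(R, t)
}

# Rodrigues rotation matrix about a unit axis.
rotation_matrix <- function(axis, angle_deg) {
  a <- unit(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rigid transform (degrees)
#' @param t A `rigid_transform`.
#' @return Rotation magnitude in degrees, in \[0, 180\].
#' @export
rt_angle <- function(t) {
  R <- t$rotation
  # atan2(sin, cos) form: well conditioned near 0 deg, where the
  # acos((trace-1)/2) form amplifies rounding error to ~sqrt(eps)
  st <- vnorm(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])) / 2
  ct <- (sum(diag(R)) - 1) / 2
  atan2(st, ct) * 180 / pi
}

#' Rotation axis of a rigid transform
#' @param t A `rigid_transform`.
#' @return Unit rotation axis (arbitrary for the identity).
#' @export
rt_axis <- function(t) {
  R <- t$rotation
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(v) < 1e-12) return(c(0, 0, 1))
  unit(v)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_invert <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param p A length-3 point or an n x 3 matrix of points (mm).
#' @return Transformed point(s), same shape as the input.
#' @export
apply_transform <- function(t, p) {
  if (is.matrix(p)) {
    p %*% t(t$rotation) + matrix(t$translation, nrow(p), 3L, byrow = TRUE)
  } else {
    as.vector(t$rotation %*% as.numeric(p)) + t$translation
  }
}

#' Apply a rigid transform to a trajectory
#' @param t A `rigid_transform`.
#' @param traj A `trajectory`.
#' @return The transformed `trajectory`.
#' @export
transform_trajectory <- function(t, traj) {
  trajectory(apply_transform(t, traj$entry),
             as.vector(t$rotation %*% traj$direction),
             traj$length, traj$radius, id = traj$id)
}

#' Random rigid transform
#'
#' Draws a rotation about a uniformly random axis with angle uniform on
#' `[0, max_angle_deg]` and a translation uniform in the ball of radius
#' `max_translation_mm`, optionally pivoting about `center`. Uses the
#' current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param max_angle_deg Maximum rotation angle (degrees).
#' @param max_translation_mm Maximum translation norm (mm).
#' @param center Pivot point for the rotation.
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_angle_deg, max_translation_mm,
                                   center = c(0, 0, 0)) {
  ax <- stats::rnorm(3)
  while (vnorm(ax) < 1e-6) ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, max_angle_deg)
  tr <- stats::rnorm(3)
  tr <- unit(tr) * max_translation_mm * stats::runif(1)^(1 / 3)
  rt_from_axis_angle(ax, ang, center = center, translation = tr)
}

#' Angle between two vectors in degrees
#'
#' The 3D angular deviation between a planned and a realized screw axis:
#' `acos(u . v / (|u||v|))` with the cosine clamped to `[-1, 1]`.
#'
#' @param u,v Non-zero 3-vectors (any magnitude; only directions matter).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' angle_between(c(0, 0, 1), c(1, 0, 0)) # 90
#' @export
angle_between <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12)
    stop("angle_between: zero-length vector", call. = FALSE)
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

# Orthonormal frame (u, v) perpendicular to a unit direction d, chosen
# deterministically so that repeated calls agree.
make_frame <- function(d) {
  d <- unit(d)
  a <- if (abs(d[1]) <= abs(d[2]) && abs(d[1]) <= abs(d[3])) c(1, 0, 0)
       else if (abs(d[2]) <= abs(d[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- unit(cross3(a, d))
  v <- cross3(d, u)
  list(u = u, v = v)
}

# Sample points on the lateral surface of a trajectory's cylinder.
cylinder_surface_points <- function(traj, n_axial, n_circ) {
  fr <- make_frame(traj$direction)
  ts <- seq(0, traj$length, length.out = n_axial)
  ph <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  tg <- rep(ts, times = n_circ)
  pg <- rep(ph, each = n_axial)
  ring <- outer(cos(pg), fr$u) + outer(sin(pg), fr$v)
  ax <- outer(tg, traj$direction)
  sweep(traj$radius * ring + ax, 2L, traj$entry, "+")
}

#' Test whether one cylinder lies inside another
#'
#' Samples the lateral surface of `screw` on an `n_axial` x `n_circ` grid
#' and reports whether every sample lies within radial distance
#' `tube$radius` of the tube axis and within the tube's axial extent.
#' This is the containment predicate used by the pedicle breach
#' simulation.
#'
#' @param screw,tube `trajectory` objects (the screw and the containing tube).
#' @param n_axial Number of axial samples (>= 2).
#' @param n_circ Number of circumferential samples (>= 8).
#' @return Logical scalar.
#' @export
cylinder_contains <- function(screw, tube, n_axial = 50L, n_circ = 64L) {
  if (n_axial < 2L || n_circ < 8L)
    stop("need n_axial >= 2 and n_circ >= 8", call. = FALSE)
  pts <- cylinder_surface_points(screw, n_axial, n_circ)
  w <- sweep(pts, 2L, tube$entry)
  s <- as.vector(w %*% tube$direction)
  r2 <- pmax(rowSums(w * w) - s * s, 0)
  eps <- 1e-9
  all(s >= -eps & s <= tube$length + eps & r2 <= (tube$radius + eps)^2)
}
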