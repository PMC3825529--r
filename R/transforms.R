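#' Rigid transforms and wrenches
#'
#' The pose of every fragment, group, handle and cursor in the toolkit is a
#' rigid transform: a unit quaternion (scalar-first, right-handed, active
#' rotation) plus a translation in millimetres. Forces are carried around as
#' wrenches: a force (N) and torque (N.mm) pair together with the world-frame
#' reference point the torque is expressed about.
#'
#' Quaternions `q` and `-q` encode the same rotation and are treated as equal
#' everywhere.
#'
#' @name core-geometry
NULL

.check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", what), call. = FALSE)
  }
  invisible(x)
}

#' Construct a rigid transform
#'
#' @param q Unit quaternion, scalar first `c(w, x, y, z)`. Renormalised on
#'   construction; the zero quaternion is rejected.
#' @param t Translation, mm, length-3.
#' @return A `rigid_transform` object.
#' @examples
#' rigid_transform()                       # identity
#' rigid_transform(q = c(sqrt(0.5), 0, 0, sqrt(0.5)), t = c(1, 2, 3))
#' @export
rigid_transform <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  .check_finite(q, "q")
  .check_finite(t, "t")
  stopifnot(length(q) == 4, length(t) == 3)
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion is not a rotation", call. = FALSE)
  structure(list(q = q / n, t = as.numeric(t)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> q = [", paste(signif(x$q, 6), collapse = ", "),
      "], t = [", paste(signif(x$t, 6), collapse = ", "), "] mm\n")
  invisible(x)
}

#' @rdname rigid_transform
#' @export
transform_identity <- function() rigid_transform()

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

#' Rotation matrix of a unit quaternion
#' @noRd
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from axis-angle
#' @noRd
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' Quaternion from a rotation vector (axis * angle, radians)
#' @noRd
quat_from_rotvec <- function(v) {
  angle <- sqrt(sum(v^2))
  if (angle < 1e-15) return(c(1, 0, 0, 0))
  quat_from_axis_angle(v / angle, angle)
}

#' Shortest-arc rotation vector (axis * angle) of a unit quaternion
#' @noRd
quat_to_rotvec <- function(q) {
  if (q[1] < 0) q <- -q
  w <- min(1, max(-1, q[1]))
  angle <- 2 * acos(w)
  s <- sqrt(max(0, 1 - w^2))
  if (s < 1e-12) return(c(0, 0, 0))
  (q[2:4] / s) * angle
}

#' Sign-insensitive angle between two unit quaternions, radians
#'
#' Uses the chord identity |a - b| = 2 sin(theta/4), which stays accurate
#' for angles far below what acos of the dot product can resolve.
#' @noRd
quat_angle <- function(a, b) {
  d <- min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))
  4 * asin(min(1, d / 2))
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` maps a point `p` as `a(b(p))`. The quaternion of the
#' result is renormalised so repeated composition never drifts off the unit
#' sphere.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  q <- quat_multiply(a$q, b$q)
  t <- as.numeric(quat_to_matrix(a$q) %*% b$t) + a$t
  rigid_transform(q, t)
}

#' Invert a rigid transform
#' @param a A `rigid_transform`.
#' @return A `rigid_transform` with `compose(a, transform_inverse(a))` the
#'   identity.
#' @export
transform_inverse <- function(a) {
  stopifnot(is_rigid_transform(a))
  qi <- quat_conjugate(a$q)
  rigid_transform(qi, -as.numeric(quat_to_matrix(qi) %*% a$t))
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param points Numeric matrix `N x 3` (mm) or a length-3 vector.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(t, points) {
  stopifnot(is_rigid_transform(t))
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, nrow = 1)
  .check_finite(points, "points")
  stopifnot(ncol(points) == 3)
  out <- points %*% t(quat_to_matrix(t$q))
  out <- sweep(out, 2, t$t, "+")
  if (vec) as.numeric(out) else out
}

#' Rotate direction vectors (no translation)
#' @noRd
rotate_vectors <- function(t, vecs) {
  vecd <- is.null(dim(vecs))
  if (vecd) vecs <- matrix(vecs, nrow = 1)
  out <- vecs %*% t(quat_to_matrix(t$q))
  if (vecd) as.numeric(out) else out
}

#' Do two transforms agree within tolerance?
#'
#' Rotation compared by sign-insensitive quaternion angle, translation by
#' Euclidean distance.
#'
#' @param a,b `rigid_transform` objects.
#' @param tol_rot Radians.
#' @param tol_trans Millimetres.
#' @export
transforms_equal <- function(a, b, tol_rot = 1e-9, tol_trans = 1e-9) {
  quat_angle(a$q, b$q) <= tol_rot && sqrt(sum((a$t - b$t)^2)) <= tol_trans
}

#' Pose error between two transforms
#'
#' @param a,b `rigid_transform` objects.
#' @param point Optional world point (mm) at which translational error is
#'   measured as `|a(point) - b(point)|`; default compares the raw
#'   translations.
#' @return Named vector `c(trans_mm, rot_deg)`; rotation is the
#'   shortest-arc angle between the two orientations.
#' @export
pose_error <- function(a, b, point = NULL) {
  rot <- quat_angle(a$q, b$q) * 180 / pi
  if (is.null(point)) {
    tr <- sqrt(sum((a$t - b$t)^2))
  } else {
    tr <- sqrt(sum((apply_transform(a, point) - apply_transform(b, point))^2))
  }
  c(trans_mm = tr, rot_deg = rot)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a wrench
#'
#' @param force Length-3 force, N.
#' @param torque Length-3 torque, N.mm, about `point`.
#' @param point World reference point, mm.
#' @return A `wrench` object.
#' @export
wrench <- function(force = c(0, 0, 0), torque = c(0, 0, 0), point = c(0, 0, 0)) {
  .check_finite(force, "force"); .check_finite(torque, "torque")
  .check_finite(point, "point")
  stopifnot(length(force) == 3, length(torque) == 3, length(point) == 3)
  structure(list(force = as.numeric(force), torque = as.numeric(torque),
                 point = as.numeric(point)),
            class = "wrench")
}

#' @export
print.wrench <- function(x, ...) {
  cat(sprintf("<wrench> |F| = %.4g N, |T| = %.4g N.mm about [%s] mm\n",
              sqrt(sum(x$force^2)), sqrt(sum(x$torque^2)),
              paste(signif(x$point, 4), collapse = ", ")))
  invisible(x)
}

#' Re-express a wrench about a new reference point
#'
#' The force is unchanged; the torque gains `(old_point - new_point) x force`.
#'
#' @param w A `wrench`.
#' @param new_point Length-3 world point, mm.
#' @return A `wrench` about `new_point`.
#' @export
shift_wrench <- function(w, new_point) {
  stopifnot(inherits(w, "wrench"))
  .check_finite(new_point, "new_point")
  wrench(w$force,
         w$torque + cross3(w$point - new_point, w$force),
         new_point)
}

#' Add wrenches about a common reference point
#' @noRd
add_wrenches <- function(a, b) {
  b <- shift_wrench(b, a$point)
  wrench(a$force + b$force, a$torque + b$torque, a$point)
}

transform_to_json <- function(tr) list(q = tr$q, t = tr$t)

transform_from_json <- function(x) {
  rigid_transform(as.numeric(unlist(x$q)), as.numeric(unlist(x$t)))
}
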