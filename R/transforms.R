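# Rigid transforms in 3-d: p' = R p + t, with R a proper rotation.
# All lengths are millimetres; user-facing angles are degrees.

#' Create a rigid transform
#'
#' A rigid transform maps a point `p` to `R p + t`. The rotation block must
#' be orthonormal with determinant +1 (reflections are rejected); the
#' translation is in millimetres.
#'
#' @param rotation 3x3 orthonormal rotation matrix (determinant +1).
#' @param translation Numeric 3-vector, mm.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' identity_tf <- rigid_transform()
#' tf <- rigid_transform(rotation_about_axis("z", 90), c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  cm_assert(is.matrix(rotation) && all(dim(rotation) == c(3L, 3L)) &&
              is.numeric(rotation) && all(is.finite(rotation)),
            "rotation must be a finite 3x3 numeric matrix", "validation_error")
  translation <- as.numeric(translation)
  cm_assert(length(translation) == 3L && all(is.finite(translation)),
            "translation must be a finite 3-vector", "validation_error")
  ortho <- max(abs(crossprod(rotation) - diag(3)))
  cm_assert(ortho < 1e-9, sprintf(
    "rotation block is not orthonormal (max |R'R - I| = %.3g)", ortho),
    "validation_error")
  dt <- det(rotation)
  cm_assert(abs(dt - 1) < 1e-9, sprintf(
    "rotation block is not a proper rotation (det = %.6f); reflections are invalid",
    dt), "validation_error")
  structure(list(R = unname(rotation), t = unname(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  ang <- rotation_angle_deg(x$R)
  cat(sprintf("  rotation angle: %.4f deg, translation: [%.4f %.4f %.4f] mm\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

rotation_angle_deg <- function(R) {
  rad2deg(acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))))
}

#' Apply a rigid transform to points
#'
#' @param points N x 3 matrix of mm coordinates.
#' @param transform A [rigid_transform()].
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(points, transform) {
  points <- as_point_matrix(points)
  sweep(points %*% t(transform$R), 2L, transform$t, "+")
}

#' Compose and invert rigid transforms
#'
#' `compose(a, b)` returns the transform that applies `b` first and then `a`;
#' `invert(a)` returns the inverse, so that `compose(invert(a), a)` is the
#' identity.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

#' @rdname compose
#' @export
invert <- function(a) {
  rigid_transform(t(a$R), as.vector(-t(a$R) %*% a$t))
}

#' Elementary rotation about a coordinate axis
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- deg2rad(angle_deg)
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

# Fixed-axes x -> y -> z convention: R = Rz(rz) %*% Ry(ry) %*% Rx(rx),
# angles in degrees. This is the one Euler convention used package-wide.
euler_to_rotation <- function(rx, ry, rz) {
  rotation_about_axis("z", rz) %*% rotation_about_axis("y", ry) %*%
    rotation_about_axis("x", rx)
}

# Inverse of euler_to_rotation. Near gimbal lock (|ry| = 90 deg) rx and rz
# are not separable; rx is set to 0 by convention and the result is flagged
# with attribute "gimbal_lock".
rotation_to_euler <- function(R) {
  sy <- -R[3, 1]
  sy <- min(1, max(-1, sy))
  ry <- asin(sy)
  gimbal <- abs(abs(ry) - pi / 2) < 1e-6
  if (gimbal) {
    rx <- 0
    # with ry = +/-90: R[1,2] = -sin(rz -/+ rx) * ..., fold into rz
    rz <- atan2(-R[1, 2], R[2, 2])
  } else {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  }
  out <- rad2deg(c(rx = rx, ry = ry, rz = rz))
  attr(out, "gimbal_lock") <- gimbal
  out
}

#' Movement components of one tooth
#'
#' The six scalars describing a tooth displacement in an arch coordinate
#' frame: translations `Tx`, `Ty`, `Tz` in millimetres along the frame axes
#' and rotations `Rx`, `Ry`, `Rz` in degrees about them (fixed-axes
#' x–y–z composition order).
#'
#' @param Tx,Ty,Tz Translations, mm.
#' @param Rx,Ry,Rz Rotations, degrees; must lie in \[-180, 180\].
#' @return Named numeric vector of class `movement_components`.
#' @export
movement_components <- function(Tx = 0, Ty = 0, Tz = 0, Rx = 0, Ry = 0, Rz = 0) {
  out <- c(Tx = Tx, Ty = Ty, Tz = Tz, Rx = Rx, Ry = Ry, Rz = Rz)
  cm_assert(all(is.finite(out)), "movement components must be finite",
            "validation_error")
  cm_assert(all(abs(out[c("Rx", "Ry", "Rz")]) <= 180),
            "rotation components must lie in [-180, 180] degrees",
            "validation_error")
  class(out) <- c("movement_components", "numeric")
  out
}

#' @export
print.movement_components <- function(x, ...) {
  cat(sprintf("T = [%.4f %.4f %.4f] mm, R = [%.4f %.4f %.4f] deg\n",
              x["Tx"], x["Ty"], x["Tz"], x["Rx"], x["Ry"], x["Rz"]))
  invisible(x)
}
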