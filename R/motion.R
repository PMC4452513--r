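#' Rigid motion (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation vector (mm).
#' @return object of class `rigid_motion`.
#' @export
rigid_motion <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-8) stop("rotation must have det +1")
  structure(list(R = rotation, t = translation), class = "rigid_motion")
}

#' @export
print.rigid_motion <- function(x, ...) {
  ang <- motion_angle(x)
  cat(sprintf("<rigid_motion> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$t[1L], x$t[2L], x$t[3L]))
  invisible(x)
}

#' Apply a rigid motion to points
#' @param motion a [rigid_motion()].
#' @param points n x 3 matrix (mm).
#' @return moved n x 3 matrix.
#' @export
apply_motion <- function(motion, points) {
  points <- rbind(points)
  sweep(points %*% t(motion$R), 2L, -motion$t)
}

#' Compose rigid motions: `a` after `b`
#' @param a,b [rigid_motion()] objects.
#' @return the motion `x -> a(b(x))`.
#' @export
compose_motion <- function(a, b) {
  rigid_motion(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid motion
#' @param motion a [rigid_motion()].
#' @return the inverse motion.
#' @export
invert_motion <- function(motion) {
  rigid_motion(t(motion$R), as.numeric(-t(motion$R) %*% motion$t))
}

#' Rotation angle of a motion in degrees
#' @param motion a [rigid_motion()].
#' @return rotation angle in degrees (0 for a pure translation).
#' @export
motion_angle <- function(motion) {
  c <- (sum(diag(motion$R)) - 1) / 2
  acos(max(-1, min(1, c))) * 180 / pi
}

#' Rotation about an axis
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @param translation optional translation.
#' @return a [rigid_motion()].
#' @export
axis_rotation <- function(axis, angle_deg, translation = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_motion(R, translation)
}

# least-squares rigid fit (Kabsch): returns the motion mapping `from`
# points onto `to` points
.fit_rigid <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- crossprod(sweep(from, 2L, cf), sweep(to, 2L, ct))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_motion(R, ct - as.numeric(R %*% cf))
}
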