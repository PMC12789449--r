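#' Rigid transform (proper rotation + translation)
#'
#' Constructs a rigid-body transform of 3-space: a proper rotation `rotation`
#' (3x3 orthonormal, det = +1) followed by a translation `translation` (mm).
#' A point `p` is mapped to `rotation %*% p + translation`.
#'
#' @param rotation 3x3 rotation matrix. Orthonormality and `det = +1` are
#'   checked to within `tol`.
#' @param translation numeric length-3 translation vector in mm.
#' @param tol tolerance for the orthonormality / determinant check.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' tf <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(1, 0, 0))
#' transform_points(tf, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-7) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!identical(dim(rotation), c(3L, 3L)) || !is.numeric(rotation)) {
    stop("`rotation` must be a numeric 3x3 matrix", call. = FALSE)
  }
  if (length(translation) != 3 || anyNA(translation)) {
    stop("`translation` must be a numeric 3-vector", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    stop("`rotation` is not orthonormal", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > tol) {
    stop("`rotation` must be a proper rotation (det = +1); reflections are rejected",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform>  rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points an n x 3 matrix of points (or a single length-3 vector), mm.
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(transform, points) {
  stopifnot(is_rigid_transform(transform))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, ncol = 3) else as.matrix(points)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  if (vec) drop(out) else out
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `second` after `first`
#' (`compose(second, first)(p) = second(first(p))`).
#'
#' @param second,first [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
transform_compose <- function(second, first) {
  stopifnot(is_rigid_transform(second), is_rigid_transform(first))
  rigid_transform(second$rotation %*% first$rotation,
                  drop(second$rotation %*% first$translation) + second$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
transform_invert <- function(transform) {
  stopifnot(is_rigid_transform(transform))
  rt <- t(transform$rotation)
  rigid_transform(rt, drop(-rt %*% transform$translation))
}

#' Rotation matrix about an arbitrary axis
#'
#' Active right-handed rotation by `angle_deg` degrees about the direction
#' `axis` (through the origin), via Rodrigues' formula.
#'
#' @param axis length-3 direction (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero", call. = FALSE)
  u <- axis / n
  a <- angle_deg * pi / 180
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * k + (1 - cos(a)) * (k %*% k)
}

#' Rigid rotation about a point
#'
#' Rotation by `angle_deg` about `axis` passing through `centre` (a rigid
#' transform that leaves `centre` fixed).
#'
#' @inheritParams rotation_about_axis
#' @param centre length-3 point the rotation axis passes through, mm.
#' @return A [rigid_transform()].
#' @export
rotation_about_point <- function(axis, angle_deg, centre = c(0, 0, 0)) {
  r <- rotation_about_axis(axis, angle_deg)
  centre <- as.numeric(centre)
  rigid_transform(r, centre - drop(r %*% centre))
}

# unsigned rotation angle of a rotation matrix, degrees
rotation_angle <- function(r) {
  c_ <- (sum(diag(r)) - 1) / 2
  acos(max(-1, min(1, c_))) * 180 / pi
}

# uniform random unit vector (consumes the global RNG)
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# uniform random rotation (axis uniform on the sphere, angle uniform): used
# only for test-style scrambling, not for the calibrated error model
random_rotation_matrix <- function(max_angle_deg = 180) {
  rotation_about_axis(random_unit_vector(), stats::runif(1, 0, max_angle_deg))
}

unit3 <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a near-zero vector", call. = FALSE)
  v / n
}

#' Rotation taking one direction onto another
#'
#' Smallest-angle proper rotation mapping direction `from` onto direction
#' `to`. Antiparallel inputs rotate 180 degrees about an arbitrary
#' perpendicular axis.
#'
#' @param from,to length-3 directions (need not be unit).
#' @return A 3x3 rotation matrix `R` with `R from ∝ to`.
#' @export
rotation_between <- function(from, to) {
  f <- unit3(from); t_ <- unit3(to)
  v <- c(f[2] * t_[3] - f[3] * t_[2],
         f[3] * t_[1] - f[1] * t_[3],
         f[1] * t_[2] - f[2] * t_[1])
  s <- sqrt(sum(v^2)); c_ <- sum(f * t_)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: any perpendicular axis works
    perp <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- perp - sum(perp * f) * f
    return(rotation_about_axis(axis, 180))
  }
  k <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + k + k %*% k * ((1 - c_) / s^2)
}
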