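#' Rigid transform (rotation + translation)
#'
#' The currency of extrinsic calibration and registration: a proper rotation
#' `R` (3 x 3, det = +1) and a translation `t` in millimetres, acting on
#' column points as `p' = R p + t`.
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 numeric translation (mm).
#' @return An object of class `rigid_transform` with fields `rotation` and
#'   `translation`.
#' @examples
#' T1 <- rigid_transform(rotation_about(c(0, 0, 1), pi / 2), c(1, 0, 0))
#' transform_points(T1, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  check_that(all(dim(rotation) == c(3, 3)), "rotation must be 3 x 3")
  translation <- as.numeric(translation)
  check_that(length(translation) == 3, "translation must be a 3-vector")
  check_that(max(abs(crossprod(rotation) - diag(3))) < 1e-9,
             "rotation must be orthogonal (R'R = I within 1e-9)")
  check_that(abs(det(rotation) - 1) < 1e-9,
             "rotation must be proper (det R = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", format(round(x$translation, 4)), "\n")
  invisible(x)
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis (normalised internally).
#' @param angle angle in radians.
#' @return 3 x 3 rotation matrix (Rodrigues formula).
#' @export
rotation_about <- function(axis, angle) {
  a <- as.numeric(axis)
  check_that(length(a) == 3 && sum(a^2) > 0, "axis must be a nonzero 3-vector")
  a <- a / sqrt(sum(a^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` returns the transform applying `b` first and
#' `a` second: `p' = a(b(p))`.
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  Rt <- t(x$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% x$translation))
}

#' Apply a rigid transform to points
#' @param transform A `rigid_transform`.
#' @param points N x 3 matrix (or single 3-vector) of points.
#' @return N x 3 matrix of transformed points.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  p <- as_point_matrix(points)
  sweep(p %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Convert to / from a 4 x 4 homogeneous matrix
#' @param x A `rigid_transform` (for `transform_matrix`) or a 4 x 4 matrix
#'   (for `transform_from_matrix`).
#' @return `transform_matrix`: 4 x 4 homogeneous matrix;
#'   `transform_from_matrix`: a `rigid_transform`.
#' @export
transform_matrix <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  m <- diag(4)
  m[1:3, 1:3] <- x$rotation
  m[1:3, 4] <- x$translation
  m
}

#' @rdname transform_matrix
#' @export
transform_from_matrix <- function(x) {
  x <- as.matrix(x)
  check_that(all(dim(x) == c(4, 4)), "expected a 4 x 4 homogeneous matrix")
  check_that(max(abs(x[4, ] - c(0, 0, 0, 1))) < 1e-9,
             "bottom row must be (0, 0, 0, 1)")
  rigid_transform(x[1:3, 1:3], x[1:3, 4])
}

#' Angle of a rotation matrix
#'
#' Magnitude of the rotation, in radians, recovered from the trace.
#' @param rotation 3 x 3 rotation matrix.
#' @return Angle in `[0, pi]`.
#' @export
rotation_angle <- function(rotation) {
  acos(max(-1, min(1, (sum(diag(rotation)) - 1) / 2)))
}
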