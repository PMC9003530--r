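#' Centroid of a point set
#'
#' Coordinate-wise mean of an N x 3 point set.
#' @param points N x 3 matrix.
#' @return Length-3 numeric centroid.
#' @export
centroid <- function(points) {
  p <- as_point_matrix(points)
  check_that(nrow(p) >= 1, "point set must be nonempty")
  colMeans(p)
}

#' Root mean square deviation between matched point sets
#'
#' `sqrt(mean(|p_k - q_k|^2))` over paired rows.
#' @param P,Q N x 3 matrices of matched points.
#' @return RMSD in the points' units.
#' @export
rmsd <- function(P, Q) {
  P <- as_point_matrix(P, "P")
  Q <- as_point_matrix(Q, "Q")
  check_that(nrow(P) == nrow(Q), "P and Q must have the same number of points")
  check_that(nrow(P) >= 1, "point sets must be nonempty")
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Kabsch rigid superposition
#'
#' Closed-form least-squares rigid alignment of matched point sets. Both
#' sets are centred, the cross-covariance `H = P'Q` of the centred sets is
#' decomposed by SVD `H = V S W'`, the sign `d = sign(det(W V'))` guards
#' against reflections, and the optimal proper rotation mapping `Q` onto
#' `P` is assembled from `V`, `W` and `d`. The translation is the standard
#' least-squares completion `t = centroid(P) - R centroid(Q)`.
#'
#' @param P N x 3 reference points (mm).
#' @param Q N x 3 matched points (mm) to be mapped onto `P`.
#' @return List with `transform` (a [rigid_transform()] such that
#'   `R q + t` best matches `p`) and `rmsd` (the residual RMSD of the
#'   aligned sets, mm).
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' R0 <- rotation_about(c(0, 0, 1), pi / 2)
#' Q <- t(t(P) - c(5, 0, 0)) %*% R0  # Q = R0^T (P - t0)
#' kabsch(P, Q)$rmsd                 # ~0: exact recovery
#' @export
kabsch <- function(P, Q) {
  P <- as_point_matrix(P, "P")
  Q <- as_point_matrix(Q, "Q")
  check_that(nrow(P) == nrow(Q), "P and Q must have the same number of points")
  if (nrow(P) < 3)
    ls_stop("at least 3 correspondences are required", "degenerate_configuration")
  cP <- colMeans(P)
  cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP)
  Qc <- sweep(Q, 2, cQ)
  # A configuration of rank < 2 (all points collinear) leaves the rotation
  # about the line undetermined.
  if (svd(Pc, nu = 0, nv = 0)$d[2] < 1e-9 * max(1, max(abs(Pc))))
    ls_stop("degenerate (collinear) point configuration", "degenerate_configuration")
  H <- crossprod(Pc, Qc)  # P'Q on the centred sets
  s <- svd(H)
  V <- s$u
  W <- s$v
  d <- sign(det(W %*% t(V)))
  # Rotation mapping Q onto P; d = -1 swaps in the reflection-free optimum.
  R <- V %*% diag(c(1, 1, d)) %*% t(W)
  t_vec <- cP - as.numeric(R %*% cQ)
  transform <- rigid_transform(R, t_vec)
  list(transform = transform,
       rmsd = rmsd(P, transform_points(transform, Q)))
}

#' Multi-camera extrinsic calibration from shared checkerboard corners
#'
#' Every camera observes the full ordered set of inner checkerboard corners
#' in its own frame. Kabsch alignment of the board model onto each
#' observation gives the camera-from-board transform; chaining through the
#' board yields each camera's pose relative to the chosen reference camera:
#' `extrinsic_i = (reference-from-board) o (camera_i-from-board)^-1`, which
#' maps camera-i coordinates into the reference camera's frame.
#'
#' @param corner_sets list (one element per camera) of N x 3 matrices of
#'   corner coordinates observed in each camera's frame, in board-model
#'   order; every camera must observe every corner.
#' @param board_model N x 3 matrix of the corner coordinates in the board
#'   frame (see [checkerboard_model()]).
#' @param reference_camera index of the camera whose frame becomes global.
#' @return Named list of [rigid_transform()], one per camera, mapping that
#'   camera's coordinates into the reference camera's frame; the reference
#'   camera maps to the identity.
#' @export
calibrate_rig <- function(corner_sets, board_model, reference_camera = 1) {
  check_that(is.list(corner_sets) && length(corner_sets) >= 1,
             "corner_sets must be a nonempty list")
  board_model <- as_point_matrix(board_model, "board_model")
  n_corner <- nrow(board_model)
  check_that(reference_camera >= 1 && reference_camera <= length(corner_sets),
             "reference_camera out of range")
  cam_from_board <- lapply(seq_along(corner_sets), function(i) {
    obs <- corner_sets[[i]]
    if (is.null(obs) || nrow(as_point_matrix(obs, "corners")) != n_corner)
      ls_stop(sprintf("camera %d does not observe all %d corners", i, n_corner),
              "incomplete_observation")
    kabsch(P = obs, Q = board_model)$transform
  })
  ref_from_board <- cam_from_board[[reference_camera]]
  out <- lapply(cam_from_board, function(T_cb)
    compose_transform(ref_from_board, invert_transform(T_cb)))
  names(out) <- names(corner_sets)
  out
}

#' Checkerboard corner model
#'
#' Ordered 3D coordinates of the inner corners of a checkerboard in the
#' board frame: origin at the first inner corner, x along columns, y along
#' rows, z = 0, row-major order.
#'
#' @param inner_rows,inner_cols inner-corner grid size (default 6 x 9).
#' @param square_mm square edge length in millimetres.
#' @return (inner_rows * inner_cols) x 3 matrix.
#' @export
checkerboard_model <- function(inner_rows = 6, inner_cols = 9, square_mm = 25) {
  check_that(inner_rows >= 2 && inner_cols >= 2, "board must be at least 2 x 2")
  check_that(square_mm > 0, "square size must be positive")
  g <- expand.grid(col = seq_len(inner_cols) - 1, row = seq_len(inner_rows) - 1)
  g <- g[order(g$row, g$col), ]
  cbind(g$col * square_mm, g$row * square_mm, 0)
}
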