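#' Camera rig layout
#'
#' Geometry of the capture rig: `n_radial` cameras equally spaced on a
#' circle of `frame_radius_mm` around the rig (z) axis, optical axes
#' pointing at the axis, each in a vertical stance (the wide image axis
#' runs along the rig axis to cover the most target length), plus an
#' optional end-view camera on the axis looking back at the distal tip.
#'
#' Default intrinsics follow a 1280 x 720 stereo depth camera with a
#' 69.4 x 42.5 degree field of view; the focal length is derived from the
#' horizontal field of view and shared by both axes (square pixels).
#'
#' @param frame_radius_mm radius of the camera circle (mm).
#' @param n_radial number of radial cameras.
#' @param end_camera add the end-view camera on the rig axis?
#' @param intrinsics a [camera_intrinsics()] shared by all cameras.
#' @param axial_position_mm height of the radial camera ring along the rig
#'   axis (mm); defaults to mid-phantom.
#' @param end_position_mm height of the end-view camera (mm), looking down
#'   the -z direction; defaults to the default phantom tip + 230 mm
#'   standoff.
#' @return An object of class `rig_layout`.
#' @export
rig_layout <- function(frame_radius_mm = 305, n_radial = 4, end_camera = TRUE,
                       intrinsics = NULL, axial_position_mm = 125,
                       end_position_mm = 480) {
  check_that(frame_radius_mm > 0 && n_radial >= 1, "invalid rig geometry")
  if (is.null(intrinsics)) {
    fx <- 640 / tan(34.7 * pi / 180)
    intrinsics <- camera_intrinsics(1280, 720, fx, fx, 640, 360)
  }
  structure(list(frame_radius_mm = frame_radius_mm,
                 n_radial = as.integer(n_radial),
                 end_camera = isTRUE(end_camera),
                 intrinsics = intrinsics,
                 axial_position_mm = axial_position_mm,
                 end_position_mm = end_position_mm),
            class = "rig_layout")
}

#' Ground-truth camera poses of a rig
#'
#' Radial poses sit on a circle of the frame radius with optical axes
#' intersecting the rig axis; consecutive radial poses are related by an
#' exact `360 / n_radial` degree rotation about the axis. The optional
#' end-view camera sits on the axis looking down at the target tip.
#'
#' @param layout A [rig_layout()].
#' @return Named list of [rigid_transform()] world-from-camera poses;
#'   radial cameras are named `radial<angle>`, the end camera `endview`.
#' @export
make_rig <- function(layout = rig_layout()) {
  stopifnot(inherits(layout, "rig_layout"))
  poses <- list()
  for (k in seq_len(layout$n_radial)) {
    theta <- 2 * pi * (k - 1) / layout$n_radial
    ct <- cos(theta); st <- sin(theta)
    # camera axes in world coordinates: +z toward the rig axis,
    # +x up the rig axis (vertical stance), +y completing right-handed
    R <- cbind(c(0, 0, 1), c(-st, ct, 0), c(-ct, -st, 0))
    t <- c(layout$frame_radius_mm * ct, layout$frame_radius_mm * st,
           layout$axial_position_mm)
    poses[[sprintf("radial%03.0f", theta * 180 / pi)]] <- rigid_transform(R, t)
  }
  if (layout$end_camera) {
    R <- cbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
    poses[["endview"]] <- rigid_transform(R, c(0, 0, layout$end_position_mm))
  }
  poses
}

# Camera-frame ray directions of every pixel, z = 1 (so the intersection
# parameter equals the camera-z depth). Returns an (H*W) x 3 matrix in
# column-major pixel order.
pixel_rays <- function(intrinsics) {
  u <- rep(seq_len(intrinsics$width_px) - 1, each = intrinsics$height_px)
  v <- rep(seq_len(intrinsics$height_px) - 1, times = intrinsics$width_px)
  cbind((u - intrinsics$cx) / intrinsics$fx,
        (v - intrinsics$cy) / intrinsics$fy,
        1)
}

#' Render an RGB-D frame of a phantom
#'
#' Analytic per-pixel ray casting (no rasterisation or z-buffer
#' quantisation): each pixel ray is intersected exactly with the phantom
#' and the green backdrop plane placed `backdrop_mm` along the optical
#' axis; depth is the camera-z range of the nearest hit in millimetres.
#'
#' @param phantom A [limb_phantom()].
#' @param pose world-from-camera [rigid_transform()].
#' @param intrinsics A [camera_intrinsics()].
#' @return List with `frame` (an [rgbd_frame()]) and `silhouette` (logical
#'   H x W mask, true exactly where the phantom is hit).
#' @export
render_rgbd <- function(phantom, pose, intrinsics) {
  stopifnot(inherits(phantom, "limb_phantom"), inherits(pose, "rigid_transform"),
            inherits(intrinsics, "camera_intrinsics"))
  rays_cam <- pixel_rays(intrinsics)
  dirs <- rays_cam %*% t(pose$rotation)
  t_hit <- ray_cast_phantom(phantom, matrix(pose$translation, 1), dirs)
  h <- intrinsics$height_px; w <- intrinsics$width_px
  sil <- matrix(t_hit < phantom$backdrop_mm, h, w)
  depth <- matrix(pmin(t_hit, phantom$backdrop_mm), h, w)
  color <- array(0, c(h, w, 3))
  for (ch in 1:3)
    color[, , ch] <- ifelse(sil, phantom$color[ch], phantom$backdrop_color[ch])
  list(frame = rgbd_frame(color, depth, intrinsics), silhouette = sil)
}

#' Distance-proportional depth noise
#'
#' Perturbs every valid depth by Gaussian noise whose standard deviation
#' grows with range, `sigma(z) = relative_sigma * (z / 2000) * z`,
#' matching a stereo depth camera's accuracy contract of <= 2% error at
#' 2 m. Deterministic under a fixed seed; zero (invalid) depths are left
#' untouched.
#'
#' @param frame An [rgbd_frame()].
#' @param relative_sigma relative accuracy at 2 m (default 0.02).
#' @param seed RNG seed (NULL leaves the caller's stream in charge).
#' @return The noisy [rgbd_frame()].
#' @export
add_depth_noise <- function(frame, relative_sigma = 0.02, seed = NULL) {
  stopifnot(inherits(frame, "rgbd_frame"))
  if (relative_sigma == 0) return(frame)
  with_seed(seed, {
    d <- frame$depth
    valid <- d > 0
    sigma <- relative_sigma * (d[valid] / 2000) * d[valid]
    d[valid] <- pmax(0, d[valid] + rnorm(sum(valid), 0, sigma))
    rgbd_frame(frame$color, d, frame$intrinsics)
  })
}

#' Checkerboard corner observations for every camera
#'
#' Transforms the board-frame inner-corner coordinates (row-major order)
#' into each camera's frame — the 3D corner sets the extrinsic calibration
#' consumes. Optional isotropic Gaussian noise emulates corner
#' localisation error.
#'
#' @param rig named list of world-from-camera [rigid_transform()] poses
#'   (see [make_rig()]).
#' @param board_pose world-from-board [rigid_transform()]; the default
#'   centres the board on the rig axis at the radial camera height.
#' @param square_mm checkerboard square size (mm).
#' @param inner_rows,inner_cols inner corner grid (default 6 x 9).
#' @param noise_sd isotropic corner noise (mm).
#' @param seed RNG seed for the noise.
#' @return List with `corner_sets` (named list of N x 3 matrices, one per
#'   camera, in camera frames) and `board_model` (N x 3 board-frame
#'   corners).
#' @export
render_checkerboard <- function(rig, board_pose = NULL, square_mm = 25,
                                inner_rows = 6, inner_cols = 9,
                                noise_sd = 0, seed = NULL) {
  board <- checkerboard_model(inner_rows, inner_cols, square_mm)
  if (is.null(board_pose)) {
    board_pose <- rigid_transform(diag(3),
                                  c(-(inner_cols - 1) * square_mm / 2,
                                    -(inner_rows - 1) * square_mm / 2, 125))
  }
  world <- transform_points(board_pose, board)
  corner_sets <- lapply(seq_along(rig), function(i) {
    obs <- transform_points(invert_transform(rig[[i]]), world)
    if (any(obs[, 3] < 0))
      ls_stop(sprintf("checkerboard corner behind camera %d", i), "visibility")
    obs
  })
  names(corner_sets) <- names(rig)
  if (noise_sd > 0) {
    corner_sets <- with_seed(seed, lapply(corner_sets, function(m)
      m + matrix(rnorm(length(m), 0, noise_sd), nrow(m), 3)))
  }
  list(corner_sets = corner_sets, board_model = board)
}
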