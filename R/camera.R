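#' Pinhole camera intrinsics
#'
#' Pinhole parameters mapping pixel coordinates to metric rays. Pixels are
#' 0-based, `(u, v) = (column, row)` with the origin at the top-left corner;
#' the camera frame is right-handed with +z along the optical axis into the
#' scene, +x right and +y down. Depth rasters store millimetres
#' (`depth_scale` millimetres per stored unit, default 1), with 0 marking an
#' invalid pixel.
#'
#' @param width_px,height_px image size in pixels.
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels (0-based).
#' @param depth_scale millimetres per stored depth unit.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' camera_intrinsics(1280, 720, fx = 924.2, fy = 924.2, cx = 640, cy = 360)
#' @export
camera_intrinsics <- function(width_px, height_px, fx, fy, cx, cy,
                              depth_scale = 1) {
  check_that(width_px > 0 && height_px > 0, "image size must be positive")
  check_that(width_px == round(width_px) && height_px == round(height_px),
             "image size must be integral")
  check_that(fx > 0 && fy > 0, "focal lengths must be positive")
  check_that(cx >= 0 && cx < width_px && cy >= 0 && cy < height_px,
             "principal point must lie inside the image")
  check_that(depth_scale > 0, "depth_scale must be positive")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 fx = fx, fy = fy, cx = cx, cy = cy,
                 depth_scale = depth_scale),
            class = "camera_intrinsics")
}

#' Paired color + aligned depth raster
#'
#' Color and depth are assumed pre-aligned (the depth camera's factory
#' parameters provide the alignment), so one set of intrinsics serves both.
#'
#' @param color H x W x 3 integer array, 8-bit per channel (0-255).
#' @param depth H x W numeric matrix of millimetres; 0 marks invalid depth.
#' @param intrinsics A [camera_intrinsics()] matching the raster size.
#' @return An object of class `rgbd_frame`.
#' @export
rgbd_frame <- function(color, depth, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  depth <- as.matrix(depth)
  check_that(length(dim(color)) == 3 && dim(color)[3] == 3,
             "color must be an H x W x 3 array")
  check_that(all(dim(color)[1:2] == dim(depth)),
             "color and depth must share H x W")
  check_that(nrow(depth) == intrinsics$height_px &&
             ncol(depth) == intrinsics$width_px,
             "raster size must match intrinsics")
  check_that(all(depth >= 0), "depth values must be non-negative")
  check_that(all(color >= 0 & color <= 255), "color must be 8-bit (0-255)")
  structure(list(color = color, depth = depth, intrinsics = intrinsics),
            class = "rgbd_frame")
}

#' Point cloud with optional per-point color and normals
#'
#' @param points N x 3 matrix of millimetres.
#' @param colors optional N x 3 matrix in `[0, 1]`.
#' @param normals optional N x 3 matrix of unit vectors.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, colors = NULL, normals = NULL) {
  points <- as_point_matrix(points)
  n <- nrow(points)
  if (!is.null(colors)) {
    colors <- as_point_matrix(colors, "colors")
    check_that(nrow(colors) == n, "colors must have one row per point")
    check_that(all(colors >= 0 & colors <= 1), "colors must lie in [0, 1]")
  }
  if (!is.null(normals)) {
    normals <- as_point_matrix(normals, "normals")
    check_that(nrow(normals) == n, "normals must have one row per point")
    len <- sqrt(rowSums(normals^2))
    check_that(all(abs(len - 1) <= 1e-6), "normals must have unit length")
  }
  structure(list(points = points, colors = colors, normals = normals),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s%s\n", nrow(x$points),
              if (!is.null(x$colors)) ", colors" else "",
              if (!is.null(x$normals)) ", normals" else ""))
  invisible(x)
}

# --- rig design mathematics -------------------------------------------------

#' Focal length from target size and distance
#'
#' The thin-lens design relation `f = (B / G) l`: the focal length in pixels
#' that makes a target of metric extent `G` fill `B` pixels at distance `l`.
#'
#' @param image_extent_px image extent in pixels along one axis.
#' @param target_extent_mm metric extent of the target (mm).
#' @param distance_mm camera-to-target distance (mm).
#' @return Focal length in pixels.
#' @examples
#' focal_length(1280, 318.52, 230)
#' @export
focal_length <- function(image_extent_px, target_extent_mm, distance_mm) {
  check_that(image_extent_px > 0 && target_extent_mm > 0 && distance_mm > 0,
             "all arguments must be positive")
  image_extent_px / target_extent_mm * distance_mm
}

#' Metric extent of the field of view at a distance
#'
#' Full extent seen by a camera with the given full field-of-view angle at
#' the given distance: `2 tan(fov / 2) d`.
#'
#' @param fov_degrees full field-of-view angle in degrees (`0 <= fov < 180`).
#' @param distance_mm distance to the viewed plane (mm).
#' @return Extent in millimetres.
#' @examples
#' fov_extent(69.4, 230)  # horizontal coverage of a D435i-class camera
#' @export
fov_extent <- function(fov_degrees, distance_mm) {
  check_that(fov_degrees >= 0 && fov_degrees < 180,
             "fov must lie in [0, 180) degrees")
  check_that(distance_mm >= 0, "distance must be non-negative")
  2 * tan(fov_degrees / 2 * pi / 180) * distance_mm
}

#' Image resolution in millimetres per pixel
#'
#' @param target_extent_mm metric extent covered by the image (mm).
#' @param image_extent_px matching extent in pixels.
#' @return Resolution in mm/px.
#' @examples
#' resolution(fov_extent(69.4, 230), 1280)
#' @export
resolution <- function(target_extent_mm, image_extent_px) {
  check_that(target_extent_mm > 0 && image_extent_px > 0,
             "both arguments must be positive")
  target_extent_mm / image_extent_px
}

#' Diameter and radius from a circumference
#'
#' @param circumference_mm measured circumference (mm).
#' @return Named list with `diameter_mm = c / pi` and `radius_mm = d / 2`.
#' @examples
#' circumference_to_radius(470)  # a healthy adult leg
#' @export
circumference_to_radius <- function(circumference_mm) {
  check_that(circumference_mm > 0, "circumference must be positive")
  d <- circumference_mm / pi
  list(diameter_mm = d, radius_mm = d / 2)
}

#' Camera-to-surface standoff distance
#'
#' Distance from a camera on the rig circle to the surface of a centred
#' cylindrical target: frame radius minus target radius.
#'
#' @param frame_radius_mm radius of the camera circle (mm).
#' @param target_radius_mm radius of the target (mm).
#' @return Standoff in millimetres.
#' @examples
#' standoff_distance(305, 75)
#' @export
standoff_distance <- function(frame_radius_mm, target_radius_mm) {
  check_that(target_radius_mm >= 0, "target radius must be non-negative")
  check_that(frame_radius_mm >= target_radius_mm,
             "frame radius must be at least the target radius")
  frame_radius_mm - target_radius_mm
}

# --- RGB-D <-> point cloud --------------------------------------------------

#' Deproject an RGB-D frame into a point cloud
#'
#' Maps every valid depth pixel through the pinhole model:
#' `x = (u - cx) z / fx`, `y = (v - cy) z / fy`. Pixels with zero depth, or
#' excluded by `mask`, emit nothing. Per-point color is copied from the
#' color raster scaled to `[0, 1]`.
#'
#' @param frame An [rgbd_frame()].
#' @param mask optional H x W logical matrix restricting the pixels used.
#' @return A [point_cloud()] with colors.
#' @export
deproject <- function(frame, mask = NULL) {
  stopifnot(inherits(frame, "rgbd_frame"))
  K <- frame$intrinsics
  depth <- frame$depth * K$depth_scale
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    check_that(all(dim(mask) == dim(depth)), "mask must match the frame shape")
    keep <- (depth > 0) & mask
  } else {
    keep <- depth > 0
  }
  idx <- which(keep)                       # column-major
  h <- nrow(depth)
  v <- (idx - 1) %% h                      # 0-based row
  u <- (idx - 1) %/% h                     # 0-based column
  z <- depth[idx]
  pts <- cbind((u - K$cx) * z / K$fx, (v - K$cy) * z / K$fy, z)
  cols <- cbind(frame$color[, , 1][idx],
                frame$color[, , 2][idx],
                frame$color[, , 3][idx]) / 255
  point_cloud(pts, colors = cols)
}

#' Project a 3D point into pixel coordinates
#'
#' Inverse of [deproject()]: `u = fx x / z + cx`, `v = fy y / z + cy`.
#'
#' @param point 3-vector or N x 3 matrix of camera-frame points (mm), z > 0.
#' @param intrinsics A [camera_intrinsics()].
#' @return Matrix with columns `u`, `v`, `depth`.
#' @export
project <- function(point, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  p <- as_point_matrix(point, "point")
  if (any(p[, 3] <= 0)) ls_stop("point lies behind the camera", "behind_camera")
  cbind(u = intrinsics$fx * p[, 1] / p[, 3] + intrinsics$cx,
        v = intrinsics$fy * p[, 2] / p[, 3] + intrinsics$cy,
        depth = p[, 3])
}
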