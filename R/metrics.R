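#' Dice similarity coefficient
#'
#' Overlap similarity of two binary masks: `2|A n B| / (|A| + |B|)`,
#' symmetric in its arguments, 1 for identical nonempty masks and 0 for
#' disjoint ones.
#'
#' @param A,B logical matrices of equal shape.
#' @return Similarity in `[0, 1]`.
#' @export
dice <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  check_that(all(dim(A) == dim(B)), "masks must share a shape")
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0)
    ls_stop("Dice is undefined for two empty masks", "undefined_metric")
  2 * sum(A & B) / (na + nb)
}

mask_coords <- function(m) {
  idx <- which(as.matrix(m))
  h <- nrow(m)
  # pixel-centre (row, col) coordinates
  cbind((idx - 1) %% h, (idx - 1) %/% h, rep(0, length(idx)))
}

#' Symmetric Hausdorff distance
#'
#' The larger of the two directed maxima of nearest-neighbour distances:
#' `max(sup_p inf_q d(p,q), sup_q inf_p d(q,p))` — the worst-case shape
#' discrepancy. Accepts two binary masks (compared via the Euclidean
#' distance between true-pixel centres, in pixels) or two point sets
#' (N x 3 matrices, in mm).
#'
#' @param A,B binary masks or point sets (both of the same kind).
#' @return Hausdorff distance (px for masks, mm for points).
#' @export
hausdorff <- function(A, B) {
  if (is.logical(A) || is.logical(B) ||
      (is.matrix(A) && ncol(A) != 3) || (is.matrix(B) && ncol(B) != 3)) {
    A <- mask_coords(A)
    B <- mask_coords(B)
  } else {
    A <- as_point_matrix(A, "A")
    B <- as_point_matrix(B, "B")
  }
  if (nrow(A) == 0 || nrow(B) == 0)
    ls_stop("Hausdorff is undefined for an empty set", "undefined_metric")
  max(max(.cpp_nearest(A, B, -1)$dist), max(.cpp_nearest(B, A, -1)$dist))
}

#' Per-point nearest-neighbour distances
#'
#' Distance from each point of `P` to its nearest point in `Q`; the
#' maximum over both directed passes equals [hausdorff()]. Exported
#' per-vertex for distance heat-map colouring.
#'
#' @param P,Q N x 3 point matrices.
#' @return Numeric vector of length `nrow(P)`.
#' @export
nearest_distances <- function(P, Q) {
  P <- as_point_matrix(P, "P")
  Q <- as_point_matrix(Q, "Q")
  if (nrow(Q) == 0) ls_stop("Q must be nonempty", "undefined_metric")
  .cpp_nearest(P, Q, -1)$dist
}

#' Summary statistics row
#'
#' The statistic row used for reporting segmentation and reconstruction
#' errors: min, quartiles (linear interpolation between order statistics),
#' mean, max, interquartile range and the root mean square of the data
#' values themselves.
#'
#' @param values nonempty numeric vector.
#' @return An object of class `summary_stats` with fields `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`, `iqr`, `rms`.
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  check_that(length(values) >= 1 && !anyNA(values),
             "values must be nonempty and free of NA")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(min = min(values), q1 = q[1], median = q[2],
                 mean = mean(values), q3 = q[3], max = max(values),
                 iqr = q[3] - q[1], rms = sqrt(mean(values^2))),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, digits = 4, ...) {
  v <- round(unlist(x), digits)
  print(v)
  invisible(x)
}

#' @export
as.data.frame.summary_stats <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Pixel-to-millimetre conversion
#'
#' @param value_px a value in pixels (e.g. a Hausdorff distance on masks).
#' @param res_mm_per_px image resolution in mm/px.
#' @return Value in millimetres.
#' @examples
#' px_to_mm(26.67, 0.24)
#' @export
px_to_mm <- function(value_px, res_mm_per_px) {
  check_that(res_mm_per_px > 0, "resolution must be positive")
  value_px * res_mm_per_px
}

#' Cross-section extent of a mesh at a height
#'
#' Intersects the mesh with the plane normal to `axis` at `height_mm` and
#' returns the extent of the section, measured along `direction` — the
#' diameter-at-height measurement used to verify scanned models against
#' their physical counterparts.
#'
#' @param mesh A [triangle_mesh()].
#' @param height_mm plane position along `axis` (mm).
#' @param axis unit 3-vector normal to the cutting plane.
#' @param direction unit 3-vector (in the plane) along which the extent is
#'   measured.
#' @return Extent in millimetres.
#' @export
cross_section_extent <- function(mesh, height_mm, axis = c(0, 0, 1),
                                 direction = c(1, 0, 0)) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  axis <- axis / sqrt(sum(axis^2))
  direction <- direction / sqrt(sum(direction^2))
  s <- as.vector(mesh$vertices %*% axis) - height_mm
  pts <- matrix(0, 0, 3)
  f <- mesh$faces
  for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
    sa <- s[f[, e[1]]]
    sb <- s[f[, e[2]]]
    hit <- (sa <= 0 & sb > 0) | (sa > 0 & sb <= 0)
    if (!any(hit)) next
    va <- mesh$vertices[f[hit, e[1]], , drop = FALSE]
    vb <- mesh$vertices[f[hit, e[2]], , drop = FALSE]
    t <- sa[hit] / (sa[hit] - sb[hit])
    pts <- rbind(pts, va + t * (vb - va))
  }
  if (nrow(pts) == 0)
    ls_stop("the plane does not intersect the mesh", "out_of_range")
  proj <- as.vector(pts %*% direction)
  max(proj) - min(proj)
}
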