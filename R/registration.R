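#' ICP parameters
#'
#' Controls the point-to-plane iterative closest point refinement and the
#' voxel downsampling used around it. The 2 mm default voxel follows the
#' pipeline's downsampling scale for faster processing; the correspondence
#' threshold, iteration cap and relative tolerance are implementation
#' defaults.
#'
#' @param max_correspondence_mm reject correspondences farther than this.
#' @param max_iterations iteration cap.
#' @param rel_tolerance stop when the relative decrease of the objective
#'   falls below this.
#' @param voxel_size_mm voxel edge for downsampling (mm).
#' @return An object of class `icp_params`.
#' @export
icp_params <- function(max_correspondence_mm = 10, max_iterations = 50,
                       rel_tolerance = 1e-6, voxel_size_mm = 2) {
  check_that(max_correspondence_mm > 0 && rel_tolerance > 0 && voxel_size_mm > 0,
             "ICP parameters must be positive")
  check_that(max_iterations >= 1, "max_iterations must be at least 1")
  structure(list(max_correspondence_mm = max_correspondence_mm,
                 max_iterations = as.integer(max_iterations),
                 rel_tolerance = rel_tolerance,
                 voxel_size_mm = voxel_size_mm),
            class = "icp_params")
}

#' Apply a rigid transform to a point cloud
#'
#' Points map as `p -> R p + t`, normals as `n -> R n`; colors are
#' untouched.
#'
#' @param cloud A [point_cloud()].
#' @param transform A [rigid_transform()].
#' @return The transformed [point_cloud()].
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(transform, "rigid_transform"))
  normals <- cloud$normals
  if (!is.null(normals)) normals <- normals %*% t(transform$rotation)
  point_cloud(transform_points(transform, cloud$points),
              colors = cloud$colors, normals = normals)
}

#' Voxel-grid downsampling
#'
#' Partitions space into axis-aligned cubes of edge `voxel_size_mm`
#' anchored at the origin and replaces the points of each occupied voxel
#' by their centroid; colors and normals are averaged (normals
#' re-normalised). Output voxels are ordered by their grid key, so the
#' result is deterministic.
#'
#' @param cloud A [point_cloud()].
#' @param voxel_size_mm voxel edge length (mm).
#' @return The downsampled [point_cloud()].
#' @export
voxel_downsample <- function(cloud, voxel_size_mm = 2) {
  stopifnot(inherits(cloud, "point_cloud"))
  check_that(voxel_size_mm > 0, "voxel size must be positive")
  key <- floor(cloud$points / voxel_size_mm)
  ord <- order(key[, 1], key[, 2], key[, 3])
  k <- key[ord, , drop = FALSE]
  newgrp <- c(TRUE, rowSums(abs(diff(k))) > 0)
  grp <- cumsum(newgrp)
  avg <- function(m) {
    if (is.null(m)) return(NULL)
    rowsum(m[ord, , drop = FALSE], grp, reorder = FALSE) /
      as.vector(table(grp))
  }
  pts <- avg(cloud$points)
  normals <- avg(cloud$normals)
  if (!is.null(normals)) {
    len <- sqrt(rowSums(normals^2))
    len[len < 1e-12] <- 1
    normals <- normals / len
  }
  point_cloud(pts, colors = avg(cloud$colors), normals = normals)
}

#' Estimate point normals from local neighbourhoods
#'
#' The normal of each point is the smallest-eigenvalue eigenvector of the
#' covariance of its `k` nearest neighbours, flipped to face the given
#' viewpoint (`n . (viewpoint - p) >= 0`).
#'
#' @param cloud A [point_cloud()].
#' @param k neighbour count (`3 <= k < N`).
#' @param viewpoint length-3 reference position.
#' @param orient `"toward"` (default) flips normals to face the viewpoint,
#'   the sensor-position convention; `"away"` flips them to point away
#'   from it, which orients a closed convex surface outward when the
#'   viewpoint is the cloud centroid.
#' @return The [point_cloud()] with unit normals attached.
#' @export
estimate_normals <- function(cloud, k = 30, viewpoint = c(0, 0, 0),
                             orient = c("toward", "away")) {
  orient <- match.arg(orient)
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$points)
  check_that(k >= 3, "k must be at least 3")
  if (n <= k) ls_stop("cloud must have more than k points", "invalid_argument")
  nn <- .cpp_knn(cloud$points, cloud$points, k + 1L)  # includes the point itself
  pts <- cloud$points
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- pts[nn[i, ], , drop = FALSE]
    cov3 <- crossprod(sweep(nb, 2, colMeans(nb))) / nrow(nb)
    ev <- eigen(cov3, symmetric = TRUE)
    normals[i, ] <- ev$vectors[, 3]
  }
  toward <- rowSums(normals * sweep(-pts, 2, viewpoint, "+"))
  flip <- if (orient == "toward") toward < 0 else toward > 0
  normals[flip, ] <- -normals[flip, ]
  len <- sqrt(rowSums(normals^2))
  point_cloud(pts, colors = cloud$colors, normals = normals / len)
}

# Point-to-plane objective sum(((p - T q) . n_p)^2) and its correspondences
# at the current transform.
p2plane_state <- function(src_pts, tgt_pts, tgt_nrm, transform, max_corr) {
  q <- sweep(src_pts %*% t(transform$rotation), 2, transform$translation, "+")
  nn <- .cpp_nearest(q, tgt_pts, max_corr)
  keep <- nn$idx > 0
  if (!any(keep)) return(NULL)
  idx <- nn$idx[keep]
  p <- tgt_pts[idx, , drop = FALSE]
  n <- tgt_nrm[idx, , drop = FALSE]
  qk <- q[keep, , drop = FALSE]
  r <- rowSums((qk - p) * n)
  list(q = qk, p = p, n = n, r = r, E = sum(r^2))
}

#' Point-to-plane ICP refinement
#'
#' Iteratively (i) matches each transformed source point to its nearest
#' target point within `max_correspondence_mm`, (ii) solves the linearised
#' least-squares update of the point-to-plane objective
#' `E(T) = sum(((p - T q) . n_p)^2)` under a small-angle rotation
#' parameterisation, and (iii) stops when the relative decrease of `E`
#' falls below `rel_tolerance` or the iteration cap is reached. The
#' objective is non-increasing across accepted iterations; an update that
#' would increase it is rejected and iteration stops.
#'
#' @param source A [point_cloud()] to be aligned.
#' @param target A [point_cloud()] with normals.
#' @param init initial [rigid_transform()] applied to `source`.
#' @param params An [icp_params()].
#' @return List with `transform` (total transform, including `init`),
#'   `objective` (final value of `E`) and `iterations`.
#' @export
icp_point_to_plane <- function(source, target, init = rigid_transform(),
                               params = icp_params()) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"))
  check_that(nrow(source$points) > 0, "source cloud is empty")
  if (is.null(target$normals))
    ls_stop("target cloud must carry normals", "invalid_argument")

  src <- source$points
  tgt <- target$points
  nrm <- target$normals
  transform <- init
  state <- p2plane_state(src, tgt, nrm, transform, params$max_correspondence_mm)
  if (is.null(state))
    ls_stop("no correspondences within the distance threshold", "no_overlap")
  E <- state$E
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    # rows [q x n, n], rhs -r: linearised normal equations in (omega, t)
    A <- cbind(state$q[, 2] * state$n[, 3] - state$q[, 3] * state$n[, 2],
               state$q[, 3] * state$n[, 1] - state$q[, 1] * state$n[, 3],
               state$q[, 1] * state$n[, 2] - state$q[, 2] * state$n[, 1],
               state$n)
    x <- tryCatch(solve(crossprod(A) + 1e-12 * diag(6), -crossprod(A, state$r)),
                  error = function(e) NULL)
    if (is.null(x)) break
    delta <- rigid_transform(rotation_about(if (sum(x[1:3]^2) > 0) x[1:3] else c(0, 0, 1),
                                            sqrt(sum(x[1:3]^2))),
                             x[4:6])
    cand <- compose_transform(delta, transform)
    cand_state <- p2plane_state(src, tgt, nrm, cand, params$max_correspondence_mm)
    if (is.null(cand_state))
      ls_stop("no correspondences within the distance threshold", "no_overlap")
    if (cand_state$E > E) break             # keep E non-increasing
    accepted_drop <- (E - cand_state$E) / max(E, .Machine$double.eps)
    transform <- cand
    state <- cand_state
    E <- cand_state$E
    if (accepted_drop < params$rel_tolerance) break
  }
  list(transform = transform, objective = E, iterations = iter)
}

#' Ordered pairwise registration and fusion
#'
#' Applies the per-camera extrinsics (the initial global alignment), fixes
#' the first cloud, then for each subsequent cloud in rig order refines
#' its pose against the accumulated merged cloud with point-to-plane ICP
#' and appends it. The merged result is voxel-downsampled at
#' `params$voxel_size_mm`. Inputs are downsampled at the same voxel size
#' before refinement for processing speed.
#'
#' @param clouds ordered list of [point_cloud()] in camera frames.
#' @param extrinsics list of [rigid_transform()] mapping each camera frame
#'   into the global frame, in the same order.
#' @param params An [icp_params()].
#' @param normal_k neighbour count for normal estimation on the target.
#' @return The merged, downsampled [point_cloud()]; per-view ICP results
#'   are attached as attribute `refinements`.
#' @export
pairwise_register <- function(clouds, extrinsics, params = icp_params(),
                              normal_k = 30) {
  check_that(is.list(clouds) && length(clouds) >= 2,
             "at least two clouds are required")
  check_that(length(extrinsics) == length(clouds),
             "one extrinsic transform per cloud is required")
  aligned <- mapply(function(cl, tr) {
    voxel_downsample(apply_transform(cl, tr), params$voxel_size_mm)
  }, clouds, extrinsics, SIMPLIFY = FALSE)

  merged <- aligned[[1]]
  refinements <- vector("list", length(clouds))
  for (i in seq_along(aligned)[-1]) {
    target <- estimate_normals(merged, k = min(normal_k, nrow(merged$points) - 1),
                               viewpoint = centroid(merged$points))
    res <- tryCatch(
      icp_point_to_plane(aligned[[i]], target, params = params),
      limbscan_no_overlap = function(e)
        ls_stop(sprintf("no overlap between view %d and the merged cloud", i),
                "no_overlap"))
    refinements[[i]] <- res
    refined <- apply_transform(aligned[[i]], res$transform)
    merged <- point_cloud(rbind(merged$points, refined$points),
                          colors = if (!is.null(merged$colors) &&
                                       !is.null(refined$colors))
                            rbind(merged$colors, refined$colors))
  }
  out <- voxel_downsample(merged, params$voxel_size_mm)
  attr(out, "refinements") <- refinements
  out
}
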