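#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the end-to-end flow
#' (calibrate -> capture/simulate -> segment -> register -> mesh ->
#' evaluate). The camera order is an explicit, required field: pairwise
#' registration follows the order in which the cameras are physically
#' placed on the frame, and no automatic ordering is attempted.
#'
#' @param camera_order character vector of camera serials in rig order.
#' @param segmentation A [segmentation_config()].
#' @param icp An [icp_params()].
#' @param grid_resolution,bandwidth_mm surface reconstruction lattice
#'   parameters (see [reconstruct_surface()]).
#' @param reference_camera serial of the calibration reference camera.
#' @param seed master seed recorded with every stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(camera_order,
                            segmentation = segmentation_config(),
                            icp = icp_params(),
                            grid_resolution = 128, bandwidth_mm = 6,
                            reference_camera = camera_order[1],
                            seed = 0) {
  check_that(is.character(camera_order) && length(camera_order) >= 2,
             "camera_order must list at least two serials", "configuration")
  structure(list(camera_order = camera_order, segmentation = segmentation,
                 icp = icp, grid_resolution = grid_resolution,
                 bandwidth_mm = bandwidth_mm,
                 reference_camera = reference_camera, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Accepts a JSON object with any subset of the [pipeline_config()]
#' fields; `segmentation` and `icp` are nested objects holding
#' [segmentation_config()] / [icp_params()] arguments. Missing fields
#' fall back to the defaults (and to `default_order` for the camera
#' order).
#'
#' @param path JSON file path.
#' @param default_order camera order used when the file does not name one.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, default_order = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  order <- if (!is.null(j$camera_order)) j$camera_order else default_order
  check_that(!is.null(order), "config names no camera_order and none is known",
             "configuration")
  args <- list(camera_order = order)
  for (f in c("grid_resolution", "bandwidth_mm", "reference_camera", "seed"))
    if (!is.null(j[[f]])) args[[f]] <- j[[f]]
  if (!is.null(j$segmentation))
    args$segmentation <- do.call(segmentation_config, as.list(j$segmentation))
  if (!is.null(j$icp))
    args$icp <- do.call(icp_params, as.list(j$icp))
  do.call(pipeline_config, args)
}

ws_path <- function(workspace, ...) {
  p <- file.path(workspace, ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}

file_crc <- function(path) {
  .cpp_crc32(readBin(path, "raw", n = file.size(path)))
}

log_stage <- function(workspace, stage, inputs, seed, t0, extra = list()) {
  entry <- c(list(stage = stage,
                  inputs = as.list(stats::setNames(
                    vapply(inputs, file_crc, numeric(1)), basename(inputs))),
                  seed = seed,
                  seconds = round(as.numeric(Sys.time()) - t0, 3)),
             extra)
  log_path <- ws_path(workspace, "report", "log.json")
  log <- if (file.exists(log_path))
    jsonlite::read_json(log_path) else list()
  log[[stage]] <- entry
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  invisible(entry)
}

#' Simulate a capture session into a workspace directory
#'
#' Renders the full synthetic stand-in for a physical capture: per-camera
#' color/depth PNGs and ground-truth silhouettes, shared intrinsics,
#' ground-truth extrinsics (all poses expressed in the reference camera's
#' frame), checkerboard corner observations for calibration, the
#' ground-truth phantom mesh, and a manifest recording every seed. All
#' writers are deterministic: the same seed reproduces the directory
#' byte-for-byte.
#'
#' @param workspace directory to create.
#' @param phantom A [limb_phantom()].
#' @param layout A [rig_layout()].
#' @param depth_noise_sigma relative depth noise at 2 m (0 = noiseless).
#' @param corner_noise_sd checkerboard corner noise (mm).
#' @param seed master seed; per-camera noise seeds are derived from it.
#' @return The workspace path, invisibly.
#' @export
simulate_capture <- function(workspace, phantom = limb_phantom(),
                             layout = rig_layout(), depth_noise_sigma = 0,
                             corner_noise_sd = 0, seed = 0) {
  rig <- make_rig(layout)
  serials <- names(rig)
  ref <- serials[1]
  K <- layout$intrinsics
  write_intrinsics_json(K, ws_path(workspace, "calib", "intrinsics.json"))

  # ground-truth extrinsics: camera -> reference-camera frame
  ref_from_world <- invert_transform(rig[[ref]])
  extr <- lapply(rig, function(p) compose_transform(ref_from_world, p))
  write_extrinsics_json(extr, ws_path(workspace, "calib", "extrinsics_gt.json"),
                        reference = ref)

  cb <- render_checkerboard(rig, noise_sd = corner_noise_sd,
                            seed = if (corner_noise_sd > 0) seed + 1000L else NULL)
  jsonlite::write_json(cb$corner_sets,
    ws_path(workspace, "calib", "corners.json"), digits = NA)
  jsonlite::write_json(cb$board_model,
    ws_path(workspace, "calib", "board_model.json"), digits = NA)

  for (i in seq_along(serials)) {
    s <- serials[i]
    r <- render_rgbd(phantom, rig[[s]], K)
    frame <- r$frame
    if (depth_noise_sigma > 0)
      frame <- add_depth_noise(frame, depth_noise_sigma, seed = seed + i)
    write_color_png(frame$color, ws_path(workspace, "frames", s, "color.png"))
    write_depth_png(frame$depth, ws_path(workspace, "frames", s, "depth.png"))
    write_mask_png(r$silhouette, ws_path(workspace, "frames", s, "silhouette.png"))
  }

  # ground truth expressed in the pipeline's global (reference camera) frame
  gt <- ground_truth_mesh(phantom)
  gt <- triangle_mesh(transform_points(ref_from_world, gt$vertices), gt$faces)
  write_ply(gt, ws_path(workspace, "mesh", "ground_truth.ply"))
  jsonlite::write_json(
    list(camera_order = serials, reference_camera = ref, seed = seed,
         depth_noise_sigma = depth_noise_sigma,
         corner_noise_sd = corner_noise_sd,
         phantom = list(profile_heights = phantom$profile_heights,
                        profile_radii = phantom$profile_radii,
                        color = phantom$color,
                        backdrop_color = phantom$backdrop_color,
                        backdrop_mm = phantom$backdrop_mm),
         layout = list(frame_radius_mm = layout$frame_radius_mm,
                       n_radial = layout$n_radial,
                       end_camera = layout$end_camera,
                       axial_position_mm = layout$axial_position_mm,
                       end_position_mm = layout$end_position_mm)),
    ws_path(workspace, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(workspace)
}

read_manifest <- function(workspace) {
  p <- file.path(workspace, "manifest.json")
  if (!file.exists(p))
    ls_stop(sprintf("workspace '%s' has no manifest.json", workspace),
            "missing_input")
  jsonlite::read_json(p, simplifyVector = TRUE)
}

need_file <- function(path, stage, camera = NULL) {
  if (!file.exists(path))
    ls_stop(sprintf("stage '%s'%s: missing input %s", stage,
                    if (is.null(camera)) "" else paste0(" (camera ", camera, ")"),
                    path), "missing_input")
  path
}

#' Run the reconstruction pipeline on a workspace
#'
#' Executes, in order: extrinsic calibration from the stored checkerboard
#' corner sets; segmentation of every frame; deprojection of the
#' segmented RGB-D frames to per-camera point clouds; ordered pairwise
#' registration; surface reconstruction and hole closing; and evaluation
#' against the ground-truth mesh and silhouettes when present. Every
#' intermediate artefact is written into the workspace, and each stage
#' logs its input checksums, seed and duration to `report/log.json`.
#' Stage errors carry the stage name and camera id. Re-running a
#' completed stage rewrites byte-identical outputs.
#'
#' @param workspace a directory prepared by [simulate_capture()] (or laid
#'   out the same way from real captures).
#' @param config A [pipeline_config()]; defaults to the manifest's camera
#'   order and stage defaults.
#' @param stages subset of
#'   `c("calibrate", "segment", "deproject", "register", "mesh", "evaluate")`
#'   to (re-)run.
#' @param verbose print one line per stage.
#' @return List with `mesh` (the final watertight [triangle_mesh()], when
#'   the mesh stage ran) and `report` (the evaluation list, when the
#'   evaluate stage ran).
#' @export
run_pipeline <- function(workspace, config = NULL,
                         stages = c("calibrate", "segment", "deproject",
                                    "register", "mesh", "evaluate"),
                         verbose = FALSE) {
  manifest <- read_manifest(workspace)
  if (is.null(config))
    config <- pipeline_config(camera_order = manifest$camera_order,
                              reference_camera = manifest$reference_camera,
                              seed = manifest$seed)
  serials <- config$camera_order
  known <- manifest$camera_order
  unknown <- setdiff(serials, known)
  if (length(unknown) > 0)
    ls_stop(sprintf("camera order names unknown serial(s): %s",
                    paste(unknown, collapse = ", ")), "configuration")
  say <- function(...) if (verbose) message(sprintf(...))
  K <- read_intrinsics_json(need_file(file.path(workspace, "calib",
                                                "intrinsics.json"),
                                      "calibrate"))
  result <- list()

  if ("calibrate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    corners_path <- need_file(file.path(workspace, "calib", "corners.json"),
                              "calibrate")
    board_path <- need_file(file.path(workspace, "calib", "board_model.json"),
                            "calibrate")
    corners <- jsonlite::read_json(corners_path, simplifyVector = TRUE)
    board <- jsonlite::read_json(board_path, simplifyVector = TRUE)
    ref_idx <- match(config$reference_camera, names(corners))
    check_that(!is.na(ref_idx), "reference camera not among the corner sets",
               "configuration")
    extr <- calibrate_rig(corners, board, reference_camera = ref_idx)
    write_extrinsics_json(extr, ws_path(workspace, "calib", "extrinsics.json"),
                          reference = config$reference_camera)
    log_stage(workspace, "calibrate", c(corners_path, board_path),
              config$seed, t0, list(cameras = length(extr)))
    say("calibrate: %d cameras, reference %s", length(extr),
        config$reference_camera)
  }

  if ("segment" %in% stages) {
    for (s in serials) {
      t0 <- as.numeric(Sys.time())
      cpath <- need_file(file.path(workspace, "frames", s, "color.png"),
                         "segment", s)
      dpath <- need_file(file.path(workspace, "frames", s, "depth.png"),
                         "segment", s)
      frame <- rgbd_frame(read_color_png(cpath), read_depth_png(dpath), K)
      seg <- segment(frame, config$segmentation)
      write_mask_png(seg$mask, ws_path(workspace, "masks", paste0(s, ".png")))
      log_stage(workspace, paste0("segment/", s), c(cpath, dpath),
                config$seed, t0, list(pixels = sum(seg$mask)))
      say("segment %s: %d pixels", s, sum(seg$mask))
    }
  }

  if ("deproject" %in% stages) {
    for (s in serials) {
      t0 <- as.numeric(Sys.time())
      cpath <- need_file(file.path(workspace, "frames", s, "color.png"),
                         "deproject", s)
      dpath <- need_file(file.path(workspace, "frames", s, "depth.png"),
                         "deproject", s)
      mpath <- need_file(file.path(workspace, "masks", paste0(s, ".png")),
                         "deproject", s)
      frame <- rgbd_frame(read_color_png(cpath), read_depth_png(dpath), K)
      cloud <- deproject(frame, read_mask_png(mpath))
      write_ply(cloud, ws_path(workspace, "clouds", paste0(s, ".ply")))
      log_stage(workspace, paste0("deproject/", s), c(cpath, dpath, mpath),
                config$seed, t0, list(points = nrow(cloud$points)))
      say("deproject %s: %d points", s, nrow(cloud$points))
    }
  }

  if ("register" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ex_path <- file.path(workspace, "calib", "extrinsics.json")
    if (!file.exists(ex_path))
      ex_path <- need_file(file.path(workspace, "calib", "extrinsics_gt.json"),
                           "register")
    ex <- read_extrinsics_json(ex_path)
    cloud_paths <- vapply(serials, function(s)
      need_file(file.path(workspace, "clouds", paste0(s, ".ply")),
                "register", s), character(1))
    clouds <- lapply(cloud_paths, read_ply)
    merged <- pairwise_register(clouds, ex$extrinsics[serials], config$icp)
    write_ply(merged, ws_path(workspace, "clouds", "merged.ply"))
    log_stage(workspace, "register", c(ex_path, cloud_paths), config$seed, t0,
              list(points = nrow(merged$points)))
    say("register: merged %d points", nrow(merged$points))
    result$merged <- merged
  }

  if ("mesh" %in% stages) {
    t0 <- as.numeric(Sys.time())
    mpath <- need_file(file.path(workspace, "clouds", "merged.ply"), "mesh")
    merged <- read_ply(mpath)
    if (is.null(merged$normals))
      merged <- estimate_normals(merged, viewpoint = centroid(merged$points),
                                 orient = "away")
    mesh <- reconstruct_surface(merged, config$grid_resolution,
                                config$bandwidth_mm)
    cell <- attr(mesh, "cell_mm")
    mesh <- close_mesh(mesh)
    attr(mesh, "cell_mm") <- cell
    write_ply(mesh, ws_path(workspace, "mesh", "reconstruction.ply"))
    write_obj(mesh, ws_path(workspace, "mesh", "reconstruction.obj"))
    log_stage(workspace, "mesh", mpath, config$seed, t0,
              list(vertices = nrow(mesh$vertices), faces = nrow(mesh$faces),
                   watertight = is_watertight(mesh),
                   cell_mm = attr(mesh, "cell_mm")))
    say("mesh: %d vertices, watertight = %s", nrow(mesh$vertices),
        is_watertight(mesh))
    result$mesh <- mesh
  }

  if ("evaluate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    rpath <- need_file(file.path(workspace, "mesh", "reconstruction.ply"),
                       "evaluate")
    mesh <- read_ply(rpath)
    report <- list()
    inputs <- rpath
    gt_path <- file.path(workspace, "mesh", "ground_truth.ply")
    if (file.exists(gt_path)) {
      gt <- read_ply(gt_path)
      d_rec <- nearest_distances(mesh$vertices, gt$vertices)
      d_gt <- nearest_distances(gt$vertices, mesh$vertices)
      report$mesh_mm <- unclass(summary_stats(c(d_rec, d_gt)))
      report$hausdorff_mm <- max(d_rec, d_gt)
      write_ply(mesh, ws_path(workspace, "mesh", "distance_map.ply"),
                quality = d_rec)
      inputs <- c(inputs, gt_path)
    }
    dc <- hd_px <- c()
    for (s in serials) {
      sil_path <- file.path(workspace, "frames", s, "silhouette.png")
      msk_path <- file.path(workspace, "masks", paste0(s, ".png"))
      if (file.exists(sil_path) && file.exists(msk_path)) {
        sil <- read_mask_png(sil_path)
        msk <- read_mask_png(msk_path)
        dc <- c(dc, dice(msk, sil))
        hd_px <- c(hd_px, hausdorff(msk, sil))
        inputs <- c(inputs, sil_path, msk_path)
      }
    }
    if (length(dc) > 0) {
      report$dice <- unclass(summary_stats(dc))
      report$hausdorff_px <- unclass(summary_stats(hd_px))
    }
    jsonlite::write_json(report, ws_path(workspace, "report", "report.json"),
                         auto_unbox = TRUE, digits = NA)
    rows <- Filter(function(x) is.list(x),
                   report[intersect(names(report),
                                    c("mesh_mm", "dice", "hausdorff_px"))])
    if (length(rows) > 0)
      utils::write.csv(cbind(metric = names(rows),
                             do.call(rbind, lapply(rows, as.data.frame))),
                       ws_path(workspace, "report", "summary.csv"),
                       row.names = FALSE)
    log_stage(workspace, "evaluate", inputs, config$seed, t0)
    say("evaluate: %s", paste(names(report), collapse = ", "))
    result$report <- report
  }

  invisible(result)
}
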