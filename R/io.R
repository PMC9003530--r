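# File formats: 8-bit RGB PNG for color, 16-bit grayscale PNG (millimetre
# units) for depth, 0/255 PNG for masks, PLY for point clouds and meshes
# (ascii or binary little-endian), OBJ for meshes, JSON for camera
# parameters. All writers are deterministic so re-runs are byte-identical.

png_u32 <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(png_u32(length(data)), td, png_u32(.cpp_crc32(td)))
}

#' Write / read a 16-bit depth PNG
#'
#' Depth in millimetres is stored as 16-bit grayscale (one stored unit =
#' one millimetre); values are rounded to the nearest millimetre and
#' clamped to the 16-bit range. Zero marks invalid depth.
#'
#' @param depth H x W numeric matrix of millimetres.
#' @param path output file.
#' @return `write_depth_png`: the path, invisibly; `read_depth_png`: the
#'   depth matrix (mm).
#' @export
write_depth_png <- function(depth, path) {
  depth <- as.matrix(depth)
  px <- pmin(pmax(round(depth), 0), 65535)
  h <- nrow(px); w <- ncol(px)
  ihdr <- c(png_u32(w), png_u32(h), as.raw(c(16, 0, 0, 0, 0)))
  rows <- lapply(seq_len(h), function(r)
    c(as.raw(0), as.raw(rbind(px[r, ] %/% 256, px[r, ] %% 256))))
  idat <- memCompress(do.call(c, rows), "gzip")  # zlib stream
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' @rdname write_depth_png
#' @export
read_depth_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 65535)
}

#' Write / read an 8-bit color PNG
#'
#' @param color H x W x 3 array, 8-bit per channel (0-255).
#' @param path file path.
#' @return `write_color_png`: the path, invisibly; `read_color_png`: the
#'   H x W x 3 integer array.
#' @export
write_color_png <- function(color, path) {
  png::writePNG(color / 255, path)
  invisible(path)
}

#' @rdname write_color_png
#' @export
read_color_png <- function(path) {
  img <- png::readPNG(path)
  check_that(length(dim(img)) == 3, "expected a color PNG")
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Write / read a binary mask PNG (0/255)
#'
#' @param mask logical H x W matrix.
#' @param path file path.
#' @return `write_mask_png`: the path, invisibly; `read_mask_png`: the
#'   logical mask.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write / read camera intrinsics as JSON
#'
#' Schema: `{width, height, fx, fy, cx, cy, depth_scale}`.
#' @param intrinsics A [camera_intrinsics()].
#' @param path file path.
#' @return `write_intrinsics_json`: the path, invisibly;
#'   `read_intrinsics_json`: a [camera_intrinsics()].
#' @export
write_intrinsics_json <- function(intrinsics, path) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  jsonlite::write_json(list(width = intrinsics$width_px,
                            height = intrinsics$height_px,
                            fx = intrinsics$fx, fy = intrinsics$fy,
                            cx = intrinsics$cx, cy = intrinsics$cy,
                            depth_scale = intrinsics$depth_scale),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intrinsics_json
#' @export
read_intrinsics_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(j$width, j$height, j$fx, j$fy, j$cx, j$cy,
                    if (is.null(j$depth_scale)) 1 else j$depth_scale)
}

#' Write / read rig extrinsics as JSON
#'
#' Each camera's transform into the reference camera frame is stored as a
#' 4 x 4 row-major homogeneous matrix, alongside the reference camera id.
#'
#' @param extrinsics named list of [rigid_transform()].
#' @param path file path.
#' @param reference name of the reference camera.
#' @return `write_extrinsics_json`: the path, invisibly;
#'   `read_extrinsics_json`: list with `extrinsics` (named list of
#'   [rigid_transform()]) and `reference`.
#' @export
write_extrinsics_json <- function(extrinsics, path, reference = names(extrinsics)[1]) {
  check_that(!is.null(names(extrinsics)), "extrinsics must be a named list")
  cams <- lapply(extrinsics, function(tr)
    as.vector(t(transform_matrix(tr))))  # row-major
  jsonlite::write_json(list(reference = reference, cameras = cams),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_extrinsics_json
#' @export
read_extrinsics_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- lapply(j$cameras, function(v)
    transform_from_matrix(matrix(as.numeric(v), 4, 4, byrow = TRUE)))
  list(extrinsics = ex, reference = j$reference)
}

#' Write a point cloud or mesh as PLY
#'
#' Supports `point_cloud` (x/y/z float, optional nx/ny/nz float and
#' red/green/blue uchar) and `triangle_mesh` (vertices + triangular
#' faces). An optional per-vertex scalar (e.g. nearest-surface distance
#' for heat-map viewing) is stored as a float property `quality`.
#'
#' @param x A [point_cloud()] or [triangle_mesh()].
#' @param path file path.
#' @param binary write binary little-endian (default) or ascii.
#' @param quality optional numeric per-vertex/per-point scalar.
#' @return The path, invisibly.
#' @export
write_ply <- function(x, path, binary = TRUE, quality = NULL) {
  if (inherits(x, "point_cloud")) {
    verts <- x$points
    normals <- x$normals
    colors <- x$colors
    faces <- NULL
  } else if (inherits(x, "triangle_mesh")) {
    verts <- x$vertices
    normals <- NULL
    colors <- NULL
    faces <- x$faces
  } else ls_stop("expected a point_cloud or triangle_mesh", "invalid_argument")
  if (!is.null(quality))
    check_that(length(quality) == nrow(verts), "quality must be per-vertex")

  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(verts)),
           "property float x", "property float y", "property float z")
  if (!is.null(normals))
    hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
  if (!is.null(colors))
    hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  if (!is.null(quality)) hdr <- c(hdr, "property float quality")
  if (!is.null(faces))
    hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")

  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  col8 <- if (!is.null(colors)) round(colors * 255) else NULL
  if (binary) {
    fm <- cbind(verts, normals)
    fb <- matrix(writeBin(as.numeric(t(fm)), raw(), size = 4, endian = "little"),
                 nrow = 4 * ncol(fm))
    parts <- list(fb)
    if (!is.null(col8))
      parts <- c(parts, list(matrix(as.raw(t(col8)), nrow = 3)))
    if (!is.null(quality))
      parts <- c(parts, list(matrix(writeBin(as.numeric(quality), raw(),
                                             size = 4, endian = "little"),
                                    nrow = 4)))
    writeBin(as.raw(do.call(rbind, parts)), con)
    if (!is.null(faces)) {
      ib <- matrix(writeBin(as.integer(t(faces - 1L)), raw(), size = 4,
                            endian = "little"), nrow = 12)
      writeBin(as.raw(rbind(matrix(as.raw(3), 1, nrow(faces)), ib)), con)
    }
  } else {
    rows <- apply(cbind(verts, normals), 1, function(v)
      paste(formatC(v, format = "g", digits = 9), collapse = " "))
    if (!is.null(col8))
      rows <- paste(rows, apply(col8, 1, paste, collapse = " "))
    if (!is.null(quality))
      rows <- paste(rows, formatC(quality, format = "g", digits = 9))
    writeLines(rows, con, sep = "\n")
    if (!is.null(faces))
      writeLines(apply(faces, 1, function(f)
        paste(c(3, f - 1L), collapse = " ")), con, sep = "\n")
  }
  invisible(path)
}

#' Read a PLY file
#'
#' Reads the subset of PLY written by [write_ply()]: float vertex
#' properties x/y/z with optional nx/ny/nz, uchar red/green/blue, float
#' quality, and triangular faces; ascii or binary little-endian.
#'
#' @param path file path.
#' @return A [point_cloud()] (no face element) or [triangle_mesh()]; a
#'   `quality` property is attached as an attribute.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    check_that(length(line) == 1, "unexpected end of PLY header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", hdr, value = TRUE))
  check_that(fmt %in% c("ascii", "binary_little_endian"),
             sprintf("unsupported PLY format '%s'", fmt))
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf_line <- grep("^element face", hdr, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("^element face ", "", nf_line)) else 0L
  vstart <- grep("^element vertex", hdr)
  vend <- if (length(nf_line)) grep("^element face", hdr) else length(hdr)
  vprops <- sub("^property ([a-z0-9]+) ", "\\1 ",
                grep("^property", hdr[vstart:vend], value = TRUE))
  ptype <- sub(" .*$", "", vprops)
  pname <- sub("^[a-z0-9]+ ", "", vprops)

  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = nv * length(pname), quiet = TRUE)
    vm <- matrix(vals, nv, length(pname), byrow = TRUE)
  } else {
    sizes <- ifelse(ptype == "uchar", 1L, 4L)
    rowbytes <- sum(sizes)
    data <- matrix(readBin(con, "raw", n = nv * rowbytes), nrow = rowbytes)
    vm <- matrix(0, nv, length(pname))
    off <- cumsum(c(0, sizes))
    for (j in seq_along(pname)) {
      chunk <- as.vector(data[(off[j] + 1):(off[j] + sizes[j]), , drop = FALSE])
      vm[, j] <- if (sizes[j] == 1) as.integer(chunk)
      else readBin(chunk, "numeric", n = nv, size = 4, endian = "little")
    }
  }
  colnames(vm) <- pname
  pts <- vm[, c("x", "y", "z"), drop = FALSE]
  normals <- if (all(c("nx", "ny", "nz") %in% pname))
    vm[, c("nx", "ny", "nz"), drop = FALSE]
  colors <- if (all(c("red", "green", "blue") %in% pname))
    vm[, c("red", "green", "blue"), drop = FALSE] / 255
  quality <- if ("quality" %in% pname) vm[, "quality"]

  if (nf > 0) {
    faces <- matrix(0L, nf, 3)
    if (fmt == "ascii") {
      fv <- scan(con, what = integer(), n = nf * 4, quiet = TRUE)
      fm <- matrix(fv, nf, 4, byrow = TRUE)
      check_that(all(fm[, 1] == 3), "only triangular faces are supported")
      faces[] <- fm[, 2:4] + 1L
    } else {
      data <- matrix(readBin(con, "raw", n = nf * 13L), nrow = 13)
      check_that(all(as.integer(data[1, ]) == 3),
                 "only triangular faces are supported")
      ints <- readBin(as.vector(data[-1, , drop = FALSE]), "integer",
                      n = nf * 3, size = 4, endian = "little")
      faces[] <- matrix(ints, nf, 3, byrow = TRUE) + 1L
    }
    out <- triangle_mesh(pts, faces)
  } else {
    if (!is.null(normals)) {
      len <- sqrt(rowSums(normals^2))
      len[len < 1e-12] <- 1
      normals <- normals / len  # float32 storage loses a little length
    }
    out <- point_cloud(pts, colors = colors, normals = normals)
  }
  if (!is.null(quality)) attr(out, "quality") <- quality
  out
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh A [triangle_mesh()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(apply(mesh$vertices, 1, function(v)
    paste("v", paste(formatC(v, format = "g", digits = 9), collapse = " "))),
    apply(mesh$faces, 1, function(f)
      paste("f", paste(f, collapse = " ")))), con, sep = "\n")
  invisible(path)
}
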