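#' Pinhole camera intrinsics
#'
#' Describes the pinhole model of the depth camera: image size, focal lengths
#' and principal point in pixels, and the metric scale of stored depth units.
#' The camera frame follows the optical convention: x right, y down, z
#' forward along the optical axis.
#'
#' @param width,height image size in pixels.
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels (zero-based pixel coordinates).
#' @param depth_scale metres per stored depth unit. The default 0.001 treats
#'   stored values as millimetres, the convention of consumer stereo depth
#'   cameras.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(width, height, fx, fy,
                              cx = (width - 1) / 2, cy = (height - 1) / 2,
                              depth_scale = 0.001) {
  stopifnot(width > 0, height > 0, fx > 0, fy > 0, depth_scale > 0)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         fx = fx, fy = fy, cx = cx, cy = cy, depth_scale = depth_scale),
    class = "camera_intrinsics"
  )
}

#' A single depth frame
#'
#' @param values integer or numeric matrix of non-negative depth samples in
#'   stored units, `height` rows by `width` columns; zero marks invalid depth.
#' @param intrinsics a [camera_intrinsics()] object.
#' @param frame_index integer frame index within the sequence.
#' @return An object of class `depth_frame`.
#' @export
depth_frame <- function(values, intrinsics, frame_index = 0L) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  values <- as.matrix(values)
  if (nrow(values) != intrinsics$height || ncol(values) != intrinsics$width) {
    stop("depth grid shape (", nrow(values), "x", ncol(values),
         ") does not match intrinsics (", intrinsics$height, "x",
         intrinsics$width, ")")
  }
  if (any(values < 0)) stop("depth samples must be non-negative")
  structure(
    list(values = values, intrinsics = intrinsics,
         frame_index = as.integer(frame_index)),
    class = "depth_frame"
  )
}

#' Unordered point cloud
#'
#' @param points n x 3 numeric matrix of coordinates in metres.
#' @param normals optional n x 3 matrix of unit normals (rows of invalid
#'   normals may be `NA`).
#' @param colors optional n x 3 matrix of RGB values in `[0, 255]`.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, colors = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (!is.null(normals)) {
    normals <- matrix(as.numeric(normals), ncol = 3)
    stopifnot(nrow(normals) == nrow(points))
    len <- sqrt(rowSums(normals^2))
    bad <- is.finite(len) & abs(len - 1) > 1e-6
    if (any(bad, na.rm = TRUE)) stop("normals must have unit length")
  }
  if (!is.null(colors)) {
    colors <- matrix(as.numeric(colors), ncol = 3)
    stopifnot(nrow(colors) == nrow(points),
              all(colors >= 0 & colors <= 255))
  }
  structure(list(points = points, normals = normals, colors = colors),
            class = "point_cloud")
}

#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates in metres.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param vertex_colors optional n x 3 matrix of RGB values in `[0, 255]`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, vertex_colors = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0) {
    if (min(triangles) < 1 || max(triangles) > nrow(vertices))
      stop("triangle indices out of range")
    degen <- triangles[, 1] == triangles[, 2] |
      triangles[, 2] == triangles[, 3] | triangles[, 1] == triangles[, 3]
    if (any(degen)) stop("degenerate triangles (repeated vertex index)")
  }
  if (!is.null(vertex_colors)) {
    vertex_colors <- matrix(as.numeric(vertex_colors), ncol = 3)
    stopifnot(nrow(vertex_colors) == nrow(vertices))
  }
  structure(list(vertices = vertices, triangles = triangles,
                 vertex_colors = vertex_colors),
            class = "surface_mesh")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics %dx%d fx=%.2f fy=%.2f cx=%.2f cy=%.2f scale=%g>\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy, x$depth_scale))
  invisible(x)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s%s>\n", nrow(x$points),
              if (!is.null(x$normals)) ", normals" else "",
              if (!is.null(x$colors)) ", colors" else ""))
  invisible(x)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d triangles%s>\n",
              nrow(x$vertices), nrow(x$triangles),
              if (!is.null(x$vertex_colors)) ", colored" else ""))
  invisible(x)
}
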