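#' Back-project a depth frame into a point cloud
#'
#' Every pixel with a strictly positive depth sample is back-projected by the
#' pinhole model: with metric depth `d = value * depth_scale`, the camera-space
#' point is `x = (u - cx) d / fx`, `y = (v - cy) d / fy`, `z = d`. Zero depth
#' marks an invalid sample and is dropped, never treated as distance zero.
#' Points are emitted in row-major pixel order (row by row).
#'
#' @param frame a [depth_frame()].
#' @return A [point_cloud()] with one point per valid pixel.
#' @export
depth_to_points <- function(frame) {
  stopifnot(inherits(frame, "depth_frame"))
  K <- frame$intrinsics
  w <- K$width; h <- K$height
  # row-major over pixels: v (row) outer, u (column) inner
  d <- as.numeric(t(frame$values))
  u <- rep(seq_len(w) - 1, times = h)
  v <- rep(seq_len(h) - 1, each = w)
  keep <- d > 0
  d <- d[keep] * K$depth_scale
  u <- u[keep]; v <- v[keep]
  pts <- cbind((u - K$cx) * d / K$fx, (v - K$cy) * d / K$fy, d)
  point_cloud(pts)
}

#' Project camera-space points to pixel coordinates
#'
#' Inverse of [depth_to_points()]: `u = x fx / z + cx`, `v = y fy / z + cy`.
#'
#' @param points n x 3 matrix of camera-space points (z > 0).
#' @param intrinsics a [camera_intrinsics()].
#' @return A data frame with columns `u`, `v` (pixels) and `depth` (metres).
#' @export
project_points <- function(points, intrinsics) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(all(points[, 3] > 0))
  data.frame(
    u = points[, 1] / points[, 3] * intrinsics$fx + intrinsics$cx,
    v = points[, 2] / points[, 3] * intrinsics$fy + intrinsics$cy,
    depth = points[, 3]
  )
}

#' Read and write camera intrinsics as YAML
#'
#' @param path file path.
#' @return `read_intrinsics` returns a [camera_intrinsics()] object.
#' @export
read_intrinsics <- function(path) {
  y <- yaml::read_yaml(path)
  camera_intrinsics(y$width, y$height, y$fx, y$fy, y$cx, y$cy,
                    if (is.null(y$depth_scale)) 0.001 else y$depth_scale)
}

#' @rdname read_intrinsics
#' @param intrinsics a [camera_intrinsics()] object to serialize.
#' @export
write_intrinsics <- function(intrinsics, path) {
  yaml::write_yaml(unclass(intrinsics), path)
  invisible(path)
}

#' Read a 16-bit grayscale depth PNG
#'
#' Stored pixel values are interpreted directly as depth units (millimetres by
#' the package default `depth_scale = 0.001`).
#'
#' @param path PNG file path.
#' @param intrinsics a [camera_intrinsics()] matching the image size.
#' @param frame_index frame index to record.
#' @return A [depth_frame()].
#' @export
read_depth_png <- function(path, intrinsics, frame_index = 0L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  vals <- round(img * 65535)
  depth_frame(vals, intrinsics, frame_index)
}

#' Write a depth frame as 16-bit grayscale PNG
#'
#' Stored depth units are written verbatim as 16-bit samples. (Written with a
#' minimal single-IDAT encoder so the full 16-bit range is preserved.)
#'
#' @param frame a [depth_frame()] with values in `[0, 65535]`.
#' @param path output file path.
#' @export
write_depth_png <- function(frame, path) {
  vals <- round(frame$values)
  if (any(vals > 65535)) stop("depth values exceed the 16-bit range")
  h <- nrow(vals); w <- ncol(vals)
  # scanlines: filter byte 0 + big-endian uint16 samples
  m <- t(vals)
  hi <- as.raw(m %/% 256L)
  lo <- as.raw(m %% 256L)
  row_bytes <- 1L + 2L * w
  scan <- raw(h * row_bytes)
  for (r in seq_len(h)) {
    off <- (r - 1L) * row_bytes
    scan[off + 1L] <- as.raw(0L)
    cols <- (r - 1L) * w + seq_len(w)
    scan[off + 1L + 2L * seq_len(w) - 1L] <- hi[cols]
    scan[off + 1L + 2L * seq_len(w)] <- lo[cols]
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  u32 <- function(x) as.raw(c(x %/% 16777216, x %/% 65536 %% 256,
                              x %/% 256 %% 256, x %% 256))
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    writeBin(u32(length(data)), con)
    writeBin(body, con)
    writeBin(u32(cpp_crc32(body, 0)), con)
  }
  ihdr <- c(u32(w), u32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  chunk("IHDR", ihdr)
  chunk("IDAT", memCompress(scan, type = "gzip"))  # zlib stream
  chunk("IEND", raw(0))
  invisible(path)
}

#' Read a lexicographically ordered directory of depth PNG frames
#'
#' @param dir directory containing `*.png` depth frames; lexicographic file
#'   order defines the frame index.
#' @param intrinsics a [camera_intrinsics()].
#' @return A list of [depth_frame()] objects.
#' @export
read_depth_sequence <- function(dir, intrinsics) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(seq_along(files), function(i) {
    read_depth_png(files[i], intrinsics, frame_index = i - 1L)
  })
}
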