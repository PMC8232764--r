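# PLY polygon-format reader/writer. Handles the two dialects the pipeline
# needs: ASCII and binary little-endian; vertex properties x,y,z with
# optional nx,ny,nz (float) and red,green,blue (uchar); triangular faces.

.ply_types <- list(
  char = c(1, "integer", TRUE),   int8 = c(1, "integer", TRUE),
  uchar = c(1, "integer", FALSE), uint8 = c(1, "integer", FALSE),
  short = c(2, "integer", TRUE),  int16 = c(2, "integer", TRUE),
  ushort = c(2, "integer", FALSE), uint16 = c(2, "integer", FALSE),
  int = c(4, "integer", TRUE),    int32 = c(4, "integer", TRUE),
  uint = c(4, "integer", TRUE),   uint32 = c(4, "integer", TRUE),
  float = c(4, "double", TRUE),   float32 = c(4, "double", TRUE),
  double = c(8, "double", TRUE),  float64 = c(8, "double", TRUE)
)

.ply_type_size <- function(t) {
  info <- .ply_types[[t]]
  if (is.null(info)) stop("unsupported PLY property type: ", t)
  as.integer(info[1])
}

#' Write a point cloud or mesh as a PLY file
#'
#' Vertex positions (and normals) are stored as 32-bit floats, colors as
#' bytes, and faces as triangles; the binary little-endian dialect is the
#' default.
#'
#' @param object a [point_cloud()] or [surface_mesh()].
#' @param path output file path.
#' @param binary write binary little-endian (default) or ASCII.
#' @export
write_ply <- function(object, path, binary = TRUE) {
  is_mesh <- inherits(object, "surface_mesh")
  if (!is_mesh && !inherits(object, "point_cloud"))
    stop("object must be a point_cloud or surface_mesh")
  V <- if (is_mesh) object$vertices else object$points
  Nrm <- if (is_mesh) NULL else object$normals
  Col <- if (is_mesh) object$vertex_colors else object$colors
  Tr <- if (is_mesh) object$triangles else NULL

  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z")
  if (!is.null(Nrm)) hdr <- c(hdr, "property float nx", "property float ny",
                              "property float nz")
  if (!is.null(Col)) hdr <- c(hdr, "property uchar red", "property uchar green",
                              "property uchar blue")
  if (!is.null(Tr)) hdr <- c(hdr, sprintf("element face %d", nrow(Tr)),
                             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")

  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  ncolumns <- 3 + 3 * (!is.null(Nrm)) + 3 * (!is.null(Col))
  if (binary) {
    Vf <- if (is.null(Nrm)) V else cbind(V, Nrm)
    nf <- ncol(Vf)
    fb <- writeBin(as.numeric(t(Vf)), raw(), size = 4, endian = "little")
    rec <- matrix(fb, nrow = 4L * nf)  # one column per vertex
    if (!is.null(Col)) {
      rec <- rbind(rec, matrix(as.raw(round(t(Col))), nrow = 3L))
    }
    writeBin(as.vector(rec), con)
    if (!is.null(Tr) && nrow(Tr) > 0) {
      ib <- writeBin(as.integer(t(Tr) - 1L), raw(), size = 4, endian = "little")
      frec <- rbind(matrix(as.raw(3L), 1L, nrow(Tr)), matrix(ib, nrow = 12L))
      writeBin(as.vector(frec), con)
    }
  } else {
    rec <- cbind(V, Nrm)
    lines <- do.call(paste, c(lapply(seq_len(ncol(rec)), function(j)
      format(rec[, j], digits = 9, trim = TRUE, scientific = FALSE)),
      if (!is.null(Col)) lapply(1:3, function(j) round(Col[, j]))))
    writeLines(lines, con)
    if (!is.null(Tr)) {
      writeLines(paste(3, Tr[, 1] - 1L, Tr[, 2] - 1L, Tr[, 3] - 1L), con)
    }
  }
  invisible(path)
}

#' Read a PLY file
#'
#' Accepts ASCII and binary little-endian dialects. Returns a
#' [surface_mesh()] when a face element with at least one face is present,
#' otherwise a [point_cloud()].
#'
#' @param path PLY file path.
#' @return A [point_cloud()] or [surface_mesh()].
#' @export
read_ply <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  # locate end of header on the raw bytes (the body may be binary)
  pos <- grepRaw("end_header", raw_all, fixed = TRUE)
  if (length(pos) == 0) stop("malformed PLY header: missing end_header")
  rest <- raw_all[seq.int(pos, length(raw_all))]
  nl <- which(rest == as.raw(10))[1]
  if (is.na(nl)) stop("malformed PLY header: missing end_header newline")
  body_off <- pos + nl - 1L
  hdr_lines <- strsplit(rawToChar(raw_all[seq_len(pos - 1L)]), "\r?\n")[[1]]
  if (length(hdr_lines) == 0 || hdr_lines[1] != "ply")
    stop("malformed PLY header at line 1: expected 'ply'")

  fmt <- NULL
  elements <- list()
  cur <- NULL
  for (li in seq_along(hdr_lines)[-1]) {
    line <- trimws(hdr_lines[li])
    if (line == "" || startsWith(line, "comment")) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format at header line ", li, ": ", line)
    } else if (tok[1] == "element") {
      cur <- length(elements) + 1L
      elements[[cur]] <- list(name = tok[2], count = as.integer(tok[3]),
                              props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY header at line ", li, ": ", line)
      p <- if (tok[2] == "list") {
        list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        list(name = tok[3], list = FALSE, type = tok[2])
      }
      elements[[cur]]$props[[length(elements[[cur]]$props) + 1L]] <- p
    } else {
      stop("malformed PLY header at line ", li, ": ", line)
    }
  }
  if (is.null(fmt)) stop("malformed PLY header: missing format line")

  body_raw <- raw_all[seq.int(body_off + 1L, length(raw_all))]
  if (fmt == "ascii") {
    tokens <- strsplit(trimws(rawToChar(body_raw)), "\\s+")[[1]]
    pos <- 1L
  }

  vert <- NULL
  faces <- NULL
  off <- 0L
  for (el in elements) {
    if (!any(vapply(el$props, function(p) p$list, logical(1)))) {
      # fixed-stride element
      nm <- vapply(el$props, `[[`, "", "name")
      if (fmt == "ascii") {
        np <- length(el$props)
        vals <- tokens[seq.int(pos, length.out = el$count * np)]
        pos <- pos + el$count * np
        M <- matrix(as.numeric(vals), nrow = el$count, byrow = TRUE)
      } else {
        sizes <- vapply(el$props, function(p) .ply_type_size(p$type), 1L)
        stride <- sum(sizes)
        offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
        block <- body_raw[seq.int(off + 1L, length.out = el$count * stride)]
        off <- off + el$count * stride
        M <- matrix(0, el$count, length(el$props))
        for (j in seq_along(el$props)) {
          info <- .ply_types[[el$props[[j]]$type]]
          s <- as.integer(info[1])
          sel <- as.vector(outer(seq_len(s), (seq_len(el$count) - 1L) * stride +
                                   offs[j], "+"))
          M[, j] <- readBin(block[sel], info[2], n = el$count, size = s,
                            signed = as.logical(info[3]), endian = "little")
        }
      }
      colnames(M) <- nm
      if (el$name == "vertex") vert <- M
    } else {
      # list element (faces)
      if (el$name != "face" || length(el$props) != 1)
        stop("unsupported PLY list element: ", el$name)
      p <- el$props[[1]]
      cs <- .ply_type_size(p$count_type)
      is_ <- .ply_type_size(p$type)
      fl <- vector("list", el$count)
      if (fmt == "ascii") {
        for (i in seq_len(el$count)) {
          cnt <- as.integer(tokens[pos]); pos <- pos + 1L
          fl[[i]] <- as.integer(tokens[seq.int(pos, length.out = cnt)])
          pos <- pos + cnt
        }
      } else {
        # fast path: uniform arity
        arity <- if (el$count > 0)
          readBin(body_raw[off + 1L], "integer", size = cs, signed = FALSE,
                  endian = "little") else 0L
        rec <- cs + arity * is_
        if (el$count > 0 && off + el$count * rec <= length(body_raw) &&
            all(body_raw[off + (seq_len(el$count) - 1L) * rec + 1L] ==
                body_raw[off + 1L])) {
          info <- .ply_types[[p$type]]
          sel <- as.vector(outer(seq_len(arity * is_),
                                 (seq_len(el$count) - 1L) * rec + cs, "+")) + off
          idx <- readBin(body_raw[sel], info[2], n = el$count * arity,
                         size = is_, signed = as.logical(info[3]),
                         endian = "little")
          fl <- split(idx, rep(seq_len(el$count), each = arity))
          off <- off + el$count * rec
        } else {
          for (i in seq_len(el$count)) {
            cnt <- readBin(body_raw[off + seq_len(cs)], "integer", size = cs,
                           signed = FALSE, endian = "little")
            off <- off + cs
            fl[[i]] <- readBin(body_raw[off + seq_len(cnt * is_)], "integer",
                               n = cnt, size = is_, endian = "little")
            off <- off + cnt * is_
          }
        }
      }
      faces <- fl
    }
  }
  if (is.null(vert)) stop("PLY file has no vertex element")
  nm <- colnames(vert)
  pts <- vert[, c("x", "y", "z"), drop = FALSE]
  nrm <- if (all(c("nx", "ny", "nz") %in% nm))
    vert[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  col <- if (all(c("red", "green", "blue") %in% nm))
    vert[, c("red", "green", "blue"), drop = FALSE] else NULL
  if (!is.null(faces) && length(faces) > 0) {
    if (any(vapply(faces, length, 1L) != 3))
      faces <- lapply(faces, function(f) f[1:3])  # triangles only
    Tr <- do.call(rbind, faces) + 1L
    surface_mesh(pts, Tr, vertex_colors = col)
  } else {
    point_cloud(pts, normals = nrm, colors = col)
  }
}
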