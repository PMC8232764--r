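#' Vertex adjacency of a triangle mesh
#'
#' @param mesh a [surface_mesh()].
#' @return A list with one sorted integer vector of 1-ring neighbor indices
#'   per vertex (symmetric relation).
#' @export
vertex_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  tr <- mesh$triangles
  from <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 2], tr[, 3], tr[, 1])
  to   <- c(tr[, 2], tr[, 3], tr[, 1], tr[, 1], tr[, 2], tr[, 3])
  adj <- split(to, factor(from, levels = seq_len(n)))
  unname(lapply(adj, function(v) sort(unique(v))))
}

#' Undirected edge list of a triangle mesh
#'
#' @param mesh a [surface_mesh()].
#' @return A list with `edges` (m x 2, first column smaller index) and
#'   `count` (number of incident triangles per edge).
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  a <- c(tr[, 1], tr[, 2], tr[, 3])
  b <- c(tr[, 2], tr[, 3], tr[, 1])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  cnt <- as.integer(table(factor(key, levels = key[first])))
  list(edges = cbind(lo[first], hi[first]), count = cnt)
}

#' Total surface area of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return Area in square metres.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; tr <- mesh$triangles
  if (nrow(tr) == 0) return(0)
  e1 <- V[tr[, 2], , drop = FALSE] - V[tr[, 1], , drop = FALSE]
  e2 <- V[tr[, 3], , drop = FALSE] - V[tr[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Area-weighted vertex normals of a mesh
#'
#' Face normals (from triangle winding) are accumulated at the vertices and
#' renormalized; when `viewpoint` is given, normals are flipped to face it.
#'
#' @param mesh a [surface_mesh()].
#' @param viewpoint optional 3-vector; normals are oriented toward it.
#' @return n x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh, viewpoint = NULL) {
  V <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(V)
  e1 <- V[tr[, 2], , drop = FALSE] - V[tr[, 1], , drop = FALSE]
  e2 <- V[tr[, 3], , drop = FALSE] - V[tr[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  rs <- rowsum(rbind(fn, fn, fn), group = c(tr[, 1], tr[, 2], tr[, 3]))
  acc <- matrix(0, n, 3)
  acc[as.integer(rownames(rs)), ] <- rs
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  nrm <- acc / len
  if (!is.null(viewpoint)) {
    tov <- sweep(-V, 2, -as.numeric(viewpoint), "+")
    flip <- rowSums(nrm * tov) < 0
    nrm[flip, ] <- -nrm[flip, ]
  }
  nrm
}

#' Euler characteristic V - E + F of a mesh
#'
#' Counts only vertices referenced by at least one triangle.
#'
#' @param mesh a [surface_mesh()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  vs <- unique(as.integer(mesh$triangles))
  e <- nrow(mesh_edges(mesh)$edges)
  length(vs) - e + nrow(mesh$triangles)
}

#' Connected components of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return Integer vector assigning a component id to every vertex (isolated
#'   vertices get their own component).
#' @export
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  ed <- mesh_edges(mesh)$edges
  for (r in seq_len(nrow(ed))) {
    a <- find(ed[r, 1]); b <- find(ed[r, 2])
    if (a != b) comp[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Estimate normals by principal component analysis
#'
#' Each point's normal is the eigenvector with the smallest eigenvalue of the
#' covariance of its k-neighborhood (neighbors plus the point itself),
#' oriented to face `viewpoint` (the camera origin by default; single-view
#' capture makes this unambiguous). Degenerate (collinear) neighborhoods get
#' an `NA` normal, flagged invalid.
#'
#' @param cloud a [point_cloud()] with at least `k + 1` points.
#' @param k number of neighbors (>= 3).
#' @param viewpoint 3-vector toward which normals are oriented.
#' @return The cloud with a `normals` matrix and attribute
#'   `normal_valid` (logical vector).
#' @export
estimate_normals_pca <- function(cloud, k = 12, viewpoint = c(0, 0, 0)) {
  stopifnot(inherits(cloud, "point_cloud"), k >= 3,
            nrow(cloud$points) >= k + 1)
  res <- cpp_pca_normals(cloud$points, as.integer(k), as.numeric(viewpoint))
  out <- cloud
  out$normals <- res$normals
  attr(out, "normal_valid") <- res$valid
  out
}

#' K-nearest-neighbor search
#'
#' Thin wrapper over the package kd-tree, exposed because several stages and
#' their tests share it.
#'
#' @param points n x 3 reference points.
#' @param queries q x 3 query points (defaults to `points`, excluding self
#'   matches).
#' @param k neighbor count.
#' @return List with `idx` (q x k, 1-based) and `dist` (q x k).
#' @export
knn_search <- function(points, queries = NULL, k = 1) {
  self <- is.null(queries)
  if (self) queries <- points
  cpp_knn(matrix(as.numeric(points), ncol = 3),
          matrix(as.numeric(queries), ncol = 3), as.integer(k), self)
}

#' Orient a closed mesh outward
#'
#' Computes the signed volume from the triangle winding and flips every
#' triangle when it is negative, so that consistently wound closed meshes
#' end up with outward normals (as assumed by the winding sign convention
#' of [mesh_to_tsdf()]).
#'
#' @param mesh a closed, consistently wound [surface_mesh()].
#' @return The mesh, possibly with all triangles flipped.
#' @export
orient_mesh_outward <- function(mesh) {
  V <- mesh$vertices; tr <- mesh$triangles
  a <- V[tr[, 1], , drop = FALSE]
  b <- V[tr[, 2], , drop = FALSE]
  c <- V[tr[, 3], , drop = FALSE]
  vol6 <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
              a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
              a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1]))
  if (vol6 < 0) mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}

#' Distance from points to a triangle mesh surface
#'
#' Exact point-to-triangle distances (accelerated by a uniform grid over
#' triangles), as used for re-projection during remeshing and for mesh
#' comparison in validation.
#'
#' @param points n x 3 query points.
#' @param mesh a [surface_mesh()].
#' @return A list with `dist` (length n), `points` (closest surface points)
#'   and `tri` (1-based triangle index per query).
#' @export
mesh_distance <- function(points, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"), nrow(mesh$triangles) > 0)
  cpp_closest_on_mesh(matrix(as.numeric(points), ncol = 3),
                      mesh$vertices, mesh$triangles)
}
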