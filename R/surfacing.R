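# Explicit surface generation: advancing-front triangulation and incremental
# isotropic remeshing (edge split / collapse / flip + tangential smoothing),
# plus deformation-graph construction.

#' Advancing-front surface reconstruction
#'
#' Triangulates an unorganized point cloud by greedy front growth: the seed
#' is the candidate triangle with the smallest circumradius (the radius of
#' the circle through its three vertices); a priority queue of candidate
#' triangles adjacent to the open front is maintained, admitted
#' smallest-circumradius-first, rejecting candidates that would create a
#' non-manifold or inconsistently oriented edge. When the front exhausts with
#' unused points left (a discontinuity), the algorithm reseeds from the
#' smallest-circumradius triangle among the remaining points. Small boundary
#' cycles (up to `max_hole_edges`) are closed by ear filling. No new vertices
#' are created: output vertices are exactly the input points.
#'
#' @param cloud a [point_cloud()] with at least 3 non-collinear points.
#' @param k neighborhood size used to generate candidate triangles.
#' @param radius_factor admissible circumradius cap, as a multiple of the
#'   median nearest-neighbor spacing (`Inf` disables the cap).
#' @param min_dot minimum dot product between normals of adjacent triangles
#'   (rejects folds).
#' @param max_hole_edges largest boundary cycle closed by hole filling.
#' @return A [surface_mesh()] over the input points.
#' @export
advancing_front_reconstruct <- function(cloud, k = 16, radius_factor = 5,
                                        min_dot = -0.5, max_hole_edges = 8) {
  stopifnot(inherits(cloud, "point_cloud"))
  P <- cloud$points
  n <- nrow(P)
  if (n < 3) stop("reconstruction needs at least 3 points")
  ctr <- sweep(P, 2, colMeans(P))
  if (sum(svd(ctr, nu = 0, nv = 0)$d > 1e-12 * max(1, max(abs(ctr)))) < 2)
    stop("reconstruction needs non-collinear points")
  k <- min(k, n - 1)
  kn <- knn_search(P, k = k)
  rmax <- if (is.finite(radius_factor))
    radius_factor * stats::median(kn$dist[, 1]) else 1e290
  knn_list <- lapply(seq_len(n), function(i) kn$idx[i, ])
  Tr <- cpp_advancing_front(P, knn_list, rmax, min_dot,
                            as.integer(max_hole_edges))
  if (nrow(Tr) == 0) stop("reconstruction failed: no admissible seed triangle")
  surface_mesh(P, Tr)
}

# encode undirected edge pairs as order-independent numeric keys
.edge_key <- function(a, b) {
  pmin(a, b) * 2^26 + pmax(a, b)
}

#' Incremental isotropic remeshing
#'
#' Per iteration: edges longer than `4/3 L` are split at their midpoint;
#' edges shorter than `4/5 L` are collapsed (skipped when the collapse would
#' create an overlong edge, flip a triangle, or break the local manifold
#' link condition); interior edges are flipped when that moves vertex
#' valences toward 6 (4 on the boundary); and vertices are relaxed by
#' tangential Laplacian smoothing with re-projection onto the original
#' surface. Boundary edges are never collapsed and boundary vertices move
#' only along the boundary.
#'
#' @param mesh a [surface_mesh()].
#' @param L target edge length in metres.
#' @param iterations remeshing iterations (default 3).
#' @return The remeshed [surface_mesh()].
#' @export
isotropic_remesh <- function(mesh, L, iterations = 3) {
  stopifnot(inherits(mesh, "surface_mesh"), L > 0, iterations >= 1)
  V <- mesh$vertices
  F <- mesh$triangles
  V0 <- V; F0 <- F  # original surface for re-projection
  ed0 <- mesh_edges(mesh)
  if (any(ed0$count > 2))
    warning("non-manifold input edges are frozen during remeshing")
  for (it in seq_len(iterations)) {
    sp <- .remesh_split(V, F, 4 / 3 * L)
    V <- sp$V; F <- sp$F
    cl <- .remesh_collapse(V, F, 4 / 5 * L, 4 / 3 * L)
    V <- cl$V; F <- cl$F
    F <- .remesh_flip(V, F)
    V <- .remesh_smooth(V, F, V0, F0)
  }
  used <- sort(unique(as.integer(F)))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  surface_mesh(V[used, , drop = FALSE],
               matrix(remap[F], ncol = 3))
}

# split every edge > Lmax that is the longest edge of all its incident
# triangles; repeat until no long edges remain
.remesh_split <- function(V, F, Lmax) {
  repeat {
    if (nrow(F) == 0) break
    m <- nrow(F)
    el <- matrix(0, m, 3)
    for (s in 1:3) {
      a <- F[, s]; b <- F[, s %% 3 + 1]
      el[, s] <- sqrt(rowSums((V[a, , drop = FALSE] - V[b, , drop = FALSE])^2))
    }
    longest <- max.col(el, ties.method = "first")
    keys <- matrix(0, m, 3)
    for (s in 1:3) keys[, s] <- .edge_key(F[, s], F[, s %% 3 + 1])
    long_any <- el > Lmax
    if (!any(long_any)) break
    # a key is eligible iff every occurrence is its triangle's longest slot
    occ_key <- as.vector(keys)
    occ_is_longest <- as.vector(col(keys) == longest)
    occ_long <- as.vector(long_any)
    bad <- unique(occ_key[!occ_is_longest])
    elig <- setdiff(unique(occ_key[occ_long & occ_is_longest]), bad)
    if (length(elig) == 0) break
    # create midpoints
    sel <- col(keys) == longest & matrix(keys %in% elig, m, 3)
    tsel <- which(rowSums(sel) > 0)
    key_t <- keys[cbind(tsel, longest[tsel])]
    ukeys <- unique(key_t)
    a_u <- floor(ukeys / 2^26); b_u <- ukeys - a_u * 2^26
    mid <- (V[a_u, , drop = FALSE] + V[b_u, , drop = FALSE]) / 2
    mid_id <- nrow(V) + seq_along(ukeys)
    V <- rbind(V, mid)
    newF <- vector("list", length(tsel))
    for (q in seq_along(tsel)) {
      t <- tsel[q]; s <- longest[t]
      a <- F[t, s]; b <- F[t, s %% 3 + 1]; c <- F[t, (s + 1) %% 3 + 1]
      mv <- mid_id[match(key_t[q], ukeys)]
      newF[[q]] <- rbind(c(a, mv, c), c(mv, b, c))
    }
    F <- rbind(F[-tsel, , drop = FALSE], do.call(rbind, newF))
  }
  list(V = V, F = F)
}

# collapse short edges sequentially with manifold / length / flip guards
.remesh_collapse <- function(V, F, Lmin, Lmax) {
  ed <- mesh_edges(surface_mesh(V, F))
  bnd_v <- unique(as.integer(ed$edges[ed$count == 1, ]))
  is_bnd <- logical(nrow(V)); is_bnd[bnd_v] <- TRUE
  lens <- sqrt(rowSums((V[ed$edges[, 1], , drop = FALSE] -
                          V[ed$edges[, 2], , drop = FALSE])^2))
  cand <- order(lens)[lens[order(lens)] < Lmin]
  if (length(cand) == 0) return(list(V = V, F = F))
  # vertex -> incident triangle ids
  inc <- split(rep(seq_len(nrow(F)), 3), as.integer(F))
  inc_full <- vector("list", nrow(V))
  inc_full[as.integer(names(inc))] <- inc
  alive <- rep(TRUE, nrow(F))
  merged <- seq_len(nrow(V))  # union-find style redirect
  res <- function(v) { while (merged[v] != v) v <- merged[v]; v }
  for (ei in cand) {
    a <- res(ed$edges[ei, 1]); b <- res(ed$edges[ei, 2])
    if (a == b) next
    if (sqrt(sum((V[a, ] - V[b, ])^2)) >= Lmin) next
    ta <- inc_full[[a]]; ta <- ta[alive[ta]]
    tb <- inc_full[[b]]; tb <- tb[alive[tb]]
    shared <- intersect(ta, tb)
    if (length(shared) == 0 || length(shared) > 2) next
    # boundary edge: never collapse
    if (length(shared) == 1) next
    na_ <- setdiff(unique(as.integer(F[ta, ])), c(a, b))
    nb_ <- setdiff(unique(as.integer(F[tb, ])), c(a, b))
    opp <- setdiff(unique(as.integer(F[shared, ])), c(a, b))
    # link condition
    if (!setequal(intersect(na_, nb_), opp)) next
    # interior edge between two boundary vertices: collapse b into a without
    # moving a, so the boundary polyline is only shortened, never displaced
    pos <- if (is_bnd[a]) V[a, ] else if (is_bnd[b]) V[b, ]
    else (V[a, ] + V[b, ]) / 2
    # resulting edge lengths
    ring <- union(na_, nb_)
    dl <- sqrt(rowSums((V[ring, , drop = FALSE] -
                          matrix(pos, length(ring), 3, byrow = TRUE))^2))
    if (any(dl > Lmax)) next
    # triangle flip check on surviving triangles
    surv <- setdiff(union(ta, tb), shared)
    flip_bad <- FALSE
    for (t in surv) {
      tri <- F[t, ]
      p_old <- V[tri, , drop = FALSE]
      p_new <- p_old
      p_new[tri == a | tri == b, ] <- matrix(pos, sum(tri == a | tri == b), 3,
                                             byrow = TRUE)
      n_old <- .tri_normal(p_old)
      n_new <- .tri_normal(p_new)
      if (sum(n_old * n_new) <= 0) { flip_bad <- TRUE; break }
    }
    if (flip_bad) next
    # apply collapse: b merges into a
    V[a, ] <- pos
    merged[b] <- a
    is_bnd[a] <- is_bnd[a] || is_bnd[b]
    alive[shared] <- FALSE
    Fsub <- F[tb, , drop = FALSE]
    Fsub[Fsub == b] <- a
    F[tb, ] <- Fsub
    inc_full[[a]] <- union(setdiff(ta, shared), setdiff(tb, shared))
    inc_full[[b]] <- integer(0)
  }
  F <- F[alive, , drop = FALSE]
  list(V = V, F = F)
}

.tri_normal <- function(p) {
  e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
  c(e1[2] * e2[3] - e1[3] * e2[2],
    e1[3] * e2[1] - e1[1] * e2[3],
    e1[1] * e2[2] - e1[2] * e2[1])
}

# flip interior edges when it moves valences toward the ideal (6 interior,
# 4 boundary); edge -> triangle incidence kept in a hashed map updated per flip
.remesh_flip <- function(V, F) {
  if (nrow(F) == 0) return(F)
  ed <- mesh_edges(surface_mesh(V, F))
  val <- tabulate(as.integer(ed$edges), nbins = nrow(V))
  bnd_v <- unique(as.integer(ed$edges[ed$count == 1, ]))
  target <- rep(6L, nrow(V)); target[bnd_v] <- 4L
  emap <- new.env(hash = TRUE, size = 4 * nrow(F))
  add_tri_edges <- function(t) {
    for (s in 1:3) {
      k <- as.character(.edge_key(F[t, s], F[t, s %% 3 + 1]))
      emap[[k]] <- c(emap[[k]], t)
    }
  }
  drop_tri_edges <- function(t, tri) {
    for (s in 1:3) {
      k <- as.character(.edge_key(tri[s], tri[s %% 3 + 1]))
      emap[[k]] <- setdiff(emap[[k]], t)
    }
  }
  for (t in seq_len(nrow(F))) add_tri_edges(t)
  interior <- ed$edges[ed$count == 2, , drop = FALSE]
  for (r in seq_len(nrow(interior))) {
    a <- interior[r, 1]; b <- interior[r, 2]
    ts <- emap[[as.character(.edge_key(a, b))]]
    if (length(ts) != 2) next
    opp <- setdiff(as.integer(F[ts, ]), c(a, b))
    if (length(opp) != 2) next
    c1 <- opp[1]; d1 <- opp[2]
    nk <- as.character(.edge_key(c1, d1))
    if (length(emap[[nk]]) > 0) next  # flipped edge already exists
    dev_before <- sum((val[c(a, b, c1, d1)] - target[c(a, b, c1, d1)])^2)
    val_after <- val[c(a, b, c1, d1)] + c(-1, -1, 1, 1)
    dev_after <- sum((val_after - target[c(a, b, c1, d1)])^2)
    if (dev_after >= dev_before) next
    # geometric guards: new triangles must not fold relative to old pair
    old_n <- .tri_normal(V[F[ts[1], ], , drop = FALSE]) +
      .tri_normal(V[F[ts[2], ], , drop = FALSE])
    t1 <- c(c1, d1, a); t2 <- c(d1, c1, b)
    n1 <- .tri_normal(V[t1, , drop = FALSE])
    n2 <- .tri_normal(V[t2, , drop = FALSE])
    if (sum(n1 * old_n) <= 0 || sum(n2 * old_n) <= 0) next
    drop_tri_edges(ts[1], F[ts[1], ])
    drop_tri_edges(ts[2], F[ts[2], ])
    F[ts[1], ] <- t1
    F[ts[2], ] <- t2
    add_tri_edges(ts[1])
    add_tri_edges(ts[2])
    val[c(a, b, c1, d1)] <- val_after
  }
  F
}

# tangential Laplacian smoothing with re-projection onto the original surface
.remesh_smooth <- function(V, F, V0, F0, lambda = 0.5) {
  if (nrow(F) == 0) return(V)
  mesh <- surface_mesh(V, F)
  ed <- mesh_edges(mesh)
  bnd_e <- ed$edges[ed$count == 1, , drop = FALSE]
  bnd_v <- unique(as.integer(bnd_e))
  adj <- vertex_adjacency(mesh)
  nrm <- mesh_vertex_normals(mesh)
  used <- sort(unique(as.integer(F)))
  newV <- V
  for (v in used) {
    nb <- adj[[v]]
    if (length(nb) == 0) next
    if (v %in% bnd_v) {
      # move only along the boundary polyline
      bn <- unique(as.integer(bnd_e[bnd_e[, 1] == v | bnd_e[, 2] == v, ]))
      bn <- setdiff(bn, v)
      if (length(bn) != 2) next
      newV[v, ] <- V[v, ] + lambda * (colMeans(V[bn, , drop = FALSE]) - V[v, ])
    } else {
      g <- colMeans(V[nb, , drop = FALSE]) - V[v, ]
      g_t <- g - sum(g * nrm[v, ]) * nrm[v, ]
      newV[v, ] <- V[v, ] + lambda * g_t
    }
  }
  # re-project interior vertices onto the original surface
  intv <- setdiff(used, bnd_v)
  if (length(intv) > 0) {
    proj <- cpp_closest_on_mesh(newV[intv, , drop = FALSE], V0, F0)
    newV[intv, ] <- proj$points
  }
  newV
}

#' Build a deformation graph from a surface
#'
#' The deformation graph is a lower-resolution isotropic remesh of the
#' surface; every graph vertex is a keypoint. `source_map` records, for each
#' graph vertex, the index of its nearest vertex on the source surface,
#' maintaining the graph-to-surface relationship used to propagate
#' deformation constraints.
#'
#' @param surface a [surface_mesh()].
#' @param L target edge length of the graph mesh (metres); typically several
#'   times the cloud standardization resolution.
#' @param iterations remeshing iterations.
#' @param viewpoint point toward which graph vertex normals are oriented
#'   (the camera origin by default, the right choice for single-view
#'   surfaces); `NULL` keeps the winding-based orientation.
#' @return An object of class `deformation_graph` with fields `graph_mesh`,
#'   `source_map`, `target_edge_length`, and per-vertex `normals`.
#' @export
build_deformation_graph <- function(surface, L, iterations = 3,
                                    viewpoint = c(0, 0, 0)) {
  stopifnot(inherits(surface, "surface_mesh"), nrow(surface$vertices) > 0)
  gm <- isotropic_remesh(surface, L, iterations)
  kn <- knn_search(surface$vertices, gm$vertices, k = 1)
  structure(
    list(graph_mesh = gm,
         source_map = as.integer(kn$idx[, 1]),
         target_edge_length = L,
         normals = mesh_vertex_normals(gm, viewpoint = viewpoint)),
    class = "deformation_graph"
  )
}

#' @export
print.deformation_graph <- function(x, ...) {
  cat(sprintf("<deformation_graph: %d keypoints, target edge %.3g m>\n",
              nrow(x$graph_mesh$vertices), x$target_edge_length))
  invisible(x)
}
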