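# Point-cloud conditioning: octree standardization, statistical outlier
# removal, and bilateral smoothing (normal smoothing + constrained
# repositioning).

#' Octree voxel downsampling
#'
#' Points are grouped into axis-aligned voxels of the given resolution
#' (octree leaves anchored at the cloud's minimum corner) and each occupied
#' voxel is consolidated to a single representative point.
#'
#' @param cloud a [point_cloud()].
#' @param resolution voxel edge length in metres.
#' @param mode consolidation mode: `"centroid_of_points"` (default; mean of
#'   the voxel's points), `"centroid_of_voxel"` (geometric voxel centre),
#'   `"first_point"` or `"last_point"` (input order defines insertion order).
#' @return Downsampled [point_cloud()]; normals/colors follow the chosen
#'   representative (averaged for the centroid-of-points mode).
#' @export
octree_downsample <- function(cloud, resolution,
                              mode = c("centroid_of_points", "centroid_of_voxel",
                                       "first_point", "last_point")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cloud, "point_cloud"), resolution > 0)
  P <- cloud$points
  n <- nrow(P)
  if (n == 0) return(cloud)
  origin <- apply(P, 2, min)
  idx <- floor(sweep(P, 2, origin) / resolution)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  fkey <- factor(key, levels = unique(key))  # first-occurrence order
  if (mode == "centroid_of_points") {
    out <- rowsum(P, fkey, reorder = FALSE) /
      as.integer(table(fkey)[levels(fkey)])
    nrm <- NULL
    if (!is.null(cloud$normals)) {
      nrm <- rowsum(cloud$normals, fkey, reorder = FALSE, na.rm = TRUE)
      l <- sqrt(rowSums(nrm^2)); l[l == 0] <- NA
      nrm <- nrm / l
    }
    col <- if (!is.null(cloud$colors))
      rowsum(cloud$colors, fkey, reorder = FALSE) /
        as.integer(table(fkey)[levels(fkey)]) else NULL
    return(point_cloud(out, normals = nrm, colors = col))
  }
  if (mode == "centroid_of_voxel") {
    first <- !duplicated(fkey)
    centres <- sweep((idx[first, , drop = FALSE] + 0.5) * resolution, 2,
                     origin, "+")
    return(point_cloud(centres))
  }
  sel <- if (mode == "first_point") which(!duplicated(fkey))
  else sort(n + 1L - which(!duplicated(rev(as.integer(fkey)))))
  subset_cloud(cloud, sel)
}

#' Mean neighbor distance of a cloud
#'
#' The global mean, over all M points, of each point's mean Euclidean
#' distance to its N nearest neighbors (self excluded):
#' `d_m = (1/M) sum_i (1/N) sum_j ||p_i - p_j||`.
#'
#' @param cloud a [point_cloud()] with more than `N` points.
#' @param N neighbor count per point.
#' @return `d_m` in metres.
#' @export
mean_neighbor_distance <- function(cloud, N = 6) {
  stopifnot(inherits(cloud, "point_cloud"), N >= 1)
  M <- nrow(cloud$points)
  if (M <= N) stop("cloud must have more than N points")
  kn <- knn_search(cloud$points, k = N)
  mean(rowMeans(kn$dist))
}

#' Statistical outlier removal
#'
#' A point is an outlier when its local mean neighbor distance exceeds
#' `f_out` times the global mean neighbor distance: `d_local > d_m * f_out`.
#' The pass is single-shot: `d_m` and all `d_local` are computed on the input
#' cloud, so the result does not depend on removal order (re-running on the
#' result is the caller's choice).
#'
#' @param cloud a [point_cloud()] with more than `N` points.
#' @param N neighbor count per point (default 6).
#' @param f_out multiplier on the global mean distance (default 2).
#' @return The filtered [point_cloud()] (subset of the input, order kept).
#' @export
remove_outliers <- function(cloud, N = 6, f_out = 2) {
  stopifnot(inherits(cloud, "point_cloud"), N >= 1, f_out > 0)
  M <- nrow(cloud$points)
  if (M <= N) stop("cloud must have more than N points")
  kn <- knn_search(cloud$points, k = N)
  d_local <- rowMeans(kn$dist)
  d_m <- mean(d_local)
  subset_cloud(cloud, which(d_local <= d_m * f_out))
}

#' Bilateral point-cloud smoothing
#'
#' Each iteration has two parts. (1) Normal smoothing: normals are
#' re-estimated by PCA, then each is replaced by the angle-weighted average
#' of its neighbors' normals with weight `exp(-(theta/sigma_angle)^2)` and
#' renormalized; weights vanish across sharp angle gaps, so discontinuities
#' (leaf edges) are preserved. (2) Repositioning: each point moves along its
#' smoothed normal onto the bilaterally weighted local plane of its
#' neighbors (spatial Gaussian x normal-angle Gaussian weights over the
#' support radius), a locally-optimal-projection style update constrained to
#' the normal direction so tangential point spacing is untouched. Point count
#' never changes; points with degenerate neighborhoods pass through
#' unmodified.
#'
#' @param cloud a [point_cloud()].
#' @param iterations smoothing iterations (>= 1).
#' @param normal_k neighbor count for PCA normal estimation.
#' @param sigma_angle angular bandwidth in degrees for the normal-domain
#'   weights.
#' @param lop_radius support radius in metres for the repositioning step
#'   (defaults to 4x the median nearest-neighbor spacing when `NULL`).
#' @param viewpoint normal orientation viewpoint.
#' @return The smoothed [point_cloud()] with smoothed unit normals attached.
#' @export
bilateral_smooth <- function(cloud, iterations = 2, normal_k = 12,
                             sigma_angle = 30, lop_radius = NULL,
                             viewpoint = c(0, 0, 0)) {
  stopifnot(inherits(cloud, "point_cloud"), iterations >= 1)
  P <- cloud$points
  n <- nrow(P)
  if (n < normal_k + 1) return(cloud)
  if (is.null(lop_radius)) {
    nn1 <- knn_search(P, k = 1)
    lop_radius <- 4 * stats::median(nn1$dist[, 1])
  }
  sig_a <- sigma_angle * pi / 180
  sig_s <- lop_radius / 2
  nrm <- NULL
  for (it in seq_len(iterations)) {
    est <- cpp_pca_normals(P, as.integer(normal_k), as.numeric(viewpoint))
    nrm <- est$normals
    valid <- est$valid
    nb <- cpp_radius_search(P, P, lop_radius, TRUE)
    newP <- P
    newN <- nrm
    for (i in seq_len(n)) {
      if (!valid[i]) next
      j <- nb[[i]]
      j <- j[valid[j]]
      if (length(j) == 0) next
      ni <- nrm[i, ]
      # (1) angle-weighted normal average (self weight 1)
      cosang <- pmin(1, pmax(-1, as.numeric(nrm[j, , drop = FALSE] %*% ni)))
      th <- acos(cosang)
      wn <- exp(-(th / sig_a)^2)
      avg <- ni + colSums(nrm[j, , drop = FALSE] * wn)
      l <- sqrt(sum(avg^2))
      if (l < 1e-12) next
      ns <- avg / l
      newN[i, ] <- ns
      # (2) projection onto the bilateral weighted plane, along ns
      d <- P[j, , drop = FALSE] - matrix(P[i, ], length(j), 3, byrow = TRUE)
      r2 <- rowSums(d^2)
      w <- exp(-r2 / sig_s^2) * wn
      sw <- sum(w)
      if (sw < 1e-12) next
      h <- sum(w * as.numeric(d %*% ns)) / sw
      newP[i, ] <- P[i, ] + h * ns
    }
    P <- newP
    nrm <- newN
  }
  point_cloud(P, normals = nrm, colors = cloud$colors)
}
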