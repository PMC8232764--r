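# Implicit-surface conversion and fusion: sparse truncated signed-distance
# volumes, weighted-average fusion, and marching-cubes extraction.

# order-preserving scalar key for voxel indices (fits in a double exactly)
.tsdf_key <- function(ijk) {
  (ijk[, 1] + 65536) * 131072^2 + (ijk[, 2] + 65536) * 131072 +
    (ijk[, 3] + 65536)
}

#' Convert a triangle mesh to a sparse TSDF volume
#'
#' Every voxel whose centre lies within the truncation distance `t` of the
#' mesh gets the signed distance to the nearest triangle, normalized by `t`
#' and clamped to `[-1, 1]`, plus a linearly tapering confidence weight
#' `1 - |d|/t`. Only near-surface voxels are materialized (sparse storage).
#' The sign convention is configurable: `"viewpoint"` orients triangle
#' normals toward the camera (positive = empty space in front of the
#' surface; well-defined for single-view captures), `"winding"` trusts the
#' mesh winding (outward-positive for consistently wound closed meshes).
#'
#' @param mesh a [surface_mesh()].
#' @param voxel_size voxel edge length in metres.
#' @param truncation truncation distance `t` in metres (>= `voxel_size`).
#' @param origin grid origin (3-vector); volumes fused together must share
#'   it. Defaults to the zero origin so independently built volumes align.
#' @param sign `"viewpoint"` or `"winding"`.
#' @param viewpoint camera position for the viewpoint sign convention.
#' @param rim_band for open sheets: voxels whose closest feature is a mesh
#'   boundary edge and that lie laterally beyond the rim by more than this
#'   many voxels have no well-defined surface crossing; their weight is
#'   scaled by `rim_weight` (0 excludes them from polygonization), which
#'   stops the extracted surface from growing sideways flanges at sheet
#'   rims.
#' @param rim_weight weight factor for beyond-rim voxels.
#' @return An object of class `tsdf_volume` with fields `ijk`, `value`,
#'   `weight`, `voxel_size`, `truncation`, `origin`.
#' @export
mesh_to_tsdf <- function(mesh, voxel_size, truncation = 5 * voxel_size,
                         origin = c(0, 0, 0), sign = c("viewpoint", "winding"),
                         viewpoint = c(0, 0, 0), rim_band = 1, rim_weight = 0) {
  stopifnot(inherits(mesh, "surface_mesh"), voxel_size > 0,
            truncation >= voxel_size)
  sign <- match.arg(sign)
  if (nrow(mesh$triangles) == 0) {
    return(structure(list(ijk = matrix(0L, 0, 3), value = numeric(0),
                          weight = numeric(0), voxel_size = voxel_size,
                          truncation = truncation, origin = origin),
                     class = "tsdf_volume"))
  }
  # per-triangle flags marking which of its edges lie on the mesh boundary
  Tr <- mesh$triangles
  ecount <- mesh_edges(mesh)
  bkey <- .edge_key(ecount$edges[, 1], ecount$edges[, 2])[ecount$count == 1]
  bnd_flags <- matrix(0L, nrow(Tr), 3)
  if (length(bkey) > 0) {
    for (s2 in 1:3) {
      k <- .edge_key(Tr[, s2], Tr[, s2 %% 3 + 1])
      bnd_flags[, s2] <- as.integer(k %in% bkey)
    }
  }
  res <- cpp_mesh_tsdf(mesh$vertices, mesh$triangles, voxel_size, truncation,
                       as.numeric(origin), if (sign == "viewpoint") 0L else 1L,
                       as.numeric(viewpoint), bnd_flags,
                       rim_band * voxel_size, rim_weight)
  structure(list(ijk = res$ijk, value = res$value, weight = res$weight,
                 voxel_size = voxel_size, truncation = truncation,
                 origin = as.numeric(origin)),
            class = "tsdf_volume")
}

#' Fuse two TSDF volumes by weighted averaging
#'
#' Voxels present in both volumes get the weighted average
#' `(w1 v1 + w2 v2) / (w1 + w2)` and summed weight (capped at `w_max`);
#' voxels present in only one volume pass through unchanged — this is how
#' newly visible plant regions accumulate into the model across frames.
#'
#' @param model_vol,input_vol [mesh_to_tsdf()] volumes on the same grid
#'   (equal voxel size, truncation and origin).
#' @param w_max weight cap (applied after summation).
#' @return The fused `tsdf_volume`.
#' @export
tsdf_fuse <- function(model_vol, input_vol, w_max = 64) {
  stopifnot(inherits(model_vol, "tsdf_volume"), inherits(input_vol, "tsdf_volume"))
  if (model_vol$voxel_size != input_vol$voxel_size ||
      model_vol$truncation != input_vol$truncation ||
      any(model_vol$origin != input_vol$origin))
    stop("volumes must share voxel size, truncation and origin")
  k1 <- .tsdf_key(model_vol$ijk)
  k2 <- .tsdf_key(input_vol$ijk)
  m <- match(k2, k1)
  shared2 <- which(!is.na(m))
  shared1 <- m[shared2]
  only2 <- which(is.na(m))
  v <- c(model_vol$value, input_vol$value[only2])
  w <- c(model_vol$weight, input_vol$weight[only2])
  ijk <- rbind(model_vol$ijk, input_vol$ijk[only2, , drop = FALSE])
  if (length(shared1) > 0) {
    w1 <- model_vol$weight[shared1]
    w2 <- input_vol$weight[shared2]
    tot <- w1 + w2
    pos <- tot > 0
    v[shared1[pos]] <- (w1[pos] * model_vol$value[shared1[pos]] +
                          w2[pos] * input_vol$value[shared2[pos]]) / tot[pos]
    w[shared1] <- tot
  }
  structure(list(ijk = ijk, value = v, weight = pmin(w, w_max),
                 voxel_size = model_vol$voxel_size,
                 truncation = model_vol$truncation,
                 origin = model_vol$origin),
            class = "tsdf_volume")
}

#' Extract the zero isosurface of a TSDF volume by marching cubes
#'
#' Cubes are spanned by 8 adjacent voxel centres; only cubes whose corners
#' are all materialized with positive weight are polygonized, with linear
#' interpolation of crossing positions along cube edges and vertex welding
#' across cube faces.
#'
#' @param vol a `tsdf_volume`.
#' @param min_weight cubes touching any corner with weight below this floor
#'   are not polygonized; a small positive floor suppresses sliver fins in
#'   the low-confidence fringe of fused volumes.
#' @return A [surface_mesh()]; empty when the volume contains no sign change.
#' @export
extract_mesh <- function(vol, min_weight = 0) {
  stopifnot(inherits(vol, "tsdf_volume"))
  if (nrow(vol$ijk) == 0 || all(vol$value >= 0) || all(vol$value <= 0))
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  wt <- vol$weight
  if (min_weight > 0) wt <- ifelse(wt >= min_weight, wt, 0)
  res <- cpp_marching_cubes(vol$ijk, vol$value, wt, vol$voxel_size,
                            as.numeric(vol$origin))
  if (nrow(res$triangles) == 0)
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  surface_mesh(res$vertices, res$triangles)
}

#' @export
print.tsdf_volume <- function(x, ...) {
  cat(sprintf("<tsdf_volume: %d voxels @ %.3g m, t = %.3g m>\n",
              nrow(x$ijk), x$voxel_size, x$truncation))
  invisible(x)
}
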