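# SHOT keypoint description on deformation-graph vertices and bidirectional
# (mutual nearest neighbor) matching in descriptor space.

#' SHOT descriptor at a deformation-graph vertex
#'
#' Signature of Histograms of Orientations: a repeatable local reference
#' frame (LRF) is built from the eigen-decomposition of the radius-weighted
#' covariance of the support points (weights `radius - distance`), with
#' eigenvector signs disambiguated toward the support majority. The
#' spherical support is then partitioned into 2 radial x 2 elevation x
#' 8 azimuth = 32 spatial bins; each holds an 11-bin histogram of the cosine
#' of the angle between each support vertex's normal and the keypoint
#' normal, accumulated with linear interpolation along the cosine axis. The
#' final 352-vector is L2-normalized.
#'
#' @param graph a [build_deformation_graph()] result (graph vertices carry
#'   normals).
#' @param vertex keypoint index into the graph mesh vertices.
#' @param radius support radius in metres.
#' @return An object of class `shot_descriptor` with fields `values`
#'   (length 352), `radius`, and `lrf` (orthonormal 3 x 3, rows = axes).
#'   Empty support yields an all-zero descriptor flagged `empty`.
#' @export
shot_descriptor <- function(graph, vertex, radius) {
  stopifnot(inherits(graph, "deformation_graph"))
  P <- graph$graph_mesh$vertices
  N <- graph$normals
  .shot_one(P, N, vertex, radius)
}

.shot_one <- function(P, N, vertex, radius, support_idx = NULL) {
  p <- P[vertex, ]
  if (is.null(support_idx)) {
    d2 <- rowSums(sweep(P, 2, p)^2)
    support_idx <- which(d2 <= radius^2 & d2 > 0)
  }
  zero <- list(values = numeric(352), radius = radius, lrf = diag(3),
               empty = TRUE)
  class(zero) <- "shot_descriptor"
  if (length(support_idx) < 1) return(zero)
  Q <- P[support_idx, , drop = FALSE]
  D <- sweep(Q, 2, p)
  dist <- sqrt(rowSums(D^2))
  w <- radius - dist
  # weighted covariance for the LRF
  C <- crossprod(D * sqrt(w / sum(w)))
  eg <- eigen(C, symmetric = TRUE)  # eigenvalues descending
  x_ax <- eg$vectors[, 1]; z_ax <- eg$vectors[, 3]
  # sign disambiguation toward the support majority, using continuous
  # moments (stable under rigid motion even when positive/negative counts
  # tie): x faces the bulk of the support offsets, z the mean support normal
  if (sum(D %*% x_ax) < 0) x_ax <- -x_ax
  mean_n <- colSums(N[support_idx, , drop = FALSE])
  zdot <- sum(z_ax * mean_n)
  if (zdot < 0 || (zdot == 0 && sum(D %*% z_ax) < 0)) z_ax <- -z_ax
  y_ax <- c(z_ax[2] * x_ax[3] - z_ax[3] * x_ax[2],
            z_ax[3] * x_ax[1] - z_ax[1] * x_ax[3],
            z_ax[1] * x_ax[2] - z_ax[2] * x_ax[1])
  lrf <- rbind(x_ax, y_ax, z_ax)
  # local coordinates and spatial bins
  Lc <- D %*% t(lrf)
  rad_bin <- ifelse(dist > radius / 2, 1L, 0L)          # 2 radial shells
  elev_bin <- ifelse(Lc[, 3] >= 0, 1L, 0L)              # 2 elevation halves
  azim <- atan2(Lc[, 2], Lc[, 1])                       # [-pi, pi]
  azim_bin <- pmin(7L, floor((azim + pi) / (2 * pi) * 8))
  spatial <- rad_bin * 16L + elev_bin * 8L + azim_bin   # 0..31
  # cosine histogram with linear interpolation
  np <- N[vertex, ]
  cosang <- pmax(-1, pmin(1, as.numeric(N[support_idx, , drop = FALSE] %*% np)))
  tpos <- (cosang + 1) / 2 * 11 - 0.5                   # continuous bin coord
  b0 <- floor(tpos)
  fr <- tpos - b0
  vals <- numeric(352)
  for (s in seq_along(support_idx)) {
    base <- spatial[s] * 11L
    lo <- b0[s]; f <- fr[s]
    if (lo >= 0 && lo < 11) vals[base + lo + 1] <- vals[base + lo + 1] + (1 - f)
    hi <- lo + 1
    if (hi >= 0 && hi < 11) vals[base + hi + 1] <- vals[base + hi + 1] + f
  }
  nv <- sqrt(sum(vals^2))
  if (nv > 0) vals <- vals / nv
  structure(list(values = vals, radius = radius, lrf = lrf, empty = FALSE),
            class = "shot_descriptor")
}

#' SHOT descriptors for every keypoint of a deformation graph
#'
#' @param graph a [build_deformation_graph()] result.
#' @param radius support radius in metres; defaults to 3x the graph's target
#'   edge length.
#' @return A list with `descriptors` (n x 352 matrix) and `empty` (logical:
#'   keypoints with empty support, excluded from matching).
#' @export
shot_descriptors <- function(graph, radius = NULL) {
  stopifnot(inherits(graph, "deformation_graph"))
  if (is.null(radius)) radius <- 3 * graph$target_edge_length
  P <- graph$graph_mesh$vertices
  N <- graph$normals
  n <- nrow(P)
  nb <- cpp_radius_search(P, P, radius, TRUE)
  vals <- matrix(0, n, 352)
  empty <- logical(n)
  for (i in seq_len(n)) {
    d <- .shot_one(P, N, i, radius, support_idx = nb[[i]])
    vals[i, ] <- d$values
    empty[i] <- d$empty
  }
  list(descriptors = vals, empty = empty, radius = radius)
}

#' Bidirectional keypoint matching in descriptor space
#'
#' Nearest neighbors are searched in both directions (model to input and
#' input to model); a pair `(i, j)` is retained iff `j` is the nearest
#' neighbor of `i` among the input descriptors AND `i` is the nearest
#' neighbor of `j` among the model descriptors (mutual nearest neighbors).
#' Ties are broken toward the lower index. Pairs with descriptor distance
#' above `max_distance` are dropped.
#'
#' @param model_desc,input_desc descriptor matrices (rows = keypoints), as
#'   produced by [shot_descriptors()], or the result lists themselves (empty
#'   descriptors are then excluded).
#' @param max_distance maximum Euclidean descriptor distance for a valid
#'   pair (descriptors are unit length, so distances lie in `[0, 2]`).
#' @return A data frame with columns `model_keypoint`, `input_keypoint`,
#'   `descriptor_distance`; zero rows when no mutual pair survives.
#' @export
match_bidirectional <- function(model_desc, input_desc, max_distance = 0.25) {
  mask_m <- NULL; mask_i <- NULL
  if (is.list(model_desc) && !is.null(model_desc$descriptors)) {
    mask_m <- !model_desc$empty
    model_desc <- model_desc$descriptors
  }
  if (is.list(input_desc) && !is.null(input_desc$descriptors)) {
    mask_i <- !input_desc$empty
    input_desc <- input_desc$descriptors
  }
  if (is.null(mask_m)) mask_m <- rep(TRUE, nrow(model_desc))
  if (is.null(mask_i)) mask_i <- rep(TRUE, nrow(input_desc))
  im <- which(mask_m); ii <- which(mask_i)
  if (length(im) == 0 || length(ii) == 0)
    return(data.frame(model_keypoint = integer(0), input_keypoint = integer(0),
                      descriptor_distance = numeric(0)))
  A <- model_desc[im, , drop = FALSE]
  B <- input_desc[ii, , drop = FALSE]
  # squared Euclidean distances via the Gram expansion
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  nn_ab <- max.col(-d2, ties.method = "first")       # for each model row
  nn_ba <- max.col(-t(d2), ties.method = "first")    # for each input row
  mutual <- which(nn_ba[nn_ab] == seq_along(im))
  if (length(mutual) == 0)
    return(data.frame(model_keypoint = integer(0), input_keypoint = integer(0),
                      descriptor_distance = numeric(0)))
  dd <- sqrt(d2[cbind(mutual, nn_ab[mutual])])
  keep <- dd <= max_distance
  data.frame(model_keypoint = im[mutual[keep]],
             input_keypoint = ii[nn_ab[mutual[keep]]],
             descriptor_distance = dd[keep])
}
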