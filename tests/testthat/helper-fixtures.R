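# Shared fixtures and independent brute-force oracles. Everything is built
# in code at test time under fixed seeds.

# near-uniform points on a sphere (Fibonacci lattice)
fib_sphere <- function(n, r = 0.1, centre = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  sweep(cbind(r * sin(phi) * cos(th), r * sin(phi) * sin(th), r * cos(phi)),
        2, centre, "+")
}

# m x n planar grid, interior points jittered in-plane
jittered_grid <- function(m, n, spacing = 0.01, jitter = 0.1, z = 0.4,
                          seed = 5) {
  set.seed(seed)
  gx <- rep(0:(m - 1), n)
  gy <- rep(0:(n - 1), each = m)
  interior <- gx > 0 & gx < m - 1 & gy > 0 & gy < n - 1
  jx <- jy <- numeric(m * n)
  jx[interior] <- runif(sum(interior), -jitter, jitter)
  jy[interior] <- runif(sum(interior), -jitter, jitter)
  cbind((gx + jx) * spacing, (gy + jy) * spacing, z)
}

# regular icosahedron vertices/faces
icosahedron <- function(r = 1) {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(rowSums(v^2)) * r
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  surface_mesh(v, f)
}

# brute-force k nearest neighbors (O(n^2))
bf_knn <- function(P, k) {
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  idx <- t(apply(D, 1, order))[, seq_len(k), drop = FALSE]
  d <- t(apply(D, 1, function(r) sort(r)[seq_len(k)]))
  list(idx = idx, dist = d)
}

# brute-force mean neighbor distance (Eq.-style double sum)
bf_mean_neighbor_distance <- function(P, N) {
  mean(bf_knn(P, N)$dist)
}

# brute-force smallest-eigenvalue eigenvector of a k-neighborhood covariance
bf_pca_normal <- function(P, i, k) {
  D <- sqrt(colSums((t(P) - P[i, ])^2))
  nb <- order(D)[2:(k + 1)]
  X <- P[c(i, nb), , drop = FALSE]
  C <- stats::cov(X) * (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  eg$vectors[, 3]
}

# brute-force voxel keys anchored at the cloud minimum
bf_voxel_keys <- function(P, res) {
  o <- apply(P, 2, min)
  idx <- floor(sweep(P, 2, o) / res)
  paste(idx[, 1], idx[, 2], idx[, 3])
}

# rigid transform helper
rigid_transform <- function(P, angle = 0.4, axis = c(0, 0, 1),
                            t = c(0.1, -0.05, 0.2)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  list(P = t(R %*% t(P)) + matrix(t, nrow(P), 3, byrow = TRUE), R = R, t = t)
}

# independent small-scale classic ARAP (alpha = 0) for cross-checking:
# dense algebra, Jacobi local step, direct solve
bf_arap <- function(mesh, cidx, cpos, iters = 200) {
  V <- mesh$vertices
  n <- nrow(V)
  # cotangent weights recomputed independently via explicit angles
  W <- matrix(0, n, n)
  for (t in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[t, ]
    for (s in 1:3) {
      a <- tri[s]; b <- tri[s %% 3 + 1]; cc <- tri[(s + 1) %% 3 + 1]
      u <- V[a, ] - V[cc, ]; w <- V[b, ] - V[cc, ]
      cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
      ang <- acos(pmin(1, pmax(-1, cosang)))
      W[a, b] <- W[a, b] + 1 / tan(ang)
      W[b, a] <- W[a, b]
    }
  }
  W[W < 1e-6 & W != 0] <- 1e-6
  Lp <- diag(rowSums(W)) - W
  free <- setdiff(seq_len(n), cidx)
  Vp <- V
  Vp[cidx, ] <- cpos
  R <- array(rep(diag(3), n), c(3, 3, n))
  for (it in seq_len(iters)) {
    for (v in seq_len(n)) {
      js <- which(W[v, ] > 0)
      e <- t(V[v, ] - t(V[js, , drop = FALSE]))
      ep <- t(Vp[v, ] - t(Vp[js, , drop = FALSE]))
      M <- crossprod(ep * W[v, js], e)
      sv <- svd(M)
      Rv <- sv$u %*% t(sv$v)
      if (det(Rv) < 0) {
        u <- sv$u; u[, 3] <- -u[, 3]; Rv <- u %*% t(sv$v)
      }
      R[, , v] <- Rv
    }
    rhs <- matrix(0, n, 3)
    for (v in seq_len(n)) {
      js <- which(W[v, ] > 0)
      for (j in js) {
        rhs[v, ] <- rhs[v, ] + W[v, j] / 2 *
          as.numeric((R[, , v] + R[, , j]) %*% (V[v, ] - V[j, ]))
      }
    }
    Vp[free, ] <- solve(Lp[free, free],
                        rhs[free, , drop = FALSE] -
                          Lp[free, cidx, drop = FALSE] %*% cpos)
    Vp[cidx, ] <- cpos
  }
  Vp
}

# render a small synthetic frame sequence for pipeline tests
render_sequence <- function(n_frames, width = 160, height = 120,
                            amplitude = 8, seed = 42L, noise = 0.002,
                            clutter = TRUE) {
  # pixel footprint at the plant ~ 0.4 / fx; keep it near the voxel size
  K <- camera_intrinsics(width, height, fx = 0.6 * width, fy = 0.6 * width)
  plant <- make_plant(plant_params(seed = seed))
  pose <- default_camera_pose()
  bg <- if (clutter) make_clutter(seed) else NULL
  frames <- lapply(seq_len(n_frames), function(fi) {
    t <- if (n_frames > 1) (fi - 1) / (n_frames - 1) else 0
    pm <- animate_plant(plant, sway_params(amplitude), t)
    render_depth(pm, K, pose, background = bg, noise_sigma = noise,
                 seed = seed + fi, frame_index = fi - 1L)
  })
  list(frames = frames, plant = plant, pose = pose, intrinsics = K)
}

# height extent of a reconstructed model along the world up axis (camera y
# points down, so up = -y); uses every triangle-referenced vertex
model_height <- function(mesh) {
  used <- unique(as.integer(mesh$triangles))
  diff(range(-mesh$vertices[used, 2]))
}
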