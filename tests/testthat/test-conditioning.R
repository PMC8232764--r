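test_that("octree downsampling matches the brute-force voxel hashing oracle", {
  set.seed(41)
  P <- matrix(runif(3000), 1000, 3)
  cl <- point_cloud(P)
  for (res in c(0.05, 0.11, 0.23)) {
    dn <- octree_downsample(cl, res, "centroid_of_points")
    keys <- bf_voxel_keys(P, res)
    expect_equal(nrow(dn$points), length(unique(keys)))
    # each representative is the centroid of its voxel's members
    o <- apply(P, 2, min)
    vox_of_out <- paste(floor((dn$points[, 1] - o[1]) / res),
                        floor((dn$points[, 2] - o[2]) / res),
                        floor((dn$points[, 3] - o[3]) / res))
    # centroids may sit on voxel boundaries; recompute directly instead
    cent <- rowsum(P, keys) / as.integer(table(keys))
    expect_equal(sort(dn$points[, 1]), sort(as.numeric(cent[, 1])),
                 tolerance = 1e-12)
  }
})

test_that("octree consolidation modes behave as specified", {
  cl <- point_cloud(rbind(c(0, 0, 0), c(0.001, 0, 0)))
  out <- octree_downsample(cl, 0.005, "centroid_of_points")
  expect_equal(out$points, matrix(c(0.0005, 0, 0), 1), ignore_attr = TRUE)

  # resolution below the minimum spacing: identity count
  set.seed(42)
  P <- matrix(runif(150, 0, 1), 50, 3)
  cl2 <- point_cloud(P)
  expect_equal(nrow(octree_downsample(cl2, 1e-5)$points), 50)

  # first/last return actual input members, order-tie-broken by insertion
  fp <- octree_downsample(cl2, 0.4, "first_point")
  lp <- octree_downsample(cl2, 0.4, "last_point")
  expect_true(all(fp$points[, 1] %in% P[, 1]))
  expect_true(all(lp$points[, 1] %in% P[, 1]))
  keys <- bf_voxel_keys(P, 0.4)
  first_idx <- which(!duplicated(keys))
  expect_equal(fp$points, P[first_idx, , drop = FALSE], ignore_attr = TRUE)
  last_idx <- sort(vapply(unique(keys), function(k) max(which(keys == k)), 1L))
  expect_equal(sort(lp$points[, 1]), sort(P[last_idx, 1]))

  # centroid_of_voxel representatives lie at geometric voxel centres
  cv <- octree_downsample(cl2, 0.4, "centroid_of_voxel")
  o <- apply(P, 2, min)
  rel <- (cv$points[, 1] - o[1]) / 0.4
  expect_lt(max(abs(rel - floor(rel) - 0.5)), 1e-9)

  # empty cloud passes through
  expect_equal(nrow(octree_downsample(point_cloud(matrix(0, 0, 3)), 0.1)$points), 0)
})

test_that("mean neighbor distance equals the exhaustive double sum", {
  # collinear unit spacing, N = 1
  expect_equal(mean_neighbor_distance(point_cloud(cbind(0:9, 0, 0)), N = 1), 1)
  # coincident points
  expect_equal(mean_neighbor_distance(point_cloud(rbind(c(1, 2, 3), c(1, 2, 3))),
                                      N = 1), 0)
  # random clouds vs O(M^2) oracle
  set.seed(43)
  for (rep in 1:5) {
    M <- sample(10:30, 1)
    N <- sample(1:5, 1)
    P <- matrix(rnorm(M * 3), M, 3)
    expect_equal(mean_neighbor_distance(point_cloud(P), N),
                 bf_mean_neighbor_distance(P, N), tolerance = 1e-12)
  }
  expect_error(mean_neighbor_distance(point_cloud(cbind(1:3, 0, 0)), N = 5),
               "more than N")
})

test_that("outlier removal drops exactly the isolated point and keeps grids", {
  g <- as.matrix(expand.grid(x = seq(0, 0.09, 0.01), y = seq(0, 0.09, 0.01)))
  grid_pts <- cbind(g, 0)
  cl <- point_cloud(rbind(grid_pts, c(1, 1, 1)))
  out <- remove_outliers(cl, N = 4, f_out = 2)
  expect_equal(nrow(out$points), 100)
  expect_false(any(out$points[, 1] == 1 & out$points[, 2] == 1))
  # uniform grid alone: nothing removed
  out2 <- remove_outliers(point_cloud(grid_pts), N = 4, f_out = 2)
  expect_equal(nrow(out2$points), 100)
  # enormous multiplier: identity
  out3 <- remove_outliers(cl, N = 4, f_out = 1e9)
  expect_equal(nrow(out3$points), 101)
})

test_that("outlier removal is single-pass on the input cloud and order-independent", {
  set.seed(44)
  P <- rbind(matrix(rnorm(60 * 3, sd = 0.01), 60, 3),
             matrix(rnorm(5 * 3, sd = 0.5) + 2, 5, 3))
  cl <- point_cloud(P)
  out <- remove_outliers(cl, N = 5, f_out = 2)
  # oracle: d_local and d_m from the brute-force kNN on the INPUT cloud
  kn <- bf_knn(P, 5)
  d_local <- rowMeans(kn$dist)
  keep <- d_local <= mean(d_local) * 2
  expect_equal(out$points, P[keep, , drop = FALSE], ignore_attr = TRUE)
  # permuted input gives the same surviving set
  perm <- sample(nrow(P))
  out_p <- remove_outliers(point_cloud(P[perm, ]), N = 5, f_out = 2)
  expect_equal(sort(out_p$points[, 1]), sort(out$points[, 1]))
})

test_that("bilateral smoothing fixes planes, denoises, and keeps counts and edges", {
  set.seed(45)
  # exactly planar cloud is a fixed point
  flat <- point_cloud(cbind(runif(250, 0, 0.1), runif(250, 0, 0.1), 0.5))
  sm <- bilateral_smooth(flat, iterations = 2, normal_k = 10)
  expect_lt(max(abs(sm$points - flat$points)), 1e-9)
  expect_equal(nrow(sm$points), 250)
  # smoothed normals are unit length
  expect_lt(max(abs(sqrt(rowSums(sm$normals^2)) - 1)), 1e-9)

  # noisy plane: RMS distance to the true plane strictly decreases per iteration
  z <- rnorm(400, 0, 0.002)
  noisy <- point_cloud(cbind(runif(400, 0, 0.1), runif(400, 0, 0.1), 0.5 + z))
  rms <- sqrt(mean((noisy$points[, 3] - 0.5)^2))
  for (it in 1:3) {
    sm_it <- bilateral_smooth(noisy, iterations = it, normal_k = 12)
    rms_it <- sqrt(mean((sm_it$points[, 3] - 0.5)^2))
    expect_lt(rms_it, rms)
    rms <- rms_it
  }

  # two perpendicular planes: dihedral angle preserved within 5 degrees
  set.seed(46)
  n2 <- 300
  pa <- cbind(runif(n2, 0.002, 0.1), runif(n2, 0, 0.1), 0.5)       # z plane
  pb <- cbind(0, runif(n2, 0, 0.1), 0.5 - runif(n2, 0.002, 0.1))   # x plane
  both <- point_cloud(rbind(pa, pb))
  smb <- bilateral_smooth(both, iterations = 3, normal_k = 10,
                          lop_radius = 0.02)
  va <- smb$points[seq_len(n2), ]
  vb <- smb$points[n2 + seq_len(n2), ]
  fit_norm <- function(X) {
    eg <- eigen(stats::cov(X), symmetric = TRUE)
    eg$vectors[, 3]
  }
  ang <- acos(min(1, abs(sum(fit_norm(va) * fit_norm(vb)))))
  expect_lt(abs(ang * 180 / pi - 90), 5)
})
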