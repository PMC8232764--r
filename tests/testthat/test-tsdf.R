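test_that("mesh-to-TSDF on-surface and truncation-boundary voxels behave", {
  # unit square pair of triangles at z = 0.5, voxel centres on the plane
  sq <- surface_mesh(rbind(c(-0.5, -0.5, 0.5), c(0.5, -0.5, 0.5),
                           c(0.5, 0.5, 0.5), c(-0.5, 0.5, 0.5)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  # voxel size 0.1 with origin shifted so centres land exactly on z = 0.5
  vol <- mesh_to_tsdf(sq, 0.1, 0.3, origin = c(0, 0, 0.45))
  zc <- (vol$ijk[, 3] + 0.5) * 0.1 + 0.45
  on_surface <- abs(zc - 0.5) < 1e-9 &
    abs((vol$ijk[, 1] + 0.5) * 0.1) < 0.4 & abs((vol$ijk[, 2] + 0.5) * 0.1) < 0.4
  expect_true(any(on_surface))
  expect_lt(max(abs(vol$value[on_surface])), 1e-12)
  expect_equal(vol$weight[on_surface], rep(1, sum(on_surface)))
  # truncation boundary: |value| = 1 has weight 0
  far <- abs(abs(vol$value) - 1) < 1e-9
  expect_true(all(vol$weight[far] < 1e-9))
  # all values normalized
  expect_true(all(abs(vol$value) <= 1))
})

test_that("sphere TSDF agrees with the analytic signed distance", {
  ms <- orient_mesh_outward(
    advancing_front_reconstruct(point_cloud(fib_sphere(1000, r = 0.05))))
  voxel <- 0.005; trunc <- 0.025
  vol <- mesh_to_tsdf(ms, voxel, trunc, sign = "winding")
  centre_d <- sqrt(rowSums(((vol$ijk + 0.5) * voxel)^2))
  analytic <- pmax(-1, pmin(1, (centre_d - 0.05) / trunc))
  expect_lt(max(abs(vol$value - analytic)), 1.5 * voxel / trunc)
})

test_that("weighted-average fusion arithmetic and union semantics", {
  mk_vol <- function(ijk, v, w) {
    structure(list(ijk = ijk, value = v, weight = w, voxel_size = 0.01,
                   truncation = 0.05, origin = c(0, 0, 0)),
              class = "tsdf_volume")
  }
  a <- mk_vol(rbind(c(0L, 0L, 0L), c(1L, 0L, 0L)), c(1, 0.5), c(1, 2))
  b <- mk_vol(rbind(c(0L, 0L, 0L), c(2L, 0L, 0L)), c(0, -0.5), c(3, 1))
  f <- tsdf_fuse(a, b)
  # shared voxel: (1*1 + 0*3) / 4 = 0.25
  k <- which(f$ijk[, 1] == 0)
  expect_equal(f$value[k], 0.25)
  expect_equal(f$weight[k], 4)
  # pass-through voxels unchanged
  expect_equal(f$value[f$ijk[, 1] == 1], 0.5)
  expect_equal(f$value[f$ijk[, 1] == 2], -0.5)
  # union size
  expect_equal(nrow(f$ijk), 3)
  # grid mismatch rejected
  bad <- mk_vol(rbind(c(0L, 0L, 0L)), 0, 1); bad$voxel_size <- 0.02
  expect_error(tsdf_fuse(a, bad), "share")
})

test_that("fusion is commutative, associative in values, and identity on zero weight", {
  set.seed(71)
  ms <- advancing_front_reconstruct(point_cloud(fib_sphere(300, r = 0.04)))
  v1 <- mesh_to_tsdf(ms, 0.005, 0.02)
  ms2 <- advancing_front_reconstruct(
    point_cloud(fib_sphere(300, r = 0.04, centre = c(0.02, 0, 0))))
  v2 <- mesh_to_tsdf(ms2, 0.005, 0.02)
  ms3 <- advancing_front_reconstruct(
    point_cloud(fib_sphere(300, r = 0.04, centre = c(0, 0.02, 0))))
  v3 <- mesh_to_tsdf(ms3, 0.005, 0.02)
  key <- function(v) paste(v$ijk[, 1], v$ijk[, 2], v$ijk[, 3])
  # commutativity
  ab <- tsdf_fuse(v1, v2); ba <- tsdf_fuse(v2, v1)
  m <- match(key(ab), key(ba))
  expect_false(anyNA(m))
  expect_lt(max(abs(ab$value - ba$value[m])), 1e-12)
  # associativity in values (weights stay far below the cap here)
  abc <- tsdf_fuse(tsdf_fuse(v1, v2), v3)
  acb <- tsdf_fuse(v1, tsdf_fuse(v2, v3))
  m2 <- match(key(abc), key(acb))
  expect_lt(max(abs(abc$value - acb$value[m2])), 1e-12)
  # fuse(V, V): identical values, doubled weights
  vv <- tsdf_fuse(v1, v1)
  m3 <- match(key(vv), key(v1))
  expect_lt(max(abs(vv$value - v1$value[m3])), 1e-12)
  expect_equal(vv$weight, pmin(2 * v1$weight[m3], 64))
  # all-zero-weight volume is the identity on values
  vz <- v1; vz$weight <- numeric(length(vz$weight)) ; vz$weight[] <- 0
  vi <- tsdf_fuse(v1, vz)
  m4 <- match(key(v1), key(vi))
  expect_equal(vi$value[m4], v1$value)
  expect_equal(vi$weight[m4], v1$weight)
  # union voxel count is exact
  expect_equal(nrow(ab$ijk), length(union(key(v1), key(v2))))
})

test_that("marching cubes cuts a single corner with one triangle at edge midpoints", {
  # 2x2x2 block of voxels with one negative corner
  ijk <- as.matrix(expand.grid(i = 0:1, j = 0:1, k = 0:1))
  vals <- rep(0.5, 8)
  vals[ijk[, 1] == 0 & ijk[, 2] == 0 & ijk[, 3] == 0] <- -0.5
  vol <- structure(list(ijk = ijk, value = vals, weight = rep(1, 8),
                        voxel_size = 1, truncation = 1, origin = c(0, 0, 0)),
                   class = "tsdf_volume")
  ms <- extract_mesh(vol)
  expect_equal(nrow(ms$triangles), 1)
  # crossings at midpoints of the three edges leaving the negative corner
  expected <- rbind(c(1, 0.5, 0.5), c(0.5, 1, 0.5), c(0.5, 0.5, 1))
  got <- ms$vertices[order(ms$vertices[, 1]), ]
  exp_s <- expected[order(expected[, 1]), ]
  expect_equal(got, exp_s, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sphere round trip through TSDF + marching cubes keeps radius and topology", {
  ms <- orient_mesh_outward(
    advancing_front_reconstruct(point_cloud(fib_sphere(1500, r = 0.05))))
  vol <- mesh_to_tsdf(ms, 0.005, 0.025, sign = "winding")
  mx <- extract_mesh(vol)
  expect_equal(euler_characteristic(mx), 2L)
  r <- sqrt(rowSums(mx$vertices^2))
  expect_lt(max(abs(r - 0.05)), 0.005)  # within one voxel
})

test_that("fusing overlapping patches closes the gap into one component", {
  # two overlapping planar patches slightly offset in z
  g1 <- jittered_grid(14, 8, spacing = 0.01, jitter = 0, z = 0.5)
  g2 <- jittered_grid(14, 8, spacing = 0.01, jitter = 0, z = 0.503)
  g2[, 1] <- g2[, 1] + 0.10  # overlap of ~3 columns
  m1 <- advancing_front_reconstruct(point_cloud(g1))
  m2 <- advancing_front_reconstruct(point_cloud(g2))
  v1 <- mesh_to_tsdf(m1, 0.005, 0.02)
  v2 <- mesh_to_tsdf(m2, 0.005, 0.02)
  fused <- tsdf_fuse(v1, v2)
  mx <- extract_mesh(fused)
  comp <- mesh_components(mx)
  used <- unique(as.integer(mx$triangles))
  expect_equal(length(unique(comp[used])), 1L)
  # and the union spans both patches
  expect_gt(diff(range(mx$vertices[, 1])), 0.2)
})

test_that("a volume without sign change extracts an empty mesh", {
  ijk <- as.matrix(expand.grid(i = 0:2, j = 0:2, k = 0:2))
  vol <- structure(list(ijk = ijk, value = rep(0.4, nrow(ijk)),
                        weight = rep(1, nrow(ijk)), voxel_size = 1,
                        truncation = 1, origin = c(0, 0, 0)),
                   class = "tsdf_volume")
  expect_equal(nrow(extract_mesh(vol)$triangles), 0)
})
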