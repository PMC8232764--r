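test_that("depth back-projection follows the pinhole model", {
  K <- camera_intrinsics(640, 480, fx = 385, fy = 385, cx = 319.5, cy = 239.5)
  # fully valid frame: one point per pixel
  fr <- depth_frame(matrix(500, 480, 640), K)
  pc <- depth_to_points(fr)
  expect_equal(nrow(pc$points), 307200)

  # principal ray: pixel at (cx, cy) maps to (0, 0, d)
  K2 <- camera_intrinsics(11, 11, fx = 100, fy = 100, cx = 5, cy = 5)
  vals <- matrix(0, 11, 11)
  vals[6, 6] <- 1500  # row v = 5, col u = 5
  pc2 <- depth_to_points(depth_frame(vals, K2))
  expect_equal(nrow(pc2$points), 1)
  expect_equal(as.numeric(pc2$points), c(0, 0, 1.5), tolerance = 1e-12)

  # pixel one focal length right of centre at 2 m depth -> (2, 0, 2)
  K3 <- camera_intrinsics(201, 11, fx = 100, fy = 100, cx = 5, cy = 5)
  vals3 <- matrix(0, 11, 201)
  vals3[6, 106] <- 2000  # u = 105 = cx + fx
  pc3 <- depth_to_points(depth_frame(vals3, K3))
  expect_equal(as.numeric(pc3$points), c(2, 0, 2), tolerance = 1e-12)
})

test_that("point count equals the strictly positive pixel count and zeros are dropped", {
  K <- camera_intrinsics(40, 30, fx = 40, fy = 40)
  set.seed(11)
  vals <- matrix(sample(c(0, 0, 400, 800), 1200, replace = TRUE), 30, 40)
  pc <- depth_to_points(depth_frame(vals, K))
  expect_equal(nrow(pc$points), sum(vals > 0))
  expect_true(all(pc$points[, 3] > 0))
  # all-zero frame: empty cloud, not an error
  expect_equal(nrow(depth_to_points(depth_frame(matrix(0, 30, 40), K))$points), 0)
  # shape mismatch is an error
  expect_error(depth_frame(matrix(0, 30, 41), K), "shape")
})

test_that("back-projection then re-projection returns the pixel grid", {
  K <- camera_intrinsics(64, 48, fx = 52, fy = 50, cx = 31.2, cy = 24.1)
  set.seed(2)
  vals <- matrix(sample(200:4000, 64 * 48, replace = TRUE), 48, 64)
  pc <- depth_to_points(depth_frame(vals, K))
  pr <- project_points(pc$points, K)
  u <- rep(0:63, times = 48)
  v <- rep(0:47, each = 64)
  expect_lt(max(abs(pr$u - u)), 1e-6)
  expect_lt(max(abs(pr$v - v)), 1e-6)
  expect_equal(pr$depth, as.numeric(t(vals)) * 0.001)
})

test_that("PCA normals match brute-force eigenvectors and the viewpoint convention", {
  set.seed(4)
  # plane z = 1: normals face the origin, so (0, 0, -1)
  P <- cbind(runif(60, -0.1, 0.1), runif(60, -0.1, 0.1), 1)
  en <- estimate_normals_pca(point_cloud(P), k = 8)
  expect_lt(max(abs(sweep(en$normals, 2, c(0, 0, -1)))), 1e-9)

  # sphere centred at origin: normal at p antiparallel to p
  S <- fib_sphere(200, r = 0.5)
  es <- estimate_normals_pca(point_cloud(S), k = 8)
  align <- rowSums(es$normals * (S / 0.5))
  expect_true(all(align < -0.9))

  # arbitrary cloud: sign-invariant agreement with brute-force eigen
  Q <- matrix(rnorm(45 * 3, sd = 0.05), 45, 3)
  eq <- estimate_normals_pca(point_cloud(Q), k = 10)
  for (i in c(1, 7, 23, 45)) {
    bf <- bf_pca_normal(Q, i, 10)
    expect_lt(min(sqrt(sum((eq$normals[i, ] - bf)^2)),
                  sqrt(sum((eq$normals[i, ] + bf)^2))), 1e-8)
  }
})

test_that("noisy-plane normals stay within 5 degrees on average", {
  set.seed(9)
  P <- cbind(runif(400, 0, 0.1), runif(400, 0, 0.1), 1 + rnorm(400, 0, 0.001))
  en <- estimate_normals_pca(point_cloud(P), k = 12)
  ang <- acos(pmin(1, abs(en$normals[, 3])))
  expect_lt(mean(ang) * 180 / pi, 5)
})

test_that("degenerate (collinear) neighborhoods are flagged invalid", {
  P <- cbind(seq(0, 1, length.out = 20), 0, 1)
  en <- estimate_normals_pca(point_cloud(P), k = 4)
  expect_false(any(attr(en, "normal_valid")))
  expect_true(all(is.na(en$normals)))
})

test_that("vertex adjacency is sorted, symmetric, and right on known meshes", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1))
  adj <- vertex_adjacency(tri)
  expect_equal(adj[[1]], c(2L, 3L))
  expect_equal(adj[[2]], c(1L, 3L))
  expect_equal(adj[[3]], c(1L, 2L))

  two <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                      rbind(c(1, 2, 3), c(2, 4, 3)))
  adj2 <- vertex_adjacency(two)
  expect_equal(lengths(adj2), c(2L, 3L, 3L, 2L))
  # symmetry
  for (v in 1:4) for (w in adj2[[v]]) expect_true(v %in% adj2[[w]])

  ico <- icosahedron()
  expect_true(all(lengths(vertex_adjacency(ico)) == 5L))
  expect_equal(euler_characteristic(ico), 2L)
})

test_that("16-bit depth PNG round trip is exact", {
  K <- camera_intrinsics(80, 60, fx = 60, fy = 60)
  set.seed(21)
  vals <- matrix(sample(0:65535, 80 * 60, replace = TRUE), 60, 80)
  f <- withr::local_tempfile(fileext = ".png")
  write_depth_png(depth_frame(vals, K), f)
  back <- read_depth_png(f, K, frame_index = 3L)
  expect_equal(back$values, vals, ignore_attr = TRUE)
  expect_equal(back$frame_index, 3L)
})

test_that("intrinsics YAML round trip preserves the pinhole parameters", {
  K <- camera_intrinsics(640, 480, fx = 385.2, fy = 384.7, cx = 320.1,
                         cy = 239.4, depth_scale = 0.001)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_intrinsics(K, f)
  K2 <- read_intrinsics(f)
  expect_equal(K2[c("width", "height", "fx", "fy", "cx", "cy", "depth_scale")],
               K[c("width", "height", "fx", "fy", "cx", "cy", "depth_scale")])
})
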