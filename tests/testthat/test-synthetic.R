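test_that("plant generation is deterministic and matches tessellation formulas", {
  p1 <- make_plant(plant_params(seed = 7L))
  p2 <- make_plant(plant_params(seed = 7L))
  expect_identical(p1$vertices, p2$vertices)
  expect_identical(p1$triangles, p2$triangles)
  # cylinder-only plant: n_seg * (n_h + 1) ring vertices + 2 cap centres
  cyl <- make_plant(plant_params(n_leaves = 0), n_seg = 16, n_h = 12)
  expect_equal(nrow(cyl$vertices), 16 * 13 + 2)
  expect_equal(nrow(cyl$triangles), 2 * 16 * 12 + 2 * 16)
  # stem is watertight
  expect_equal(sum(mesh_edges(cyl)$count == 1), 0)
})

test_that("leaf area approximates length x width within 15 percent", {
  params <- plant_params()
  plant <- make_plant(params)
  part <- attr(plant, "part")
  tri <- plant$triangles
  for (li in 1:params$n_leaves) {
    sel <- rowSums(matrix(part[tri] == li, ncol = 3)) == 3
    leaf_mesh <- surface_mesh(plant$vertices, tri[sel, , drop = FALSE])
    a <- mesh_area(leaf_mesh)
    expect_lt(abs(a - params$leaf_length * params$leaf_width) /
                (params$leaf_length * params$leaf_width), 0.15)
  }
})

test_that("animation is identity at t = 0 and amplitude 0, closed form at the tip", {
  plant <- make_plant(plant_params(seed = 3L))
  sw <- sway_params(amplitude_deg = 10, frequency = 1, phases = rep(0, 4))
  a0 <- animate_plant(plant, sw, 0)
  expect_equal(a0$vertices, plant$vertices)
  expect_equal(animate_plant(plant, sway_params(0), 0.7)$vertices,
               plant$vertices)
  # tip displacement at t = 0.25, frequency 1, phase 0: full-amplitude
  # rotation of the tip about the attachment axis
  at <- animate_plant(plant, sw, 0.25)
  part <- attr(plant, "part"); s <- attr(plant, "leaf_s")
  lf <- attr(plant, "leaves")[[1]]
  tipi <- which(part == 1L & abs(s - 1) < 1e-12)
  ang <- 10 * pi / 180 * sin(2 * pi * 0.25)
  K <- matrix(c(0, lf$axis[3], -lf$axis[2], -lf$axis[3], 0, lf$axis[1],
                lf$axis[2], -lf$axis[1], 0), 3, 3)
  Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  for (v in tipi) {
    expected <- as.numeric(Rm %*% (plant$vertices[v, ] - lf$attach)) + lf$attach
    expect_equal(at$vertices[v, ], expected, tolerance = 1e-12)
  }
  # stem (rigid part) edge lengths preserved exactly under any sway
  stem_tri <- plant$triangles[rowSums(matrix(part[plant$triangles] == 0L,
                                             ncol = 3)) == 3, ]
  el <- function(V) sqrt(rowSums((V[stem_tri[, 1], ] - V[stem_tri[, 2], ])^2))
  expect_equal(el(at$vertices), el(plant$vertices))
})

test_that("depth rendering z-buffers correctly and respects the seeded noise level", {
  K <- camera_intrinsics(160, 120, 80, 80)
  pose <- default_camera_pose(distance = 0, height = 0)  # camera at origin
  # camera-facing square at 0.4 m in front (world -z)
  sq <- surface_mesh(rbind(c(-0.1, -0.1, -0.4), c(0.1, -0.1, -0.4),
                           c(0.1, 0.1, -0.4), c(-0.1, 0.1, -0.4)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  fr <- render_depth(sq, K, pose, noise_sigma = 0)
  hit <- fr$values > 0
  expect_gt(sum(hit), 500)
  expect_true(all(fr$values[hit] == 400))  # exactly 0.4 m in millimetres
  # occlusion: square in front of a wall at 5 m: covered pixels never 5 m
  wall <- surface_mesh(rbind(c(-3, -3, -5), c(3, -3, -5),
                             c(3, 3, -5), c(-3, 3, -5)),
                       rbind(c(1, 2, 3), c(1, 3, 4)))
  both <- render_depth(sq, K, pose, background = wall, noise_sigma = 0)
  expect_true(all(both$values[fr$values > 0] == 400))
  expect_true(any(both$values == 5000))
  # noise: sample sd of the flat patch within [1.6, 2.4] mm at n >= 500
  frn <- render_depth(sq, K, pose, noise_sigma = 0.002, seed = 99L)
  depths <- frn$values[fr$values > 0] * 0.001
  expect_gte(length(depths), 500)
  expect_gte(stats::sd(depths), 0.0016)
  expect_lte(stats::sd(depths), 0.0024)
  # determinism under the seed
  frn2 <- render_depth(sq, K, pose, noise_sigma = 0.002, seed = 99L)
  expect_identical(frn$values, frn2$values)
})

test_that("rendered depth back-projects onto the plant surface", {
  K <- camera_intrinsics(160, 120, 80, 80)
  plant <- make_plant(plant_params(seed = 5L))
  pose <- default_camera_pose()
  fr <- render_depth(plant, K, pose, noise_sigma = 0.001, seed = 4L)
  cloud <- depth_to_points(fr)
  # camera-frame plant surface for exact point-to-mesh distances
  Vc <- t(pose[1:3, 1:3] %*% t(plant$vertices) + pose[1:3, 4])
  cp <- mesh_distance(cloud$points, surface_mesh(Vc, plant$triangles))
  # within noise + half-pixel footprint (~depth/fx)
  tol <- 0.001 + 0.5 * max(cloud$points[, 3]) / K$fx
  expect_lt(stats::quantile(cp$dist, 0.95), tol)
})

test_that("sensor profiles follow the qualitative field orderings", {
  h <- c(0.35, 1.35, 1.70)
  ci <- make_sensor_profile("cloudy_inside", h)
  co <- make_sensor_profile("cloudy_outside", h)
  si <- make_sensor_profile("sunny_inside", h)
  so <- make_sensor_profile("sunny_outside", h)
  v <- function(p, var) p$value[p$variable == var]
  # three readings per variable at the default heights
  expect_equal(nrow(ci), 9)
  # inside base receives less light than outside base (same weather)
  expect_lt(v(ci, "luminosity")[1], v(co, "luminosity")[1])
  expect_lt(v(si, "luminosity")[1], v(so, "luminosity")[1])
  # inside base cooler and wetter than its top (stronger gradient inside)
  expect_lt(v(ci, "temperature")[1], v(ci, "temperature")[3])
  expect_gt(v(ci, "humidity")[1], v(ci, "humidity")[3])
  expect_gt(diff(range(v(ci, "temperature"))), diff(range(v(co, "temperature"))))
  # sunny vs cloudy, same position: hotter, drier, brighter everywhere
  for (pos in list(c("sunny_inside", "cloudy_inside"),
                   c("sunny_outside", "cloudy_outside"))) {
    a <- make_sensor_profile(pos[1], h); b <- make_sensor_profile(pos[2], h)
    expect_true(all(v(a, "temperature") > v(b, "temperature")))
    expect_true(all(v(a, "humidity") < v(b, "humidity")))
    expect_true(all(v(a, "luminosity") > v(b, "luminosity")))
  }
})

test_that("scene export writes frames, intrinsics, sensors and ground truth", {
  dir <- withr::local_tempdir()
  K <- camera_intrinsics(64, 48, 32, 32)
  out <- synth_scene(dir, frames = 2, seed = 11L, intrinsics = K,
                     noise_sigma = 0.001)
  expect_length(list.files(dir, pattern = "frame_.*\\.png"), 2)
  expect_true(file.exists(file.path(dir, "intrinsics.yaml")))
  expect_true(file.exists(file.path(dir, "sensors.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.ply")))
  # frames re-read identically through the sequence reader
  frames <- read_depth_sequence(dir, K)
  expect_length(frames, 2)
  expect_equal(frames[[1]]$frame_index, 0L)
  # determinism: a second export is byte-identical
  dir2 <- withr::local_tempdir()
  synth_scene(dir2, frames = 2, seed = 11L, intrinsics = K,
              noise_sigma = 0.001)
  f1 <- readBin(file.path(dir, "frame_0000.png"), "raw", 1e6)
  f2 <- readBin(file.path(dir2, "frame_0000.png"), "raw", 1e6)
  expect_identical(f1, f2)
})
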