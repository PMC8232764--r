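test_that("cotangent weights reproduce closed-form angle combinations", {
  # two equilateral triangles sharing edge (1,2): both opposite angles 60deg
  eq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0),
                           c(0.5, sqrt(3) / 2, 0), c(0.5, -sqrt(3) / 2, 0)),
                     rbind(c(1, 2, 3), c(2, 1, 4)))
  cw <- cotangent_weights(eq)
  k12 <- which(cw$edges[, 1] == 1 & cw$edges[, 2] == 2)
  expect_equal(cw$weights[k12], 2 / sqrt(3), tolerance = 1e-12)
  # boundary edge (1,3) has a single opposite angle of 60 degrees
  k13 <- which(cw$edges[, 1] == 1 & cw$edges[, 2] == 3)
  expect_equal(cw$weights[k13], 1 / sqrt(3), tolerance = 1e-12)

  # 45/90 pair on edge (1,2): cot 45 + cot 90 = 1 + 0 = 1
  ri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(0.5, -0.5, 0)),
                     rbind(c(1, 2, 3), c(2, 1, 4)))
  cwr <- cotangent_weights(ri)
  k <- which(cwr$edges[, 1] == 1 & cwr$edges[, 2] == 2)
  expect_equal(cwr$weights[k], 1, tolerance = 1e-12)
})

test_that("zero-area triangles are excluded with a warning", {
  degen <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 4), c(1, 2, 3)))
  expect_warning(cw <- cotangent_weights(degen), "zero-area")
  expect_true(all(is.finite(cw$weights)))
})

test_that("SR-ARAP energy vanishes for identity and global rigid motions", {
  sp <- advancing_front_reconstruct(point_cloud(fib_sphere(150)))
  n <- nrow(sp$vertices)
  prob <- deformation_problem(sp, 1L, sp$vertices[1, , drop = FALSE])
  Rid <- array(rep(diag(3), n), c(3, 3, n))
  expect_equal(srarap_energy(prob, sp$vertices, Rid), 0)
  # random global rigid motions
  set.seed(61)
  for (rep in 1:3) {
    rt <- rigid_transform(sp$vertices, angle = runif(1, -1, 1),
                          axis = rnorm(3), t = rnorm(3, sd = 0.2))
    RR <- array(rep(rt$R, n), c(3, 3, n))
    expect_lt(srarap_energy(prob, rt$P, RR), 1e-20)
  }
})

test_that("SR-ARAP energy matches explicit arithmetic on a 2-triangle strip", {
  strip <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                        rbind(c(1, 2, 3), c(2, 4, 3)))
  prob <- deformation_problem(strip, 1L, strip$vertices[1, , drop = FALSE],
                              alpha = 0)
  Sp <- strip$vertices
  Sp[4, ] <- Sp[4, ] + c(0, 0, 0.5)  # displace one vertex
  Rid <- array(rep(diag(3), 4), c(3, 3, 4))
  # hand computation: per directed edge w * ||ep - e||^2; only edges touching
  # vertex 4 have nonzero residual (0.5^2), each counted in both directions
  cw <- cotangent_weights(strip)
  touching <- cw$edges[, 1] == 4 | cw$edges[, 2] == 4
  expected <- 2 * sum(cw$weights[touching] * 0.25)
  expect_equal(srarap_energy(prob, Sp, Rid), expected, tolerance = 1e-12)
})

test_that("constraints at current positions give a fixed point", {
  sp <- advancing_front_reconstruct(point_cloud(fib_sphere(150)))
  ctrl <- c(3L, 40L, 90L)
  res <- deform(deformation_problem(sp, ctrl,
                                    sp$vertices[ctrl, , drop = FALSE],
                                    max_iterations = 5))
  expect_lt(max(abs(res$S_prime$vertices - sp$vertices)), 1e-9)
  expect_lt(res$energy_trace[length(res$energy_trace)], 1e-20)
})

test_that("a rigid transform of a few controls is propagated to every vertex", {
  sp <- advancing_front_reconstruct(point_cloud(fib_sphere(300)))
  rt <- rigid_transform(sp$vertices, angle = 0.3, axis = c(0, 0, 1),
                        t = c(0.05, -0.02, 0.03))
  ctrl <- c(1L, 80L, 160L, 240L)  # non-coplanar on the sphere
  res <- deform(deformation_problem(sp, ctrl, rt$P[ctrl, , drop = FALSE],
                                    max_iterations = 800, tolerance = 1e-10))
  err <- max(sqrt(rowSums((res$S_prime$vertices - rt$P)^2)))
  expect_lt(err, 1e-4)
  # controls land exactly on their targets
  expect_equal(res$S_prime$vertices[ctrl, ], rt$P[ctrl, ], ignore_attr = TRUE)
  # rotations are proper within tolerance
  for (v in c(1, 50, 150)) {
    R <- res$rotations[, , v]
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-6)
    expect_equal(det(R), 1, tolerance = 1e-6)
  }
})

test_that("the energy trace is monotonically non-increasing", {
  set.seed(62)
  sp <- advancing_front_reconstruct(point_cloud(fib_sphere(200)))
  ctrl <- sample(200, 12)
  targets <- sp$vertices[ctrl, ] + matrix(rnorm(36, sd = 0.02), 12, 3)
  res <- deform(deformation_problem(sp, ctrl, targets, max_iterations = 30))
  expect_true(all(diff(res$energy_trace) <= 1e-10))
})

test_that("alpha = 0 reduces to classic ARAP (independent small-scale check)", {
  ico <- icosahedron(r = 0.1)
  ctrl <- c(1L, 4L)
  targets <- ico$vertices[ctrl, , drop = FALSE]
  targets[2, ] <- targets[2, ] + c(0.01, -0.005, 0.02)
  ours <- deform(deformation_problem(ico, ctrl, targets, alpha = 0,
                                     max_iterations = 200, tolerance = 0))
  ref <- bf_arap(ico, ctrl, targets, iters = 200)
  expect_lt(max(abs(ours$S_prime$vertices - ref)), 1e-6)
})

test_that("a synthetic leaf bent by a known rotation field is recovered", {
  plant <- make_plant(plant_params(seed = 42L))
  part <- attr(plant, "part")
  keep <- which(part == 2L)
  remap <- integer(nrow(plant$vertices)); remap[keep] <- seq_along(keep)
  tri <- plant$triangles
  ok <- rowSums(matrix(tri %in% keep, ncol = 3)) == 3
  leaf <- surface_mesh(plant$vertices[keep, , drop = FALSE],
                       matrix(remap[tri[ok, ]], ncol = 3))
  bent <- animate_plant(plant, sway_params(20), 0.25)  # known smooth field
  truth <- bent$vertices[keep, , drop = FALSE]
  set.seed(63)
  ctrl <- sample(nrow(leaf$vertices), max(2, round(0.1 * nrow(leaf$vertices))))
  res <- deform(deformation_problem(leaf, ctrl, truth[ctrl, , drop = FALSE],
                                    max_iterations = 60))
  err <- mean(sqrt(rowSums((res$S_prime$vertices - truth)^2)))
  leaf_len <- plant_params()$leaf_length
  expect_lt(err, 0.1 * leaf_len)
  expect_true(all(diff(res$energy_trace) <= 1e-10))
})

test_that("components without constraints ride along with a warning", {
  sp1 <- advancing_front_reconstruct(point_cloud(fib_sphere(80)))
  sp2v <- fib_sphere(80, centre = c(0.5, 0, 0))
  two <- surface_mesh(rbind(sp1$vertices, sp2v),
                      rbind(sp1$triangles,
                            advancing_front_reconstruct(point_cloud(sp2v))$triangles + 80L))
  ctrl <- c(1L, 20L, 40L)
  tgt <- two$vertices[ctrl, , drop = FALSE] +
    matrix(c(0.01, 0, 0), 3, 3, byrow = TRUE)
  expect_warning(res <- deform(deformation_problem(two, ctrl, tgt,
                                                   max_iterations = 5)),
                 "components without constraints")
  expect_equal(nrow(res$S_prime$vertices), 160)
  expect_true(all(is.finite(res$S_prime$vertices)))
})
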