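# a distinctive curved test patch: one synthetic leaf with its graph
leaf_graph <- function(seed = 42L, t = 0, L = 0.016,
                       params = plant_params(seed = seed)) {
  plant <- make_plant(params)
  pm <- animate_plant(plant, sway_params(8), t)
  part <- attr(plant, "part")
  keep <- which(part == 1L)
  remap <- integer(nrow(pm$vertices)); remap[keep] <- seq_along(keep)
  tri <- pm$triangles
  ok <- rowSums(matrix(tri %in% keep, ncol = 3)) == 3
  leaf <- surface_mesh(pm$vertices[keep, , drop = FALSE],
                       matrix(remap[tri[ok, ]], ncol = 3))
  list(surface = leaf,
       graph = build_deformation_graph(leaf, L, viewpoint = NULL),
       orig_idx = keep, plant = plant, animated = pm)
}

test_that("SHOT descriptors are unit length with the canonical 352 bins", {
  lg <- leaf_graph()
  ds <- shot_descriptors(lg$graph)
  expect_equal(ncol(ds$descriptors), 352)
  norms <- sqrt(rowSums(ds$descriptors^2))
  expect_true(all(abs(norms[!ds$empty] - 1) < 1e-9))
  # LRF is orthonormal
  d1 <- shot_descriptor(lg$graph, 1, 3 * 0.016)
  expect_lt(max(abs(d1$lrf %*% t(d1$lrf) - diag(3))), 1e-6)
})

test_that("a flat patch puts all histogram mass at cosine ~ 1", {
  g <- jittered_grid(9, 9, spacing = 0.01, jitter = 0.05)
  pm <- advancing_front_reconstruct(point_cloud(g))
  gr <- build_deformation_graph(pm, 0.01, iterations = 1, viewpoint = NULL)
  centre <- which.min(rowSums(sweep(gr$graph_mesh$vertices, 2,
                                    colMeans(gr$graph_mesh$vertices))^2))
  d <- shot_descriptor(gr, centre, 0.03)
  mass <- matrix(d$values, nrow = 11)  # cosine bins x spatial bins
  # parallel normals: cos = 1 maps to the top bin (split with its neighbor
  # by linear interpolation)
  expect_gt(sum(mass[10:11, ]), 0.99 * sum(mass))
})

test_that("SHOT is invariant to rigid motion of the patch", {
  lg <- leaf_graph()
  g <- lg$graph
  ds <- shot_descriptors(g)
  rt <- rigid_transform(g$graph_mesh$vertices, angle = 0.5, axis = c(0.2, 1, 0.4))
  g2 <- g
  g2$graph_mesh <- surface_mesh(rt$P, g$graph_mesh$triangles)
  g2$normals <- mesh_vertex_normals(g2$graph_mesh)
  ds2 <- shot_descriptors(g2)
  dd <- sqrt(rowSums((ds$descriptors - ds2$descriptors)^2))
  expect_lt(max(dd[!ds$empty]), 1e-6)

  # ranking: self-distance under rigid motion beats distance to other patches
  other <- shot_descriptors(leaf_graph(
    params = plant_params(leaf_length = 0.17, leaf_width = 0.04))$graph)
  n_common <- min(nrow(ds$descriptors), nrow(other$descriptors))
  cross <- sqrt(rowSums((ds$descriptors[1:n_common, ] -
                           other$descriptors[1:n_common, ])^2))
  expect_gt(stats::median(cross), max(dd[!ds$empty]))
})

test_that("bidirectional matching is mutual, unique and symmetric", {
  lg <- leaf_graph()
  ds <- shot_descriptors(lg$graph)
  # identical sets: identity matching over non-empty descriptors
  mt <- match_bidirectional(ds, ds, max_distance = 0.25)
  expect_equal(mt$model_keypoint, mt$input_keypoint)
  expect_equal(nrow(mt), sum(!ds$empty))
  expect_true(all(mt$descriptor_distance < 1e-7))

  # an extra descriptor far from all others finds no mutual pair
  extra <- rbind(ds$descriptors, rep(1 / sqrt(352), 352))
  mt2 <- match_bidirectional(ds$descriptors, extra, max_distance = 2)
  expect_false((nrow(extra)) %in% mt2$input_keypoint &&
                 any(duplicated(mt2$model_keypoint)))
  # uniqueness: each keypoint appears at most once per side
  expect_false(any(duplicated(mt2$model_keypoint)))
  expect_false(any(duplicated(mt2$input_keypoint)))

  # symmetry: swapping sides swaps the pair columns
  other <- shot_descriptors(leaf_graph(
    params = plant_params(leaf_length = 0.19, leaf_width = 0.045))$graph)
  ab <- match_bidirectional(ds$descriptors, other$descriptors, max_distance = 2)
  ba <- match_bidirectional(other$descriptors, ds$descriptors, max_distance = 2)
  key_ab <- paste(ab$model_keypoint, ab$input_keypoint)
  key_ba <- paste(ba$input_keypoint, ba$model_keypoint)
  expect_setequal(key_ab, key_ba)
})

test_that("graphs of the same leaf one frame apart match mostly correctly", {
  L <- 0.016
  lg0 <- leaf_graph(t = 0, L = L)
  lg1 <- leaf_graph(t = 1 / 12, L = L)
  d0 <- shot_descriptors(lg0$graph)
  d1 <- shot_descriptors(lg1$graph)
  # pipeline-style spatially augmented matching between consecutive frames
  lam <- 0.32 / L
  a0 <- list(descriptors = cbind(d0$descriptors,
                                 lam * lg0$graph$graph_mesh$vertices),
             empty = d0$empty)
  a1 <- list(descriptors = cbind(d1$descriptors,
                                 lam * lg1$graph$graph_mesh$vertices),
             empty = d1$empty)
  mt <- match_bidirectional(a0, a1, max_distance = 1.2)
  expect_gt(nrow(mt), 10)
  # ground truth: a frame-0 graph keypoint corresponds to the animated
  # position of its mapped source vertex (identity index map on the plant)
  src0 <- lg0$orig_idx[lg0$graph$source_map[mt$model_keypoint]]
  truth <- lg1$animated$vertices[src0, , drop = FALSE]
  matched <- lg1$graph$graph_mesh$vertices[mt$input_keypoint, , drop = FALSE]
  err <- sqrt(rowSums((matched - truth)^2))
  expect_gte(mean(err <= L), 0.7)
})
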