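# Synthetic test bed: a corn-like plant mesh with ground-truth metadata, a
# smooth non-rigid sway animation with identity vertex correspondence, depth
# rendering with background clutter and sensor noise, and qualitative sensor
# profiles. All generators are pure functions of (parameters, seed).

#' Parameters of the synthetic corn-like plant
#'
#' The defaults describe a young plant that fits the frustum of a 640x480
#' depth camera placed about 0.4 m away: a 0.4 m stem of corn-like girth
#' (30 mm diameter) with four arching leaves.
#'
#' @param stem_height,stem_radius stem size in metres.
#' @param n_leaves number of leaves.
#' @param leaf_length,leaf_width leaf size in metres.
#' @param leaf_attach_heights attachment heights (metres); default spreads
#'   them along the upper stem.
#' @param seed integer seed making the geometry reproducible.
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(stem_height = 0.4, stem_radius = 0.015, n_leaves = 4,
                         leaf_length = 0.22, leaf_width = 0.05,
                         leaf_attach_heights = NULL, seed = 42L) {
  stopifnot(stem_height > 0, stem_radius > 0, n_leaves >= 0,
            leaf_length > 0, leaf_width > 0)
  if (is.null(leaf_attach_heights)) {
    leaf_attach_heights <- if (n_leaves > 0)
      seq(0.35, 0.85, length.out = n_leaves) * stem_height else numeric(0)
  }
  stopifnot(length(leaf_attach_heights) == n_leaves)
  structure(list(stem_height = stem_height, stem_radius = stem_radius,
                 n_leaves = as.integer(n_leaves), leaf_length = leaf_length,
                 leaf_width = leaf_width,
                 leaf_attach_heights = leaf_attach_heights,
                 seed = as.integer(seed)),
            class = "plant_params")
}

# rotation matrix about unit axis by angle (Rodrigues)
.rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate the synthetic plant mesh with ground-truth metadata
#'
#' The stem is a capped cylinder standing on the world origin (world y up);
#' each leaf is a swept curved ribbon attached at its height, rising at
#' about 35 degrees and drooping toward the tip. Ground truth records
#' per-vertex part labels (0 = stem, i = leaf i), the normalized position
#' `s` along each leaf, and each leaf's attachment point and swing axis.
#'
#' @param params a [plant_params()].
#' @param n_seg cylinder segments around the stem.
#' @param n_h cylinder segments along the stem.
#' @param n_l,n_w ribbon segments along / across each leaf.
#' @return A [surface_mesh()] with attributes `part` (integer per vertex),
#'   `leaf_s` (numeric per vertex), and `leaves` (list of attachment
#'   metadata).
#' @export
make_plant <- function(params, n_seg = 16, n_h = 12, n_l = 12, n_w = 4) {
  stopifnot(inherits(params, "plant_params"))
  set.seed(params$seed)
  H <- params$stem_height; R <- params$stem_radius
  th <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  ring <- cbind(cos(th) * R, 0, sin(th) * R)
  V <- NULL; F <- NULL; part <- integer(0); leaf_s <- numeric(0)
  # stem rings
  for (lev in 0:n_h) {
    V <- rbind(V, sweep(ring, 2, c(0, lev / n_h * H, 0), "+"))
  }
  part <- rep(0L, nrow(V)); leaf_s <- rep(0, nrow(V))
  for (lev in 0:(n_h - 1)) {
    for (s in 0:(n_seg - 1)) {
      a <- lev * n_seg + s + 1
      b <- lev * n_seg + (s + 1) %% n_seg + 1
      c2 <- (lev + 1) * n_seg + s + 1
      d <- (lev + 1) * n_seg + (s + 1) %% n_seg + 1
      F <- rbind(F, c(a, b, d), c(a, d, c2))
    }
  }
  # caps
  cb <- nrow(V) + 1L; ct <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, 0), c(0, H, 0))
  part <- c(part, 0L, 0L); leaf_s <- c(leaf_s, 0, 0)
  for (s in 0:(n_seg - 1)) {
    a <- s + 1; b <- (s + 1) %% n_seg + 1
    F <- rbind(F, c(cb, b, a))
    a2 <- n_h * n_seg + s + 1; b2 <- n_h * n_seg + (s + 1) %% n_seg + 1
    F <- rbind(F, c(ct, a2, b2))
  }
  leaves <- list()
  if (params$n_leaves > 0) {
    azim <- (seq_len(params$n_leaves) - 1) * 137.5 * pi / 180 + pi / 2
    for (li in seq_len(params$n_leaves)) {
      h <- params$leaf_attach_heights[li]
      out_dir <- c(cos(azim[li]), 0, sin(azim[li]))
      width_ax <- c(-sin(azim[li]), 0, cos(azim[li]))
      attach <- c(out_dir * R * 0.8) + c(0, h, 0)
      # centerline: rises at 35 deg, droops 75 deg along the length
      ss <- seq(0, 1, length.out = n_l + 1)
      ang <- 35 * pi / 180 - ss * 75 * pi / 180
      step <- params$leaf_length / n_l
      ctr <- matrix(0, n_l + 1, 3)
      ctr[1, ] <- attach
      for (q in seq_len(n_l)) {
        a_mid <- (ang[q] + ang[q + 1]) / 2
        d <- cos(a_mid) * out_dir + sin(a_mid) * c(0, 1, 0)
        ctr[q + 1, ] <- ctr[q, ] + step * d
      }
      # near-constant width, tapering over the last fifth
      wprof <- ifelse(ss < 0.8, 1, 1 - 0.7 * (ss - 0.8) / 0.2) *
        params$leaf_width / 2
      wo <- seq(-1, 1, length.out = n_w + 1)
      base_id <- nrow(V)
      for (q in 0:n_l) {
        row <- sweep(outer(wo * wprof[q + 1], width_ax), 2, ctr[q + 1, ], "+")
        V <- rbind(V, row)
        part <- c(part, rep(li, n_w + 1))
        leaf_s <- c(leaf_s, rep(ss[q + 1], n_w + 1))
      }
      for (q in 0:(n_l - 1)) {
        for (r in 0:(n_w - 1)) {
          a <- base_id + q * (n_w + 1) + r + 1
          b <- a + 1
          c2 <- base_id + (q + 1) * (n_w + 1) + r + 1
          d <- c2 + 1
          F <- rbind(F, c(a, b, d), c(a, d, c2))
        }
      }
      leaves[[li]] <- list(attach = attach, axis = width_ax,
                           phase = (li - 1) * pi / 2)
    }
  }
  mesh <- surface_mesh(V, F)
  attr(mesh, "part") <- part
  attr(mesh, "leaf_s") <- leaf_s
  attr(mesh, "leaves") <- leaves
  mesh
}

#' Sway animation parameters
#'
#' @param amplitude_deg maximum leaf swing over the sequence (degrees);
#'   bounded so leaves never reach back to the stem.
#' @param frequency swing cycles per (normalized) sequence.
#' @param phases optional per-leaf phase offsets (radians).
#' @return An object of class `sway_params`.
#' @export
sway_params <- function(amplitude_deg = 8, frequency = 1, phases = NULL) {
  stopifnot(amplitude_deg >= 0, amplitude_deg < 45, frequency >= 0)
  structure(list(amplitude_deg = amplitude_deg, frequency = frequency,
                 phases = phases),
            class = "sway_params")
}

#' Animate the plant at normalized time t
#'
#' Each leaf rotates about its attachment axis by
#' `amplitude * sin(2 pi frequency t + phase)`, blended smoothly along the
#' leaf (root fixed, tip at the full angle, scaled by the normalized
#' position `s`). The stem is rigid. Vertex order is preserved, so the
#' correspondence to `t = 0` is the identity index map — the ground truth
#' for matching and deformation tests.
#'
#' @param plant mesh from [make_plant()] (with its metadata attributes).
#' @param sway a [sway_params()].
#' @param t normalized time in `[0, 1]`.
#' @return The animated [surface_mesh()] (metadata preserved).
#' @export
animate_plant <- function(plant, sway, t) {
  stopifnot(inherits(plant, "surface_mesh"), t >= 0, t <= 1)
  leaves <- attr(plant, "leaves")
  part <- attr(plant, "part")
  leaf_s <- attr(plant, "leaf_s")
  V <- plant$vertices
  amp <- sway$amplitude_deg * pi / 180
  for (li in seq_along(leaves)) {
    lf <- leaves[[li]]
    phase <- if (!is.null(sway$phases)) sway$phases[li] else lf$phase
    angle <- amp * sin(2 * pi * sway$frequency * t + phase)
    idx <- which(part == li)
    if (length(idx) == 0 || angle == 0) next
    for (v in idx) {
      a_v <- angle * leaf_s[v]
      if (a_v == 0) next
      Rm <- .rot_axis(lf$axis, a_v)
      V[v, ] <- as.numeric(Rm %*% (V[v, ] - lf$attach)) + lf$attach
    }
  }
  out <- surface_mesh(V, plant$triangles)
  attr(out, "part") <- part
  attr(out, "leaf_s") <- leaf_s
  attr(out, "leaves") <- leaves
  out
}

#' Default camera pose for the synthetic scene
#'
#' The camera sits `distance` metres in front of the plant at height
#' `height`, level and facing it; world y is up, the camera frame is
#' optical (x right, y down, z forward).
#'
#' @param distance camera-to-plant distance (metres).
#' @param height camera height above the plant base (metres).
#' @return A 4 x 4 world-to-camera rigid transform.
#' @export
default_camera_pose <- function(distance = 0.4, height = 0.2) {
  R <- matrix(c(1, 0, 0,
                0, -1, 0,
                0, 0, -1), 3, 3, byrow = TRUE)
  p <- c(0, height, distance)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- -as.numeric(R %*% p)
  M
}

#' Background clutter for the synthetic scene
#'
#' A far wall (about 22.5 m behind the plant), several partial "other
#' plant" ribbons between 0.8 and 2 m, and a small near object at about
#' 0.29 m from the camera, so rendered frames span the depth range typical
#' of field captures.
#'
#' @param seed integer seed.
#' @return A [surface_mesh()] in world coordinates.
#' @export
make_clutter <- function(seed = 1L) {
  set.seed(seed)
  quad <- function(center, right, up, hw, hh) {
    v <- rbind(center - right * hw - up * hh, center + right * hw - up * hh,
               center + right * hw + up * hh, center - right * hw + up * hh)
    list(v = v, f = rbind(c(1, 2, 3), c(1, 3, 4)))
  }
  V <- NULL; F <- NULL
  add <- function(q) {
    off <- if (is.null(V)) 0L else nrow(V)
    V <<- rbind(V, q$v)
    F <<- rbind(F, q$f + off)
  }
  # far wall, 22.5 m behind the plant base
  add(quad(c(0, 5, -22.5), c(1, 0, 0), c(0, 1, 0), 30, 15))
  # small pieces of leaves from neighboring plants, 0.4-1.6 m behind the
  # plant: sparse narrow strips the outlier / small-component filters are
  # meant to remove
  for (i in 1:10) {
    cx <- runif(1, -0.6, 0.6)
    cy <- runif(1, 0.05, 0.45)
    cz <- runif(1, -1.6, -0.4)
    ang <- runif(1, 0, pi)
    right <- c(cos(ang), 0, sin(ang))
    up <- c(0.2 * runif(1, -1, 1), 1, 0)
    up <- up / sqrt(sum(up^2))
    add(quad(c(cx, cy, cz), right, up, runif(1, 0.004, 0.008),
             runif(1, 0.015, 0.03)))
  }
  # small near object at ~0.29 m from the camera (frame corner)
  add(quad(c(-0.16, 0.06, 0.11), c(1, 0, 0), c(0, 1, 0), 0.008, 0.008))
  surface_mesh(V, F)
}

#' Render a depth frame of a scene
#'
#' Z-buffer rasterization (nearest hit per pixel) of the plant plus
#' background geometry, with optional Gaussian depth noise on valid pixels.
#' Deterministic for a given seed.
#'
#' @param mesh scene geometry in world coordinates (plant, possibly with
#'   clutter appended).
#' @param intrinsics a [camera_intrinsics()].
#' @param camera_pose 4 x 4 world-to-camera transform
#'   ([default_camera_pose()]).
#' @param background optional extra [surface_mesh()] rendered behind/around
#'   the subject.
#' @param noise_sigma depth noise standard deviation in metres.
#' @param seed integer seed for the noise.
#' @param frame_index frame index stamped on the result.
#' @return A [depth_frame()] (stored units = `depth_scale` metres).
#' @export
render_depth <- function(mesh, intrinsics, camera_pose = default_camera_pose(),
                         background = NULL, noise_sigma = 0, seed = 1L,
                         frame_index = 0L) {
  V <- mesh$vertices
  F <- mesh$triangles
  if (!is.null(background)) {
    F <- rbind(F, background$triangles + nrow(V))
    V <- rbind(V, background$vertices)
  }
  Vc <- t(camera_pose[1:3, 1:3] %*% t(V) + camera_pose[1:3, 4])
  Z <- cpp_rasterize(Vc, F, intrinsics$width, intrinsics$height,
                     intrinsics$fx, intrinsics$fy, intrinsics$cx, intrinsics$cy)
  if (noise_sigma > 0) {
    set.seed(seed)
    hit <- Z > 0
    Z[hit] <- pmax(1e-4, Z[hit] + rnorm(sum(hit), 0, noise_sigma))
  }
  vals <- round(Z / intrinsics$depth_scale)
  vals[vals > 65535] <- 65535
  depth_frame(vals, intrinsics, frame_index)
}

#' Qualitative sensor profiles for the four field conditions
#'
#' Profiles follow the expected field behavior: a plant inside the row has a
#' stronger base-to-top gradient (its base sees less light and heat but
#' keeps more humidity than its top); sunny conditions are uniformly
#' hotter, drier and brighter than cloudy ones.
#'
#' @param kind one of `"cloudy_inside"`, `"cloudy_outside"`,
#'   `"sunny_inside"`, `"sunny_outside"`.
#' @param heights sorted sensor mounting heights (metres).
#' @return A data frame with columns `variable`, `height_m`, `value`.
#' @export
make_sensor_profile <- function(kind = c("cloudy_inside", "cloudy_outside",
                                         "sunny_inside", "sunny_outside"),
                                heights = c(0.35, 1.35, 1.70)) {
  kind <- match.arg(kind)
  stopifnot(!is.unsorted(heights), length(heights) >= 2)
  h01 <- (heights - heights[1]) / (heights[length(heights)] - heights[1])
  prof <- switch(kind,
    cloudy_outside = list(temp = 24.0 + 0.8 * h01, hum = 62 - 2 * h01,
                          lux = 8000 + 1000 * h01),
    cloudy_inside = list(temp = 21.5 + 3.0 * h01, hum = 72 - 10 * h01,
                         lux = 2000 + 6500 * h01),
    sunny_outside = list(temp = 30.0 + 0.8 * h01, hum = 47 - 2 * h01,
                         lux = 40000 + 5000 * h01),
    sunny_inside = list(temp = 27.5 + 3.0 * h01, hum = 57 - 10 * h01,
                        lux = 10000 + 32500 * h01)
  )
  data.frame(
    variable = rep(c("temperature", "humidity", "luminosity"),
                   each = length(heights)),
    height_m = rep(heights, 3),
    value = c(prof$temp, prof$hum, prof$lux)
  )
}

#' Write a full synthetic scene to disk
#'
#' Renders a depth-frame sequence of the swaying (or static, or
#' occlusion-scenario) plant with clutter and noise, and writes depth PNGs,
#' the intrinsics YAML, a sensor CSV, and ground-truth PLY meshes.
#'
#' @param out_dir output directory (created if missing).
#' @param frames number of frames.
#' @param seed integer seed.
#' @param scenario `"sway"`, `"static"`, or `"occlusion"` (a card occludes
#'   the lower-right region early in the sequence, then slides away).
#' @param params a [plant_params()].
#' @param intrinsics a [camera_intrinsics()].
#' @param noise_sigma depth noise (metres).
#' @param sensor_kind profile passed to [make_sensor_profile()].
#' @return Invisibly, a list with the ground-truth plant and file paths.
#' @export
synth_scene <- function(out_dir, frames = 13, seed = 42L,
                        scenario = c("sway", "static", "occlusion"),
                        params = plant_params(seed = seed),
                        intrinsics = camera_intrinsics(640, 480, 385, 385),
                        noise_sigma = 0.002,
                        sensor_kind = "cloudy_inside") {
  scenario <- match.arg(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plant <- make_plant(params)
  sway <- if (scenario == "static") sway_params(0) else sway_params(8)
  clutter <- make_clutter(seed)
  pose <- default_camera_pose()
  paths <- character(frames)
  for (fi in seq_len(frames)) {
    t <- if (frames > 1) (fi - 1) / (frames - 1) else 0
    pm <- animate_plant(plant, sway, t)
    scene_bg <- clutter
    if (scenario == "occlusion" && t < 0.3) {
      card <- surface_mesh(
        rbind(c(0.02, 0.02, 0.28), c(0.20, 0.02, 0.28),
              c(0.20, 0.16, 0.28), c(0.02, 0.16, 0.28)),
        rbind(c(1, 2, 3), c(1, 3, 4)))
      scene_bg <- surface_mesh(rbind(clutter$vertices, card$vertices),
                               rbind(clutter$triangles,
                                     card$triangles + nrow(clutter$vertices)))
    }
    df <- render_depth(pm, intrinsics, pose, background = scene_bg,
                       noise_sigma = noise_sigma, seed = seed + fi,
                       frame_index = fi - 1L)
    paths[fi] <- file.path(out_dir, sprintf("frame_%04d.png", fi - 1L))
    write_depth_png(df, paths[fi])
  }
  write_intrinsics(intrinsics, file.path(out_dir, "intrinsics.yaml"))
  sensors <- make_sensor_profile(sensor_kind,
                                 heights = c(0.25, 0.6, 0.9) *
                                   params$stem_height)
  utils::write.csv(sensors, file.path(out_dir, "sensors.csv"),
                   row.names = FALSE)
  write_ply(plant, file.path(out_dir, "ground_truth.ply"))
  invisible(list(plant = plant, frames = paths, sensors = sensors,
                 intrinsics = intrinsics, pose = pose))
}
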