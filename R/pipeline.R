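# Per-frame reconstruction flow: frame selection, conditioning, surfacing,
# registration, deformation, TSDF fusion, and final export/colorization.

#' Pipeline configuration
#'
#' Collects every stage's tunable parameters with the package defaults.
#' Derived defaults (deformation-graph edge length, SHOT radius, LOP radius,
#' TSDF truncation) follow the cloud standardization resolution unless set
#' explicitly.
#'
#' @param frame_start,frame_end,frame_step frame selection (the defaults
#'   drop the first 30 frames for camera startup distortion and keep a
#'   10-frame interval up to frame 150).
#' @param background list: `factor`, `base`, `fixed_dmin`, `fixed_dmax`.
#' @param voxel list: `resolution` (metres), `mode`.
#' @param outlier list: `N`, `factor`.
#' @param smooth list: `iterations`, `normal_k`, `sigma_angle`, `lop_radius`.
#' @param surface list: `k`, `radius_factor`, `max_hole_edges`.
#' @param graph list: `edge_length`, `iterations`.
#' @param shot list: `radius`, `max_distance` (in the augmented matching
#'   space), `position_weight` (spatial weight for consecutive-frame
#'   matching), `max_displacement` (match sanity cap).
#' @param deform list: `alpha`, `max_iterations`, `tolerance`.
#' @param tsdf list: `voxel`, `truncation`, `max_weight`, `sign`.
#' @param color list: `height_axis`, `ramps`.
#' @param model list: `remesh` (logical: regenerate the model surface
#'   isotropically each frame, keeping its complexity bounded),
#'   `edge_length` (target edge, default 1.5x the voxel resolution).
#' @param final list: `edge_length`, `iterations` (final isotropic remesh).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(frame_start = 30L, frame_end = 150L,
                            frame_step = 10L,
                            background = list(), voxel = list(),
                            outlier = list(), smooth = list(),
                            surface = list(), graph = list(), shot = list(),
                            deform = list(), tsdf = list(), color = list(),
                            model = list(), final = list()) {
  merge <- function(def, usr) utils::modifyList(def, usr)
  voxel <- merge(list(resolution = 0.003, mode = "centroid_of_points"), voxel)
  res <- voxel$resolution
  cfg <- list(
    frame_start = as.integer(frame_start),
    frame_end = as.integer(frame_end),
    frame_step = as.integer(frame_step),
    background = merge(list(factor = 0.2, base = 10,
                            fixed_dmin = NULL, fixed_dmax = NULL), background),
    voxel = voxel,
    outlier = merge(list(N = 6, factor = 2), outlier),
    smooth = merge(list(iterations = 2, normal_k = 12, sigma_angle = 30,
                        lop_radius = 4 * res), smooth),
    surface = merge(list(k = 16, radius_factor = 5, max_hole_edges = 8,
                         min_component_frac = 0.05), surface),
    graph = merge(list(edge_length = 4 * res, iterations = 2), graph),
    shot = merge(list(radius = NULL, max_distance = 1.2,
                      position_weight = NULL, max_displacement = NULL), shot),
    deform = merge(list(alpha = 0.01, max_iterations = 15, tolerance = NULL),
                   deform),
    tsdf = merge(list(voxel = res, truncation = 5 * res, max_weight = 64,
                      sign = "viewpoint", min_weight = 0.25,
                      model_weight_scale = 0.4), tsdf),
    color = merge(list(height_axis = "-y", ramps = NULL), color),
    model = merge(list(remesh = TRUE, edge_length = 1.5 * res), model),
    final = merge(list(edge_length = 2 * res, iterations = 2), final)
  )
  if (is.null(cfg$shot$radius)) cfg$shot$radius <- 3 * cfg$graph$edge_length
  if (is.null(cfg$shot$position_weight))
    cfg$shot$position_weight <- 0.32 / cfg$graph$edge_length
  stopifnot(cfg$frame_start <= cfg$frame_end, cfg$frame_step >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Select the frame indices to process
#'
#' Arithmetic sequence from `start` to `end` (inclusive when aligned) with
#' the given step; e.g. frames 30 to 150 with a 10-frame interval give 13
#' frames.
#'
#' @param start,end first and last candidate frame index (`start <= end`).
#' @param step frame interval (>= 1).
#' @return Integer vector of selected frame indices.
#' @export
select_frames <- function(start, end, step = 1L) {
  if (start > end) stop("frame_start must be <= frame_end")
  stopifnot(step >= 1)
  seq.int(start, end, by = step)
}

#' Fresh reconstruction state
#'
#' @return A `reconstruction_state` holding the accumulated model mesh, its
#'   TSDF volume, the processed-frame count and per-frame log records.
#' @export
new_reconstruction_state <- function() {
  structure(list(model = NULL, model_volume = NULL, frames_processed = 0L,
                 log = list()),
            class = "reconstruction_state")
}

# conditioning + surfacing of one depth frame
.input_surface <- function(frame, config) {
  cloud <- depth_to_points(frame)
  cloud <- remove_background(cloud, config$background$factor,
                             config$background$base,
                             config$background$fixed_dmin,
                             config$background$fixed_dmax)
  cloud <- octree_downsample(cloud, config$voxel$resolution, config$voxel$mode)
  if (nrow(cloud$points) > config$outlier$N)
    cloud <- remove_outliers(cloud, config$outlier$N, config$outlier$factor)
  cloud <- bilateral_smooth(cloud, config$smooth$iterations,
                            config$smooth$normal_k, config$smooth$sigma_angle,
                            config$smooth$lop_radius)
  srf <- advancing_front_reconstruct(
    cloud, k = config$surface$k,
    radius_factor = config$surface$radius_factor,
    max_hole_edges = config$surface$max_hole_edges)
  .drop_small_components(srf, config$surface$min_component_frac)
}

# drop connected components holding fewer than frac of the referenced
# vertices: residual background fragments that survived the point filters
.drop_small_components <- function(mesh, frac) {
  if (frac <= 0 || nrow(mesh$triangles) == 0) return(mesh)
  comp <- mesh_components(mesh)
  used <- unique(as.integer(mesh$triangles))
  sizes <- table(comp[used])
  keep_comp <- as.integer(names(sizes)[sizes >= frac * length(used)])
  if (length(keep_comp) == length(sizes)) return(mesh)
  keep <- which(comp %in% keep_comp)
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  tri <- mesh$triangles
  ok <- rowSums(matrix(tri %in% keep, ncol = 3)) == 3
  surface_mesh(mesh$vertices[keep, , drop = FALSE],
               matrix(remap[tri[ok, , drop = FALSE]], ncol = 3),
               vertex_colors = if (!is.null(mesh$vertex_colors))
                 mesh$vertex_colors[keep, , drop = FALSE])
}

# light in-loop post-pass: outlier vertices dropped, vertices smoothed,
# surface regenerated isotropically so model complexity stays bounded
.mesh_postpass <- function(mesh, config) {
  n <- nrow(mesh$vertices)
  if (n > config$outlier$N + 1) {
    kn <- knn_search(mesh$vertices, k = config$outlier$N)
    d_local <- rowMeans(kn$dist)
    keep <- which(d_local <= mean(d_local) * config$outlier$factor)
    if (length(keep) < n) {
      remap <- integer(n); remap[keep] <- seq_along(keep)
      tri <- mesh$triangles
      ok <- rowSums(matrix(tri %in% keep, ncol = 3)) == 3
      mesh <- surface_mesh(mesh$vertices[keep, , drop = FALSE],
                           matrix(remap[tri[ok, ]], ncol = 3))
    }
  }
  if (nrow(mesh$vertices) > config$smooth$normal_k + 1) {
    sm <- bilateral_smooth(point_cloud(mesh$vertices), iterations = 1,
                           normal_k = config$smooth$normal_k,
                           sigma_angle = config$smooth$sigma_angle,
                           lop_radius = config$smooth$lop_radius)
    mesh <- surface_mesh(sm$points, mesh$triangles,
                         vertex_colors = mesh$vertex_colors)
  }
  if (isTRUE(config$model$remesh) && nrow(mesh$triangles) > 0)
    mesh <- isotropic_remesh(mesh, config$model$edge_length, iterations = 1)
  .drop_small_components(mesh, config$surface$min_component_frac)
}

#' Process one depth frame into the reconstruction state
#'
#' The input path is: back-projection, logarithmic background removal,
#' octree standardization, outlier removal, bilateral smoothing,
#' advancing-front reconstruction. The first frame initializes the model;
#' for later frames deformation graphs are built for model and input, SHOT
#' descriptors matched bidirectionally, targets propagated to the model
#' surface, the model deformed (SR-ARAP) toward the input, both surfaces
#' converted to TSDF and fused, and the fused mesh extracted, followed by a
#' light outlier/smoothing post-pass. When no mutual matches are found the
#' frame is skipped with a warning and the model carried forward.
#'
#' @param state a `reconstruction_state`.
#' @param frame a [depth_frame()].
#' @param config a [pipeline_config()].
#' @return The updated state.
#' @export
process_frame <- function(state, frame, config = pipeline_config()) {
  stopifnot(inherits(state, "reconstruction_state"),
            inherits(frame, "depth_frame"))
  input <- .input_surface(frame, config)
  rec <- list(frame_index = frame$frame_index,
              input_vertices = nrow(input$vertices),
              matches = NA_integer_, energy = NA_real_,
              voxels = NA_integer_, skipped = FALSE)
  if (is.null(state$model)) {
    state$model <- input
    state$model_volume <- mesh_to_tsdf(input, config$tsdf$voxel,
                                       config$tsdf$truncation,
                                       sign = config$tsdf$sign)
    rec$voxels <- nrow(state$model_volume$ijk)
  } else {
    L <- config$graph$edge_length
    mg <- build_deformation_graph(state$model, L, config$graph$iterations)
    ig <- build_deformation_graph(input, L, config$graph$iterations)
    md <- shot_descriptors(mg, config$shot$radius)
    id <- shot_descriptors(ig, config$shot$radius)
    # consecutive frames move little, so descriptors are augmented with
    # weighted keypoint positions: mutual nearest neighbors then combine
    # shape similarity with spatial plausibility
    lam <- config$shot$position_weight
    am <- list(descriptors = cbind(md$descriptors,
                                   lam * mg$graph_mesh$vertices),
               empty = md$empty)
    ai <- list(descriptors = cbind(id$descriptors,
                                   lam * ig$graph_mesh$vertices),
               empty = id$empty)
    matches <- match_bidirectional(am, ai, config$shot$max_distance)
    # geometric sanity filter: between consecutive frames true keypoint
    # motion is small, so pairs with implausibly large spatial displacement
    # are descriptor mismatches and are dropped
    if (nrow(matches) > 0) {
      disp <- sqrt(rowSums((
        ig$graph_mesh$vertices[matches$input_keypoint, , drop = FALSE] -
        mg$graph_mesh$vertices[matches$model_keypoint, , drop = FALSE])^2))
      cap <- config$shot$max_displacement
      if (is.null(cap)) cap <- max(3 * stats::median(disp), 2 * L)
      matches <- matches[disp <= cap, , drop = FALSE]
    }
    rec$matches <- nrow(matches)
    if (nrow(matches) == 0) {
      warning("frame ", frame$frame_index,
              ": no mutual keypoint matches; frame skipped")
      rec$skipped <- TRUE
      state$log <- c(state$log, list(rec))
      return(state)
    }
    cons <- propagate_constraints(state$model, mg, ig, matches)
    prob <- deformation_problem(state$model, cons$idx, cons$pos,
                                alpha = config$deform$alpha,
                                max_iterations = config$deform$max_iterations,
                                tolerance = config$deform$tolerance)
    dres <- deform(prob)
    rec$energy <- dres$energy_trace[length(dres$energy_trace)]
    mv <- mesh_to_tsdf(dres$S_prime, config$tsdf$voxel, config$tsdf$truncation,
                       sign = config$tsdf$sign)
    # the warped historical model carries more uncertainty than a fresh
    # observation: scale its confidence down so the fused surface tracks
    # the current frame where both observe the same region
    mv$weight <- mv$weight * config$tsdf$model_weight_scale
    iv <- mesh_to_tsdf(input, config$tsdf$voxel, config$tsdf$truncation,
                       sign = config$tsdf$sign)
    fused <- tsdf_fuse(mv, iv, config$tsdf$max_weight)
    state$model_volume <- fused
    rec$voxels <- nrow(fused$ijk)
    merged <- extract_mesh(fused, min_weight = config$tsdf$min_weight)
    if (nrow(merged$triangles) > 0)
      state$model <- .mesh_postpass(merged, config)
  }
  state$frames_processed <- state$frames_processed + 1L
  state$log <- c(state$log, list(rec))
  state
}

#' Finalize the reconstruction
#'
#' Applies the final smoothing and outlier pass, regenerates an isotropic
#' surface, then (when sensor readings are given) colorizes one model copy
#' per variable and exports everything as PLY.
#'
#' @param state a processed `reconstruction_state` (>= 1 frame).
#' @param config a [pipeline_config()].
#' @param sensors optional data frame from [read_sensor_csv()].
#' @param out_dir optional output directory for the PLY exports (the
#'   uncolored `model.ply` plus one `model_<variable>.ply` per variable).
#' @return The final uncolored [surface_mesh()], with colorized copies in
#'   attribute `colorized`.
#' @export
finalize_model <- function(state, config = pipeline_config(), sensors = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(state, "reconstruction_state"),
            state$frames_processed >= 1, !is.null(state$model))
  model <- .mesh_postpass(state$model, config)
  if (nrow(model$triangles) > 0)
    model <- isotropic_remesh(model, config$final$edge_length,
                              config$final$iterations)
  colorized <- NULL
  if (!is.null(sensors)) {
    colorized <- colorize_by_sensors(model, sensors,
                                     ramps = config$color$ramps,
                                     height_axis = config$color$height_axis)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ply(model, file.path(out_dir, "model.ply"))
    for (v in names(colorized))
      write_ply(colorized[[v]], file.path(out_dir, sprintf("model_%s.ply", v)))
  }
  attr(model, "colorized") <- colorized
  model
}

#' Run the full reconstruction over a frame sequence
#'
#' @param frames list of [depth_frame()] objects (e.g. from
#'   [read_depth_sequence()]) indexed by their `frame_index`.
#' @param config a [pipeline_config()]; frames are selected by
#'   `frame_start`/`frame_end`/`frame_step` against each frame's index.
#' @param sensors optional sensor readings data frame.
#' @param out_dir optional export directory.
#' @param verbose log per-frame records to stderr.
#' @return The final model mesh (see [finalize_model()]); the state is
#'   attached as attribute `state`.
#' @export
reconstruct <- function(frames, config = pipeline_config(), sensors = NULL,
                        out_dir = NULL, verbose = TRUE) {
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  sel <- select_frames(config$frame_start, config$frame_end, config$frame_step)
  use <- which(idx %in% sel)
  if (length(use) == 0) stop("no frames fall inside the selection window")
  state <- new_reconstruction_state()
  for (u in use) {
    state <- process_frame(state, frames[[u]], config)
    if (verbose) {
      r <- state$log[[length(state$log)]]
      message(sprintf(
        "frame %d: %d input vertices, %s matches, energy %s, %s voxels%s",
        r$frame_index, r$input_vertices,
        ifelse(is.na(r$matches), "-", r$matches),
        ifelse(is.na(r$energy), "-", sprintf("%.3g", r$energy)),
        ifelse(is.na(r$voxels), "-", r$voxels),
        ifelse(r$skipped, " [skipped]", "")))
    }
  }
  model <- finalize_model(state, config, sensors, out_dir)
  attr(model, "state") <- state
  model
}
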