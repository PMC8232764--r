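# Logarithmic background removal.
#
# A percentage cutoff factor f_bg is converted into an absolute depth
# threshold by mapping [0, 1] onto [1, b] through x_b = b^f_bg (so that
# log_b(1) = 0 and log_b(b) = 1 bracket the factor range), then linearly
# relating [1, b] to the cloud's depth range [d_min, d_max]:
#
#   (b - x_b) / (b - 1) = (d_max - d_bg) / (d_max - d_min)
#   d_bg = -((b - b^f_bg) / (b - 1)) * (d_max - d_min) + d_max
#
# Because (b^f - 1)/(b - 1) <= f for b > 1, the logarithmic threshold always
# sits at or below the linear one: near depths are favoured, which suits
# scenes whose subject is the closest object to the camera.

#' Logarithmic background cutoff depth
#'
#' @param f_bg cutoff factor in `[0, 1]` (dimensionless fraction of the depth
#'   range, taken through the logarithmic map).
#' @param b logarithm base, > 1. Larger bases cut closer to `d_min`.
#' @param d_min,d_max minimum and maximum depth in the cloud (metres).
#' @return Cutoff depth `d_bg` in metres; depths greater than it are
#'   background. Equals `d_min` at `f_bg = 0` and `d_max` at `f_bg = 1`.
#' @examples
#' cutoff_depth(0.2, 10, 0.29, 22.9)   # 1.76 m
#' cutoff_depth(0.2, 100, 0.29, 22.9)  # 0.63 m
#' @export
cutoff_depth <- function(f_bg, b, d_min, d_max) {
  stopifnot(f_bg >= 0, f_bg <= 1)
  if (b <= 1) stop("logarithm base must be > 1")
  if (d_max < d_min) stop("d_max must be >= d_min")
  delta_d <- d_max - d_min
  -((b - b^f_bg) / (b - 1)) * delta_d + d_max
}

#' Linear background cutoff depth (baseline)
#'
#' The plain pass-through threshold `d_min + f_bg * (d_max - d_min)`, kept as
#' the reference the logarithmic filter is compared against.
#'
#' @inheritParams cutoff_depth
#' @return Cutoff depth in metres.
#' @export
linear_cutoff_depth <- function(f_bg, d_min, d_max) {
  stopifnot(f_bg >= 0, f_bg <= 1)
  if (d_max < d_min) stop("d_max must be >= d_min")
  d_min + f_bg * (d_max - d_min)
}

#' Remove background points by logarithmic depth threshold
#'
#' Depth is the z coordinate (optical-axis distance): the filter is a
#' pass-through filter on z. `d_min`/`d_max` are recomputed from the cloud
#' per call unless fixed values are supplied, which makes the cut adapt to
#' each frame's depth range.
#'
#' @param cloud a [point_cloud()].
#' @param f_bg cutoff factor in `[0, 1]`.
#' @param b logarithm base (> 1), default 10.
#' @param fixed_dmin,fixed_dmax optional fixed depth range overriding the
#'   per-cloud range.
#' @return The filtered [point_cloud()], input order preserved. A degenerate
#'   cloud (`d_min == d_max`) is returned unchanged.
#' @export
remove_background <- function(cloud, f_bg = 0.2, b = 10,
                              fixed_dmin = NULL, fixed_dmax = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (nrow(cloud$points) == 0) return(cloud)
  z <- cloud$points[, 3]
  z_valid <- z[z > 0]
  d_min <- if (is.null(fixed_dmin)) min(z_valid) else fixed_dmin
  d_max <- if (is.null(fixed_dmax)) max(z_valid) else fixed_dmax
  if (d_min == d_max) return(cloud)
  d_bg <- cutoff_depth(f_bg, b, d_min, d_max)
  subset_cloud(cloud, which(z > 0 & z <= d_bg))
}

# subset a cloud preserving parallel arrays and order
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              normals = if (!is.null(cloud$normals))
                cloud$normals[idx, , drop = FALSE],
              colors = if (!is.null(cloud$colors))
                cloud$colors[idx, , drop = FALSE])
}
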