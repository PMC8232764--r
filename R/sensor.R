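# Fusion of height-indexed environmental sensor readings into the model by
# linear color interpolation: each reading becomes an RGB stop at its
# mounting height and the model is gradient-colored between stops.

#' Linear color ramp
#'
#' @param x_min,x_max variable limits (same units as the measured value);
#'   `x_min < x_max`.
#' @param c_min,c_max RGB triplets (each channel in `[0, 255]`) at the two
#'   limits; channels interpolate independently.
#' @return An object of class `color_ramp`.
#' @export
color_ramp <- function(x_min, x_max, c_min, c_max) {
  if (x_min >= x_max) stop("invalid ramp: x_min must be < x_max")
  stopifnot(length(c_min) == 3, length(c_max) == 3,
            all(c_min >= 0 & c_min <= 255), all(c_max >= 0 & c_max <= 255))
  structure(list(x_min = x_min, x_max = x_max,
                 c_min = as.numeric(c_min), c_max = as.numeric(c_max)),
            class = "color_ramp")
}

#' Default ramps for the three monitored variables
#'
#' Temperature runs blue (cold) to red (hot), humidity white (dry) to blue
#' (wet), luminosity black (dark) to yellow (bright).
#'
#' @param variable one of `"temperature"`, `"humidity"`, `"luminosity"`.
#' @return A [color_ramp()].
#' @export
default_ramp <- function(variable = c("temperature", "humidity", "luminosity")) {
  switch(match.arg(variable),
    temperature = color_ramp(15, 40, c(0, 0, 255), c(255, 0, 0)),
    humidity = color_ramp(20, 90, c(255, 255, 255), c(0, 0, 255)),
    luminosity = color_ramp(0, 60000, c(0, 0, 0), c(255, 255, 0))
  )
}

#' Interpolate one color channel on a ramp
#'
#' `c(x) = c_min + (x - x_min)/(x_max - x_min) * (c_max - c_min)`; values of
#' `x` outside the limits are clamped before interpolation.
#'
#' @param x measured value(s).
#' @param ramp a [color_ramp()].
#' @param channel 1 (red), 2 (green) or 3 (blue).
#' @return Interpolated channel value(s) in `[0, 255]` (unrounded).
#' @export
interp_channel <- function(x, ramp, channel) {
  stopifnot(inherits(ramp, "color_ramp"), channel %in% 1:3)
  x <- pmin(pmax(x, ramp$x_min), ramp$x_max)
  ramp$c_min[channel] + (x - ramp$x_min) / (ramp$x_max - ramp$x_min) *
    (ramp$c_max[channel] - ramp$c_min[channel])
}

#' Map sensor readings to per-height RGB stops
#'
#' @param readings data frame with columns `height_m` and `value` (one
#'   variable), heights strictly increasing; at least 2 rows.
#' @param ramp a [color_ramp()] for the variable.
#' @return A list with `heights` and `colors` (k x 3 matrix, unrounded).
#' @export
readings_to_colors <- function(readings, ramp) {
  stopifnot(nrow(readings) >= 2)
  if (anyDuplicated(readings$height_m))
    stop("duplicate sensor heights for one variable")
  o <- order(readings$height_m)
  readings <- readings[o, ]
  cols <- vapply(1:3, function(ch) interp_channel(readings$value, ramp, ch),
                 numeric(nrow(readings)))
  list(heights = readings$height_m, colors = matrix(cols, ncol = 3))
}

#' Gradient-colorize a model from height-indexed color stops
#'
#' Each vertex's height-axis coordinate is interpolated piecewise-linearly
#' between the bracketing stops `(h_{i-1}, h_i)` / `(RGB_{i-1}, RGB_i)`;
#' heights below the first or above the last stop clamp to the end colors.
#' Geometry and connectivity are untouched — only vertex colors change.
#'
#' @param mesh a [surface_mesh()].
#' @param heights sorted stop heights (metres), length >= 2.
#' @param colors k x 3 RGB stop matrix.
#' @param height_axis which vertex coordinate carries height: `"x"`, `"y"`,
#'   `"z"`, or a negated form `"-y"` for axes pointing downward (the optical
#'   camera frame's y axis points down, so height there is `-y`).
#' @return The mesh with `vertex_colors` set (bytes, round-half-up).
#' @export
colorize_model <- function(mesh, heights, colors, height_axis = "-y") {
  stopifnot(inherits(mesh, "surface_mesh"), length(heights) >= 2,
            !is.unsorted(heights), nrow(colors) == length(heights))
  if (nrow(mesh$vertices) == 0) return(mesh)
  ax <- sub("^-", "", height_axis)
  sgn <- if (startsWith(height_axis, "-")) -1 else 1
  col_i <- match(ax, c("x", "y", "z"))
  if (is.na(col_i)) stop("height_axis must be one of x, y, z, -x, -y, -z")
  h <- sgn * mesh$vertices[, col_i]
  vc <- vapply(1:3, function(ch) {
    stats::approx(heights, colors[, ch], xout = h, rule = 2)$y
  }, numeric(length(h)))
  mesh$vertex_colors <- matrix(floor(vc + 0.5), ncol = 3)
  mesh
}

#' Read per-plant sensor readings from CSV
#'
#' Expected columns: `variable` (temperature | humidity | luminosity),
#' `height_m`, `value`.
#'
#' @param path CSV file path.
#' @return A data frame with one row per reading.
#' @export
read_sensor_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "height_m", "value")
  if (!all(need %in% names(df)))
    stop("sensor CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Colorize one model copy per sensor variable
#'
#' @param mesh the final model [surface_mesh()].
#' @param readings data frame from [read_sensor_csv()].
#' @param ramps named list of [color_ramp()] per variable (defaults via
#'   [default_ramp()]).
#' @param height_axis forwarded to [colorize_model()].
#' @return Named list of colorized meshes, one per variable present.
#' @export
colorize_by_sensors <- function(mesh, readings, ramps = NULL,
                                height_axis = "-y") {
  vars <- unique(readings$variable)
  out <- list()
  for (v in vars) {
    ramp <- if (!is.null(ramps[[v]])) ramps[[v]] else default_ramp(v)
    stops <- readings_to_colors(readings[readings$variable == v, ], ramp)
    out[[v]] <- colorize_model(mesh, stops$heights, stops$colors, height_axis)
  }
  out
}
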