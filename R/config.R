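#' Run configuration for the circumnutation pipeline
#'
#' Bundles the tunable parameters shared by the segmentation and feature
#' stages. Defaults follow the acquisition protocol the package targets:
#' time-lapse at 0.0056 Hz (one frame every ~178.6 s), a five-sample moving
#' average on the turning-angle signal, and a direction tolerance of 1.2 rad
#' around \eqn{\pm 2\pi} for the handedness rule.
#'
#' @param frame_interval_s Nominal time between frames in seconds. Used when a
#'   trajectory carries no explicit timestamps. Default `1 / 0.0056`.
#' @param smoothing_window Width (samples) of the centred moving average
#'   applied to the turning-angle series before peak picking. Odd, >= 3.
#' @param min_prominence Minimum prominence (radians) a local maximum of the
#'   smoothed turning-angle series must have to delimit a circumnutation.
#'   Set to 0 for literal every-local-maximum segmentation.
#' @param direction_tolerance Half-width (radians) of the acceptance band
#'   around \eqn{\pm 2\pi} for the signed turning sum in the
#'   clockwise/counterclockwise rule. Must lie in (0, pi).
#' @param raster_resolution_mm Cell size (mm) of the grid used to rasterize a
#'   circumnutation's planar loop for area/centroid computation.
#' @param stimulus Optional [stimulus()] object (support position).
#' @param speed_unit `"mm/h"` (default) or `"mm/s"` for reported speeds.
#' @param seed Optional integer seed recorded with the run.
#'
#' @return An object of class `cn_config` (a named list).
#' @export
run_config <- function(frame_interval_s = 1 / 0.0056,
                       smoothing_window = 5L,
                       min_prominence = pi / 2,
                       direction_tolerance = 1.2,
                       raster_resolution_mm = 0.1,
                       stimulus = NULL,
                       speed_unit = c("mm/h", "mm/s"),
                       seed = NULL) {
  speed_unit <- match.arg(speed_unit)
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    stopf("frame_interval_s must be a positive number")
  }
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 3L || smoothing_window %% 2L == 0L) {
    stopf("smoothing_window must be odd and >= 3 (got %d)", smoothing_window)
  }
  if (direction_tolerance <= 0 || direction_tolerance >= pi) {
    stopf("direction_tolerance must lie in (0, pi)")
  }
  if (raster_resolution_mm <= 0) stopf("raster_resolution_mm must be > 0")
  if (min_prominence < 0) stopf("min_prominence must be >= 0")
  if (!is.null(stimulus) && !inherits(stimulus, "cn_stimulus")) {
    stopf("stimulus must be created with stimulus()")
  }
  structure(
    list(
      frame_interval_s = frame_interval_s,
      smoothing_window = smoothing_window,
      min_prominence = min_prominence,
      direction_tolerance = direction_tolerance,
      raster_resolution_mm = raster_resolution_mm,
      stimulus = stimulus,
      speed_unit = speed_unit,
      seed = seed
    ),
    class = "cn_config"
  )
}

#' Stimulus (support) description
#'
#' Position of the support the plant moves toward, used for the
#' stimulus-relative features. The `point` model measures 3D distances to a
#' fixed point; the `vertical-line` model measures planar X-Z distances to a
#' vertical pole through (x, z).
#'
#' @param x,z Planar position of the stimulus (mm, plant frame).
#' @param y Optional height coordinate (mm); required for the `point` model.
#' @param model `"vertical-line"` (default) or `"point"`.
#' @param radius_mm Optional support radius (informational only).
#' @return Object of class `cn_stimulus`.
#' @export
stimulus <- function(x, z, y = NULL, model = c("vertical-line", "point"),
                     radius_mm = NULL) {
  model <- match.arg(model)
  if (!is.finite(x) || !is.finite(z)) stopf("stimulus position must be finite")
  if (model == "point") {
    if (is.null(y) || !is.finite(y)) {
      stopf("the point stimulus model requires a finite y coordinate")
    }
  }
  structure(
    list(x = x, z = z, y = y, model = model, radius_mm = radius_mm),
    class = "cn_stimulus"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file holds top-level keys matching the arguments of [run_config()];
#' the stimulus is a nested section with keys `x`, `z`, optional `y`,
#' `model`, `radius_mm`.
#'
#' @param path Path to a YAML configuration file.
#' @return A `cn_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  stim <- NULL
  if (!is.null(raw$stimulus)) {
    s <- raw$stimulus
    stim <- stimulus(
      x = s$x, z = s$z, y = s$y,
      model = if (is.null(s$model)) "vertical-line" else s$model,
      radius_mm = s$radius_mm
    )
  }
  args <- raw[intersect(
    names(raw),
    c("frame_interval_s", "smoothing_window", "min_prominence",
      "direction_tolerance", "raster_resolution_mm", "speed_unit", "seed")
  )]
  args$stimulus <- stim
  do.call(run_config, args)
}
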