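# Kinematic feature catalogue: per-circumnutation, whole-movement, per-point
# and stimulus-relative families. All internal computation is in mm and
# seconds; reported speeds follow the configured unit (default mm/h).

circ_traj <- function(circ) {
  if (inherits(circ, "cn_circumnutation")) circ$traj
  else if (inherits(circ, "cn_traj3d")) circ
  else stopf("expected a cn_circumnutation or cn_traj3d")
}

speed_factor <- function(unit) if (unit == "mm/h") 3600 else 1

#' 3D path length of a circumnutation
#'
#' Sum of the Euclidean distances between subsequent 3D point positions
#' (the line integral of the sampled path).
#'
#' @param circ A `cn_circumnutation` or `cn_traj3d` (>= 2 points).
#' @return Path length in mm.
#' @export
path_length <- function(circ) {
  traj <- circ_traj(circ)
  if (nrow(traj) < 2L) stopf("need >= 2 points for a path length")
  sum(row_norms(diff(traj_xyz(traj))))
}

#' Speed statistics over a circumnutation
#'
#' Per-segment speed is the 3D segment length divided by the time between
#' its two frames; the statistics are taken over segments.
#'
#' @param circ A `cn_circumnutation` or `cn_traj3d`.
#' @param unit `"mm/h"` (default) or `"mm/s"`.
#' @return Named vector `c(mean, max, min)` in the requested unit.
#' @export
speed_stats <- function(circ, unit = c("mm/h", "mm/s")) {
  unit <- match.arg(unit)
  traj <- circ_traj(circ)
  mv <- movement_vectors(traj)
  if (any(mv$dt <= 0)) stopf("non-positive frame interval in trajectory")
  v <- mv$norm3d / mv$dt * speed_factor(unit)
  c(mean = mean(v), max = max(v), min = min(v))
}

#' Planar centre of a circumnutation
#'
#' Geometric centre of gravity in the X-Z plane: the mean of each coordinate
#' over all trajectory points of the circumnutation.
#'
#' @param circ A `cn_circumnutation` or `cn_traj3d`.
#' @return Named vector `c(x, z)` in mm.
#' @export
circ_center <- function(circ) {
  traj <- circ_traj(circ)
  c(x = mean(traj$x), z = mean(traj$z))
}

#' Rasterized centroid and area of a circumnutation loop
#'
#' The planar X-Z polyline is closed into a polygon and rasterized on a grid
#' of the given resolution with the even-odd fill rule (so self-intersecting
#' loops still enclose a defined region). The centroid is the mean position
#' of the filled cells and the area their count times the cell area.
#'
#' @param circ A `cn_circumnutation` or `cn_traj3d` (>= 3 points).
#' @param resolution_mm Grid cell size in mm (default 0.1).
#' @return List with `centroid` (named x/z, mm), `area_mm2`, and `n_cells`.
#'   Degenerate (collinear) polygons get area 0, the vertex mean as
#'   centroid, and a warning.
#' @export
centroid_and_area <- function(circ, resolution_mm = 0.1) {
  traj <- circ_traj(circ)
  if (nrow(traj) < 3L) stopf("need >= 3 points to enclose an area")
  if (resolution_mm <= 0) stopf("resolution must be > 0")
  px <- traj$x; pz <- traj$z
  # drop consecutive duplicates; close the polygon implicitly
  keep <- c(TRUE, diff(px) != 0 | diff(pz) != 0)
  px <- px[keep]; pz <- pz[keep]
  degenerate_out <- function() {
    warnf("degenerate (collinear) circumnutation polygon; area set to 0")
    list(centroid = c(x = mean(traj$x), z = mean(traj$z)),
         area_mm2 = 0, n_cells = 0L)
  }
  if (length(px) < 3L) return(degenerate_out())
  # collinearity check via the shoelace area of the vertex polygon
  shoelace <- abs(sum(px * c(pz[-1], pz[1]) - c(px[-1], px[1]) * pz)) / 2
  if (shoelace < resolution_mm^2) return(degenerate_out())
  xs <- seq(floor(min(px) / resolution_mm) * resolution_mm + resolution_mm / 2,
            max(px), by = resolution_mm)
  zs <- seq(floor(min(pz) / resolution_mm) * resolution_mm + resolution_mm / 2,
            max(pz), by = resolution_mm)
  gx <- rep(xs, times = length(zs))
  gz <- rep(zs, each = length(xs))
  # even-odd rule: count edge crossings of a ray cast in +x from each cell
  crossings <- integer(length(gx))
  nv <- length(px)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- px[i]; zi <- pz[i]; xj <- px[j]; zj <- pz[j]
    if (zi != zj) {
      hit <- ((zi > gz) != (zj > gz)) &
        (gx < (xj - xi) * (gz - zi) / (zj - zi) + xi)
      crossings <- crossings + hit
    }
    j <- i
  }
  inside <- crossings %% 2L == 1L
  n_cells <- sum(inside)
  if (n_cells == 0L) return(degenerate_out())
  res <- list(
    centroid = c(x = mean(gx[inside]), z = mean(gz[inside])),
    area_mm2 = n_cells * resolution_mm^2,
    n_cells = n_cells
  )
  cn_log("centroid_and_area: res=%.3g mm, %d filled cells, area=%.3f mm^2",
         resolution_mm, n_cells, res$area_mm2)
  res
}

#' Main axis of a circumnutation
#'
#' The longest chord of the planar trajectory: the maximum pairwise distance
#' between two trajectory points in the X-Z plane (exact; computed on the
#' convex hull).
#'
#' @param circ A `cn_circumnutation` or `cn_traj3d` (>= 2 points).
#' @return List with `length_mm` and `endpoints` (2 x 2 matrix, x/z rows).
#' @export
main_axis <- function(circ) {
  traj <- circ_traj(circ)
  if (nrow(traj) < 2L) stopf("need >= 2 points for a main axis")
  pts <- cbind(traj$x, traj$z)
  upts <- unique(pts)
  idx <- if (nrow(upts) >= 3L) grDevices::chull(upts) else seq_len(nrow(upts))
  hull <- upts[idx, , drop = FALSE]
  dm <- as.matrix(stats::dist(hull))
  w <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  list(
    length_mm = max(dm),
    endpoints = hull[c(w[1], w[2]), , drop = FALSE]
  )
}

#' Rotation direction of a circumnutation
#'
#' Sums the signed turning angles between consecutive planar movement
#' vectors (each difference wrapped to (-pi, pi\]; counterclockwise positive
#' in the X-Z plane seen from +y). A sum within `2*pi +/- tolerance` is
#' counterclockwise, within `-2*pi +/- tolerance` clockwise, anything else
#' unassigned (`"none"`). Zero-length vectors are skipped.
#'
#' @param circ A `cn_circumnutation` or `cn_traj3d`.
#' @param tolerance Acceptance half-width in radians (default 1.2).
#' @return Character scalar `"counterclockwise"`, `"clockwise"` or `"none"`,
#'   with the turning sum (radians) as attribute `turning_sum`.
#' @export
circ_direction <- function(circ, tolerance = 1.2) {
  traj <- circ_traj(circ)
  mv <- movement_vectors(traj)
  keep <- sqrt(mv$dx^2 + mv$dz^2) > 0
  dx <- mv$dx[keep]; dz <- mv$dz[keep]
  if (length(dx) < 3L) {
    return(structure("none", turning_sum = NA_real_))
  }
  ang <- atan2(dz, dx)
  turn <- wrap_pi(diff(ang))
  s <- sum(turn)
  dir <- if (abs(s - 2 * pi) <= tolerance) {
    "counterclockwise"
  } else if (abs(s + 2 * pi) <= tolerance) {
    "clockwise"
  } else {
    "none"
  }
  structure(dir, turning_sum = s)
}

#' Per-circumnutation feature table
#'
#' Computes the full per-circumnutation feature family for a list of
#' segmented circumnutations: duration, speed statistics, 3D path length,
#' planar centre and rasterized centroid with their distances from the
#' plant origin and their cycle-to-cycle speeds, main axis, enclosed area
#' and rotation direction. Column names follow the conventional feature
#' identifiers (`duration_circumnutation`, `line_integral`, ...);
#' `line_integral` is an alias of the 3D path length.
#'
#' @param circs List of `cn_circumnutation` from [segment_circumnutations()].
#' @param config A [run_config()].
#' @return `data.frame`, one row per circumnutation. Centre/centroid speeds
#'   (displacement between consecutive circumnutations' centres over the
#'   time between their midpoints) are `NA` for the last circumnutation.
#' @export
circ_features <- function(circs, config = run_config()) {
  if (!length(circs)) stopf("no circumnutations to compute features for")
  unit <- config$speed_unit
  n <- length(circs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- circs[[i]]
    traj <- ci$traj
    dur <- traj$time_s[nrow(traj)] - traj$time_s[1]
    sp <- speed_stats(ci, unit)
    ctr <- circ_center(ci)
    ca <- centroid_and_area(ci, config$raster_resolution_mm)
    ax <- main_axis(ci)
    dir <- circ_direction(ci, config$direction_tolerance)
    rows[[i]] <- data.frame(
      circumnutation = i,
      start_frame = ci$start_frame,
      end_frame = ci$end_frame,
      t_mid_s = (traj$time_s[1] + traj$time_s[nrow(traj)]) / 2,
      duration_circumnutation = dur,
      mean_speed_circumnutations = sp[["mean"]],
      max_speed_circumnutations = sp[["max"]],
      min_speed_circumnutations = sp[["min"]],
      line_integral = path_length(ci),
      x_center_coordinates_XZ = ctr[["x"]],
      z_center_coordinates_XZ = ctr[["z"]],
      center_distance_from_origin = sqrt(sum(ctr^2)),
      x_centroid_coordinates_XZ = ca$centroid[["x"]],
      z_centroid_coordinates_XZ = ca$centroid[["z"]],
      centroid_distance_from_origin = sqrt(sum(ca$centroid^2)),
      length_major_axis = ax$length_mm,
      area_circumnutation = ca$area_mm2,
      direction = as.character(dir),
      turning_sum = attr(dir, "turning_sum"),
      axis_x1 = ax$endpoints[1, 1], axis_z1 = ax$endpoints[1, 2],
      axis_x2 = ax$endpoints[2, 1], axis_z2 = ax$endpoints[2, 2]
    )
  }
  tab <- do.call(rbind, rows)
  # centre/centroid speeds between consecutive circumnutations
  fac <- speed_factor(unit)
  dtm <- diff(tab$t_mid_s)
  dcen <- sqrt(diff(tab$x_center_coordinates_XZ)^2 +
                 diff(tab$z_center_coordinates_XZ)^2)
  dctd <- sqrt(diff(tab$x_centroid_coordinates_XZ)^2 +
                 diff(tab$z_centroid_coordinates_XZ)^2)
  tab$speed_center_XZ <- c(dcen / dtm * fac, NA_real_)
  tab$speed_centroid_XZ <- c(dctd / dtm * fac, NA_real_)
  cn_log("circ_features: %d circumnutations, speeds in %s", n, unit)
  tab
}

#' Whole-movement features
#'
#' @param feats Per-circumnutation table from [circ_features()].
#' @return One-row `data.frame`: `max_path_length` (mm), `max_area` (mm^2)
#'   and `direction_switches` - the number of adjacent circumnutation pairs
#'   whose assigned directions differ, skipping unassigned (`"none"`)
#'   entries.
#' @export
whole_features <- function(feats) {
  if (!nrow(feats)) stopf("empty feature table")
  dirs <- feats$direction[feats$direction != "none"]
  switches <- if (length(dirs) > 1L) sum(dirs[-1] != dirs[-length(dirs)]) else 0L
  data.frame(
    max_path_length = max(feats$line_integral),
    max_area = max(feats$area_circumnutation),
    direction_switches = switches
  )
}

#' Point-related features over the whole movement
#'
#' Speed statistics over the entire trajectory and the time at which the
#' maximum speed occurs - as absolute time (midpoint of the fastest
#' segment) and as a percentage of the whole movement duration.
#'
#' @param traj A `cn_traj3d` (>= 2 frames).
#' @param unit `"mm/h"` (default) or `"mm/s"`.
#' @return One-row `data.frame`: `mean_speed`, `max_speed`,
#'   `time_of_max_speed_s`, `time_of_max_speed_pct`. For an all-stationary
#'   trajectory the maximum is 0 and the times are `NA`.
#' @export
point_features <- function(traj, unit = c("mm/h", "mm/s")) {
  unit <- match.arg(unit)
  stopifnot(inherits(traj, "cn_traj3d"))
  mv <- movement_vectors(traj)
  v <- mv$norm3d / mv$dt * speed_factor(unit)
  if (max(v) == 0) {
    return(data.frame(mean_speed = 0, max_speed = 0,
                      time_of_max_speed_s = NA_real_,
                      time_of_max_speed_pct = NA_real_))
  }
  imax <- which.max(v)
  tmax <- mv$t_mid[imax]
  t0 <- traj$time_s[1]; t1 <- traj$time_s[nrow(traj)]
  data.frame(
    mean_speed = mean(v),
    max_speed = max(v),
    time_of_max_speed_s = tmax - t0,
    time_of_max_speed_pct = 100 * (tmax - t0) / (t1 - t0)
  )
}

#' Stimulus-relative features
#'
#' Distances of each circumnutation's centre and centroid from the stimulus
#' in the X-Z plane, the angle between the circumnutation main axis and the
#' plant-stimulus axis (undirected, folded into \[0, 90\] degrees), and the
#' minimum distance between the trajectory and the stimulus (3D for the
#' point model, planar for the vertical-line model).
#'
#' @param circs List of `cn_circumnutation`.
#' @param feats Matching table from [circ_features()].
#' @param stim A [stimulus()].
#' @param plant_origin_xz Planar plant origin (default `c(0, 0)`; the plant
#'   frame puts it there).
#' @return `data.frame`, one row per circumnutation:
#'   `center_distance_from_stimulus`, `centroid_distance_from_stimulus`,
#'   `angle_axis_stimulus` (degrees), `min_dist_stimulus` (mm). The angle is
#'   `NA` (with a warning) when the stimulus coincides with the plant
#'   origin.
#' @export
stimulus_features <- function(circs, feats, stim,
                              plant_origin_xz = c(0, 0)) {
  stopifnot(inherits(stim, "cn_stimulus"))
  if (length(circs) != nrow(feats)) {
    stopf("circs and feature table disagree (%d vs %d)",
          length(circs), nrow(feats))
  }
  sxz <- c(stim$x, stim$z)
  axis_vec <- sxz - plant_origin_xz
  axis_ok <- sqrt(sum(axis_vec^2)) > 1e-12
  if (!axis_ok) {
    warnf("stimulus coincides with the plant origin; axis angle undefined")
  }
  n <- length(circs)
  out <- data.frame(
    circumnutation = seq_len(n),
    center_distance_from_stimulus = numeric(n),
    centroid_distance_from_stimulus = numeric(n),
    angle_axis_stimulus = NA_real_,
    min_dist_stimulus = numeric(n)
  )
  for (i in seq_len(n)) {
    traj <- circs[[i]]$traj
    out$center_distance_from_stimulus[i] <- sqrt(
      (feats$x_center_coordinates_XZ[i] - stim$x)^2 +
        (feats$z_center_coordinates_XZ[i] - stim$z)^2
    )
    out$centroid_distance_from_stimulus[i] <- sqrt(
      (feats$x_centroid_coordinates_XZ[i] - stim$x)^2 +
        (feats$z_centroid_coordinates_XZ[i] - stim$z)^2
    )
    if (axis_ok) {
      chord <- c(feats$axis_x2[i] - feats$axis_x1[i],
                 feats$axis_z2[i] - feats$axis_z1[i])
      cosang <- abs(sum(chord * axis_vec)) /
        (sqrt(sum(chord^2)) * sqrt(sum(axis_vec^2)))
      out$angle_axis_stimulus[i] <- acos(min(1, cosang)) * 180 / pi
    }
    out$min_dist_stimulus[i] <- if (stim$model == "point") {
      min(sqrt((traj$x - stim$x)^2 + (traj$y - stim$y)^2 +
                 (traj$z - stim$z)^2))
    } else {
      min(sqrt((traj$x - stim$x)^2 + (traj$z - stim$z)^2))
    }
  }
  out
}

#' Write the feature tables to CSV files
#'
#' One file per feature family: `circ_features.csv` (one row per
#' circumnutation), `whole_features.csv` and `point_features.csv` (one
#' summary row each) and, when a stimulus is configured,
#' `stimulus_features.csv` (one row per circumnutation; omitted with a
#' logged notice otherwise).
#'
#' @param circ_feats,whole,point Tables from [circ_features()],
#'   [whole_features()], [point_features()].
#' @param stimulus_feats Optional table from [stimulus_features()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_feature_tables <- function(circ_feats, whole, point,
                                 stimulus_feats = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 6))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(paths, wr(circ_feats, "circ_features.csv"))
  paths <- c(paths, wr(whole, "whole_features.csv"))
  paths <- c(paths, wr(point, "point_features.csv"))
  if (!is.null(stimulus_feats)) {
    paths <- c(paths, wr(stimulus_feats, "stimulus_features.csv"))
  } else {
    cn_log("write_feature_tables: no stimulus configured, table omitted")
  }
  cn_log("write_feature_tables: %d circumnutation rows -> %s",
         nrow(circ_feats), dir)
  invisible(paths)
}
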