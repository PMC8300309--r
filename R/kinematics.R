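# Plant-frame transformation and segmentation of the movement into
# circumnutations via local maxima of the turning-angle (alpha) signal.

#' Plant reference frame
#'
#' The plant frame puts its origin at a stable point on the stem (the first
#' internode for pea plants) and its y-axis through a second point higher up
#' the stem (the second internode). The x and z axes span the horizontal
#' plane in which circumnutation is analysed.
#'
#' @param origin Length-3 world coordinates (mm) of the frame origin.
#' @param axis_point Length-3 world coordinates (mm) of a second point on
#'   the plant's vertical axis; must differ from `origin`.
#' @return Object of class `cn_plant_frame`.
#' @export
plant_frame <- function(origin, axis_point) {
  origin <- as.numeric(origin); axis_point <- as.numeric(axis_point)
  stopifnot(length(origin) == 3L, length(axis_point) == 3L)
  if (sqrt(sum((axis_point - origin)^2)) <= 1e-12) {
    stopf("origin and axis_point coincide; plant axis is undefined")
  }
  structure(list(origin = origin, axis_point = axis_point),
            class = "cn_plant_frame")
}

# Rotation matrix (world -> plant) for a plant frame. The y-axis maps to the
# plant axis; the in-plane orientation is fixed by projecting the world
# x-axis onto the plane perpendicular to the plant axis (world z-axis as
# fallback when the plant axis is parallel to world x).
plant_rotation <- function(pf) {
  yp <- pf$axis_point - pf$origin
  yp <- yp / sqrt(sum(yp^2))
  xw <- c(1, 0, 0)
  xp <- xw - sum(xw * yp) * yp
  if (sqrt(sum(xp^2)) < 1e-8) {
    zw <- c(0, 0, 1)
    xp <- zw - sum(zw * yp) * yp
  }
  xp <- xp / sqrt(sum(xp^2))
  zp <- c(xp[2] * yp[3] - xp[3] * yp[2],
          xp[3] * yp[1] - xp[1] * yp[3],
          xp[1] * yp[2] - xp[2] * yp[1])  # z = x cross y (right-handed)
  rbind(xp, yp, zp, deparse.level = 0)
}

#' Transform a 3D trajectory into the plant reference frame
#'
#' Rigid, orientation-preserving roto-translation: the plant origin maps to
#' (0,0,0) and the axis point to (0, d, 0) with d its distance from the
#' origin. All pairwise distances are preserved.
#'
#' @param traj A `cn_traj3d` in the camera/world frame.
#' @param pf A [plant_frame()].
#' @return A `cn_traj3d` with `reference_frame = "plant"`.
#' @export
to_plant_frame <- function(traj, pf) {
  stopifnot(inherits(traj, "cn_traj3d"), inherits(pf, "cn_plant_frame"))
  R <- plant_rotation(pf)
  p <- sweep(traj_xyz(traj), 2, pf$origin) %*% t(R)
  out <- trajectory3d(traj$frame, traj$time_s, p[, 1], p[, 2], p[, 3],
                      point_id = attr(traj, "point_id"),
                      reference_frame = "plant")
  cn_log("to_plant_frame: %d frames roto-translated", nrow(out))
  out
}

#' Frame-to-frame movement vectors
#'
#' Finite differences of positions and times between consecutive frames:
#' vector t joins the landmark position at frame t to its position at frame
#' t+1. The planar (dx, dz) component feeds the alpha-angle signal.
#'
#' @param traj A `cn_traj3d` (at least 2 frames).
#' @return `data.frame` with one row per frame pair: `dx, dy, dz` (mm),
#'   `dt` (s), `t_mid` (midpoint time, s) and `norm3d` (mm).
#' @export
movement_vectors <- function(traj) {
  stopifnot(inherits(traj, "cn_traj3d"))
  if (nrow(traj) < 2L) stopf("need at least 2 frames for movement vectors")
  p <- traj_xyz(traj)
  d <- diff(p)
  dt <- diff(traj$time_s)
  data.frame(
    dx = d[, 1], dy = d[, 2], dz = d[, 3],
    dt = dt,
    t_mid = (traj$time_s[-nrow(traj)] + traj$time_s[-1]) / 2,
    norm3d = row_norms(d)
  )
}

#' Alpha-angle series of a movement
#'
#' The alpha angle is the four-quadrant angle between the horizontal x-axis
#' and the planar (x-z) component of each movement vector, mapped to
#' \[0, 2*pi). A frame pair with zero planar displacement inherits the
#' previous angle (0 when there is no previous angle).
#'
#' @param mv Movement vectors from [movement_vectors()].
#' @return Numeric vector of angles in \[0, 2*pi), one per frame pair.
#' @export
alpha_series <- function(mv) {
  planar <- sqrt(mv$dx^2 + mv$dz^2)
  a <- wrap_2pi(atan2(mv$dz, mv$dx))
  zero <- planar == 0
  if (any(zero)) {
    prev <- 0
    for (i in seq_along(a)) {
      if (zero[i]) a[i] <- prev else prev <- a[i]
    }
  }
  a
}

#' Moving-average smoothing of the alpha series
#'
#' Centred moving average on the wrapped angle values (the sawtooth shape of
#' the series is deliberately preserved - its wrap discontinuities mark the
#' cycle boundaries). At the edges the window shrinks symmetrically so the
#' average stays centred.
#'
#' @param a Alpha series (radians).
#' @param window Odd window width in samples (default 5; 1 = identity).
#' @return Smoothed series, same length.
#' @export
smooth_alpha <- function(a, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 1L) stopf("window must be odd and >= 1")
  n <- length(a)
  if (window > n) stopf("window (%d) larger than series (%d)", window, n)
  if (window == 1L) return(a)
  h <- window %/% 2L
  cs <- cumsum(c(0, a))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + hi + 1L] - cs[i - hi]) / (2L * hi + 1L)
  }
  out
}

#' Local maxima of the smoothed alpha series
#'
#' Strict local maxima (greater than both neighbours; a plateau yields its
#' last index) filtered by topographic prominence: the peak height minus the
#' higher of the two valley floors separating it from the nearest greater
#' samples (or the series edges).
#'
#' @param a Smoothed alpha series.
#' @param min_prominence Minimum prominence in radians (default pi/2).
#' @return Integer indices of the retained maxima.
#' @export
find_alpha_maxima <- function(a, min_prominence = pi / 2) {
  n <- length(a)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (a[i] > a[i - 1L]) {
      j <- i
      while (j < n && a[j + 1L] == a[j]) j <- j + 1L  # walk plateau
      if (j < n && a[j + 1L] < a[j]) peaks <- c(peaks, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(peaks) || min_prominence <= 0) return(peaks)
  prom <- vapply(peaks, function(p) {
    left <- a[p]
    k <- p
    while (k > 1L && a[k - 1L] <= a[p]) {
      k <- k - 1L
      left <- min(left, a[k])
    }
    right <- a[p]
    k <- p
    while (k < n && a[k + 1L] <= a[p]) {
      k <- k + 1L
      right <- min(right, a[k])
    }
    a[p] - max(left, right)
  }, numeric(1))
  peaks[prom >= min_prominence]
}

#' Segment a plant-frame trajectory into circumnutations
#'
#' A circumnutation is the movement between two consecutive local maxima of
#' the smoothed alpha-angle signal. Frames before the first and after the
#' last maximum belong to no circumnutation.
#'
#' @param traj A `cn_traj3d` in the plant frame.
#' @param config A [run_config()]; uses `smoothing_window` and
#'   `min_prominence`.
#' @return List of `cn_circumnutation` objects; each holds the trajectory
#'   slice (`traj`), point-row indices `start`/`end` into `traj`'s parent,
#'   and the frame numbers spanned. Empty list (with a logged notice) when
#'   fewer than two maxima exist.
#' @export
segment_circumnutations <- function(traj, config = run_config()) {
  stopifnot(inherits(traj, "cn_traj3d"))
  if (attr(traj, "reference_frame") != "plant") {
    warnf("trajectory is not in the plant frame; segmenting as-is")
  }
  mv <- movement_vectors(traj)
  a <- alpha_series(mv)
  sm <- smooth_alpha(a, config$smoothing_window)
  peaks <- find_alpha_maxima(sm, config$min_prominence)
  if (length(peaks) < 2L) {
    cn_log("segment: %d alpha maxima found - no circumnutations", length(peaks))
    return(list())
  }
  circs <- vector("list", length(peaks) - 1L)
  for (j in seq_len(length(peaks) - 1L)) {
    s <- peaks[j]; e <- peaks[j + 1L]
    # alpha index t describes the movement from point row t to t+1; the
    # circumnutation between maxima s and e spans point rows s..e.
    slice <- trajectory3d(
      traj$frame[s:e], traj$time_s[s:e],
      traj$x[s:e], traj$y[s:e], traj$z[s:e],
      point_id = attr(traj, "point_id"), reference_frame = "plant"
    )
    circs[[j]] <- structure(
      list(traj = slice, start = s, end = e,
           start_frame = traj$frame[s], end_frame = traj$frame[e]),
      class = "cn_circumnutation"
    )
  }
  cn_log("segment: window=%d prominence=%.3f -> %d maxima, %d circumnutations",
         config$smoothing_window, config$min_prominence, length(peaks),
         length(circs))
  circs
}

#' @export
print.cn_circumnutation <- function(x, ...) {
  cat(sprintf("<cn_circumnutation> frames %d-%d (%d points, %.0f s)\n",
              x$start_frame, x$end_frame, nrow(x$traj),
              diff(range(x$traj$time_s))))
  invisible(x)
}
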