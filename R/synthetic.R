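# Ground-truthed simulator: elliptical-helix tip motion with drifting orbit
# centre, scheduled handedness switches and additive noise; stereo
# observations through distorting pinhole cameras; rendered blob stacks;
# simulated operator (rater) pairs. The test bed for every other module.

#' Simulation parameters for a circumnutating trajectory
#'
#' The tip moves on an ellipse in the horizontal X-Z plane whose centre
#' drifts linearly while the plant grows along y; per-cycle handedness can
#' switch on a schedule. Defaults mimic a pea seedling under the targeted
#' acquisition protocol: a ~10 mm orbit, a 1 h period sampled at the
#' time-lapse interval of one frame per ~179 s.
#'
#' @param a,b Ellipse semi-axes in mm (x and z respectively).
#' @param period_s Mean circumnutation period T in seconds.
#' @param period_sd_s Per-cycle Gaussian jitter of the period (s, default 0:
#'   perfectly rhythmic). Draws are truncated to \[T/2, 2T\].
#' @param amp_sd_frac Per-cycle fractional Gaussian jitter of the semi-axes
#'   (default 0). The amplitude scale is interpolated linearly within each
#'   cycle so the path stays continuous; draws are truncated to \[0.5, 1.5\].
#' @param n_cycles Number of cycles simulated (>= 1).
#' @param dt_s Frame interval in seconds; must satisfy `dt_s <= period_s/8`
#'   (coarser sampling cannot resolve a cycle).
#' @param drift_mm_h Length-2 planar drift velocity of the orbit centre
#'   `(vx, vz)` in mm/h.
#' @param growth_mm_h Vertical growth rate in mm/h.
#' @param direction_schedule `data.frame` with columns `cycle` (1-based
#'   cycle index at which the handedness takes effect) and `handedness`
#'   (`"counterclockwise"`/`"clockwise"`). Default: all counterclockwise.
#' @param noise_sd_mm Standard deviation of iid Gaussian positional noise
#'   per coordinate, mm.
#' @param phase_rad Initial phase of the ellipse parameter (default 0).
#' @param center_mm Length-3 initial position `(x, y, z)` of the orbit
#'   centre, mm.
#' @param stimulus Optional [stimulus()] carried as ground truth.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return Object of class `cn_sim_params`.
#' @export
sim_params <- function(a = 10, b = 10, period_s = 3600, period_sd_s = 0,
                       amp_sd_frac = 0, n_cycles = 10,
                       dt_s = 180,
                       drift_mm_h = c(0, 0), growth_mm_h = 2,
                       direction_schedule = NULL, noise_sd_mm = 0,
                       phase_rad = 0, center_mm = c(0, 50, 0),
                       stimulus = NULL, seed = 1L) {
  if (a <= 0 || b <= 0 || period_s <= 0 || dt_s <= 0) {
    stopf("a, b, period_s, dt_s must be > 0")
  }
  if (n_cycles < 1) stopf("n_cycles must be >= 1")
  if (noise_sd_mm < 0 || period_sd_s < 0 || amp_sd_frac < 0) {
    stopf("noise_sd_mm, period_sd_s, amp_sd_frac must be >= 0")
  }
  if (dt_s > period_s / 8) {
    stopf("dt_s = %g s undersamples the period (need dt_s <= T/8 = %g s)",
          dt_s, period_s / 8)
  }
  if (is.null(direction_schedule)) {
    direction_schedule <- data.frame(cycle = 1L,
                                     handedness = "counterclockwise")
  }
  check_columns(direction_schedule, c("cycle", "handedness"),
                "direction_schedule")
  if (!all(direction_schedule$handedness %in%
             c("clockwise", "counterclockwise"))) {
    stopf("handedness must be clockwise/counterclockwise")
  }
  structure(
    list(a = a, b = b, period_s = period_s, period_sd_s = period_sd_s,
         amp_sd_frac = amp_sd_frac, n_cycles = n_cycles, dt_s = dt_s,
         drift_mm_h = drift_mm_h, growth_mm_h = growth_mm_h,
         direction_schedule = direction_schedule, noise_sd_mm = noise_sd_mm,
         phase_rad = phase_rad, center_mm = center_mm, stimulus = stimulus,
         seed = as.integer(seed)),
    class = "cn_sim_params"
  )
}

# Handedness sign (+1 CCW, -1 CW) per cycle index.
schedule_signs <- function(params) {
  sched <- params$direction_schedule[order(params$direction_schedule$cycle), ]
  signs <- rep(1, params$n_cycles)
  current <- 1
  for (cy in seq_len(params$n_cycles)) {
    hit <- sched$handedness[sched$cycle <= cy]
    if (length(hit)) current <- if (hit[length(hit)] == "clockwise") -1 else 1
    signs[cy] <- current
  }
  signs
}

#' Generate a synthetic circumnutating trajectory with ground truth
#'
#' The noise-free tip position is
#' `x(t) = cx(t) + a cos(phi(t))`, `z(t) = cz(t) + b sin(phi(t))`,
#' `y(t) = y0 + growth * t`, with the phase advancing by `+/- 2*pi / T`
#' according to the handedness schedule (counterclockwise = increasing
#' phase) and the orbit centre drifting linearly. Gaussian noise is added
#' per coordinate.
#'
#' @param params A [sim_params()].
#' @return List with `traj` (a `cn_traj3d`, plant frame) and `truth`: the
#'   noise-free positions, per-frame phase and cycle index, per-cycle
#'   handedness, true period, ellipse area `pi*a*b` and centre path.
#' @export
gen_trajectory <- function(params) {
  stopifnot(inherits(params, "cn_sim_params"))
  set.seed(params$seed)
  nc <- params$n_cycles
  # per-cycle periods and amplitude scales (degenerate draws truncated)
  periods <- params$period_s + if (params$period_sd_s > 0) {
    stats::rnorm(nc, sd = params$period_sd_s)
  } else {
    rep(0, nc)
  }
  periods <- pmin(pmax(periods, params$period_s / 2), 2 * params$period_s)
  amp <- 1 + if (params$amp_sd_frac > 0) {
    stats::rnorm(nc + 1L, sd = params$amp_sd_frac)
  } else {
    rep(0, nc + 1L)
  }
  amp <- pmin(pmax(amp, 0.5), 1.5)
  bounds <- c(0, cumsum(periods))
  total_t <- bounds[nc + 1L]
  n <- floor(total_t / params$dt_s) + 1L
  t_s <- (seq_len(n) - 1) * params$dt_s
  cycle <- pmin(findInterval(t_s, bounds, rightmost.closed = TRUE),
                nc)
  signs <- schedule_signs(params)
  omega <- signs[cycle] * 2 * pi / periods[cycle]
  # phase integrates the signed angular rate so switches keep continuity
  phi <- params$phase_rad + c(0, cumsum(omega[-n] * diff(t_s)))
  # amplitude scale interpolated linearly across each cycle (continuous)
  frac <- (t_s - bounds[cycle]) / periods[cycle]
  scale <- amp[cycle] + (amp[cycle + 1L] - amp[cycle]) * frac
  cx <- params$center_mm[1] + params$drift_mm_h[1] / 3600 * t_s
  cz <- params$center_mm[3] + params$drift_mm_h[2] / 3600 * t_s
  cy <- params$center_mm[2] + params$growth_mm_h / 3600 * t_s
  x <- cx + scale * params$a * cos(phi)
  z <- cz + scale * params$b * sin(phi)
  y <- cy
  clean <- cbind(x, y, z)
  noisy <- clean
  if (params$noise_sd_mm > 0) {
    noisy <- clean + matrix(stats::rnorm(3 * n, sd = params$noise_sd_mm), n, 3)
  }
  traj <- trajectory3d(seq_len(n) - 1L, t_s,
                       noisy[, 1], noisy[, 2], noisy[, 3],
                       point_id = "tip", reference_frame = "plant")
  truth <- list(
    positions = clean, phase = phi, cycle = cycle,
    handedness = ifelse(signs > 0, "counterclockwise", "clockwise"),
    period_s = params$period_s,
    cycle_periods_s = periods,
    cycle_amp_scale = amp,
    area_mm2 = pi * params$a * params$b,
    center_path = cbind(x = cx, y = cy, z = cz),
    params = params
  )
  cn_log("gen_trajectory: %d frames, %d cycles, noise sd %.3g mm",
         n, params$n_cycles, params$noise_sd_mm)
  list(traj = traj, truth = truth)
}

#' A plausible default stereo rig for simulation
#'
#' Two converging full-HD cameras ~300 mm apart at ~800 mm from the plant,
#' with mild radial/tangential distortion. Values are package defaults for
#' simulation, matched in scale to a growth-chamber setup.
#'
#' @param baseline_mm Distance between the camera centres (default 300).
#' @param range_mm Distance from the rig to the world origin (default 800).
#' @param distortion If `FALSE`, all distortion coefficients are 0.
#' @return A [camera_rig()].
#' @export
default_rig <- function(baseline_mm = 300, range_mm = 800,
                        distortion = TRUE) {
  look_at <- function(center, target = c(0, 0, 0)) {
    zc <- target - center
    zc <- zc / sqrt(sum(zc^2))
    up <- c(0, -1, 0)  # image v grows downward
    xc <- c(up[2] * zc[3] - up[3] * zc[2],
            up[3] * zc[1] - up[1] * zc[3],
            up[1] * zc[2] - up[2] * zc[1])
    xc <- xc / sqrt(sum(xc^2))
    yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
            zc[3] * xc[1] - zc[1] * xc[3],
            zc[1] * xc[2] - zc[2] * xc[1])
    R <- rbind(xc, yc, zc, deparse.level = 0)
    list(rotation = R, translation = as.numeric(-R %*% center))
  }
  mk <- function(center, k) {
    pose <- look_at(center)
    camera_model(
      fx = 2000, fy = 2000, cx = 960, cy = 540, skew = 0,
      k1 = if (distortion) k[1] else 0,
      k2 = if (distortion) k[2] else 0,
      k3 = 0,
      p1 = if (distortion) 5e-4 else 0,
      p2 = if (distortion) -3e-4 else 0,
      rotation = pose$rotation, translation = pose$translation,
      image_size = c(1920L, 1080L)
    )
  }
  camera_rig(
    left = mk(c(-baseline_mm / 2, 0, -range_mm), c(-0.12, 0.03)),
    right = mk(c(baseline_mm / 2, 0, -range_mm), c(-0.10, 0.02)),
    world_origin = "simulated calibration target corner"
  )
}

#' Project a 3D trajectory into stereo observations
#'
#' Projects every frame through both cameras of a rig (applying lens
#' distortion) and optionally adds iid Gaussian pixel noise - the
#' observation model for the triangulation stage.
#'
#' @param traj A `cn_traj3d` in the rig's world frame.
#' @param rig A [camera_rig()].
#' @param pixel_noise_sd Gaussian pixel noise sd (default 0).
#' @param seed Seed for the pixel noise.
#' @return List of two `cn_traj2d` (`left`, `right`). A point behind either
#'   camera raises an error naming the frame.
#' @export
gen_stereo <- function(traj, rig, pixel_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(traj, "cn_traj3d"), inherits(rig, "cn_rig"))
  pts <- traj_xyz(traj)
  px_l <- tryCatch(project_points(pts, rig$left), error = function(e) {
    stopf("left camera: %s", conditionMessage(e))
  })
  px_r <- tryCatch(project_points(pts, rig$right), error = function(e) {
    stopf("right camera: %s", conditionMessage(e))
  })
  if (pixel_noise_sd > 0) {
    set.seed(seed)
    px_l <- px_l + matrix(stats::rnorm(length(px_l), sd = pixel_noise_sd),
                          ncol = 2)
    px_r <- px_r + matrix(stats::rnorm(length(px_r), sd = pixel_noise_sd),
                          ncol = 2)
  }
  pid <- attr(traj, "point_id")
  list(
    left = trajectory2d(traj$frame, traj$time_s, px_l[, 1], px_l[, 2],
                        point_id = pid, camera_id = "left"),
    right = trajectory2d(traj$frame, traj$time_s, px_r[, 1], px_r[, 2],
                         point_id = pid, camera_id = "right")
  )
}

#' Render a 2D trajectory as a blob image stack
#'
#' One isotropic Gaussian blob per frame at the trajectory position over a
#' noisy background - the synthetic footage used to exercise the tracker.
#'
#' @param traj2d A `cn_traj2d` whose positions all lie inside the image
#'   (with a margin of 3 blob sigmas).
#' @param width,height Image size in pixels.
#' @param blob_sd_px Blob standard deviation in pixels (default 2).
#' @param background_sd Additive Gaussian background noise sd in intensity
#'   units (default 0).
#' @param amplitude Peak blob intensity (default 0.8).
#' @param seed Seed for the background noise.
#' @return A `cn_stack`.
#' @export
render_stack <- function(traj2d, width = 128L, height = 128L,
                         blob_sd_px = 2, background_sd = 0,
                         amplitude = 0.8, seed = 1L) {
  stopifnot(inherits(traj2d, "cn_traj2d"))
  m <- 3 * blob_sd_px
  if (any(traj2d$u < m | traj2d$u > width - 1 - m |
            traj2d$v < m | traj2d$v > height - 1 - m)) {
    stopf("trajectory leaves the image bounds (with %.0f px margin)", m)
  }
  set.seed(seed)
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  ys <- matrix(rep(0:(height - 1), times = width), height, width)
  frames <- vector("list", nrow(traj2d))
  for (f in seq_len(nrow(traj2d))) {
    img <- amplitude * exp(-((xs - traj2d$u[f])^2 + (ys - traj2d$v[f])^2) /
                             (2 * blob_sd_px^2))
    if (background_sd > 0) {
      img <- img + matrix(stats::rnorm(height * width, sd = background_sd),
                          height, width)
    }
    frames[[f]] <- pmin(pmax(img, 0), 1)
  }
  cn_log("render_stack: %d frames of %dx%d, blob sd %.2g px",
         length(frames), width, height, blob_sd_px)
  image_stack(frames, traj2d$time_s)
}

#' Simulate two operators tracking the same landmark
#'
#' Two independent noisy copies of a 3D trajectory, emulating the
#' operator-dependent placement error of manual/semi-automatic tracking.
#'
#' @param traj A `cn_traj3d`.
#' @param rater_sd_mm Per-coordinate Gaussian sd of operator error (>= 0).
#' @param seed Integer seed.
#' @return List of two `cn_traj3d` (`a`, `b`).
#' @export
gen_rater_pair <- function(traj, rater_sd_mm, seed = 1L) {
  stopifnot(inherits(traj, "cn_traj3d"))
  if (rater_sd_mm < 0) stopf("rater_sd_mm must be >= 0")
  set.seed(seed)
  n <- nrow(traj)
  noisy <- function() {
    e <- matrix(stats::rnorm(3 * n, sd = rater_sd_mm), n, 3)
    trajectory3d(traj$frame, traj$time_s,
                 traj$x + e[, 1], traj$y + e[, 2], traj$z + e[, 3],
                 point_id = attr(traj, "point_id"),
                 reference_frame = attr(traj, "reference_frame"))
  }
  list(a = noisy(), b = noisy())
}
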