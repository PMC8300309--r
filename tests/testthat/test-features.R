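test_that("path length sums 3D segment lengths", {
  seg <- trajectory3d(0:1, c(0, 100), c(0, 1), c(0, 2), c(0, 2))
  expect_equal(path_length(seg), 3)
  cst <- trajectory3d(0:4, (0:4) * 10, rep(0, 5), rep(0, 5), rep(0, 5))
  expect_equal(path_length(cst), 0)
  circ <- circle_traj(r = 10, n = 360, extra = 1L)
  expect_equal(path_length(circ), 2 * pi * 10, tolerance = 1e-3)
})

test_that("speed statistics convert units and bracket the motion", {
  # uniform motion: 1 mm per 100 s = 36 mm/h
  lin <- trajectory3d(0:9, (0:9) * 100, (0:9) * 1, rep(0, 10), rep(0, 10))
  sp <- speed_stats(lin, "mm/h")
  expect_equal(unname(sp), rep(36, 3))
  expect_equal(unname(speed_stats(lin, "mm/s")), rep(0.01, 3))
  # one stationary segment drives the minimum to 0
  stall <- trajectory3d(0:3, (0:3) * 100, c(0, 1, 1, 2), rep(0, 4),
                        rep(0, 4))
  expect_equal(speed_stats(stall)[["min"]], 0)
  # elliptical motion: discrete max speed matches the analytic parametric
  # speed max omega * a (a > b) within 2%
  a <- 15; b <- 5; T <- 3600; dt <- 2
  th <- 2 * pi * (0:(T / dt - 1)) * dt / T
  ell <- trajectory3d(seq_along(th) - 1L, (seq_along(th) - 1) * dt,
                      a * cos(th), rep(0, length(th)), b * sin(th))
  expect_equal(speed_stats(ell, "mm/s")[["max"]], 2 * pi / T * a,
               tolerance = 0.02)
})

test_that("centre, centre distance and centre speed follow their definitions", {
  circ <- circle_traj(r = 7, n = 360, center = c(5, -3))
  ctr <- circ_center(circ)
  expect_equal(unname(ctr), c(5, -3), tolerance = 0.05)
  expect_equal(sqrt(sum(c(3, 4)^2)), 5)  # distance contract used below
  # two circumnutations with centres 6 mm apart and midpoints 3600 s apart
  # give a centre speed of 6 mm/h
  c1 <- circle_traj(r = 2, n = 36, center = c(0, 0), dt = 100)
  c2 <- circle_traj(r = 2, n = 36, center = c(6, 0), dt = 100)
  c2$time_s <- c2$time_s + 3600
  c2$frame <- c2$frame + 100L
  feats <- circ_features(list(as_circ(c1), as_circ(c2)),
                         run_config(raster_resolution_mm = 0.05))
  expect_equal(feats$speed_center_XZ[1], 6, tolerance = 1e-9)
  expect_true(is.na(feats$speed_center_XZ[2]))
  expect_equal(feats$center_distance_from_origin[2],
               sqrt(feats$x_center_coordinates_XZ[2]^2 +
                      feats$z_center_coordinates_XZ[2]^2))
})

test_that("rasterized area and centroid match closed forms", {
  # square path, side 10 mm
  sq <- trajectory3d(0:3, (0:3) * 10, c(0, 10, 10, 0), rep(0, 4),
                     c(0, 0, 10, 10), reference_frame = "plant")
  res <- centroid_and_area(sq, 0.1)
  expect_equal(res$area_mm2, 100, tolerance = 0.02)
  expect_lt(max(abs(res$centroid - c(5, 5))), 0.1)
  # circle radius 10 mm
  ca <- centroid_and_area(circle_traj(r = 10, n = 360), 0.1)
  expect_equal(ca$area_mm2, pi * 100, tolerance = 0.02)
  # collinear path: area 0, centroid = vertex mean, with a warning
  line <- trajectory3d(0:3, (0:3) * 10, 0:3, rep(0, 4), (0:3) * 2,
                       reference_frame = "plant")
  expect_warning(res0 <- centroid_and_area(line, 0.1), "degenerate")
  expect_equal(res0$area_mm2, 0)
  expect_equal(unname(res0$centroid), c(1.5, 3))
})

test_that("the main axis is the longest planar chord", {
  sq <- trajectory3d(0:3, (0:3) * 10, c(0, 10, 10, 0), rep(0, 4),
                     c(0, 0, 10, 10))
  expect_equal(main_axis(sq)$length_mm, 10 * sqrt(2))
  expect_equal(main_axis(circle_traj(r = 10, n = 360))$length_mm, 20,
               tolerance = 1e-3)
  two <- trajectory3d(0:1, c(0, 10), c(0, 3), c(0, 0), c(0, 4))
  expect_equal(main_axis(two)$length_mm, 5)
})

test_that("direction follows the signed turning sum with the 2*pi band", {
  ccw <- circle_traj(r = 10, n = 36, extra = 2L)
  d <- circ_direction(ccw)
  expect_equal(as.character(d), "counterclockwise")
  expect_equal(attr(d, "turning_sum"), 2 * pi, tolerance = 1e-9)
  # the reversed path turns the other way
  rev_traj <- trajectory3d(ccw$frame, ccw$time_s, rev(ccw$x), rev(ccw$y),
                           rev(ccw$z), reference_frame = "plant")
  dr <- circ_direction(rev_traj)
  expect_equal(as.character(dr), "clockwise")
  expect_equal(attr(dr, "turning_sum"), -2 * pi, tolerance = 1e-9)
  # figure-eight: two opposed loops cancel
  t8 <- seq(0, 2 * pi, length.out = 100)
  fig8 <- trajectory3d(0:99, (0:99) * 10, 10 * sin(t8), rep(0, 100),
                       5 * sin(2 * t8), reference_frame = "plant")
  d8 <- circ_direction(fig8)
  expect_equal(as.character(d8), "none")
  expect_lt(abs(attr(d8, "turning_sum")), 1)
  # fewer than 3 usable vectors
  tiny <- trajectory3d(0:2, (0:2) * 10, c(0, 1, 2), rep(0, 3), c(0, 0, 0))
  expect_equal(as.character(circ_direction(tiny)), "none")
})

test_that("whole-movement features aggregate the circumnutation table", {
  feats <- data.frame(
    line_integral = c(5, 9, 7, 6, 8),
    area_circumnutation = c(10, 40, 20, 30, 25),
    direction = c("counterclockwise", "counterclockwise", "clockwise",
                  "none", "counterclockwise")
  )
  w <- whole_features(feats)
  expect_equal(w$max_path_length, 9)
  expect_equal(w$max_area, 40)
  expect_equal(w$direction_switches, 2L)  # CCW->CW and CW->CCW, none skipped
  one <- whole_features(feats[1, ])
  expect_equal(one$direction_switches, 0L)
})

test_that("point features locate the speed maximum in time", {
  # fastest segment exactly mid-movement
  x <- c(0, 1, 2, 5, 6, 7)
  traj <- trajectory3d(0:5, (0:5) * 100, x, rep(0, 6), rep(0, 6))
  pf <- point_features(traj)
  expect_equal(pf$time_of_max_speed_pct, 50)
  expect_equal(pf$max_speed, 3 / 100 * 3600)
  # monotone-accelerating motion peaks at the end
  tacc <- (0:100)
  acc <- trajectory3d(tacc, tacc * 10, tacc^2, rep(0, 101), rep(0, 101))
  expect_gte(point_features(acc)$time_of_max_speed_pct, 99)
  # uniform motion: mean equals max
  lin <- trajectory3d(0:9, (0:9) * 100, 0:9, rep(0, 10), rep(0, 10))
  pl <- point_features(lin)
  expect_equal(pl$mean_speed, pl$max_speed)
  # all-stationary: max 0 and undefined timing
  cst <- trajectory3d(0:9, (0:9) * 100, rep(0, 10), rep(0, 10), rep(0, 10))
  pc <- point_features(cst)
  expect_equal(pc$max_speed, 0)
  expect_true(is.na(pc$time_of_max_speed_pct))
})

test_that("stimulus features measure planar distances and the axis angle", {
  # centre at (0, 3), stimulus at (4, 0): planar distance 5
  circ <- circle_traj(r = 1, n = 72, center = c(0, 3))
  feats <- circ_features(list(as_circ(circ)),
                         run_config(raster_resolution_mm = 0.02))
  stim <- stimulus(4, 0)
  sf <- stimulus_features(list(as_circ(circ)), feats, stim)
  expect_equal(sf$center_distance_from_stimulus, 5, tolerance = 0.01)
  expect_gte(sf$angle_axis_stimulus, 0)
  expect_lte(sf$angle_axis_stimulus, 90)
  # main axis along the origin-stimulus line: angle 0
  seg <- trajectory3d(0:2, (0:2) * 10, c(1, 2, 3), rep(0, 3), c(0, 0.01, 0))
  fseg <- suppressWarnings(circ_features(list(as_circ(seg)), run_config()))
  sfa <- stimulus_features(list(as_circ(seg)), fseg, stimulus(10, 0))
  expect_lt(sfa$angle_axis_stimulus, 0.5)
  # trajectory passing through the stimulus: min distance 0
  through <- trajectory3d(0:2, (0:2) * 10, c(0, 4, 8), c(0, 1, 2),
                          c(0, 0, 0))
  fthr <- suppressWarnings(circ_features(list(as_circ(through)),
                                         run_config()))
  sft <- stimulus_features(list(as_circ(through)), fthr, stimulus(4, 0))
  expect_equal(sft$min_dist_stimulus, 0)
  # point model uses the 3D distance
  sfp <- stimulus_features(list(as_circ(through)), fthr,
                           stimulus(4, 0, y = 5, model = "point"))
  expect_equal(sfp$min_dist_stimulus, 4)
  # stimulus at the plant origin: angle undefined with a warning
  expect_warning(
    sf0 <- stimulus_features(list(as_circ(through)), fthr, stimulus(0, 0)),
    "origin"
  )
  expect_true(is.na(sf0$angle_axis_stimulus))
})

test_that("features respect rotation and time-reversal symmetries", {
  sim <- gen_trajectory(sim_params(a = 12, b = 8, n_cycles = 4,
                                   noise_sd_mm = 0.2, seed = 35))
  circs <- segment_circumnutations(sim$traj)
  feats <- circ_features(circs)
  expect_true(all(feats$line_integral >= feats$length_major_axis))
  # rotate each segmented loop about the y-axis: magnitude features are
  # invariant, centres co-rotate. (Re-segmenting a rotated path moves the
  # alpha-wrap boundaries, so the comparison is on matched slices.)
  th <- 0.7
  rot_circs <- lapply(circs, function(ci) {
    tr <- ci$traj
    as_circ(trajectory3d(
      tr$frame, tr$time_s,
      cos(th) * tr$x - sin(th) * tr$z,
      tr$y,
      sin(th) * tr$x + cos(th) * tr$z,
      reference_frame = "plant"
    ))
  })
  feats_rot <- circ_features(rot_circs)
  expect_equal(nrow(feats_rot), nrow(feats))
  for (col in c("duration_circumnutation", "line_integral",
                "length_major_axis", "mean_speed_circumnutations")) {
    expect_equal(feats_rot[[col]], feats[[col]], tolerance = 1e-6)
  }
  expect_equal(feats_rot$area_circumnutation, feats$area_circumnutation,
               tolerance = 0.01)
  expect_equal(feats_rot$direction, feats$direction)
  # centres rotate correspondingly
  expect_equal(feats_rot$x_center_coordinates_XZ,
               cos(th) * feats$x_center_coordinates_XZ -
                 sin(th) * feats$z_center_coordinates_XZ,
               tolerance = 1e-6)
  # reversing time flips handedness, preserves magnitudes
  n <- nrow(sim$traj)
  rev_traj <- trajectory3d(sim$traj$frame, sim$traj$time_s,
                           rev(sim$traj$x), rev(sim$traj$y),
                           rev(sim$traj$z), reference_frame = "plant")
  c1 <- as_circ(circs[[2]]$traj)
  rtr <- c1$traj
  rev1 <- as_circ(trajectory3d(rtr$frame, rtr$time_s, rev(rtr$x),
                               rev(rtr$y), rev(rtr$z),
                               reference_frame = "plant"))
  expect_equal(path_length(rev1), path_length(c1))
  d_fwd <- circ_direction(c1)
  d_rev <- circ_direction(rev1)
  expect_true(as.character(d_fwd) != as.character(d_rev))
  expect_equal(attr(d_rev, "turning_sum"), -attr(d_fwd, "turning_sum"),
               tolerance = 1e-9)
})
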