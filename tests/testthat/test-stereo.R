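test_that("projection follows the pinhole + distortion model", {
  # point on the optical axis of a distortion-free camera hits the
  # principal point
  cam0 <- camera_model(fx = 1000, fy = 1000, cx = 500, cy = 500)
  expect_equal(as.numeric(project_points(c(0, 0, 1000), cam0)),
               c(500, 500), tolerance = 1e-12)
  # similar triangles: 10 mm lateral at 1000 mm depth, f = 1000 px
  expect_equal(as.numeric(project_points(c(10, 0, 1000), cam0)),
               c(510, 500), tolerance = 1e-12)
  # distorted projection matches a brute-force evaluation of the polynomial
  cam <- camera_model(fx = 1400, fy = 1350, cx = 960, cy = 540, skew = 0.5,
                      k1 = 0.1, k2 = -0.02, k3 = 0.001,
                      p1 = 1e-3, p2 = -5e-4)
  set.seed(21)
  pts <- cbind(runif(50, -100, 100), runif(50, -100, 100),
               runif(50, 800, 1200))
  got <- project_points(pts, cam)
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1] / pts[i, 3]
    y <- pts[i, 2] / pts[i, 3]
    r2 <- x^2 + y^2
    rad <- 1 + 0.1 * r2 + (-0.02) * r2^2 + 0.001 * r2^3
    xd <- x * rad + 2 * 1e-3 * x * y + (-5e-4) * (r2 + 2 * x^2)
    yd <- y * rad + 1e-3 * (r2 + 2 * y^2) + 2 * (-5e-4) * x * y
    expect_equal(unname(got[i, 1]), 1400 * xd + 0.5 * yd + 960,
                 tolerance = 1e-10)
    expect_equal(unname(got[i, 2]), 1350 * yd + 540, tolerance = 1e-10)
  }
  # non-positive depth is a geometry error
  expect_error(project_points(c(0, 0, -10), cam0), "depth")
})

test_that("undistortion inverts the distortion model", {
  cam0 <- camera_model(fx = 1000, fy = 1000, cx = 500, cy = 500)
  set.seed(22)
  px <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  expect_equal(undistort_points(px, cam0), px, tolerance = 1e-12,
               ignore_attr = TRUE)
  # distort-then-undistort round trip on a moderately distorting lens
  cam <- camera_model(fx = 1400, fy = 1400, cx = 960, cy = 540,
                      k1 = -0.2, k2 = 0.05)
  ideal <- cbind(runif(200, 200, 1700), runif(200, 100, 980))
  xy <- circumnut:::pixel_to_normalized(ideal, cam)
  d <- circumnut:::distort_normalized(xy, cam)
  observed <- cbind(cam$fx * d[, 1] + cam$cx, cam$fy * d[, 2] + cam$cy)
  expect_lt(max(abs(undistort_points(observed, cam) - ideal)), 1e-6)
  # the principal point is a fixed point of the map
  pp <- c(cam$cx, cam$cy)
  expect_equal(as.numeric(undistort_points(pp, cam)), pp, tolerance = 1e-9)
})

test_that("triangulation inverts projection at zero noise", {
  rig <- default_rig()  # with distortion
  pts <- random_points(500, seed = 23)
  px_l <- project_points(pts, rig$left)
  px_r <- project_points(pts, rig$right)
  rec <- triangulate_points(px_l, px_r, rig)
  expect_lt(max(abs(rec - pts)), 1e-6)
  expect_false(any(attr(rec, "degenerate")))
  # reprojection of the noiseless reconstruction is exact
  expect_lt(max(reprojection_error(rec, px_l, px_r, rig)), 1e-9)
})

test_that("zero-baseline rigs are rejected and the midplane is symmetric", {
  cam <- default_rig(distortion = FALSE)$left
  expect_error(camera_rig(cam, cam), "baseline")
  # symmetric converging rig: a point on the midplane triangulates to x = 0
  rig <- clean_rig()
  p <- c(0, 17.3, 42.0)
  rec <- triangulate_points(project_points(p, rig$left),
                            project_points(p, rig$right), rig)
  expect_lt(abs(rec[1, 1]), 1e-9)
})

test_that("reprojection error averages the two view residuals", {
  rig <- clean_rig()
  p <- c(5, -3, 20)
  pl <- project_points(p, rig$left)
  pr <- project_points(p, rig$right)
  expect_lt(reprojection_error(p, pl, pr, rig), 1e-12)
  # a (3, 4) px perturbation in one view only gives mean error 5/2
  expect_equal(as.numeric(reprojection_error(p, pl + c(3, 4), pr, rig)),
               2.5, tolerance = 1e-12)
})

test_that("pixel noise propagates to reprojection error at the expected scale", {
  # observing a known point through sigma = 0.5 px noise in both views
  # gives a mean residual of sigma * sqrt(pi/2) ~ 0.63 px
  rig <- clean_rig()
  pts <- random_points(1000, seed = 24)
  px_l <- project_points(pts, rig$left)
  px_r <- project_points(pts, rig$right)
  set.seed(25)
  px_l <- px_l + matrix(rnorm(2000, sd = 0.5), ncol = 2)
  px_r <- px_r + matrix(rnorm(2000, sd = 0.5), ncol = 2)
  err <- reprojection_error(pts, px_l, px_r, rig)
  expect_gt(mean(err), 0.3)
  expect_lt(mean(err), 0.9)
})

test_that("triangulation residuals are invariant under a rigid world motion", {
  rig <- clean_rig()
  pts <- random_points(100, seed = 26)
  px_l <- project_points(pts, rig$left)
  px_r <- project_points(pts, rig$right)
  set.seed(27)
  px_l <- px_l + matrix(rnorm(200, sd = 1), ncol = 2)
  px_r <- px_r + matrix(rnorm(200, sd = 1), ncol = 2)
  res0 <- reprojection_error(
    triangulate_points(px_l, px_r, rig, undistort = FALSE),
    px_l, px_r, rig
  )
  # move the whole world (points and cameras) by a rigid transform; pixel
  # observations are unchanged, so residuals must be too
  Q <- random_rotation(seed = 28)
  shift <- c(100, -50, 30)
  move_cam <- function(cam) {
    camera_model(cam$fx, cam$fy, cam$cx, cam$cy, cam$skew,
                 cam$k1, cam$k2, cam$k3, cam$p1, cam$p2,
                 rotation = cam$rotation %*% t(Q),
                 translation = cam$translation -
                   as.numeric(cam$rotation %*% t(Q) %*% shift),
                 image_size = cam$image_size)
  }
  rig2 <- camera_rig(move_cam(rig$left), move_cam(rig$right))
  res1 <- reprojection_error(
    triangulate_points(px_l, px_r, rig2, undistort = FALSE),
    px_l, px_r, rig2
  )
  expect_lt(max(abs(res1 - res0)), 1e-3)
})

test_that("3D error grows as the baseline shrinks under fixed pixel noise", {
  err_for_baseline <- function(baseline) {
    rig <- default_rig(baseline_mm = baseline, distortion = FALSE)
    pts <- random_points(300, seed = 29)
    px_l <- project_points(pts, rig$left)
    px_r <- project_points(pts, rig$right)
    set.seed(30)
    px_l <- px_l + matrix(rnorm(600, sd = 0.5), ncol = 2)
    px_r <- px_r + matrix(rnorm(600, sd = 0.5), ncol = 2)
    rec <- triangulate_points(px_l, px_r, rig, undistort = FALSE)
    mean(sqrt(rowSums((rec - pts)^2)))
  }
  e <- vapply(c(300, 100, 30), err_for_baseline, numeric(1))
  expect_true(all(diff(e) > 0))
})
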