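# Stereo geometry: forward projection with lens distortion, iterative point
# undistortion, two-view DLT triangulation and reprojection error.

# Apply the Brown-Conrady distortion model to normalized coordinates.
# xy: n x 2 matrix of ideal normalized coordinates. Returns n x 2 distorted.
distort_normalized <- function(xy, cam) {
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + cam$k1 * r2 + cam$k2 * r2^2 + cam$k3 * r2^3
  xd <- x * radial + 2 * cam$p1 * x * y + cam$p2 * (r2 + 2 * x^2)
  yd <- y * radial + cam$p1 * (r2 + 2 * y^2) + 2 * cam$p2 * x * y
  cbind(xd, yd)
}

#' Project 3D world points into a camera image
#'
#' Standard pinhole projection with lens distortion: world points are mapped
#' into the camera frame, perspective-divided, distorted on normalized
#' coordinates (radial k1-k3 and tangential p1-p2) and mapped to pixels by
#' the intrinsics.
#'
#' @param points Numeric n x 3 matrix (or length-3 vector) of world points, mm.
#' @param cam A [camera_model()].
#' @return n x 2 matrix of pixel coordinates `(u, v)`.
#' @export
project_points <- function(points, cam) {
  stopifnot(inherits(cam, "cn_camera"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  pc <- points %*% t(cam$rotation) +
    matrix(cam$translation, nrow(points), 3, byrow = TRUE)
  z <- pc[, 3]
  bad <- which(z <= 0)
  if (length(bad)) {
    stopf("point %d has non-positive depth (z = %.3g mm) in the camera frame",
          bad[1], z[bad[1]])
  }
  xy <- cbind(pc[, 1] / z, pc[, 2] / z)
  d <- distort_normalized(xy, cam)
  u <- cam$fx * d[, 1] + cam$skew * d[, 2] + cam$cx
  v <- cam$fy * d[, 2] + cam$cy
  cbind(u = u, v = v)
}

# Pixel -> distorted normalized coordinates (inverse intrinsics).
pixel_to_normalized <- function(px, cam) {
  if (is.null(dim(px))) px <- matrix(px, nrow = 1)
  y <- (px[, 2] - cam$cy) / cam$fy
  x <- (px[, 1] - cam$cx - cam$skew * y) / cam$fx
  cbind(x, y)
}

#' Undistort pixel coordinates
#'
#' Inverts the lens distortion by damped fixed-point iteration on normalized
#' coordinates (at most `max_iter` sweeps, convergence at `tol` in normalized
#' units), then maps back through the intrinsics. For a distortion-free
#' camera this is the identity.
#'
#' @param px n x 2 matrix (or length-2 vector) of observed pixel coordinates.
#' @param cam A [camera_model()].
#' @param max_iter Maximum fixed-point iterations (default 50).
#' @param tol Convergence tolerance in normalized coordinates (default 1e-10).
#' @return n x 2 matrix of ideal (undistorted) pixel coordinates.
#' @export
undistort_points <- function(px, cam, max_iter = 50L, tol = 1e-10) {
  stopifnot(inherits(cam, "cn_camera"))
  if (is.null(dim(px))) px <- matrix(px, nrow = 1)
  if (!all(is.finite(px))) stopf("pixel coordinates must be finite")
  xyd <- pixel_to_normalized(px, cam)
  xy <- xyd  # initial guess: distorted == ideal
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    x <- xy[, 1]; y <- xy[, 2]
    r2 <- x^2 + y^2
    radial <- 1 + cam$k1 * r2 + cam$k2 * r2^2 + cam$k3 * r2^3
    dx <- 2 * cam$p1 * x * y + cam$p2 * (r2 + 2 * x^2)
    dy <- cam$p1 * (r2 + 2 * y^2) + 2 * cam$p2 * x * y
    xy_new <- cbind((xyd[, 1] - dx) / radial, (xyd[, 2] - dy) / radial)
    step <- max(abs(xy_new - xy))
    xy <- xy_new
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    resid <- max(abs(distort_normalized(xy, cam) - xyd))
    stopf(paste0("undistortion did not converge after %d iterations ",
                 "(residual %.3g in normalized units)"), max_iter, resid)
  }
  u <- cam$fx * xy[, 1] + cam$skew * xy[, 2] + cam$cx
  v <- cam$fy * xy[, 2] + cam$cy
  cbind(u = u, v = v)
}

# 3x4 projection matrix K [R | t].
projection_matrix <- function(cam) {
  camera_K(cam) %*% cbind(cam$rotation, cam$translation)
}

#' Triangulate 3D points from two views
#'
#' Homogeneous linear least-squares (direct linear transform): each view
#' contributes two rows to a 4x4 system whose smallest-singular-vector
#' solution is the homogeneous world point. Deterministic, no RANSAC - the
#' use case is a single tracked landmark per frame.
#'
#' @param px_left,px_right n x 2 matrices (or length-2 vectors) of pixel
#'   coordinates in the left/right cameras.
#' @param rig A [camera_rig()].
#' @param undistort If `TRUE` (default), pixels are undistorted first; pass
#'   `FALSE` when coordinates are already ideal.
#' @param condition_threshold Condition number of the rank-3 part of the
#'   DLT system (ratio of its largest to third-largest singular value) above
#'   which a `degenerate` warning flag is attached (near-parallel rays). The
#'   smallest singular value is the fit residual, not a conditioning
#'   measure.
#' @return n x 3 matrix of world points (mm) with attribute `degenerate`,
#'   a logical vector flagging ill-conditioned solutions.
#' @export
triangulate_points <- function(px_left, px_right, rig, undistort = TRUE,
                               condition_threshold = 1e8) {
  stopifnot(inherits(rig, "cn_rig"))
  if (is.null(dim(px_left))) px_left <- matrix(px_left, nrow = 1)
  if (is.null(dim(px_right))) px_right <- matrix(px_right, nrow = 1)
  if (nrow(px_left) != nrow(px_right)) {
    stopf("left and right observations must have the same number of rows")
  }
  if (undistort) {
    px_left <- undistort_points(px_left, rig$left)
    px_right <- undistort_points(px_right, rig$right)
  }
  # condition the system by working in normalized camera coordinates
  # (inverse intrinsics applied), with P = [R | t]
  nl <- pixel_to_normalized(px_left, rig$left)
  nr <- pixel_to_normalized(px_right, rig$right)
  P1 <- cbind(rig$left$rotation, rig$left$translation)
  P2 <- cbind(rig$right$rotation, rig$right$translation)
  n <- nrow(px_left)
  out <- matrix(NA_real_, n, 3)
  colnames(out) <- c("x", "y", "z")
  degen <- logical(n)
  for (i in seq_len(n)) {
    A0 <- rbind(
      nl[i, 1] * P1[3, ] - P1[1, ],
      nl[i, 2] * P1[3, ] - P1[2, ],
      nr[i, 1] * P2[3, ] - P2[1, ],
      nr[i, 2] * P2[3, ] - P2[2, ]
    )
    # iteratively reweighted DLT: rows are divided by the current
    # projective depths so the algebraic residual approaches the geometric
    # one (which is invariant under rigid changes of the world frame)
    w <- rep(1, 4)
    X <- NULL
    sv <- NULL
    for (iter in 1:10) {
      A <- A0 / w
      # equilibrate columns (the homogeneous column is otherwise dwarfed
      # by the mm-scale coordinate columns); rows must NOT be normalized
      # or the depth weights would cancel
      cs <- pmax(sqrt(colSums(A^2)), .Machine$double.eps)
      A <- sweep(A, 2, cs, "/")
      sv <- svd(A)
      X <- sv$v[, 4] / cs
      d1 <- sum(P1[3, ] * X)
      d2 <- sum(P2[3, ] * X)
      if (abs(X[4]) < .Machine$double.eps * 1e3 ||
            abs(d1) < 1e-12 || abs(d2) < 1e-12) break
      w_new <- abs(c(d1, d1, d2, d2)) / abs(X[4])
      if (max(abs(w_new - w) / w) < 1e-12) {
        w <- w_new
        break
      }
      w <- w_new
    }
    if (abs(X[4]) < .Machine$double.eps * 1e3) {
      degen[i] <- TRUE
      next
    }
    degen[i] <- sv$d[1] / max(sv$d[3], .Machine$double.xmin) >
      condition_threshold
    out[i, ] <- X[1:3] / X[4]
  }
  if (any(degen)) {
    warnf("%d of %d triangulations are near-degenerate (condition number > %g)",
          sum(degen), n, condition_threshold)
  }
  attr(out, "degenerate") <- degen
  out
}

#' Mean reprojection error of a reconstructed point
#'
#' Projects 3D world points through both cameras (with distortion) and
#' returns the mean of the two Euclidean pixel distances to the observed
#' positions, per point. This is the residual used to vet calibration
#' quality (observations with mean residual above ~1 px are suspect).
#'
#' @param points n x 3 matrix of world points (mm).
#' @param px_left,px_right Observed pixel coordinates, n x 2.
#' @param rig A [camera_rig()].
#' @return Numeric vector of mean pixel errors, one per point.
#' @export
reprojection_error <- function(points, px_left, px_right, rig) {
  stopifnot(inherits(rig, "cn_rig"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (is.null(dim(px_left))) px_left <- matrix(px_left, nrow = 1)
  if (is.null(dim(px_right))) px_right <- matrix(px_right, nrow = 1)
  pl <- project_points(points, rig$left)
  pr <- project_points(points, rig$right)
  (row_norms(pl - px_left) + row_norms(pr - px_right)) / 2
}
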