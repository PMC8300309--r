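#' Pinhole camera with lens distortion
#'
#' A calibrated camera: pinhole intrinsics, Brown-Conrady lens distortion
#' (three radial and two tangential coefficients) and a rigid pose mapping
#' world coordinates (mm) into the camera frame, `p_cam = R p_world + t`.
#' The camera looks down its +z axis.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @param skew Skew coefficient in pixels (default 0).
#' @param k1,k2,k3 Radial distortion coefficients (dimensionless).
#' @param p1,p2 Tangential distortion coefficients (dimensionless).
#' @param rotation 3x3 orthonormal rotation matrix (world -> camera),
#'   `det = +1`, orthonormal within 1e-9.
#' @param translation Length-3 translation vector in mm (world -> camera).
#' @param image_size Integer `c(width, height)` in pixels.
#'
#' @return An object of class `cn_camera`.
#' @export
camera_model <- function(fx, fy, cx, cy, skew = 0,
                         k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0,
                         rotation = diag(3), translation = c(0, 0, 0),
                         image_size = c(1920L, 1080L)) {
  if (!is.numeric(fx) || !is.numeric(fy) || fx <= 0 || fy <= 0) {
    stopf("focal lengths fx, fy must be positive")
  }
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stopf("rotation must be 3x3")
  ortho_err <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho_err > 1e-9) {
    stopf("rotation is not orthonormal (max |R'R - I| = %.3g)", ortho_err)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stopf("rotation must be proper (det = +1, got %.6f)", det(rotation))
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stopf("translation must have length 3")
  structure(
    list(
      fx = fx, fy = fy, cx = cx, cy = cy, skew = skew,
      k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2,
      rotation = rotation, translation = translation,
      image_size = as.integer(image_size)
    ),
    class = "cn_camera"
  )
}

#' @export
print.cn_camera <- function(x, ...) {
  cat(sprintf(
    "<cn_camera> %dx%d px, f = (%.1f, %.1f), c = (%.1f, %.1f)\n",
    x$image_size[1], x$image_size[2], x$fx, x$fy, x$cx, x$cy
  ))
  cat(sprintf(
    "  distortion k = (%g, %g, %g), p = (%g, %g)\n",
    x$k1, x$k2, x$k3, x$p1, x$p2
  ))
  invisible(x)
}

# Optical centre of the camera in world coordinates.
camera_center <- function(cam) {
  as.numeric(-crossprod(cam$rotation, cam$translation))
}

# 3x3 intrinsic matrix.
camera_K <- function(cam) {
  matrix(
    c(cam$fx, cam$skew, cam$cx,
      0, cam$fy, cam$cy,
      0, 0, 1),
    nrow = 3, byrow = TRUE
  )
}

#' Two-camera stereo rig
#'
#' @param left,right [camera_model()] objects sharing one world frame. The
#'   world origin is wherever the calibration placed it (typically a corner
#'   of the calibration target); conversion to the plant frame happens later.
#' @param world_origin Free-text description of the world origin.
#' @return Object of class `cn_rig`.
#' @export
camera_rig <- function(left, right,
                       world_origin = "calibration target corner") {
  stopifnot(inherits(left, "cn_camera"), inherits(right, "cn_camera"))
  baseline <- sqrt(sum((camera_center(left) - camera_center(right))^2))
  if (baseline <= 1e-9) {
    stopf("camera centres coincide (baseline = %.3g mm); rig is degenerate",
          baseline)
  }
  structure(
    list(left = left, right = right, world_origin = world_origin,
         baseline_mm = baseline),
    class = "cn_rig"
  )
}

#' @export
print.cn_rig <- function(x, ...) {
  cat(sprintf("<cn_rig> baseline %.1f mm, origin: %s\n",
              x$baseline_mm, x$world_origin))
  invisible(x)
}

cam_to_list <- function(cam) {
  list(
    fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy, skew = cam$skew,
    distortion = list(k1 = cam$k1, k2 = cam$k2, k3 = cam$k3,
                      p1 = cam$p1, p2 = cam$p2),
    rotation = as.numeric(t(cam$rotation)),  # row-major
    translation = as.numeric(cam$translation),
    image_size = as.integer(cam$image_size)
  )
}

cam_from_list <- function(x) {
  d <- x$distortion
  if (is.null(d)) d <- list()
  g <- function(lst, nm, default = 0) {
    if (is.null(lst[[nm]])) default else as.numeric(lst[[nm]])
  }
  R <- matrix(as.numeric(x$rotation), nrow = 3, byrow = TRUE)
  # rig files may store limited digits; project near-rotations onto the
  # closest proper rotation, reject anything genuinely non-orthonormal
  ortho_err <- max(abs(crossprod(R) - diag(3)))
  if (ortho_err > 1e-5) {
    stopf("rig rotation is not orthonormal (max |R'R - I| = %.3g)", ortho_err)
  }
  if (ortho_err > 1e-10) {
    sv <- svd(R)
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) stopf("rig rotation is improper (det < 0)")
  }
  camera_model(
    fx = x$fx, fy = x$fy, cx = x$cx, cy = x$cy, skew = g(x, "skew"),
    k1 = g(d, "k1"), k2 = g(d, "k2"), k3 = g(d, "k3"),
    p1 = g(d, "p1"), p2 = g(d, "p2"),
    rotation = R,
    translation = as.numeric(x$translation),
    image_size = as.integer(x$image_size)
  )
}

#' Read / write a camera-rig parameter file
#'
#' The rig file is YAML with sections `left` and `right`, each holding
#' `fx, fy, cx, cy, skew`, a `distortion` section (`k1, k2, k3, p1, p2`;
#' absent coefficients default to 0), `rotation` (9 numbers, row-major),
#' `translation` (3 numbers, mm) and `image_size` (width, height).
#' Calibration itself (chessboard detection, parameter fitting) is out of
#' scope: rig files are inputs produced by a standard calibration tool.
#'
#' @param path File path.
#' @return `read_camera_rig()` returns a `cn_rig`.
#' @export
read_camera_rig <- function(path) {
  if (!file.exists(path)) stopf("rig file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$left) || is.null(raw$right)) {
    stopf("rig file must contain 'left' and 'right' camera sections")
  }
  camera_rig(
    left = cam_from_list(raw$left),
    right = cam_from_list(raw$right),
    world_origin = if (is.null(raw$world_origin)) {
      "calibration target corner"
    } else {
      raw$world_origin
    }
  )
}

#' @param rig A `cn_rig` object.
#' @rdname read_camera_rig
#' @export
write_camera_rig <- function(rig, path) {
  stopifnot(inherits(rig, "cn_rig"))
  yaml::write_yaml(
    list(
      world_origin = rig$world_origin,
      left = cam_to_list(rig$left),
      right = cam_to_list(rig$right)
    ),
    path,
    precision = 12
  )
  invisible(path)
}
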