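# Semi-automatic landmark tracking: pyramidal Lucas-Kanade optical flow
# chained frame-to-frame, with manual corrections re-seeding the tracker.
#
# Images are grayscale matrices (rows = image rows) with intensities in
# [0, 1]. Pixel coordinates are 0-based with (0, 0) at the centre of the
# top-left pixel, u along columns and v along rows.

#' Time-lapse image stack
#'
#' @param frames List of numeric H x W matrices (grayscale, \[0, 1\]), all
#'   of identical dimensions.
#' @param timestamps Strictly increasing acquisition times in seconds; by
#'   default multiples of `frame_interval_s`.
#' @param frame_interval_s Used when `timestamps` is `NULL`.
#' @return Object of class `cn_stack`.
#' @export
image_stack <- function(frames, timestamps = NULL,
                        frame_interval_s = 1 / 0.0056) {
  if (!length(frames)) stopf("stack has no frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("all frames must have identical dimensions")
  }
  if (is.null(timestamps)) {
    timestamps <- (seq_along(frames) - 1) * frame_interval_s
  }
  if (any(diff(timestamps) <= 0)) {
    stopf("timestamps must be strictly increasing")
  }
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         height = dims[1, 1], width = dims[2, 1]),
    class = "cn_stack"
  )
}

#' @export
print.cn_stack <- function(x, ...) {
  cat(sprintf("<cn_stack> %d frames of %dx%d px over %.0f s\n",
              length(x$frames), x$width, x$height, diff(range(x$timestamps))))
  invisible(x)
}

# RGB array -> luminance matrix.
to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img
  }
}

#' Read an image stack from PNG/TIFF files
#'
#' Accepts a vector of single-image files (numbered sequence, PNG or TIFF)
#' or one multi-page TIFF. RGB frames are converted to grayscale by
#' luminance (0.299 R + 0.587 G + 0.114 B), which is logged.
#'
#' @param paths Character vector of image paths (or one multi-page TIFF).
#' @param timestamps,frame_interval_s Passed to [image_stack()].
#' @return A `cn_stack`.
#' @export
read_image_stack <- function(paths, timestamps = NULL,
                             frame_interval_s = 1 / 0.0056) {
  if (!length(paths)) stopf("no image paths given")
  is_tiff <- grepl("\\.tiff?$", paths, ignore.case = TRUE)
  frames <- list()
  rgb_seen <- FALSE
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stopf("image not found: %s", paths[i])
    imgs <- if (is_tiff[i]) {
      tiff::readTIFF(paths[i], all = TRUE)
    } else {
      list(png::readPNG(paths[i]))
    }
    for (img in imgs) {
      if (length(dim(img)) == 3L) rgb_seen <- TRUE
      frames[[length(frames) + 1L]] <- to_gray(img)
    }
  }
  if (rgb_seen) cn_log("read_image_stack: RGB frames converted by luminance")
  cn_log("read_image_stack: %d frames read", length(frames))
  image_stack(frames, timestamps, frame_interval_s)
}

#' Write an image stack as a multi-page TIFF
#'
#' @param stack A `cn_stack`.
#' @param path Output `.tif` path.
#' @return Invisibly, `path`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "cn_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(f) pmin(pmax(f, 0), 1)), path)
  invisible(path)
}

# Bilinear sample of img (H x W, 0-based coords) at the points (x, y);
# x, y equal-length vectors. Caller guarantees 0 <= x <= W-1, 0 <= y <= H-1.
bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- pmax(pmin(floor(x), w - 2), 0); y0 <- pmax(pmin(floor(y), h - 2), 0)
  fx <- x - x0; fy <- y - y0
  # img[row, col] with row = y + 1, col = x + 1; column-major linear index
  idx <- function(yy, xx) (xx) * h + yy + 1
  v00 <- img[idx(y0, x0)]
  v10 <- img[idx(y0, x0 + 1)]
  v01 <- img[idx(y0 + 1, x0)]
  v11 <- img[idx(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

# 5-tap binomial blur with replicated borders, then 2x decimation.
pyr_down <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  pad <- function(m, n = 2L) {
    m <- rbind(m[rep(1, n), , drop = FALSE], m,
               m[rep(nrow(m), n), , drop = FALSE])
    cbind(m[, rep(1, n), drop = FALSE], m,
          m[, rep(ncol(m), n), drop = FALSE])
  }
  p <- pad(img)
  h <- nrow(img); w <- ncol(img)
  # separable convolution
  tmp <- matrix(0, h, w + 4L)
  for (d in -2:2) {
    tmp <- tmp + k[d + 3] * p[(3 + d):(h + 2 + d), , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (d in -2:2) {
    out <- out + k[d + 3] * tmp[, (3 + d):(w + 2 + d), drop = FALSE]
  }
  out[seq(1, h, by = 2), seq(1, w, by = 2), drop = FALSE]
}

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels + 1L)
  pyr[[1]] <- img
  for (l in seq_len(levels)) pyr[[l + 1]] <- pyr_down(pyr[[l]])
  pyr
}

# Effective pyramid depth for an image: halving must keep the tracking
# window inside the image.
effective_levels <- function(h, w, window, requested) {
  cap <- max(0L, floor(log2(min(h, w) / window)))
  min(as.integer(requested), cap)
}

#' Single Lucas-Kanade tracking step
#'
#' Estimates the displacement of one landmark between two frames with the
#' iterative pyramidal Lucas-Kanade method: at each pyramid level the local
#' optical-flow equations are solved over a centred window, iterating until
#' the update falls below `eps` or `max_iter` iterations, and the result
#' seeds the next finer level.
#'
#' @param img_a,img_b Grayscale matrices of identical size.
#' @param point Length-2 pixel position `(u, v)` in `img_a` (0-based).
#' @param window Odd window side in pixels (default 11; a nominal "10 by
#'   10" search window is centred as 11 x 11).
#' @param max_pyramid_levels Requested pyramid depth; the effective depth is
#'   capped at `floor(log2(min(H, W) / window))` and logged.
#' @param max_iter Maximum iterations per level (default 30).
#' @param eps Convergence threshold on the update step in pixels
#'   (default 0.01).
#' @return List with `point` (length-2, the position in `img_b`) and
#'   `status` (`"tracked"` or `"lost"` - window left the image or the
#'   spatial-gradient matrix is singular).
#' @export
lk_step <- function(img_a, img_b, point, window = 11L,
                    max_pyramid_levels = 3L, max_iter = 30L, eps = 0.01) {
  if (!all(dim(img_a) == dim(img_b))) stopf("images have mismatched sizes")
  h <- nrow(img_a); w <- ncol(img_a)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  margin <- half + 1L
  if (point[1] < margin || point[1] > w - 1 - margin ||
      point[2] < margin || point[2] > h - 1 - margin) {
    return(list(point = c(NA_real_, NA_real_), status = "lost"))
  }
  levels <- effective_levels(h, w, window, max_pyramid_levels)
  pyr_a <- build_pyramid(img_a, levels)
  pyr_b <- build_pyramid(img_b, levels)
  off <- as.matrix(expand.grid(du = -half:half, dv = -half:half))
  g <- c(0, 0)
  for (l in seq(levels, 0)) {
    a <- pyr_a[[l + 1]]; b <- pyr_b[[l + 1]]
    hl <- nrow(a); wl <- ncol(a)
    p <- point / 2^l
    xs <- p[1] + off[, 1]; ys <- p[2] + off[, 2]
    inside <- function(x, y, ww, hh) {
      all(x >= 1) && all(x <= ww - 2) && all(y >= 1) && all(y <= hh - 2)
    }
    if (!inside(xs, ys, wl, hl)) {
      if (l == 0) return(list(point = c(NA_real_, NA_real_), status = "lost"))
      g <- 2 * g
      next
    }
    patch_a <- bilinear(a, xs, ys)
    ix <- (bilinear(a, xs + 1, ys) - bilinear(a, xs - 1, ys)) / 2
    iy <- (bilinear(a, xs, ys + 1) - bilinear(a, xs, ys - 1)) / 2
    G <- matrix(c(sum(ix * ix), sum(ix * iy), sum(ix * iy), sum(iy * iy)), 2)
    if (abs(det(G)) < 1e-14) {
      return(list(point = c(NA_real_, NA_real_), status = "lost"))
    }
    v <- c(0, 0)
    for (iter in seq_len(max_iter)) {
      xb <- xs + g[1] + v[1]; yb <- ys + g[2] + v[2]
      if (!inside(xb, yb, wl, hl)) {
        if (l == 0) return(list(point = c(NA_real_, NA_real_),
                                status = "lost"))
        v <- c(0, 0)
        break
      }
      di <- patch_a - bilinear(b, xb, yb)
      bv <- c(sum(di * ix), sum(di * iy))
      d <- solve(G, bv)
      v <- v + d
      if (sqrt(sum(d^2)) < eps) break
    }
    g <- if (l > 0) 2 * (g + v) else g + v
  }
  new_point <- point + g
  if (new_point[1] < margin || new_point[1] > w - 1 - margin ||
      new_point[2] < margin || new_point[2] > h - 1 - margin) {
    return(list(point = c(NA_real_, NA_real_), status = "lost"))
  }
  list(point = as.numeric(new_point), status = "tracked")
}

#' Track landmarks through an image stack
#'
#' Chains [lk_step()] frame by frame from user-placed seeds. A correction
#' overwrites the position at its frame (status `"corrected"`) and tracking
#' resumes from it; a lost landmark stays lost until a correction re-seeds
#' it.
#'
#' @param stack A `cn_stack`.
#' @param seeds `data.frame` with columns `point_id, u, v`: initial
#'   positions in the first frame (0-based pixels).
#' @param corrections Optional `data.frame` `frame, point_id, u, v` (see
#'   [read_corrections()]). A correction for an unknown `point_id` is an
#'   error.
#' @param window,max_pyramid_levels,max_iter,eps Passed to [lk_step()].
#' @return Named list of `cn_traj2d`, one per seed.
#' @export
track_points <- function(stack, seeds, corrections = NULL, window = 11L,
                         max_pyramid_levels = 3L, max_iter = 30L,
                         eps = 0.01) {
  stopifnot(inherits(stack, "cn_stack"))
  check_columns(seeds, c("point_id", "u", "v"), "seeds")
  if (!is.null(corrections)) {
    check_columns(corrections, c("frame", "point_id", "u", "v"), "corrections")
    unknown <- setdiff(corrections$point_id, seeds$point_id)
    if (length(unknown)) {
      stopf("correction for unknown point_id '%s'", unknown[1])
    }
    if (any(corrections$frame < 0L |
              corrections$frame >= length(stack$frames))) {
      stopf("correction frame outside stack bounds")
    }
  }
  nf <- length(stack$frames)
  lev <- effective_levels(stack$height, stack$width, window,
                          max_pyramid_levels)
  cn_log(paste0("track_points: %d seeds, %d frames, window=%d, ",
                "pyramid levels %d (requested %d), max_iter=%d"),
         nrow(seeds), nf, window, lev, max_pyramid_levels, max_iter)
  out <- vector("list", nrow(seeds))
  names(out) <- seeds$point_id
  for (s in seq_len(nrow(seeds))) {
    pid <- seeds$point_id[s]
    u <- numeric(nf); v <- numeric(nf); status <- character(nf)
    pos <- c(seeds$u[s], seeds$v[s])
    st <- "tracked"
    corr <- if (is.null(corrections)) NULL else {
      corrections[corrections$point_id == pid, , drop = FALSE]
    }
    for (f in seq_len(nf)) {
      fi <- f - 1L
      if (!is.null(corr) && fi %in% corr$frame) {
        row <- corr[corr$frame == fi, ][1, ]
        pos <- c(row$u, row$v)
        st <- "corrected"
      } else if (f > 1L && st != "lost") {
        step <- lk_step(stack$frames[[f - 1L]], stack$frames[[f]], pos,
                        window, max_pyramid_levels, max_iter, eps)
        pos <- step$point
        st <- if (step$status == "lost") "lost" else "tracked"
      }
      u[f] <- pos[1]; v[f] <- pos[2]; status[f] <- st
    }
    out[[s]] <- trajectory2d(seq_len(nf) - 1L, stack$timestamps, u, v,
                             status, point_id = pid, camera_id = "left")
    cn_log("track_points: '%s' tracked, %d lost frames", pid,
           sum(status == "lost"))
  }
  out
}
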