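# Trajectory containers and their CSV readers/writers. A trajectory is a
# plain data.frame with metadata attributes; files are comma-separated with
# '.' decimal separator, UTF-8, a leading block of '# key,value' metadata
# lines and one header line. Coordinates round-trip at 6 decimal places.

#' 2D pixel trajectory of one tracked landmark
#'
#' @param frame Integer frame indices (>= 0), strictly increasing.
#' @param time_s Time in seconds from the first frame.
#' @param u,v Pixel coordinates; must be finite whenever `status != "lost"`.
#' @param status Per-frame tracking status: `"tracked"`, `"corrected"` or
#'   `"lost"`.
#' @param point_id Label of the tracked landmark.
#' @param camera_id `"left"` or `"right"`.
#' @return A `data.frame` of class `cn_traj2d` with columns
#'   `frame, time_s, u, v, status` and attributes `point_id`, `camera_id`.
#' @export
trajectory2d <- function(frame, time_s, u, v,
                         status = rep("tracked", length(frame)),
                         point_id = "P1", camera_id = c("left", "right")) {
  camera_id <- match.arg(camera_id)
  frame <- as.integer(frame)
  if (length(frame) == 0L) stopf("trajectory has no rows")
  if (any(frame < 0L)) stopf("frame indices must be >= 0")
  if (any(diff(frame) <= 0L)) {
    stopf("frame indices must be strictly increasing (violation at frame %d)",
          frame[which(diff(frame) <= 0L)[1] + 1L])
  }
  status <- as.character(status)
  if (!all(status %in% c("tracked", "corrected", "lost"))) {
    stopf("status must be one of tracked/corrected/lost")
  }
  live <- status != "lost"
  if (any(!is.finite(u[live])) || any(!is.finite(v[live]))) {
    stopf("u, v must be finite when status != 'lost'")
  }
  structure(
    data.frame(frame = frame, time_s = as.numeric(time_s),
               u = as.numeric(u), v = as.numeric(v), status = status),
    point_id = point_id, camera_id = camera_id,
    class = c("cn_traj2d", "data.frame")
  )
}

#' 3D trajectory of one tracked landmark
#'
#' @param frame Integer frame indices (>= 0), strictly increasing.
#' @param time_s Time in seconds from the first frame.
#' @param x,y,z Coordinates in mm; must be finite.
#' @param point_id Label of the tracked landmark.
#' @param reference_frame `"camera"` (calibration/world frame) or `"plant"`.
#' @return A `data.frame` of class `cn_traj3d` with columns
#'   `frame, time_s, x, y, z` and attributes `point_id`, `reference_frame`.
#' @export
trajectory3d <- function(frame, time_s, x, y, z, point_id = "P1",
                         reference_frame = c("camera", "plant")) {
  reference_frame <- match.arg(reference_frame)
  frame <- as.integer(frame)
  if (length(frame) == 0L) stopf("trajectory has no rows")
  if (any(frame < 0L)) stopf("frame indices must be >= 0")
  if (any(diff(frame) <= 0L)) {
    stopf("frame indices must be strictly increasing (violation at frame %d)",
          frame[which(diff(frame) <= 0L)[1] + 1L])
  }
  if (!all(is.finite(c(x, y, z)))) stopf("coordinates must be finite")
  structure(
    data.frame(frame = frame, time_s = as.numeric(time_s),
               x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
    point_id = point_id, reference_frame = reference_frame,
    class = c("cn_traj3d", "data.frame")
  )
}

#' @export
print.cn_traj2d <- function(x, ...) {
  cat(sprintf("<cn_traj2d> point '%s', camera %s, %d frames (%d lost)\n",
              attr(x, "point_id"), attr(x, "camera_id"), nrow(x),
              sum(x$status == "lost")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more rows\n", nrow(x) - 5))
  invisible(x)
}

#' @export
print.cn_traj3d <- function(x, ...) {
  cat(sprintf("<cn_traj3d> point '%s', %s frame, %d frames\n",
              attr(x, "point_id"), attr(x, "reference_frame"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more rows\n", nrow(x) - 5))
  invisible(x)
}

# n x 3 coordinate matrix of a 3D trajectory.
traj_xyz <- function(traj) {
  as.matrix(traj[, c("x", "y", "z")])
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6f", x))
}

read_meta_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ",", fixed = TRUE)[[1]]
    if (length(kv) >= 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stopf("no rows in %s", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(meta = meta, df = df)
}

check_columns <- function(df, needed, path) {
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stopf("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  }
}

check_frames <- function(frame, path) {
  if (anyNA(frame)) {
    stopf("%s: unparseable frame index at row %d", path, which(is.na(frame))[1])
  }
  d <- diff(frame)
  if (any(d == 0)) {
    stopf("%s: duplicated frame %d", path, frame[which(d == 0)[1] + 1L])
  }
  if (any(d < 0)) {
    stopf("%s: frame indices not increasing at frame %d",
          path, frame[which(d < 0)[1] + 1L])
  }
}

#' Read / write a 2D trajectory CSV
#'
#' The file starts with metadata lines `# point_id,<id>` and
#' `# camera_id,left|right`, followed by a header and rows
#' `frame,time_s,u,v,status`. Numeric values are written with 6 decimal
#' places; the round trip is lossless at that precision.
#'
#' @param path File path.
#' @return `read_trajectory2d()` returns a `cn_traj2d`.
#' @export
read_trajectory2d <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  parsed <- read_meta_csv(path)
  df <- parsed$df
  check_columns(df, c("frame", "time_s", "u", "v", "status"), path)
  if (is.null(parsed$meta$point_id) || is.null(parsed$meta$camera_id)) {
    stopf("%s: header must declare point_id and camera_id", path)
  }
  suppressWarnings({
    frame <- as.integer(df$frame)
    u <- as.numeric(df$u); v <- as.numeric(df$v)
    t_s <- as.numeric(df$time_s)
  })
  check_frames(frame, path)
  live <- df$status != "lost"
  badnum <- which(live & (!is.finite(u) | !is.finite(v) | !is.finite(t_s)))
  if (length(badnum)) stopf("%s: unparseable numeric at row %d", path, badnum[1])
  traj <- trajectory2d(frame, t_s, u, v, df$status,
                       point_id = parsed$meta$point_id,
                       camera_id = parsed$meta$camera_id)
  cn_log("read_trajectory2d: %d frames from %s", nrow(traj), path)
  traj
}

#' @param traj Trajectory object to write.
#' @rdname read_trajectory2d
#' @export
write_trajectory2d <- function(traj, path) {
  stopifnot(inherits(traj, "cn_traj2d"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# point_id,%s", attr(traj, "point_id")),
    sprintf("# camera_id,%s", attr(traj, "camera_id")),
    "frame,time_s,u,v,status",
    sprintf("%d,%s,%s,%s,%s", traj$frame, fmt6(traj$time_s),
            fmt6(traj$u), fmt6(traj$v), traj$status)
  ), con)
  invisible(path)
}

#' Read / write a 3D trajectory CSV
#'
#' Native files carry metadata lines `# point_id,<id>` and
#' `# reference_frame,camera|plant` and columns `frame,time_s,x,y,z` (mm).
#' Plain operator exports with only `x,y,z` columns (case-insensitive,
#' optional `frame`/`time` columns) are also accepted; missing frames are
#' numbered 0..n-1 and missing times filled from `frame_interval_s`.
#'
#' @param path File path.
#' @param frame_interval_s Frame interval used to synthesise times when the
#'   file has no time column (default 1/0.0056 s).
#' @return `read_trajectory3d()` returns a `cn_traj3d`.
#' @export
read_trajectory3d <- function(path, frame_interval_s = 1 / 0.0056) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  parsed <- read_meta_csv(path)
  df <- parsed$df
  names(df) <- tolower(names(df))
  if (!all(c("x", "y", "z") %in% names(df))) {
    stopf("%s: missing column(s) %s", path,
          paste(setdiff(c("x", "y", "z"), names(df)), collapse = ", "))
  }
  n <- nrow(df)
  if (n == 0L) stopf("no rows in %s", path)
  frame <- if ("frame" %in% names(df)) {
    suppressWarnings(as.integer(df$frame))
  } else {
    seq_len(n) - 1L
  }
  check_frames(frame, path)
  t_s <- if ("time_s" %in% names(df)) {
    suppressWarnings(as.numeric(df$time_s))
  } else if ("time" %in% names(df)) {
    suppressWarnings(as.numeric(df$time))
  } else {
    frame * frame_interval_s
  }
  suppressWarnings({
    x <- as.numeric(df$x); y <- as.numeric(df$y); z <- as.numeric(df$z)
  })
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | !is.finite(t_s))
  if (length(bad)) stopf("%s: unparseable numeric at row %d", path, bad[1])
  pid <- parsed$meta$point_id
  rf <- parsed$meta$reference_frame
  traj <- trajectory3d(frame, t_s, x, y, z,
                       point_id = if (is.null(pid)) "P1" else pid,
                       reference_frame = if (is.null(rf)) "camera" else rf)
  cn_log("read_trajectory3d: %d frames from %s (%s frame)",
         nrow(traj), path, attr(traj, "reference_frame"))
  traj
}

#' @param traj Trajectory object to write.
#' @rdname read_trajectory3d
#' @export
write_trajectory3d <- function(traj, path) {
  stopifnot(inherits(traj, "cn_traj3d"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# point_id,%s", attr(traj, "point_id")),
    sprintf("# reference_frame,%s", attr(traj, "reference_frame")),
    "frame,time_s,x,y,z",
    sprintf("%d,%s,%s,%s,%s", traj$frame, fmt6(traj$time_s),
            fmt6(traj$x), fmt6(traj$y), fmt6(traj$z))
  ), con)
  invisible(path)
}

#' Read a manual-corrections file
#'
#' Corrections replace the interactive re-marking loop of a GUI tracker: a
#' CSV with columns `frame,point_id,u,v`, each row re-seeding one landmark
#' at one frame.
#'
#' @param path File path.
#' @return `data.frame` with columns `frame, point_id, u, v`.
#' @export
read_corrections <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  check_columns(df, c("frame", "point_id", "u", "v"), path)
  df$frame <- as.integer(df$frame)
  cn_log("read_corrections: %d corrections from %s", nrow(df), path)
  df
}
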