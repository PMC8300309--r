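# Inter-operator agreement: per-frame trajectory distances, per-axis
# correlations and the absolute-agreement intraclass correlation ICC(A,1)
# over extracted feature tables.

join_frames <- function(traj_a, traj_b) {
  common <- intersect(traj_a$frame, traj_b$frame)
  if (!length(common)) stopf("trajectories share no frames")
  if (length(common) < nrow(traj_a) || length(common) < nrow(traj_b)) {
    cn_log("frame join: %d common frames (of %d / %d)",
           length(common), nrow(traj_a), nrow(traj_b))
  }
  list(
    a = traj_a[match(common, traj_a$frame), , drop = FALSE],
    b = traj_b[match(common, traj_b$frame), , drop = FALSE]
  )
}

#' Per-frame distance between two operators' trajectories
#'
#' The 3D Euclidean distance between the two reconstructed positions of the
#' same landmark at each common frame, plus a histogram of those distances.
#'
#' @param traj_a,traj_b `cn_traj3d` objects of the same landmark tracked by
#'   two operators. Frames are matched by index (inner join, logged when
#'   rows are dropped).
#' @param bin_width_mm Histogram bin width in mm (default 1).
#' @return Object of class `cn_frame_dist`: list with `distances` (mm, one
#'   per common frame), `histogram` (`data.frame` of bin edges and counts)
#'   and `frac_below(threshold_mm)` - the fraction of frames whose distance
#'   is below a threshold.
#' @export
per_frame_distance <- function(traj_a, traj_b, bin_width_mm = 1) {
  stopifnot(inherits(traj_a, "cn_traj3d"), inherits(traj_b, "cn_traj3d"))
  j <- join_frames(traj_a, traj_b)
  d <- row_norms(traj_xyz(j$a) - traj_xyz(j$b))
  breaks <- seq(0, max(d, bin_width_mm) + bin_width_mm, by = bin_width_mm)
  counts <- tabulate(findInterval(d, breaks, left.open = FALSE,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  structure(
    list(
      distances = d,
      histogram = data.frame(lower_mm = breaks[-length(breaks)],
                             upper_mm = breaks[-1], count = counts),
      frac_below = function(threshold_mm) mean(d < threshold_mm)
    ),
    class = "cn_frame_dist"
  )
}

#' @export
print.cn_frame_dist <- function(x, ...) {
  cat(sprintf(
    "<cn_frame_dist> %d frames, mean %.2f mm, median %.2f mm, %.1f%% < 5 mm\n",
    length(x$distances), mean(x$distances), stats::median(x$distances),
    100 * x$frac_below(5)
  ))
  invisible(x)
}

#' Per-axis correlation between two operators' trajectories
#'
#' Pearson correlation of the x, y and z coordinate series over common
#' frames.
#'
#' @param traj_a,traj_b `cn_traj3d` objects (>= 3 common frames).
#' @return Named numeric vector `c(x, y, z)`; an axis with zero variance in
#'   either trajectory yields `NA` with a warning.
#' @export
axis_correlation <- function(traj_a, traj_b) {
  stopifnot(inherits(traj_a, "cn_traj3d"), inherits(traj_b, "cn_traj3d"))
  j <- join_frames(traj_a, traj_b)
  if (nrow(j$a) < 3L) stopf("need >= 3 common frames for correlations")
  out <- c(x = NA_real_, y = NA_real_, z = NA_real_)
  for (ax in c("x", "y", "z")) {
    va <- j$a[[ax]]; vb <- j$b[[ax]]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      warnf("axis %s has zero variance; correlation undefined", ax)
    } else {
      out[ax] <- stats::cor(va, vb)
    }
  }
  out
}

#' Intraclass correlation ICC(A,1)
#'
#' Single-rater, absolute-agreement, two-way random-effects intraclass
#' correlation. From the two-way mean squares (rows = subjects `MSR`,
#' columns = raters `MSC`, residual `MSE`):
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}}
#' The null hypothesis ICC = 0 is tested with `F = MSR/MSE` on
#' `(n-1, n(k-1))` degrees of freedom.
#'
#' @param ratings Numeric n x k matrix: n subjects (circumnutations) rated
#'   by k raters (operators). No missing cells; n >= 3, k >= 2.
#' @return List with `icc`, `p_value`, `F`, `df1`, `df2` and the mean
#'   squares `MSR`, `MSC`, `MSE`.
#' @export
icc_a1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stopf("ratings matrix must have no missing cells")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L) stopf("need n >= 3 subjects and k >= 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  if (ss_total < .Machine$double.eps * n * k) {
    stopf("ratings have zero total variance; ICC undefined")
  }
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- max(ss_err / ((n - 1) * (k - 1)), 0)
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  f <- if (mse > 0) msr / mse else Inf
  df1 <- n - 1
  df2 <- n * (k - 1)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(icc = icc, p_value = p, F = f, df1 = df1, df2 = df2,
       MSR = msr, MSC = msc, MSE = mse)
}

# Feature columns compared between operators, in the conventional report
# order.
agreement_feature_order <- c(
  "duration_circumnutation",
  "x_center_coordinates_XZ", "z_center_coordinates_XZ",
  "x_centroid_coordinates_XZ", "z_centroid_coordinates_XZ",
  "center_distance_from_origin", "centroid_distance_from_origin",
  "length_major_axis", "line_integral", "area_circumnutation",
  "speed_center_XZ", "speed_centroid_XZ",
  "min_speed_circumnutations", "max_speed_circumnutations",
  "mean_speed_circumnutations",
  "center_distance_from_stimulus", "centroid_distance_from_stimulus",
  "angle_axis_stimulus", "min_dist_stimulus"
)

#' Per-feature inter-operator agreement
#'
#' Computes [icc_a1()] for every shared numeric feature column of two
#' operators' per-circumnutation tables (optionally merged with their
#' stimulus tables). Circumnutations are aligned by index; counts differing
#' by up to 20% are trimmed to the common length (logged), larger
#' mismatches are an error requiring manual alignment.
#'
#' @param feats_a,feats_b Feature tables from [circ_features()] (optionally
#'   `cbind`-ed with [stimulus_features()] columns) for operators A and B.
#' @return `data.frame` with columns `feature`, `icc`, `p_value`, ordered by
#'   the conventional feature order (extra shared columns follow).
#' @export
feature_agreement <- function(feats_a, feats_b) {
  na <- nrow(feats_a); nb <- nrow(feats_b)
  if (abs(na - nb) > 0.2 * max(na, nb)) {
    stopf(paste0("circumnutation counts differ by more than 20%% ",
                 "(%d vs %d); align the segmentations manually"), na, nb)
  }
  n <- min(na, nb)
  if (na != nb) {
    cn_log("feature_agreement: trimming to %d common circumnutations", n)
  }
  feats_a <- feats_a[seq_len(n), , drop = FALSE]
  feats_b <- feats_b[seq_len(n), , drop = FALSE]
  shared <- intersect(names(feats_a), names(feats_b))
  shared <- shared[vapply(
    shared,
    function(cl) is.numeric(feats_a[[cl]]) && is.numeric(feats_b[[cl]]),
    logical(1)
  )]
  shared <- setdiff(shared, c("circumnutation", "start_frame", "end_frame",
                              "t_mid_s", "turning_sum",
                              "axis_x1", "axis_z1", "axis_x2", "axis_z2"))
  shared <- c(intersect(agreement_feature_order, shared),
              setdiff(shared, agreement_feature_order))
  rows <- lapply(shared, function(cl) {
    a <- feats_a[[cl]]; b <- feats_b[[cl]]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3L) {
      return(data.frame(feature = cl, icc = NA_real_, p_value = NA_real_))
    }
    r <- tryCatch(icc_a1(cbind(a[ok], b[ok])), error = function(e) NULL)
    if (is.null(r)) {
      data.frame(feature = cl, icc = NA_real_, p_value = NA_real_)
    } else {
      data.frame(feature = cl, icc = r$icc, p_value = r$p_value)
    }
  })
  out <- do.call(rbind, rows)
  cn_log("feature_agreement: %d features over %d circumnutations",
         nrow(out), n)
  out
}
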