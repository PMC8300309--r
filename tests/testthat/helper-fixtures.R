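# Shared fixtures, all built in code.

options(circumnut.verbose = FALSE)

# Distortion-free rig for geometric identities.
clean_rig <- function() default_rig(distortion = FALSE)

# Planar circle trajectory in the plant frame (X-Z plane), CCW.
# n samples per revolution, `turns` revolutions, dt seconds apart. extra
# appends samples continuing around: extra = 1 closes the polyline (full
# perimeter), extra = 2 additionally closes the movement-vector loop
# (turning sum exactly 2*pi per turn).
circle_traj <- function(r = 10, n = 360, center = c(0, 0), y = 50,
                        turns = 1, dt = 10, extra = 0L) {
  k <- n * turns + extra
  th <- 2 * pi * (seq_len(k) - 1) / n
  trajectory3d(seq_len(k) - 1L, (seq_len(k) - 1) * dt,
               center[1] + r * cos(th), rep(y, k), center[2] + r * sin(th),
               reference_frame = "plant")
}

# One cn_circumnutation wrapping a whole trajectory.
as_circ <- function(traj) {
  structure(
    list(traj = traj, start = 1L, end = nrow(traj),
         start_frame = traj$frame[1], end_frame = traj$frame[nrow(traj)]),
    class = "cn_circumnutation"
  )
}

# Random world points inside the simulated working volume.
random_points <- function(n, seed = 1) {
  set.seed(seed)
  cbind(runif(n, -60, 60), runif(n, -60, 60), runif(n, -60, 60))
}

# Random 3D rotation matrix (det +1).
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
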