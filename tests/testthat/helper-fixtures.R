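# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# constant-pole trajectory over a frame range
pole_traj <- function(p, frames = 0:10, dt = 1) {
  data.frame(frame = frames, t_min = frames * dt,
             x_um = p[1], y_um = p[2], z_um = if (length(p) > 2) p[3] else 0)
}

# canonical axis-aligned spindle: poles (0,0,0) and (10,0,0), 11 frames
canonical_frames <- function(frames = 0:10) {
  spindle_frames(pole_traj(c(0, 0, 0), frames),
                 pole_traj(c(10, 0, 0), frames))
}

# one-row spindle frame directly from two pole points
frame_from_poles <- function(pa, pb, eps_pole = 1) {
  spindle_frames(pole_traj(pa, 0:1), pole_traj(pb, 0:1),
                 eps_pole = eps_pole)[1, ]
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(p, R, shift) as.numeric(R %*% as_point3(p) + shift)

as_point3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 2) p <- c(p, 0)
  p
}

# minimal kinematics table for event-rule tests: only the columns the
# event module consumes need real values
kin_stub <- function(t, d_plane, d_pole = 10, cx = 0, cy = 0, cz = 0) {
  tibble::tibble(frame = seq_along(t) - 1L, t_min = t,
                 cx = cx, cy = cy, cz = cz,
                 d_plane = d_plane, d_pole = d_pole,
                 nearest_pole = "A", d_kt = 1,
                 theta_pos = 0, theta_orient = 0)
}

# brute-force distance to a plane through m with unit normal u:
# coarse grid over the plane, then a fine grid around the best point
brute_force_plane_distance <- function(p, m, u) {
  p <- as_point3(p); m <- as_point3(m); u <- u / sqrt(sum(u^2))
  # orthonormal in-plane basis
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  scan <- function(center, half, step) {
    g <- seq(-half, half, by = step)
    pts <- expand.grid(a = g, b = g)
    px <- m[1] + center[1] * e1[1] + center[2] * e2[1] +
      pts$a * e1[1] + pts$b * e2[1]
    py <- m[2] + center[1] * e1[2] + center[2] * e2[2] +
      pts$a * e1[2] + pts$b * e2[2]
    pz <- m[3] + center[1] * e1[3] + center[2] * e2[3] +
      pts$a * e1[3] + pts$b * e2[3]
    d2 <- (p[1] - px)^2 + (p[2] - py)^2 + (p[3] - pz)^2
    i <- which.min(d2)
    list(d = sqrt(d2[i]), ab = center + c(pts$a[i], pts$b[i]))
  }
  coarse <- scan(c(0, 0), 25, 0.25)
  fine <- scan(coarse$ab, 0.3, 0.001)
  fine$d
}
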