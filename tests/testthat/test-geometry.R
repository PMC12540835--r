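test_that("spindle frame reconstruction: midpoint, axis, separation", {
  fr <- canonical_frames()[1, ]
  expect_equal(c(fr$mx, fr$my, fr$mz), c(5, 0, 0))
  expect_equal(c(fr$ux, fr$uy, fr$uz), c(1, 0, 0))
  expect_equal(fr$L, 10)

  # same spindle rotated 30 deg about z and translated: the oracle is the
  # same rigid transform applied to the expected axis
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(3, -2, 0)
  pa <- as.numeric(R %*% c(0, 0, 0) + shift)
  pb <- as.numeric(R %*% c(10, 0, 0) + shift)
  fr2 <- frame_from_poles(pa, pb)
  expect_equal(c(fr2$ux, fr2$uy, fr2$uz), as.numeric(R %*% c(1, 0, 0)),
               tolerance = 1e-12)
  expect_equal(fr2$L, 10, tolerance = 1e-12)
  expect_equal(c(fr2$mx, fr2$my, fr2$mz), as.numeric(R %*% c(5, 0, 0) + shift),
               tolerance = 1e-12)
})

test_that("degenerate spindles are rejected, not fabricated", {
  expect_error(frame_from_poles(c(1, 1, 0), c(1, 1, 0)), "degenerate")
  # below the separation floor on every frame
  expect_error(frame_from_poles(c(0, 0, 0), c(0.5, 0, 0)), "degenerate")
  # disjoint frame support
  expect_error(spindle_frames(pole_traj(c(0, 0, 0), 0:3),
                              pole_traj(c(10, 0, 0), 10:13)),
               "no defined frames")
})

test_that("pair center and interkinetochore distance", {
  expect_equal(pair_center(c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0))
  expect_equal(pair_center(c(1, 2, 3), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(interkinetochore_distance(c(0, 0, 0), c(0, 1.1, 0)), 1.1)
  expect_equal(interkinetochore_distance(c(1, 2, 3), c(1, 2, 3)), 0)

  set.seed(42)
  for (i in 1:20) {
    p1 <- rnorm(3); p2 <- rnorm(3)
    ctr <- pair_center(p1, p2)
    # equidistance oracle
    expect_equal(sqrt(sum((ctr - p1)^2)), sqrt(sum((ctr - p2)^2)),
                 tolerance = 1e-12)
    # rigid invariance of the distance
    R <- random_rotation(); sh <- rnorm(3, 0, 5)
    expect_equal(interkinetochore_distance(apply_rigid(p1, R, sh),
                                           apply_rigid(p2, R, sh)),
                 interkinetochore_distance(p1, p2), tolerance = 1e-9)
  }
})

test_that("distance to the equatorial plane", {
  fr <- canonical_frames()[1, ]          # plane x = 5
  expect_equal(plane_distance(c(7, 3, 0), fr), 2)
  expect_equal(plane_distance(c(5, 0, 0), fr), 0)
  expect_equal(plane_distance(c(fr$mx, fr$my, fr$mz), fr), 0)
})

test_that("nearest pole distance with deterministic tie-break", {
  fr <- canonical_frames()[1, ]
  r <- nearest_pole_distance(c(1, 0, 0), fr)
  expect_equal(r$distance, 1)
  expect_equal(r$pole, "A")
  tie <- nearest_pole_distance(c(5, 0, 0), fr)
  expect_equal(tie$distance, 5)
  expect_equal(tie$pole, "A")

  set.seed(7)
  for (i in 1:20) {
    pa <- rnorm(3, 0, 5); pb <- rnorm(3, 0, 5)
    if (sqrt(sum((pa - pb)^2)) < 1.5) next
    fr2 <- frame_from_poles(pa, pb)
    p <- rnorm(3, 0, 5)
    got <- nearest_pole_distance(p, fr2)
    da <- sqrt(sum((p - pa)^2)); db <- sqrt(sum((p - pb)^2))
    expect_equal(got$distance, min(da, db), tolerance = 1e-12)
    expect_equal(got$pole, if (da <= db) "A" else "B")
  }
})

test_that("positional angle is the acute line-line angle", {
  fr <- canonical_frames()[1, ]
  expect_equal(positional_angle(c(2, 2, 0), fr), 45, tolerance = 1e-9)
  expect_equal(positional_angle(c(2, 0, 0), fr), 0, tolerance = 1e-9)
  expect_error(positional_angle(c(0, 0, 0), fr), "coincides")

  set.seed(11)
  for (i in 1:20) {
    pa <- rnorm(3, 0, 5); pb <- rnorm(3, 0, 5)
    if (sqrt(sum((pa - pb)^2)) < 1.5) next
    fr2 <- frame_from_poles(pa, pb)
    p <- rnorm(3, 0, 5)
    u <- (pb - pa) / sqrt(sum((pb - pa)^2))
    pole <- if (sqrt(sum((p - pa)^2)) <= sqrt(sum((p - pb)^2))) pa else pb
    v <- p - pole
    exp_angle <- acos(min(1, abs(sum(v * u)) / sqrt(sum(v^2)))) * 180 / pi
    expect_equal(positional_angle(p, fr2), exp_angle, tolerance = 1e-9)
    expect_gte(positional_angle(p, fr2), 0)
    expect_lte(positional_angle(p, fr2), 90)
  }
})

test_that("sister-axis orientation angle", {
  fr <- canonical_frames()[1, ]
  expect_equal(pair_orientation_angle(c(1, 0, 0), c(2, 0, 0), fr), 0)
  expect_equal(pair_orientation_angle(c(1, 0, 0), c(1, 1, 0), fr), 90)
  expect_error(pair_orientation_angle(c(1, 0, 0), c(1, 0, 0), fr),
               "coincident")
})

test_that("all kinematic scalars are rigid-motion invariant", {
  set.seed(101)
  for (i in 1:25) {
    pa <- rnorm(3, 0, 5); pb <- rnorm(3, 0, 5)
    if (sqrt(sum((pa - pb)^2)) < 1.5) next
    s1 <- rnorm(3, 0, 5); s2 <- s1 + rnorm(3, 0, 0.5)
    if (sqrt(sum((s1 - s2)^2)) < 1e-3) next
    ctr <- pair_center(s1, s2)
    fr <- frame_from_poles(pa, pb)
    R <- random_rotation(); sh <- rnorm(3, 0, 10)
    frT <- frame_from_poles(apply_rigid(pa, R, sh), apply_rigid(pb, R, sh))
    s1T <- apply_rigid(s1, R, sh); s2T <- apply_rigid(s2, R, sh)
    ctrT <- pair_center(s1T, s2T)
    expect_equal(plane_distance(ctrT, frT), plane_distance(ctr, fr),
                 tolerance = 1e-9)
    expect_equal(nearest_pole_distance(ctrT, frT)$distance,
                 nearest_pole_distance(ctr, fr)$distance, tolerance = 1e-9)
    expect_equal(interkinetochore_distance(s1T, s2T),
                 interkinetochore_distance(s1, s2), tolerance = 1e-9)
    expect_equal(positional_angle(ctrT, frT), positional_angle(ctr, fr),
                 tolerance = 1e-7)
    expect_equal(pair_orientation_angle(s1T, s2T, frT),
                 pair_orientation_angle(s1, s2, fr), tolerance = 1e-7)
  }
})

test_that("swapping pole labels flips nearest-pole labels only", {
  set.seed(202)
  for (i in 1:10) {
    pa <- rnorm(3, 0, 5); pb <- rnorm(3, 0, 5)
    if (sqrt(sum((pa - pb)^2)) < 1.5) next
    p <- rnorm(3, 0, 5)
    fr <- frame_from_poles(pa, pb)
    frS <- frame_from_poles(pb, pa)
    expect_equal(plane_distance(p, frS), plane_distance(p, fr),
                 tolerance = 1e-12)
    a <- nearest_pole_distance(p, fr); b <- nearest_pole_distance(p, frS)
    expect_equal(a$distance, b$distance, tolerance = 1e-12)
    if (abs(sqrt(sum((p - pa)^2)) - sqrt(sum((p - pb)^2))) > 1e-9)
      expect_true(a$pole != b$pole)
  }
})

test_that("gap filling: short gaps interpolated, long gaps undefined", {
  traj <- data.frame(frame = c(0, 1, 3, 4), t_min = c(0, 1, 3, 4),
                     x_um = c(0, 1, 3, 4), y_um = 0, z_um = 0)
  filled <- fill_trajectory_gaps(traj, max_gap = 2)
  expect_true(filled$defined[filled$frame == 2])
  expect_equal(filled$x_um[filled$frame == 2], 2)   # midpoint of neighbours

  long <- data.frame(frame = c(0, 1, 6, 7), t_min = c(0, 1, 6, 7),
                     x_um = c(0, 1, 6, 7), y_um = 0, z_um = 0)
  filled2 <- fill_trajectory_gaps(long, max_gap = 2)
  expect_false(any(filled2$defined[filled2$frame %in% 2:5]))

  bad <- data.frame(frame = c(0, 2, 1), t_min = 0:2, x_um = 0, y_um = 0)
  expect_error(fill_trajectory_gaps(bad), "strictly increasing")
})

test_that("pair kinematics: assembly, identity, gap policy", {
  frames <- canonical_frames(0:4)
  s1 <- data.frame(frame = 0:4, t_min = 0:4, x_um = 2, y_um = 1, z_um = 0)
  s2 <- data.frame(frame = 0:4, t_min = 0:4, x_um = 2, y_um = -1, z_um = 0)
  kin <- pair_kinematics(s1, s2, frames)
  expect_equal(nrow(kin), 5)
  expect_true(all(kin$d_plane == 3))   # center (2,0), plane x=5
  expect_true(all(kin$d_pole == 2))
  expect_true(all(kin$nearest_pole == "A"))
  expect_true(all(kin$d_kt == 2))
  expect_true(all(kin$theta_orient == 90))
  # plane projection identity
  expect_equal(kin$d_plane, abs(kin$cx - 5), tolerance = 1e-12)

  # one-frame sister gap: interpolated kinematics equal neighbour midpoint
  s1g <- s1[-3, ]
  king <- pair_kinematics(s1g, s2, frames)
  expect_equal(nrow(king), 5)
  expect_equal(king$cx[king$frame == 2], 2)

  # 4-frame gap with max_gap 2: records absent
  frames10 <- canonical_frames(0:9)
  s1l <- data.frame(frame = c(0:2, 7:9), t_min = c(0:2, 7:9),
                    x_um = 2, y_um = 1, z_um = 0)
  s2l <- data.frame(frame = 0:9, t_min = 0:9, x_um = 2, y_um = -1, z_um = 0)
  kinl <- pair_kinematics(s1l, s2l, frames10)
  expect_false(any(kinl$frame %in% 3:6))

  expect_error(pair_kinematics(
    data.frame(frame = 0:2, t_min = 0:2, x_um = 0, y_um = 0, z_um = 0),
    data.frame(frame = 10:12, t_min = 10:12, x_um = 0, y_um = 0, z_um = 0),
    frames), "no defined frames")
})
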