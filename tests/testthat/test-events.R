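test_that("polar classification: strictly closer to a pole than to the plane", {
  frames <- canonical_frames(0:4)
  near_pole <- pair_kinematics(
    data.frame(frame = 0:4, t_min = 0:4, x_um = 1, y_um = 0.5, z_um = 0),
    data.frame(frame = 0:4, t_min = 0:4, x_um = 1, y_um = -0.5, z_um = 0),
    frames)
  expect_true(is_polar(near_pole, 0))      # d_pole 1 < d_plane 4

  at_plate <- pair_kinematics(
    data.frame(frame = 0:4, t_min = 0:4, x_um = 5, y_um = 1.5, z_um = 0),
    data.frame(frame = 0:4, t_min = 0:4, x_um = 5, y_um = 0.5, z_um = 0),
    frames)
  expect_false(is_polar(at_plate, 0))      # d_pole ~4.12 > d_plane 0

  tie <- kin_stub(0:4, d_plane = 2.5, d_pole = 2.5)
  expect_false(is_polar(tie, 0))           # tie is not polar
  expect_error(is_polar(tie, 99), "undefined")
})

test_that("ever-aligned uses an inclusive 3-um boundary", {
  expect_true(is_aligned_ever(kin_stub(0:3, c(5, 4, 2.9, 4))))
  expect_true(is_aligned_ever(kin_stub(0:3, c(5, 4, 3.0, 4))))
  expect_false(is_aligned_ever(kin_stub(0:3, c(5, 4, 3.1, 4))))
  expect_error(is_aligned_ever(kin_stub(numeric(0), numeric(0))), "empty")
})

test_that("plate crossing is the first strict drop below 2 um", {
  expect_equal(detect_plate_crossing(kin_stub(0:4, c(5, 4, 3, 1.8, 1.5))), 3)
  expect_true(is.na(detect_plate_crossing(kin_stub(0:4, c(5, 4, 3, 2, 2)))))
  # first crossing counts even without persistence
  expect_equal(detect_plate_crossing(kin_stub(0:3, c(5, 1.9, 2.5, 1.7))), 1)
  # exact 2.0 does not cross (strict rule)
  expect_true(is.na(detect_plate_crossing(kin_stub(0:2, c(5, 2.0, 2.0)))))
  # optional dwell requirement discards transient dips
  th_dwell <- congression_thresholds(min_dwell = 2)
  expect_equal(detect_plate_crossing(kin_stub(0:5, c(5, 1.9, 2.5, 1.7, 1.6, 1.5)),
                                     th_dwell), 3)
})

test_that("congression velocity over the pre-crossing window", {
  # constant approach at 0.5 um/min, dt = 1, crossing at d < 2
  d <- 8 - 0.5 * (0:13)
  kin <- kin_stub(0:13, d)
  tc <- detect_plate_crossing(kin)
  expect_equal(tc, 13)   # d = 1.5 at t = 13
  cv <- congression_velocity(kin, tc)
  expect_equal(cv$velocity, 0.5, tolerance = 1e-12)
  expect_equal(cv$window_used, 6)

  # movement away from the plate at 0.3 um/min over the window preceding a
  # (supplied) crossing time gives a negative velocity of that magnitude
  kin2 <- kin_stub(0:10, 1 + 0.3 * (0:10))
  cv2 <- congression_velocity(kin2, t_cross = 6)
  expect_equal(cv2$velocity, -0.3, tolerance = 1e-12)

  # a shortened window is accepted down to half the nominal window
  d3 <- c(4.4, 3.6, 2.8, 1.9)
  cv3 <- congression_velocity(kin_stub(0:3, d3), 3)
  expect_equal(cv3$window_used, 3)
  expect_equal(cv3$velocity, (4.4 - 1.9) / 3, tolerance = 1e-12)
  d4 <- c(3.6, 2.8, 1.9)
  expect_error(congression_velocity(kin_stub(0:2, d4), 2), "less than half")
})

test_that("mean speed over an interval follows the plate sign convention", {
  expect_equal(mean_speed_over_interval(kin_stub(0:30, seq(8, 2, length.out = 31)),
                                        0, 30), 0.2, tolerance = 1e-12)
  expect_equal(mean_speed_over_interval(kin_stub(0:30, rep(5, 31)), 0, 30), 0)
  expect_equal(mean_speed_over_interval(kin_stub(0:30, seq(4, 5.5, length.out = 31)),
                                        0, 30), -0.05, tolerance = 1e-12)
  expect_error(mean_speed_over_interval(kin_stub(0:5, rep(5, 6)), 0, 30),
               "endpoints")
})

test_that("alignment success fraction over initially polar pairs", {
  cross <- kin_stub(0:31, c(rep(4, 10), rep(1.5, 22)), d_pole = 1)
  stay <- kin_stub(0:31, rep(4, 32), d_pole = 1)
  expect_equal(alignment_success_fraction(list(cross, cross, cross, stay)), 75)
  expect_equal(alignment_success_fraction(list(stay, stay, stay, stay, stay)), 0)
  # aligned-from-the-start pairs are not in the denominator
  aligned <- kin_stub(0:31, rep(0.5, 32), d_pole = 5)
  expect_equal(alignment_success_fraction(list(cross, stay, aligned)), 50)
  expect_error(alignment_success_fraction(list(aligned)), "no pairs are polar")
  # crossing after the window does not count
  late <- kin_stub(0:40, c(rep(4, 35), rep(1.5, 6)), d_pole = 1)
  expect_equal(alignment_success_fraction(list(late)), 0)
})

test_that("polar count timeline at 12 min and every 6 min", {
  polar <- kin_stub(0:24, rep(5, 25), d_pole = 1)
  tl <- polar_counts_timeline(list(polar, polar, polar),
                              t_end = 24)
  expect_equal(tl$t_min, c(12, 18, 24))
  expect_equal(tl$n_polar, c(3L, 3L, 3L))
  aligned <- kin_stub(0:24, rep(1, 25), d_pole = 6)
  tl2 <- polar_counts_timeline(list(aligned, aligned), t_end = 24)
  expect_equal(tl2$n_polar, c(0L, 0L, 0L))
})

test_that("misalignment categories follow the outside-pair counts", {
  th <- congression_thresholds()
  expect_equal(misalignment_category(rep(1, 40), th), "tight")
  expect_equal(misalignment_category(c(rep(1, 37), rep(6, 3)), th), "low")
  expect_equal(misalignment_category(c(rep(1, 35), rep(6, 5)), th), "high")
  expect_equal(misalignment_category(c(rep(1, 34), rep(6, 6)), th), "high")
  # plate not formed: under 75% of pairs near the plane
  expect_equal(misalignment_category(c(rep(1, 10), rep(6, 10)), th), "no_plate")
  expect_error(misalignment_category(rep(NA_real_, 3), th), "no pairs")
})

test_that("maximum chromosome spread equals the exhaustive pairwise scan", {
  expect_equal(max_chromosome_spread(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(max_chromosome_spread(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  set.seed(5)
  centers <- matrix(rnorm(40, 0, 4), ncol = 2)
  brute <- 0
  for (i in 1:19) for (j in (i + 1):20)
    brute <- max(brute, sqrt(sum((centers[i, ] - centers[j, ])^2)))
  expect_equal(max_chromosome_spread(centers), brute, tolerance = 1e-12)
  expect_error(max_chromosome_spread(matrix(0, 1, 2)), "at least two")
})

test_that("event registration re-indexes time around the event", {
  kin <- kin_stub(0:20, seq(20, 0, length.out = 21))
  reg <- register_to_event(kin, event_time = 10, pre = 5, post = 5)
  expect_equal(range(reg$t_rel), c(-5, 5))
  expect_equal(reg$d_plane[reg$t_rel == 0], kin$d_plane[kin$t_min == 10])
  reg0 <- register_to_event(kin, event_time = 0, pre = 5, post = 5)
  expect_true(all(reg0$t_rel >= 0))
  expect_error(register_to_event(kin, NA, 5, 5), "undefined")
})

test_that("per-pair event table assembles the rules coherently", {
  cross <- kin_stub(0:31, pmax(8 - 0.5 * (0:31), 0.5), d_pole = 1)
  stay <- kin_stub(0:31, rep(4, 32), d_pole = 1)
  ev <- pair_event_table(list(cross, stay), c("p1", "p2"))
  expect_equal(ev$pair_id, c("p1", "p2"))
  expect_true(ev$polar_initial[1] && ev$polar_initial[2])
  expect_equal(ev$t_cross_min[1], 13)
  expect_equal(ev$v_congress_um_per_min[1], 0.5, tolerance = 1e-12)
  expect_true(is.na(ev$t_cross_min[2]))
  expect_true(ev$success_30min[1])
  expect_false(ev$success_30min[2])
})
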