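test_that("segment_movement reads bouts and stops off the displacement series", {
  # m m i m i i m -> 3 bouts, 2 stops
  seg <- segment_movement(traj_from_steps(c(1, 1, 0, 1, 0, 0, 1)), 0.1)
  expect_equal(nrow(seg$bouts), 3)
  expect_equal(count_stops(seg), 2)
  expect_equal(count_stops(seg), nrow(seg$bouts) - 1)

  # all immobile: degenerate, no bouts, no stops
  seg0 <- segment_movement(traj_from_steps(rep(0, 6)), 0.1)
  expect_equal(nrow(seg0$bouts), 0)
  expect_equal(count_stops(seg0), 0)

  # leading/trailing immobility does not create stops
  seg1 <- segment_movement(traj_from_steps(c(0, 0, 1, 1, 0, 0)), 0.1)
  expect_equal(nrow(seg1$bouts), 1)
  expect_equal(count_stops(seg1), 0)

  # moving is strict: a step exactly at epsilon is immobile
  sege <- segment_movement(traj_from_steps(c(0.3, 0.4)), 0.3)
  expect_equal(as.vector(sege$moving), c(FALSE, TRUE))

  expect_error(segment_movement(traj_from_steps(1), -1), class = "ek_invalid_input")
})

test_that("the five statistics match their defining arithmetic", {
  # 3-4-5 triangle: one step of 5 cm
  tr <- trajectory(c(0, 3), c(0, 4), dt_s = 0.1)
  expect_equal(traveled_distance(segment_movement(tr, 0)), 5)

  # no moving steps -> distance 0, velocity NA
  seg0 <- segment_movement(traj_from_steps(rep(0, 5)), 0.1)
  expect_equal(traveled_distance(seg0), 0)
  expect_true(is.na(effective_velocity(seg0)))

  # immobile time excluded: 10 moving cm + 90 immobile frames, dt 0.1
  seg <- segment_movement(traj_from_steps(c(rep(1, 10), rep(0, 90))), 0.1)
  expect_equal(effective_velocity(seg), 10)

  # speeds 10,20,30 cm/s at dt 0.1 -> dv = +10,+10 -> 100 cm/s^2
  seg <- segment_movement(traj_from_steps(c(1, 2, 3)), 0.1)
  expect_equal(mean_acceleration(seg), 100)

  # constant-speed bout: no positive increments
  seg <- segment_movement(traj_from_steps(rep(2, 10)), 0.1)
  expect_equal(mean_acceleration(seg), 0)

  # alternating 10,20,10,20: positive deltas {+10,+10} -> 100
  seg <- segment_movement(traj_from_steps(c(1, 2, 1, 2)), 0.1)
  expect_equal(mean_acceleration(seg), 100)

  # all_pairs reading divides by all moving pairs: {+10,-10,+10} -> 200/3
  expect_equal(mean_acceleration(seg, "all_pairs"), (10 + 0 + 10) / 3 / 0.1)

  # distance/stop identities
  seg <- segment_movement(traj_from_steps(c(25, 25, 0, 25, 0, 25)), 0.1)
  expect_equal(count_stops(seg), 2)
  expect_equal(distance_per_stop(seg), 50)
  expect_equal(distance_per_stop(seg) * count_stops(seg),
               traveled_distance(seg))
  expect_true(is.na(distance_per_stop(segment_movement(
    traj_from_steps(rep(1, 4)), 0.1))))
})

test_that("summaries satisfy the defining identities on random walks", {
  for (seed in 1:25) {
    tr <- rw_traj(300, seed = seed)
    seg <- segment_movement(tr, 0.3)
    sm <- summarize_kinematics(tr, 0.3)
    if (sm$moving_time_s > 0) {
      expect_equal(sm$eff_vel_cm_s * sm$moving_time_s, sm$distance_cm,
                   tolerance = 1e-9)
    }
    if (sm$stops > 0) {
      expect_equal(sm$dist_per_stop_cm * sm$stops, sm$distance_cm,
                   tolerance = 1e-9)
    }
    expect_equal(sm$stops, max(0, nrow(seg$bouts) - 1))
  }
})

test_that("statistics are scale-equivariant and stops are time-reversal invariant", {
  for (seed in 1:10) {
    tr <- rw_traj(300, seed = seed)
    c_ <- 3.7
    tr_scaled <- trajectory(tr$x_cm * c_, tr$y_cm * c_, dt_s = attr(tr, "dt_s"))
    a <- summarize_kinematics(tr, 0.3)
    b <- summarize_kinematics(tr_scaled, 0.3 * c_)
    expect_equal(b$distance_cm, c_ * a$distance_cm)
    expect_equal(b$eff_vel_cm_s, c_ * a$eff_vel_cm_s)
    expect_equal(b$mean_acc_cm_s2, c_ * a$mean_acc_cm_s2)
    expect_equal(b$stops, a$stops)
    expect_equal(b$dist_per_stop_cm, c_ * a$dist_per_stop_cm)
    # reversal
    tr_rev <- trajectory(rev(tr$x_cm), rev(tr$y_cm), dt_s = attr(tr, "dt_s"))
    expect_equal(summarize_kinematics(tr_rev, 0.3)$stops, a$stops)
  }
})

test_that("traveled distance and moving-step count are non-increasing in epsilon", {
  tr <- rw_traj(400, seed = 11)
  eps_grid <- seq(0, 2, by = 0.1)
  dists <- vapply(eps_grid, function(e) traveled_distance(segment_movement(tr, e)),
                  numeric(1))
  movs <- vapply(eps_grid, function(e) sum(segment_movement(tr, e)$moving),
                 numeric(1))
  expect_true(all(diff(dists) <= 1e-12))
  expect_true(all(diff(movs) <= 0))
})

test_that("minute bins are independent half-open windows", {
  # uniform speed, dt 0.5 s, 10 min: equal bins up to one boundary step
  tr <- traj_from_steps(rep(1, 599), dt = 0.5)
  bins <- bin_by_minute(tr, epsilon_cm = 0.1, bin_s = 60)
  expect_equal(nrow(bins), 5)
  expect_true(max(bins$distance_cm) - min(bins$distance_cm) <= 1)

  # session shorter than one bin -> one partial bin
  short <- bin_by_minute(traj_from_steps(rep(1, 20), dt = 0.5), 0.1, 60)
  expect_equal(nrow(short), 1)

  # boundary accounting on a random walk
  tr <- rw_traj(3000, seed = 3)
  whole <- traveled_distance(segment_movement(tr, 0.3))
  bins <- bin_by_minute(tr, 0.3, bin_s = 10)
  max_step <- max(segment_movement(tr, 0.3)$step_cm)
  expect_lte(whole - sum(bins$distance_cm), (nrow(bins) - 1) * max_step)
  expect_gte(whole - sum(bins$distance_cm), 0)
})

test_that("straight-walk segments match definition and an exhaustive scan", {
  # perfectly straight 10-step run at 2 cm/step
  tr <- traj_from_steps(rep(2, 10), dt = 0.1)
  seg <- straight_walk_segments(tr, min_steps = 3, straightness_min = 0.95,
                                epsilon_cm = 0.3)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$straightness, 1)
  expect_equal(seg$walking_velocity_cm_s, 20)
  expect_equal(seg$duration_s, 1)

  # circle: no straight segments at 0.95 (30 degrees of turn per step, so
  # every >= 3-step window bends well past the straightness threshold)
  th <- seq(0, 2 * pi, length.out = 13)
  circ <- trajectory(5 * cos(th), 5 * sin(th), dt_s = 0.1)
  expect_equal(nrow(straight_walk_segments(circ, 3, 0.95, 0.3)), 0)

  # mixed path: agree with an independent full window scan
  tr <- rw_traj(150, seed = 21)
  got <- straight_walk_segments(tr, 3, 0.9, 0.3)
  seg <- segment_movement(tr, 0.3)
  cum <- c(0, cumsum(seg$step_cm))
  qual <- list()
  n <- length(seg$moving)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (!all(seg$moving[i:j])) next
      path <- cum[j + 1] - cum[i]
      net <- sqrt((tr$x_cm[j + 1] - tr$x_cm[i])^2 +
                  (tr$y_cm[j + 1] - tr$y_cm[i])^2)
      if (path > 0 && net / path >= 0.9) qual[[length(qual) + 1]] <- c(i, j)
    }
  }
  keep <- Filter(function(w) {
    !any(vapply(qual, function(v) v[1] <= w[1] && v[2] >= w[2] &&
                  (v[1] < w[1] || v[2] > w[2]), logical(1)))
  }, qual)
  expect_equal(nrow(got), length(keep))
  if (length(keep)) {
    want <- do.call(rbind, keep)
    expect_equal(got$start_frame, want[, 1] - 1)
    expect_equal(got$end_frame, want[, 2])
  }
})

test_that("turning events count full and half turns", {
  dt <- 1 / 30
  # slightly more than one full circle
  th <- seq(0, 2 * pi * 1.02, length.out = 40)
  circ <- trajectory(5 * cos(th), 5 * sin(th), dt_s = dt)
  ev <- turning_events(circ, window_s = 3, epsilon_cm = 0.3)
  expect_equal(ev$circlings, 1)
  expect_equal(ev$returns, 0)

  # straight out-and-back
  oab <- traj_from_steps(c(rep(1, 10), rep(-1, 10)), dt = dt)
  ev <- turning_events(oab, window_s = 3, epsilon_cm = 0.3)
  expect_equal(ev$returns, 1)
  expect_equal(ev$circlings, 0)

  # two full loops -> 2 circlings
  th2 <- seq(0, 4 * pi * 1.01, length.out = 80)
  loops <- trajectory(5 * cos(th2), 5 * sin(th2), dt_s = dt)
  expect_equal(turning_events(loops, 3, 0.3)$circlings, 2)
})
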