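test_that("direct differentiation reproduces simple motions per 2-ms interval", {
  n <- 101
  tt <- (0:(n - 1)) * 0.002
  lin <- make_traj(z = rep(5, n), x = 30 * tt)
  v <- lateral_velocity(lin)
  expect_equal(v$v, rep(30, n - 1))
  expect_length(v$time, n - 1)
  flat <- make_traj(z = rep(5, n), x = rep(2, n))
  expect_equal(lateral_velocity(flat)$v, rep(0, n - 1))
  expect_error(lateral_velocity(make_traj(z = 1)), "two samples")
})

test_that("differentiating a minimum-jerk reach matches its analytic derivative", {
  tt <- (0:350) * 0.002
  x <- min_jerk_pos(tt, 0.1, 0.662, 0, -20)
  tr <- make_traj(z = rep(5, length(tt)), x = x)
  v <- lateral_velocity(tr)
  mid <- v$time + 0.001
  expect_lt(max(abs(v$v - min_jerk_vel(mid, 0.1, 0.662, 0, -20))), 0.05)
})

test_that("velocity intervals touching a missing sample are flagged", {
  n <- 50
  tr <- make_traj(z = rep(5, n), x = (0:(n - 1)) * 0.1)
  tr$missing[20] <- TRUE
  tr$x[20] <- NA
  v <- lateral_velocity(tr)
  expect_true(all(v$missing[19:20]))
  expect_true(all(is.na(v$v[19:20])))
  expect_false(any(v$missing[-(19:20)]))
})

test_that("cumulative summation of the velocity recovers lateral displacement", {
  tr <- simulate_trial(make_spec(), seed = 31, reach = reach_fixed())
  v <- lateral_velocity(tr)
  rebuilt <- tr$x[1] + cumsum(v$v) * 0.002
  expect_equal(rebuilt, tr$x[-1], tolerance = 1e-10)
})

test_that("a constant-velocity descent through the screen plane yields no tap", {
  z <- 3 - 0.25 * (0:20)  # crosses zero with no deceleration
  expect_null(detect_tap(make_traj(z = z)))
})

test_that("the tap fires at the first sample satisfying the 1-mm/2-cm rule", {
  # approach at 0.3 cm/sample, halving to 0.15 cm/sample from z = 1 cm
  z <- c(seq(2.5, 1.0, by = -0.3), seq(0.85, 0.1, by = -0.15))
  tr <- make_traj(z = z, x = 0.1 * seq_along(z), y = rep(8, length(z)))
  tap <- detect_tap(tr)
  # hand application of the rule: delta drops from 0.30 to 0.15 (> 0.1 cm)
  # first at sample 7, where z = 0.85 < 2
  expect_equal(tap$sample_index, 7L)
  expect_equal(tap$tap_time, tr$time[7])
  expect_equal(tap$tap_position, c(tr$x[7], tr$y[7]))
})

test_that("tap detection is translation-invariant in x and y and reports one event", {
  z <- c(seq(2.5, 1.0, by = -0.3), seq(0.85, 0.1, by = -0.15), rep(0.05, 10))
  t1 <- detect_tap(make_traj(z = z))
  t2 <- detect_tap(make_traj(z = z, x = rep(50, length(z)),
                             y = rep(-40, length(z))))
  expect_equal(t1$sample_index, t2$sample_index)
  expect_equal(t1$tap_time, t2$tap_time)
})

test_that("detected taps sit within 2 samples of ground-truth contact on noise-free trials", {
  sched <- build_schedule(2, 1, seed = 41)  # 24 trials, all conditions
  session <- simulate_session(sched, noise = noise_off(), seed = 42)
  err <- vapply(session, function(tr) {
    tap <- detect_tap(tr)
    if (is.null(tap)) return(Inf)
    abs(tap$sample_index - (round(tr$contact_time / 0.002) + 1))
  }, numeric(1))
  expect_true(all(err <= 2))
})

test_that("hit classification tests the fingertip against target and zone outlines", {
  geom <- mfr_geometry()
  # land exactly on the zone center at the time the target is centered there
  n <- 340
  tt <- (0:(n - 1)) * 0.002
  z <- pmax(0.2 * (333 - (0:(n - 1))), 0)  # 100 cm/s descent, lands at ~666 ms
  tr <- make_traj(z = z, x = rep(0, n), y = rep(10, n), time = tt)
  tap <- detect_tap(tr, geom)
  expect_false(is.null(tap))
  expect_true(tap$hit_zone)
  # target center at ~666 ms is within 0.1 cm of the zone center: a hit
  expect_true(tap$hit_target)
  # landing 1.5 cm off the target center but inside the 3-cm zone radius
  tr2 <- make_traj(z = z, x = rep(1.6, n), y = rep(10, n), time = tt)
  tap2 <- detect_tap(tr2, geom)
  expect_false(tap2$hit_target)
  expect_true(tap2$hit_zone)
})
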