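test_that("trajectories sample at exactly 500 Hz and are seed-reproducible", {
  tr <- simulate_trial(make_spec(), seed = 1)
  expect_equal(unique(round(diff(tr$time), 12)), 0.002)
  tr2 <- simulate_trial(make_spec(), seed = 1)
  expect_identical(tr, tr2)
  tr3 <- simulate_trial(make_spec(), seed = 2)
  expect_false(identical(tr$x, tr3$x))
})

test_that("the finger stays on or in front of the screen and lands at contact", {
  tr <- simulate_trial(make_spec(), noise = noise_off(), seed = 4,
                       reach = reach_fixed())
  expect_true(all(tr$z >= 0))
  expect_true(all(tr$z[tr$time >= tr$contact_time] == 0))
  expect_true(all(tr$z[tr$time < tr$reach_onset] == 0))
  expect_gt(max(tr$z), 5)
})

test_that("with zero gain, left and right trials of a cell are identical", {
  resp0 <- response_model(gain_by_size = c("7" = 0, "37" = 0, "67" = 0))
  trR <- simulate_trial(make_spec(direction = "right"), resp0, noise_off(),
                        seed = 9, reach = reach_fixed())
  trL <- simulate_trial(make_spec(direction = "left"), resp0, noise_off(),
                        seed = 9, reach = reach_fixed())
  expect_equal(trR$x, trL$x, tolerance = 1e-12)
  expect_equal(trR$y, trL$y, tolerance = 1e-12)
})

test_that("noise-free right-left velocity difference is exactly twice the injected bump", {
  resp <- response_model()
  g <- response_gain(resp, 7, "frame")
  trR <- simulate_trial(make_spec(direction = "right"), resp, noise_off(),
                        seed = 9, reach = reach_fixed())
  trL <- simulate_trial(make_spec(direction = "left"), resp, noise_off(),
                        seed = 9, reach = reach_fixed())
  vR <- lateral_velocity(trR); vL <- lateral_velocity(trL)
  diff_v <- vR$v - vL$v
  # expected: twice the interval-average of the injected velocity, by
  # independent quadrature of the closed-form bump over each 2-ms interval
  pre <- vR$time < trR$contact_time - 0.002
  expected <- vapply(vR$time[pre], function(t0) {
    2 * stats::integrate(injected_velocity, t0, t0 + 0.002, gain = g,
                         rel.tol = 1e-10)$value / 0.002
  }, numeric(1))
  expect_equal(diff_v[pre], expected, tolerance = 1e-6)
  expect_gt(max(diff_v[pre]), 2 * g * 20 * 0.9)  # the bump is actually there
})

test_that("injected response displacement is independent of sampling phase", {
  resp <- response_model()
  g <- response_gain(resp, 7, "frame")
  final_disp <- vapply(c(0.331, 0.3523, 0.3747), function(onset) {
    trR <- simulate_trial(make_spec(direction = "right", square_onset = onset),
                          resp, noise_off(), seed = 3, reach = reach_fixed())
    trL <- simulate_trial(make_spec(direction = "left", square_onset = onset),
                          resp, noise_off(), seed = 3, reach = reach_fixed())
    n <- length(trR$x)
    trR$x[n] - trL$x[n]
  }, numeric(1))
  expect_equal(final_disp, rep(2 * g * 20 * resp$kernel_width * 0.5, 3),
               tolerance = 1e-9)
})

test_that("missing gaps are contiguous, 10-50 samples, and inside the analysis window", {
  nz <- noise_model(position_sd = 0, endpoint_sd = 0, missing_rate = 1,
                    timing_issue_rate = 0)
  for (seed in 1:5) {
    tr <- simulate_trial(make_spec(), noise = nz, seed = seed,
                         reach = reach_fixed())
    runs <- rle(tr$missing)
    gap <- runs$lengths[runs$values]
    expect_length(gap, 1)
    expect_true(gap >= 10 && gap <= 50)
    tmiss <- range(tr$time[tr$missing])
    expect_true(tmiss[1] >= tr$recorded_square_onset - 1e-9)
    expect_true(tmiss[1] <= tr$recorded_square_onset + 0.3 + 1e-9)
    expect_true(all(is.na(tr$x[tr$missing])))
  }
})

test_that("timing issues shift the recorded square motion by more than one frame", {
  nz <- noise_model(position_sd = 0, endpoint_sd = 0, missing_rate = 0,
                    timing_issue_rate = 1)
  for (seed in 1:5) {
    tr <- simulate_trial(make_spec(), noise = nz, seed = seed)
    expect_gt(abs(tr$recorded_square_onset - tr$trial$square_onset), 1 / 120)
    expect_equal(tr$recorded_square_offset - tr$recorded_square_onset, 0.1)
  }
  tr <- simulate_trial(make_spec(), noise = noise_off(), seed = 1)
  expect_equal(tr$recorded_square_onset, tr$trial$square_onset)
})

test_that("sessions are deterministic and sized to their schedule", {
  sched <- build_schedule(2, 1, seed = 6)
  s1 <- simulate_session(sched, seed = 10)
  s2 <- simulate_session(sched, seed = 10)
  expect_identical(s1, s2)
  expect_length(s1, 24)
  expect_error(simulate_session(sched[0, ], seed = 1), "at least one")
})

test_that("the per-session missing-trial count is binomially plausible at 1%", {
  sched <- build_schedule(25, 2, seed = 13)
  session <- simulate_session(sched, noise = noise_model(missing_rate = 0.01),
                              seed = 14)
  n_missing <- sum(vapply(session, function(tr) any(tr$missing), logical(1)))
  bounds <- stats::qbinom(c(0.005, 0.995), 600, 0.01)
  expect_true(n_missing >= bounds[1] && n_missing <= bounds[2])
})
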