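test_that("a clean session loses no trials to exclusion", {
  sched <- build_schedule(1, 1, seed = 51)
  session <- simulate_session(sched, noise = noise_off(), seed = 52)
  excl <- exclude_trials(session)
  expect_equal(excl$report$n_kept, 12)
  expect_equal(excl$report$n_timing + excl$report$n_missing, 0)
})

test_that("timing-issue and in-window missing trials are removed, others kept", {
  nz <- noise_model(position_sd = 0, endpoint_sd = 0, missing_rate = 0,
                    timing_issue_rate = 1)
  bad_timing <- simulate_trial(make_spec(), noise = nz, seed = 1)
  clean <- simulate_trial(make_spec(), noise = noise_off(), seed = 2)
  # missing samples only before the square's motion onset: trial is kept
  outside <- simulate_trial(make_spec(), noise = noise_off(), seed = 3)
  idx <- which(outside$time < outside$recorded_square_onset - 0.05)[1:20]
  outside$missing[idx] <- TRUE
  outside$x[idx] <- NA
  # missing samples inside the window: removed
  inside <- simulate_trial(make_spec(), noise = noise_off(), seed = 4)
  j <- which(inside$time >= inside$recorded_square_onset + 0.1)[1:5]
  inside$missing[j] <- TRUE
  inside$x[j] <- NA
  session <- structure(list(bad_timing, clean, outside, inside),
                       class = "mfr_session")
  excl <- exclude_trials(session)
  expect_equal(excl$reason, c("timing", "", "", "missing"))
  expect_equal(excl$report$n_kept, 2)
})

test_that("exclusion counts match the generator rates within binomial bounds", {
  sched <- build_schedule(25, 2, seed = 61)
  nz <- noise_model(position_sd = 0, endpoint_sd = 0, missing_rate = 0.01,
                    timing_issue_rate = 0.005)
  session <- simulate_session(sched, noise = nz, seed = 62)
  excl <- exclude_trials(session)
  b_timing <- stats::qbinom(c(0.005, 0.995), 600, 0.005)
  b_missing <- stats::qbinom(c(0.005, 0.995), 600, 0.01)
  expect_true(excl$report$n_timing >= b_timing[1] &&
                excl$report$n_timing <= b_timing[2])
  expect_true(excl$report$n_missing >= b_missing[1] &&
                excl$report$n_missing <= b_missing[2])
})

make_condition_trials <- function(resp, n_per_dir = 1, onset = 0.35,
                                  seed0 = 100) {
  trials <- list()
  for (i in seq_len(n_per_dir)) {
    trials[[2 * i - 1]] <- simulate_trial(
      make_spec(direction = "right", square_onset = onset), resp, noise_off(),
      seed = seed0 + i, reach = reach_fixed())
    trials[[2 * i]] <- simulate_trial(
      make_spec(direction = "left", square_onset = onset), resp, noise_off(),
      seed = seed0 + i, reach = reach_fixed())
  }
  trials
}

test_that("with zero gain the response curve is numerically zero", {
  resp0 <- response_model(gain_by_size = c("7" = 0, "37" = 0, "67" = 0))
  curve <- response_curve(make_condition_trials(resp0))
  expect_length(curve$value, 150)
  expect_equal(curve$lag, (0:149) * 0.002)
  expect_lt(max(abs(curve$value)), 1e-9)
})

test_that("the curve recovers twice the injected velocity profile", {
  resp <- response_model()
  g <- response_gain(resp, 7, "frame")
  curve <- response_curve(make_condition_trials(resp))
  expected <- vapply(curve$lag, function(lag) {
    t0 <- 0.35 + lag
    2 * stats::integrate(injected_velocity, t0, t0 + 0.002, gain = g,
                         rel.tol = 1e-10)$value / 0.002
  }, numeric(1))
  expect_equal(curve$value, expected, tolerance = 1e-6)
})

test_that("swapping direction labels negates the curve and magnitude exactly", {
  resp <- response_model()
  trials <- make_condition_trials(resp, n_per_dir = 2)
  curve <- response_curve(trials)
  swapped <- lapply(trials, function(tr) {
    tr$trial$direction <- if (tr$trial$direction == "right") "left" else "right"
    tr
  })
  curve_sw <- response_curve(swapped)
  expect_equal(curve_sw$value, -curve$value)
  expect_equal(response_magnitude(curve_sw)$value,
               -response_magnitude(curve)$value)
})

test_that("a direction with no trials yields a diagnostic, not a silent curve", {
  resp <- response_model()
  trials <- make_condition_trials(resp)
  only_right <- trials[c(1)]
  expect_error(response_curve(only_right), "leftward")
  mixed <- c(trials, list(simulate_trial(make_spec(side = 37), resp,
                                         noise_off(), seed = 7)))
  expect_error(response_curve(mixed), "one kind")
})

test_that("the magnitude is the window mean over 26 inclusive grid points", {
  curve <- structure(list(lag = (0:149) * 0.002,
                          value = rep(1.7, 150),
                          participant = "P", kind = "frame", side = 7),
                     class = "mfr_response_curve")
  m <- response_magnitude(curve)
  expect_equal(m$value, 1.7)
  idx <- curve$lag >= 0.15 - 1e-9 & curve$lag <= 0.20 + 1e-9
  expect_equal(sum(idx), 26)
  expect_error(response_magnitude(curve, window = c(0.25, 0.35)), "window")
})

test_that("the pipeline magnitude matches the kernel's window mean within 2%", {
  resp <- response_model()
  for (side in c(7, 67)) {
    trials <- lapply(make_condition_trials(resp), function(tr) tr)
    trials <- list(
      simulate_trial(make_spec(side = side, direction = "right"), resp,
                     noise_off(), seed = 11, reach = reach_fixed()),
      simulate_trial(make_spec(side = side, direction = "left"), resp,
                     noise_off(), seed = 11, reach = reach_fixed()))
    m <- response_magnitude(response_curve(trials))
    g <- response_gain(resp, side, "frame")
    expect_equal(m$value, expected_magnitude(g), tolerance = 0.02)
  }
})

test_that("velocity samples at and after the tap are excluded from averaging", {
  resp <- response_model()
  # late square onset: the analysis window outlives an early tap
  trials <- list(
    simulate_trial(make_spec(direction = "right", square_onset = 0.4), resp,
                   noise_off(), seed = 21, reach = reach_fixed(0.58)),
    simulate_trial(make_spec(direction = "left", square_onset = 0.4), resp,
                   noise_off(), seed = 21, reach = reach_fixed(0.58)))
  curve <- response_curve(trials)
  # lags at/after the tap (0.58 s - 0.4 s = 0.18 s) have no surviving trials
  expect_true(all(is.na(curve$value[curve$lag > 0.182])))
  expect_true(all(!is.na(curve$value[curve$lag < 0.17])))
})
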