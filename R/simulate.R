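#' Simulate one 500-Hz finger-marker trajectory
#'
#' Generates a single trial of the interception task: a minimum-jerk baseline
#' reach from the starting point to a planned contact point on the moving
#' target, with the manual following response injected as a lateral velocity
#' perturbation (see [response_model()]), plus measurement noise, optional
#' dropped-sample gaps and square-motion timing issues per [noise_model()].
#' The fingertip's perpendicular distance `z` reaches zero at contact with an
#' abrupt stop, so the deceleration-based tap rule fires at the landing
#' sample.
#'
#' The planned contact point is the target's position at the trial's drawn
#' contact time (the simulated participant tracks the target) plus isotropic
#' endpoint scatter. The lateral perturbation displaces the finger until
#' contact; after contact the finger rests at its landing position.
#'
#' @param spec Trial spec: a row of an [build_schedule()] schedule (or an
#'   equivalent list) with `kind`, `side`, `direction`, `square_onset`.
#' @param resp An [response_model()].
#' @param noise An [noise_model()].
#' @param geom An [mfr_geometry()].
#' @param seed Optional integer seed for this trial's random draws.
#' @param reach An [reach_model()].
#' @return An `mfr_trajectory`: list with `time` (s, exact 2-ms grid from
#'   target appearance), `x`, `y`, `z` (cm), `missing` (logical),
#'   `trial` (the spec), `recorded_square_onset`, `recorded_square_offset`
#'   (s; deviating from commanded on timing-issue trials), and ground truth
#'   `contact_time` and `reach_onset` for validation.
#' @export
simulate_trial <- function(spec, resp = response_model(), noise = noise_model(),
                           geom = mfr_geometry(), seed = NULL,
                           reach = reach_model()) {
  spec <- as.list(spec)
  if (!is.null(seed)) set.seed(seed)
  dt <- 0.002
  t_on <- reach$onset

  t_c <- stats::rnorm(1, reach$contact_mean, reach$contact_sd)
  if (t_c <= t_on) {
    stop("inconsistent geometry: planned contact precedes movement onset")
  }

  # commanded vs recorded square motion; timing issues shift the whole epoch
  on_cmd <- spec$square_onset
  a_on <- on_cmd
  if (stats::runif(1) < noise$timing_issue_rate) {
    a_on <- a_on + sample(c(-1, 1), 1) * stats::runif(1, 0.009, 0.020)
  }
  a_off <- a_on + geom$square_motion_duration

  n <- ceiling((t_c + 0.05) / dt) + 1L
  tt <- (seq_len(n) - 1) * dt

  aim <- as.numeric(target_position(t_c, geom))
  if (noise$endpoint_sd > 0) aim <- aim + stats::rnorm(2, 0, noise$endpoint_sd)
  start <- c(geom$zone_center[1], geom$zone_center[2] - geom$start_offset)

  x <- min_jerk_pos(tt, t_on, t_c, start[1], aim[1])
  y <- min_jerk_pos(tt, t_on, t_c, start[2], aim[2])
  tau <- (tt - t_on) / (t_c - t_on)
  z <- reach$lift_height * 6.75 * tau^2 * (1 - tau)
  z[tau < 0 | tau > 1] <- 0

  g <- response_gain(resp, spec$side, spec$kind)
  if (g > 0) {
    sgn <- direction_sign(spec$direction)
    u <- (pmin(tt, t_c) - a_on - resp$latency) / resp$kernel_width
    x <- x + sgn * g * geom$square_speed * resp$kernel_width *
      response_kernel_integral(u)
  }

  if (noise$position_sd > 0) {
    x <- x + stats::rnorm(n, 0, noise$position_sd)
    y <- y + stats::rnorm(n, 0, noise$position_sd)
    z <- pmax(z + stats::rnorm(n, 0, noise$position_sd), 0)
  }

  missing <- logical(n)
  if (noise$missing_rate > 0 && stats::runif(1) < noise$missing_rate) {
    gap <- sample(10:50, 1)
    # place the gap inside the analysis window (onset .. onset + 300 ms)
    i0 <- max(1L, as.integer(round(a_on / dt)) + 1L)
    i1 <- min(n - gap, as.integer(round((a_on + 0.3) / dt)) + 1L)
    s <- if (i1 > i0) sample(i0:i1, 1) else i0
    idx <- s:(s + gap - 1L)
    missing[idx] <- TRUE
    x[idx] <- NA_real_
    y[idx] <- NA_real_
    z[idx] <- NA_real_
  }

  structure(list(time = tt, x = x, y = y, z = z, missing = missing,
                 trial = spec,
                 recorded_square_onset = a_on,
                 recorded_square_offset = a_off,
                 contact_time = t_c,
                 reach_onset = t_on),
            class = "mfr_trajectory")
}

#' @export
print.mfr_trajectory <- function(x, ...) {
  cat(sprintf("500-Hz trajectory: %d samples (%.3f s), %s %g-cm square moving %s\n",
              length(x$time), max(x$time), x$trial$kind, x$trial$side,
              x$trial$direction))
  cat(sprintf("  square onset %.3f s (recorded %.3f s), contact %.3f s, %d missing samples\n",
              x$trial$square_onset, x$recorded_square_onset, x$contact_time,
              sum(x$missing)))
  invisible(x)
}

#' Simulate a whole session of trajectories
#'
#' One trajectory per schedule row; per-trial seeds are derived
#' deterministically from the session seed so the output is reproducible.
#'
#' @param schedule An [build_schedule()] schedule (non-empty).
#' @param resp,noise,geom,reach Models as in [simulate_trial()].
#' @param seed Integer session seed.
#' @return An `mfr_session`: a list of `mfr_trajectory` objects.
#' @export
simulate_session <- function(schedule, resp = response_model(),
                             noise = noise_model(), geom = mfr_geometry(),
                             seed = 1L, reach = reach_model()) {
  n <- nrow(schedule)
  if (is.null(n) || n < 1) stop("schedule must contain at least one trial")
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n)
  specs <- split(schedule, seq_len(n))
  session <- vector("list", n)
  for (i in seq_len(n)) {
    session[[i]] <- simulate_trial(specs[[i]], resp, noise, geom,
                                   seed = trial_seeds[i], reach = reach)
  }
  class(session) <- "mfr_session"
  session
}

#' @export
print.mfr_session <- function(x, ...) {
  cat(sprintf("Session of %d simulated trials (%d with missing samples)\n",
              length(x), sum(vapply(x, function(tr) any(tr$missing), logical(1)))))
  invisible(x)
}
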