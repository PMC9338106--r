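# Shared fixtures: deterministic models and hand-built trial specs.

make_spec <- function(kind = "frame", side = 7, direction = "right",
                      square_onset = 0.35, trial_index = 1L, block_index = 1L) {
  list(trial_index = trial_index, block_index = block_index, kind = kind,
       side = side, direction = direction, start_delay = 0.6,
       square_onset = square_onset)
}

# fixed contact time so left/right trials are exactly mirrored
reach_fixed <- function(contact_mean = 0.662) {
  reach_model(contact_mean = contact_mean, contact_sd = 0, onset = 0.10,
              lift_height = 15)
}

# the closed-form injected response velocity (cm/s) at time t for one trial,
# written out independently of the package's kernel helpers
injected_velocity <- function(t, gain, square_onset = 0.35, latency = 0.12,
                              width = 0.15, square_speed = 20) {
  u <- (t - square_onset - latency) / width
  ifelse(u > 0 & u < 1, gain * square_speed * 0.5 * (1 - cos(2 * pi * u)), 0)
}

# expected window-mean response magnitude 2 * g * S * m, with the kernel's
# window mean m obtained by numerical quadrature over the 26 velocity
# intervals (lags 0.150 .. 0.200 s, interval length 2 ms)
expected_magnitude <- function(gain, latency = 0.12, width = 0.15,
                               square_speed = 20, window = c(0.15, 0.20)) {
  k <- function(lag) {
    u <- (lag - latency) / width
    ifelse(u > 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
  }
  total <- stats::integrate(k, window[1], window[2] + 0.002,
                            rel.tol = 1e-10)$value
  2 * gain * square_speed * total / (window[2] + 0.002 - window[1])
}

# minimal hand-built trajectory for kinematics tests
make_traj <- function(z, x = NULL, y = NULL, time = NULL) {
  n <- length(z)
  structure(list(time = if (is.null(time)) (seq_len(n) - 1) * 0.002 else time,
                 x = if (is.null(x)) rep(0, n) else x,
                 y = if (is.null(y)) rep(10, n) else y,
                 z = z,
                 missing = rep(FALSE, n),
                 trial = make_spec(),
                 recorded_square_onset = 0.35,
                 recorded_square_offset = 0.45,
                 contact_time = NA_real_,
                 reach_onset = 0.1),
            class = "mfr_trajectory")
}
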