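#' Following-response model for the synthetic generator
#'
#' The hand's response to the square's motion is injected as a lateral
#' velocity perturbation: a raised-cosine bump of unit peak starting `latency`
#' seconds after the square's motion onset and lasting `kernel_width` seconds,
#' scaled by `gain x square_speed` and signed by the motion direction. The
#' gain depends on square size through `gain_by_size` and on square kind
#' through the multiplier `gain_by_kind`.
#'
#' Default gains decrease with square size (a small drop from the 7-cm to the
#' 37-cm square, a clear drop to the 67-cm square) and are identical for frame
#' and tile, emulating the finding that the response is driven by local edge
#' motion irrespective of the surface interpretation. With the default
#' latency (120 ms) and width (150 ms) the injected response rises between
#' 120 and 270 ms after motion onset, peaking at 195 ms.
#'
#' @param latency Response onset after square-motion onset, s (>= 0).
#' @param kernel_width Duration of the raised-cosine velocity bump, s (> 0).
#' @param gain_by_size Named numeric vector mapping side length (cm) to gain
#'   (peak lateral hand velocity as a fraction of square speed, >= 0).
#' @param gain_by_kind Named numeric vector of multipliers for `frame` and
#'   `tile`.
#' @return An object of class `mfr_response_model`.
#' @export
response_model <- function(latency = 0.12,
                           kernel_width = 0.15,
                           gain_by_size = c("7" = 0.10, "37" = 0.085, "67" = 0.05),
                           gain_by_kind = c(frame = 1, tile = 1)) {
  if (latency < 0) stop("latency must be non-negative")
  if (kernel_width <= 0) stop("kernel_width must be positive")
  if (any(gain_by_size < 0) || any(gain_by_kind < 0)) {
    stop("gains must be non-negative")
  }
  if (is.null(names(gain_by_size))) stop("gain_by_size must be named by side length")
  if (!all(c("frame", "tile") %in% names(gain_by_kind))) {
    stop("gain_by_kind must name 'frame' and 'tile'")
  }
  structure(list(latency = latency, kernel_width = kernel_width,
                 gain_by_size = gain_by_size, gain_by_kind = gain_by_kind),
            class = "mfr_response_model")
}

#' Effective response gain for one condition
#'
#' @param resp An [response_model()].
#' @param side Square side, cm.
#' @param kind `"frame"` or `"tile"`.
#' @return The dimensionless gain `gain_by_size[side] * gain_by_kind[kind]`.
#' @export
response_gain <- function(resp, side, kind) {
  key <- as.character(side)
  if (!key %in% names(resp$gain_by_size)) {
    stop("no gain configured for square side ", side)
  }
  unname(resp$gain_by_size[[key]] * resp$gain_by_kind[[kind]])
}

#' Raised-cosine response kernel and its running integral
#'
#' `response_kernel(u)` is the unit-peak bump `0.5 * (1 - cos(2 pi u))` on
#' `[0, 1]` and zero elsewhere; `response_kernel_integral(u)` is its integral
#' from 0 to `u` (so the full bump integrates to 0.5). In trial time the
#' argument is `(t - square_onset - latency) / kernel_width`.
#'
#' @param u Dimensionless kernel time (vectorized).
#' @return Kernel value, or integral in kernel-time units.
#' @export
response_kernel <- function(u) {
  ifelse(u > 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' @rdname response_kernel
#' @export
response_kernel_integral <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  0.5 * (u - sin(2 * pi * u) / (2 * pi))
}

#' Measurement and behavioral noise model for the synthetic generator
#'
#' `position_sd` is additive Gaussian noise on every marker coordinate
#' (Optotrak-grade, hundredths of a cm). `endpoint_sd` scatters the planned
#' tap position around the target; its default is calibrated so that about
#' 70% of taps land inside the 2-cm target. `missing_rate` is the probability
#' that a trial contains one contiguous dropped-sample gap (10-50 samples)
#' inside the analysis window; `timing_issue_rate` is the probability that the
#' recorded square motion deviates from the commanded onset by more than one
#' 120-Hz display frame. Defaults mirror the removal rates of the original
#' sessions (1% missing, <1% timing issues).
#'
#' @param position_sd Marker noise SD per coordinate, cm (>= 0).
#' @param endpoint_sd Tap scatter SD per screen axis, cm (>= 0).
#' @param missing_rate Probability of a dropped-sample gap, in `[0, 1]`.
#' @param timing_issue_rate Probability of a square-motion timing issue, in
#'   `[0, 1]`.
#' @return An object of class `mfr_noise_model`.
#' @export
noise_model <- function(position_sd = 0.01,
                        endpoint_sd = 0.62,
                        missing_rate = 0.01,
                        timing_issue_rate = 0.005) {
  if (position_sd < 0 || endpoint_sd < 0) stop("noise SDs must be non-negative")
  if (missing_rate < 0 || missing_rate > 1 ||
      timing_issue_rate < 0 || timing_issue_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  structure(list(position_sd = position_sd, endpoint_sd = endpoint_sd,
                 missing_rate = missing_rate,
                 timing_issue_rate = timing_issue_rate),
            class = "mfr_noise_model")
}

#' Noise-free variant of a noise model
#'
#' Convenience for oracle tests: all rates and SDs set to zero.
#' @return An `mfr_noise_model` with every field 0.
#' @export
noise_off <- function() {
  noise_model(position_sd = 0, endpoint_sd = 0, missing_rate = 0,
              timing_issue_rate = 0)
}

#' Baseline reach model for the synthetic generator
#'
#' The baseline reach starts on the starting point, moves along a
#' minimum-jerk path in the screen plane to the planned contact point, and
#' lifts off the screen following a smooth asymmetric profile
#' `z = h * 6.75 * tau^2 * (1 - tau)` that returns to the screen with a
#' substantial approach velocity (`6.75 * h / duration`), as rapid taps do.
#' Contact time is drawn per trial around `contact_mean` (the ~662 ms
#' screen-contact latency of the original sessions) with SD `contact_sd`.
#'
#' @param contact_mean Mean screen-contact time after target appearance, s.
#' @param contact_sd SD of the contact time across trials, s.
#' @param onset Movement onset after target appearance, s.
#' @param lift_height Peak perpendicular lift of the fingertip, cm.
#' @return An object of class `mfr_reach_model`.
#' @export
reach_model <- function(contact_mean = 0.662,
                        contact_sd = 0.027,
                        onset = 0.10,
                        lift_height = 15) {
  if (contact_sd < 0) stop("contact_sd must be non-negative")
  if (lift_height <= 0) stop("lift_height must be positive")
  if (contact_mean <= onset) stop("mean contact time must follow movement onset")
  structure(list(contact_mean = contact_mean, contact_sd = contact_sd,
                 onset = onset, lift_height = lift_height),
            class = "mfr_reach_model")
}
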