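#' Lateral velocity by direct differentiation
#'
#' Forward difference of the lateral (x) position over every 2-ms interval,
#' with no smoothing: `v[i] = (x[i+1] - x[i]) / 0.002`, indexed to the
#' interval start. Intervals touching a missing sample are flagged missing
#' (and their velocity is NA).
#'
#' @param traj An `mfr_trajectory` with at least two samples.
#' @return A list with `time` (interval-start times, s), `v` (cm/s) and
#'   `missing` (logical), each of length `n - 1`.
#' @export
lateral_velocity <- function(traj) {
  n <- length(traj$x)
  if (n < 2) stop("trajectory must contain at least two samples")
  v <- diff(traj$x) / 0.002
  missing <- traj$missing[-n] | traj$missing[-1]
  v[missing] <- NA_real_
  list(time = traj$time[-n], v = v, missing = missing)
}

#' Detect the tap on the screen
#'
#' Implements the deceleration rule used for on-line feedback: with the
#' per-sample approach `delta[i] = z[i-1] - z[i]`, a tap is the first sample
#' `i` at which the approach drops by more than `threshold` (default 1 mm)
#' between consecutive measurements while the finger is within `height`
#' (default 2 cm) of the screen. The tap position is the screen (x, y) at
#' that sample; the target is hit if the fingertip lies within the target's
#' outline at the tap time (boundary counts as hit), and likewise for the
#' interception zone.
#'
#' @param traj An `mfr_trajectory` in screen coordinates (z = perpendicular
#'   distance to the screen).
#' @param geom An [mfr_geometry()].
#' @param threshold Drop in per-sample approach that signals the tap, cm.
#' @param height Maximum distance to the screen at the tap, cm.
#' @return An `mfr_tap` (list with `tap_time`, `tap_position`, `hit_target`,
#'   `hit_zone`, `sample_index`) or `NULL` when no sample qualifies.
#' @export
detect_tap <- function(traj, geom = mfr_geometry(), threshold = 0.1, height = 2) {
  z <- traj$z
  n <- length(z)
  if (n < 3) return(NULL)
  d <- z[-n] - z[-1]              # d[i]: approach into sample i + 1
  drop <- d[-(n - 1)] - d[-1]     # drop[j]: between samples j + 1 and j + 2
  ok <- drop > threshold & z[3:n] < height
  ok[is.na(ok)] <- FALSE
  j <- which(ok)
  if (!length(j)) return(NULL)
  i <- j[1] + 2L
  tap_time <- traj$time[i]
  pos <- c(traj$x[i], traj$y[i])
  tgt <- as.numeric(target_position(tap_time, geom))
  hit_target <- sqrt(sum((pos - tgt)^2)) <= geom$target_diameter / 2
  hit_zone <- sqrt(sum((pos - geom$zone_center)^2)) <= geom$zone_diameter / 2
  structure(list(tap_time = tap_time, tap_position = pos,
                 hit_target = hit_target, hit_zone = hit_zone,
                 sample_index = i),
            class = "mfr_tap")
}

#' Detect taps for a whole session
#'
#' @param session An `mfr_session` (list of trajectories).
#' @param geom An [mfr_geometry()].
#' @param threshold,height As in [detect_tap()].
#' @return A data frame with one row per trial: `trial_index`, `tap_time_s`,
#'   `x_cm`, `y_cm`, `hit_target`, `hit_zone` (NA where no tap was detected).
#' @export
detect_taps <- function(session, geom = mfr_geometry(), threshold = 0.1,
                        height = 2) {
  rows <- lapply(session, function(tr) {
    tap <- detect_tap(tr, geom, threshold, height)
    if (is.null(tap)) {
      data.frame(trial_index = tr$trial$trial_index, tap_time_s = NA_real_,
                 x_cm = NA_real_, y_cm = NA_real_, hit_target = NA,
                 hit_zone = NA)
    } else {
      data.frame(trial_index = tr$trial$trial_index, tap_time_s = tap$tap_time,
                 x_cm = tap$tap_position[1], y_cm = tap$tap_position[2],
                 hit_target = tap$hit_target, hit_zone = tap$hit_zone)
    }
  })
  do.call(rbind, rows)
}
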