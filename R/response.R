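#' Remove trials with timing issues or missing data
#'
#' A trial is removed when its recorded square-motion onset or offset deviates
#' from the commanded value by more than one display frame (`frame_s`,
#' default 1/120 s), or when any sample is missing inside the analysis window
#' (recorded onset to onset + 300 ms, plus the extra sample the last velocity
#' interval needs). All other trials are kept irrespective of performance.
#'
#' @param session An `mfr_session`.
#' @param geom An [mfr_geometry()] (for the commanded motion duration).
#' @param frame_s Timing tolerance, s.
#' @param window Analysis-window length after the square's motion onset, s.
#' @return A list with `kept` (an `mfr_session`), `report` (one-row data
#'   frame with `n_total`, `n_timing`, `n_missing`, `n_kept`) and `reason`
#'   (per-trial character vector, `""` for kept trials; timing issues take
#'   precedence in the counts).
#' @export
exclude_trials <- function(session, geom = mfr_geometry(), frame_s = 1 / 120,
                           window = 0.3) {
  reason <- vapply(session, function(tr) {
    cmd_on <- tr$trial$square_onset
    cmd_off <- cmd_on + geom$square_motion_duration
    if (abs(tr$recorded_square_onset - cmd_on) > frame_s ||
        abs(tr$recorded_square_offset - cmd_off) > frame_s) {
      return("timing")
    }
    w <- tr$time >= tr$recorded_square_onset - 1e-9 &
      tr$time <= tr$recorded_square_onset + window + 0.002 + 1e-9
    if (any(tr$missing[w])) return("missing")
    ""
  }, character(1))
  kept <- session[reason == ""]
  class(kept) <- "mfr_session"
  list(kept = kept,
       report = data.frame(n_total = length(session),
                           n_timing = sum(reason == "timing"),
                           n_missing = sum(reason == "missing"),
                           n_kept = length(kept)),
       reason = reason)
}

#' Direction-difference response curve for one participant and condition
#'
#' Each trial's lateral velocity series is re-indexed to lag after its own
#' recorded square-motion onset (nearest-sample alignment) on the 2-ms grid
#' over 0-298 ms (150 points). Velocities are averaged per lag within each
#' motion direction, and the curve is the rightward mean minus the leftward
#' mean, so positive values are in the direction of the square's motion.
#' Velocity samples at or after the trial's tap are excluded (the finger has
#' landed), as are missing intervals.
#'
#' @param trials List of kept `mfr_trajectory` objects of one participant and
#'   one kind x size condition, both directions present.
#' @param tap_times Optional numeric vector of tap times (s) per trial; when
#'   `NULL` taps are detected with [detect_tap()]. Use `NA` for no tap.
#' @param participant Participant identifier carried into the result.
#' @param geom An [mfr_geometry()] (for tap detection).
#' @return An `mfr_response_curve`: list with `lag` (s), `value` (cm/s),
#'   `mean_right`, `mean_left`, `n_right`, `n_left`, `participant`, `kind`,
#'   `side`.
#' @export
response_curve <- function(trials, tap_times = NULL,
                           participant = NA_character_,
                           geom = mfr_geometry()) {
  if (!length(trials)) stop("no trials supplied")
  kinds <- unique(vapply(trials, function(tr) tr$trial$kind, character(1)))
  sides <- unique(vapply(trials, function(tr) tr$trial$side, numeric(1)))
  if (length(kinds) != 1 || length(sides) != 1) {
    stop("trials must all belong to one kind x size condition")
  }
  dirs <- vapply(trials, function(tr) tr$trial$direction, character(1))
  if (!any(dirs == "right")) stop("no rightward-motion trials in this condition")
  if (!any(dirs == "left")) stop("no leftward-motion trials in this condition")
  if (is.null(tap_times)) {
    tap_times <- vapply(trials, function(tr) {
      tap <- detect_tap(tr, geom)
      if (is.null(tap)) NA_real_ else tap$tap_time
    }, numeric(1))
  }
  n_lag <- 150L
  lags <- (seq_len(n_lag) - 1) * 0.002
  sums <- matrix(0, n_lag, 2)
  counts <- matrix(0L, n_lag, 2)
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    n <- length(tr$x)
    v <- diff(tr$x) / 0.002
    mi <- tr$missing[-n] | tr$missing[-1]
    j <- as.integer(round(tr$recorded_square_onset / 0.002)) + 1L
    idx <- j + seq_len(n_lag) - 1L
    vv <- rep(NA_real_, n_lag)
    ok <- idx >= 1L & idx <= n - 1L
    vv[ok] <- v[idx[ok]]
    vv[ok][mi[idx[ok]]] <- NA_real_
    if (!is.na(tap_times[k])) {
      vv[tr$time[pmin(idx, n)] >= tap_times[k] - 1e-9] <- NA_real_
    }
    col <- if (dirs[k] == "right") 1L else 2L
    use <- !is.na(vv)
    sums[use, col] <- sums[use, col] + vv[use]
    counts[use, col] <- counts[use, col] + 1L
  }
  mean_right <- ifelse(counts[, 1] > 0, sums[, 1] / counts[, 1], NA_real_)
  mean_left <- ifelse(counts[, 2] > 0, sums[, 2] / counts[, 2], NA_real_)
  structure(list(lag = lags, value = mean_right - mean_left,
                 mean_right = mean_right, mean_left = mean_left,
                 n_right = sum(dirs == "right"), n_left = sum(dirs == "left"),
                 participant = participant,
                 kind = kinds, side = sides),
            class = "mfr_response_curve")
}

#' @export
print.mfr_response_curve <- function(x, ...) {
  cat(sprintf("Response curve (%s, %g cm): %d right / %d left trials, peak %.2f cm/s\n",
              x$kind, x$side, x$n_right, x$n_left, max(abs(x$value), na.rm = TRUE)))
  invisible(x)
}

#' Window-mean response magnitude
#'
#' The arithmetic mean of the response curve over lags between 150 and 200 ms
#' after the square's motion onset (window endpoints inclusive: 26 grid
#' points at the default 2-ms spacing).
#'
#' @param curve An [response_curve()] result.
#' @param window Length-2 numeric window in s after motion onset.
#' @return An `mfr_response_magnitude`: list with `value` (cm/s),
#'   `participant`, `kind`, `side`, `window`.
#' @export
response_magnitude <- function(curve, window = c(0.15, 0.20)) {
  if (window[1] < min(curve$lag) - 1e-9 || window[2] > max(curve$lag) + 0.002 + 1e-9) {
    stop("response curve does not cover the requested window")
  }
  idx <- curve$lag >= window[1] - 1e-9 & curve$lag <= window[2] + 1e-9
  if (!any(idx)) stop("no curve samples inside the requested window")
  structure(list(value = mean(curve$value[idx]),
                 participant = curve$participant,
                 kind = curve$kind, side = curve$side, window = window),
            class = "mfr_response_magnitude")
}

#' Analyze one participant's session
#'
#' Runs the per-participant stages in order: tap detection, trial exclusion,
#' per-condition response curves and window-mean magnitudes.
#'
#' @param session An `mfr_session`.
#' @param participant Participant identifier.
#' @param geom An [mfr_geometry()].
#' @param window Magnitude window, s after motion onset.
#' @param frame_s Timing-exclusion tolerance, s.
#' @return A list with `curves` (long data frame: `participant`, `kind`,
#'   `side_cm`, `lag_s`, `value_cm_s`), `magnitudes` (data frame:
#'   `participant`, `kind`, `side_cm`, `value_cm_s`), `exclusions` (report
#'   row), `taps` (the [detect_taps()] table of kept trials) and `hit_rate`
#'   (fraction of kept trials whose tap hit the target inside the zone).
#' @export
analyze_session <- function(session, participant = "P01",
                            geom = mfr_geometry(), window = c(0.15, 0.20),
                            frame_s = 1 / 120) {
  excl <- exclude_trials(session, geom, frame_s)
  kept <- excl$kept
  taps <- detect_taps(kept, geom)
  tap_times <- taps$tap_time_s
  kinds <- vapply(kept, function(tr) tr$trial$kind, character(1))
  sides <- vapply(kept, function(tr) tr$trial$side, numeric(1))
  cells <- unique(condition_cells()[, c("kind", "side")])
  curve_rows <- list()
  mag_rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- kinds == cells$kind[i] & sides == cells$side[i]
    curve <- response_curve(kept[sel], tap_times = tap_times[sel],
                            participant = participant, geom = geom)
    mag <- response_magnitude(curve, window)
    curve_rows[[i]] <- data.frame(participant = participant,
                                  kind = cells$kind[i],
                                  side_cm = cells$side[i],
                                  lag_s = curve$lag,
                                  value_cm_s = curve$value)
    mag_rows[[i]] <- data.frame(participant = participant,
                                kind = cells$kind[i],
                                side_cm = cells$side[i],
                                value_cm_s = mag$value)
  }
  hit <- taps$hit_target & taps$hit_zone
  list(curves = do.call(rbind, curve_rows),
       magnitudes = do.call(rbind, mag_rows),
       exclusions = cbind(participant = participant, excl$report),
       taps = taps,
       hit_rate = mean(hit, na.rm = TRUE))
}
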