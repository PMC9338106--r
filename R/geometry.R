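#' Task geometry for the interception paradigm
#'
#' All positions are screen-plane coordinates in cm with the origin at the
#' screen center, x rightward and y upward; z is the perpendicular distance of
#' the finger marker to the screen surface. Times are seconds from target
#' appearance unless stated otherwise.
#'
#' The defaults describe the paradigm: a 6-cm interception zone centered 10 cm
#' above the screen center, a 2-cm target that appears 20 cm to the left of the
#' zone center and moves rightward at 30 cm/s (reaching the zone center
#' 667 ms after appearing), a 4-cm starting point 30 cm below the zone, and a
#' square (frame or tile) initially centered on the zone that translates left
#' or right at 20 cm/s for 100 ms (2 cm of displacement). The static background
#' carries 600 randomly placed 1-cm black discs; the frame's line width is 5%
#' of its side length.
#'
#' @param zone_center Interception-zone center, cm (length-2).
#' @param zone_diameter Interception-zone diameter, cm.
#' @param target_diameter Target diameter, cm.
#' @param start_diameter Starting-point diameter, cm.
#' @param start_offset Distance of the starting point below the zone center, cm.
#' @param target_start_offset Distance the target appears left of the zone
#'   center, cm.
#' @param target_speed Target speed, cm/s (rightward).
#' @param square_speed Square speed during its motion epoch, cm/s.
#' @param square_motion_duration Duration of the square's motion epoch, s.
#' @param disc_count Number of background discs.
#' @param disc_diameter Background disc diameter, cm.
#' @param frame_width_fraction Frame line width as a fraction of the square
#'   side.
#' @param screen_width,screen_height Projection surface extent, cm.
#'
#' @return An object of class `mfr_geometry` (a validated list).
#' @examples
#' geom <- mfr_geometry()
#' geom$target_start_offset / geom$target_speed  # transit time to zone center
#' @export
mfr_geometry <- function(zone_center = c(0, 10),
                         zone_diameter = 6,
                         target_diameter = 2,
                         start_diameter = 4,
                         start_offset = 30,
                         target_start_offset = 20,
                         target_speed = 30,
                         square_speed = 20,
                         square_motion_duration = 0.1,
                         disc_count = 600,
                         disc_diameter = 1,
                         frame_width_fraction = 0.05,
                         screen_width = 125,
                         screen_height = 100) {
  stopifnot(length(zone_center) == 2, is.numeric(zone_center))
  if (target_speed <= 0) stop("target_speed must be positive")
  if (square_motion_duration <= 0) stop("square_motion_duration must be positive")
  if (square_speed < 0) stop("square_speed must be non-negative")
  if (disc_count < 0) stop("disc_count must be non-negative")
  structure(list(
    zone_center = as.numeric(zone_center),
    zone_diameter = zone_diameter,
    target_diameter = target_diameter,
    start_diameter = start_diameter,
    start_offset = start_offset,
    target_start_offset = target_start_offset,
    target_speed = target_speed,
    square_speed = square_speed,
    square_motion_duration = square_motion_duration,
    disc_count = disc_count,
    disc_diameter = disc_diameter,
    frame_width_fraction = frame_width_fraction,
    screen_width = screen_width,
    screen_height = screen_height
  ), class = "mfr_geometry")
}

#' @export
print.mfr_geometry <- function(x, ...) {
  cat("Interception-task geometry (cm, s):\n")
  cat(sprintf("  zone: %.1f cm at (%.1f, %.1f); target: %.1f cm, %g cm/s\n",
              x$zone_diameter, x$zone_center[1], x$zone_center[2],
              x$target_diameter, x$target_speed))
  cat(sprintf("  square: %g cm/s for %g s; start point %g cm below zone\n",
              x$square_speed, x$square_motion_duration, x$start_offset))
  invisible(x)
}

#' The 12 condition cells of the design
#'
#' Two square kinds (frame, tile) crossed with three side lengths (7, 37,
#' 67 cm) and two motion directions (left, right).
#'
#' @return A data frame with columns `kind`, `side`, `direction` (12 rows).
#' @export
condition_cells <- function() {
  expand.grid(kind = c("frame", "tile"),
              side = c(7, 37, 67),
              direction = c("left", "right"),
              KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

#' Target position at a given time after its appearance
#'
#' The target appears `target_start_offset` cm left of the interception-zone
#' center and moves rightward at `target_speed` cm/s along the zone's height.
#'
#' @param t Time after target appearance, s (vectorized). Negative times are
#'   rejected.
#' @param geom An [mfr_geometry()].
#' @return A matrix with columns `x`, `y` (screen cm), one row per time.
#' @export
target_position <- function(t, geom = mfr_geometry()) {
  if (any(t < 0)) stop("t must be non-negative (target has not yet appeared)")
  x <- geom$zone_center[1] - geom$target_start_offset + geom$target_speed * t
  cbind(x = x, y = rep(geom$zone_center[2], length(t)))
}

#' Horizontal offset of the square's center at a given time
#'
#' Zero before the square's motion onset; then a linear ramp at
#' `square_speed` (signed by motion direction) for `square_motion_duration`;
#' constant afterwards.
#'
#' @param t Time after target appearance, s (vectorized).
#' @param spec A trial spec: list or one-row data frame with `square_onset`
#'   (s) and `direction` (`"left"` or `"right"`).
#' @param geom An [mfr_geometry()].
#' @return Numeric vector of horizontal offsets, cm.
#' @export
square_position <- function(t, spec, geom = mfr_geometry()) {
  spec <- as.list(spec)
  sgn <- direction_sign(spec$direction)
  moved <- pmin(pmax(t - spec$square_onset, 0), geom$square_motion_duration)
  sgn * geom$square_speed * moved
}

direction_sign <- function(direction) {
  switch(match.arg(direction, c("left", "right")), left = -1, right = 1)
}

#' Initial distance from the zone center to the square's nearest vertical edge
#'
#' The square is centered on the interception zone, so the nearest moving edge
#' starts half a side length away: 3.5, 18.5 and 33.5 cm for the three sizes.
#'
#' @param cond A condition (list or data frame row with a `side` field) or a
#'   numeric side length in cm.
#' @return Distance in cm.
#' @export
nearest_edge_distance <- function(cond) {
  side <- if (is.numeric(cond)) cond else as.list(cond)$side
  if (is.null(side) || !is.numeric(side) || any(side <= 0)) {
    stop("condition must carry a positive numeric square side")
  }
  side / 2
}

#' Random background scene of discs
#'
#' Positions `disc_count` disc centers uniformly over the screen extent,
#' reproducibly for a given seed.
#'
#' @param seed Integer seed.
#' @param geom An [mfr_geometry()].
#' @return A data frame with columns `x`, `y` (cm).
#' @export
generate_scene <- function(seed = 1L, geom = mfr_geometry()) {
  set.seed(seed)
  n <- geom$disc_count
  data.frame(x = stats::runif(n, -geom$screen_width / 2, geom$screen_width / 2),
             y = stats::runif(n, -geom$screen_height / 2, geom$screen_height / 2))
}
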