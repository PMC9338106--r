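#' Fit a four-point screen calibration
#'
#' Relates raw 3-D marker coordinates to 2-D screen coordinates plus
#' perpendicular distance to the screen, from four point correspondences
#' (marker positions recorded while the fingertip touched four known screen
#' locations). A plane is fitted to the four marker positions; within that
#' plane a projective map (homography) is determined exactly by the four
#' pairs, so each calibration point maps onto its screen target to machine
#' precision when the marker points are coplanar. Perpendicular distance is
#' taken along the fitted plane normal.
#'
#' @param raw_points 4 x 3 matrix of marker positions.
#' @param screen_points 4 x 2 matrix of the corresponding screen positions,
#'   cm. No three may be collinear.
#' @param front_point Optional 3-D marker position known to lie on the
#'   participant's side of the screen; orients the sign of the perpendicular
#'   distance. Without it the normal's orientation follows its largest
#'   component.
#' @return An `mfr_calibration` object.
#' @export
fit_calibration <- function(raw_points, screen_points, front_point = NULL) {
  raw_points <- as.matrix(raw_points)
  screen_points <- as.matrix(screen_points)
  if (!all(dim(raw_points) == c(4, 3)) || !all(dim(screen_points) == c(4, 2))) {
    stop("need four 3-D marker points and four 2-D screen points")
  }
  check_non_collinear(screen_points, "screen")
  ctr <- colMeans(raw_points)
  centered <- sweep(raw_points, 2, ctr)
  sv <- svd(centered)
  scale <- sv$d[1]
  if (sv$d[2] < 1e-9 * scale) {
    stop("degenerate calibration: marker points are (nearly) collinear")
  }
  e1 <- sv$v[, 1]
  e2 <- sv$v[, 2]
  normal <- sv$v[, 3]
  uv <- centered %*% cbind(e1, e2)
  check_non_collinear(uv, "marker")
  H <- solve_homography(uv, screen_points)
  if (!is.null(front_point)) {
    if (sum((as.numeric(front_point) - ctr) * normal) < 0) normal <- -normal
  } else {
    k <- which.max(abs(normal))
    if (normal[k] < 0) normal <- -normal
  }
  res <- structure(list(center = ctr, e1 = e1, e2 = e2, normal = normal, H = H,
                        raw_points = raw_points, screen_points = screen_points),
                   class = "mfr_calibration")
  fitted <- apply_calibration(res, raw_points)
  res$residual <- max(abs(fitted[, 1:2] - screen_points))
  res
}

check_non_collinear <- function(pts, what) {
  combs <- utils::combn(nrow(pts), 3)
  span <- max(stats::dist(pts))
  for (j in seq_len(ncol(combs))) {
    p <- pts[combs[, j], , drop = FALSE]
    area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    if (area < 1e-9 * span^2) {
      stop("degenerate calibration: three ", what, " points are collinear")
    }
  }
}

# Exact plane projectivity from four point pairs (direct linear transform;
# the 8 x 9 system has a one-dimensional null space for non-degenerate input).
solve_homography <- function(from, to) {
  A <- matrix(0, 8, 9)
  for (i in 1:4) {
    u <- from[i, 1]; v <- from[i, 2]
    x <- to[i, 1]; y <- to[i, 2]
    A[2 * i - 1, ] <- c(u, v, 1, 0, 0, 0, -x * u, -x * v, -x)
    A[2 * i, ]     <- c(0, 0, 0, u, v, 1, -y * u, -y * v, -y)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  matrix(h, 3, 3, byrow = TRUE)
}

#' Apply a calibration to marker positions
#'
#' @param cal An [fit_calibration()] result.
#' @param points N x 3 matrix of raw marker positions (rows with NA pass
#'   through as NA).
#' @return N x 3 matrix with columns `x`, `y` (screen cm) and `z`
#'   (perpendicular distance to the screen along the fitted normal).
#' @export
apply_calibration <- function(cal, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  centered <- sweep(points, 2, cal$center)
  uv <- centered %*% cbind(cal$e1, cal$e2)
  hp <- cbind(uv, 1) %*% t(cal$H)
  cbind(x = hp[, 1] / hp[, 3],
        y = hp[, 2] / hp[, 3],
        z = as.numeric(centered %*% cal$normal))
}

#' Calibrate a trajectory from raw marker to screen coordinates
#'
#' @param traj An `mfr_trajectory` whose `x`, `y`, `z` hold raw marker
#'   coordinates.
#' @param cal An [fit_calibration()] result.
#' @return The trajectory with `x`, `y` as screen cm and `z` as perpendicular
#'   screen distance.
#' @export
calibrate_trajectory <- function(traj, cal) {
  mapped <- apply_calibration(cal, cbind(traj$x, traj$y, traj$z))
  traj$x <- mapped[, "x"]
  traj$y <- mapped[, "y"]
  traj$z <- mapped[, "z"]
  traj
}

#' @export
print.mfr_calibration <- function(x, ...) {
  cat(sprintf("Four-point screen calibration; fitting residual %.2e cm\n",
              x$residual))
  invisible(x)
}

#' Synthetic marker-to-screen miscalibration
#'
#' A rigid map (rotation by Euler angles plus offset) from true screen-frame
#' coordinates to raw marker coordinates, used to exercise the calibration
#' end to end: the generator's trajectories are pushed through the forward
#' map and recovered with [fit_calibration()] on the four corner
#' correspondences the map produces.
#'
#' @param angles_deg Rotations about x, y, z in degrees.
#' @param offset 3-D translation, cm.
#' @return An `mfr_miscalibration` with elements `R` (rotation matrix) and
#'   `offset`.
#' @export
miscalibration_map <- function(angles_deg = c(2, -1.5, 1), offset = c(0.8, -0.4, 1.2)) {
  a <- angles_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  structure(list(R = Rz %*% Ry %*% Rx, offset = as.numeric(offset)),
            class = "mfr_miscalibration")
}

#' @rdname miscalibration_map
#' @param traj An `mfr_trajectory` in screen coordinates.
#' @param map An `mfr_miscalibration`.
#' @export
apply_miscalibration <- function(traj, map) {
  p <- cbind(traj$x, traj$y, traj$z) %*% t(map$R)
  traj$x <- p[, 1] + map$offset[1]
  traj$y <- p[, 2] + map$offset[2]
  traj$z <- p[, 3] + map$offset[3]
  traj
}

#' @rdname miscalibration_map
#' @param geom An [mfr_geometry()]; the four calibration targets are the
#'   corners of its central 80 x 60 cm region.
#' @return `calibration_points()` returns a list with `raw` (4 x 3 marker
#'   positions), `screen` (4 x 2 targets) and `front` (a marker point in
#'   front of the screen), ready for [fit_calibration()].
#' @export
calibration_points <- function(map, geom = mfr_geometry()) {
  screen <- rbind(c(-40, -30), c(40, -30), c(40, 30), c(-40, 30))
  raw <- cbind(screen, 0) %*% t(map$R)
  raw <- sweep(raw, 2, -map$offset)
  front <- as.numeric(map$R %*% c(0, 0, 10) + map$offset)
  list(raw = raw, screen = screen, front = front)
}
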