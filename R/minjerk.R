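#' Minimum-jerk point-to-point trajectory
#'
#' The standard fifth-order polynomial reach profile with zero velocity and
#' acceleration at both endpoints, used as the stylized baseline for the
#' synthetic reaches. Positions are clamped to the endpoints outside
#' `[t0, t1]`.
#'
#' @param t Times, s (vectorized).
#' @param t0,t1 Movement onset and offset, s (`t1 > t0`).
#' @param p0,p1 Start and end positions, cm.
#' @return Position (`min_jerk_pos`) or velocity (`min_jerk_vel`) at `t`.
#' @export
min_jerk_pos <- function(t, t0, t1, p0, p1) {
  if (t1 <= t0) stop("movement offset must follow onset")
  tau <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  p0 + (p1 - p0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' @rdname min_jerk_pos
#' @export
min_jerk_vel <- function(t, t0, t1, p0, p1) {
  if (t1 <= t0) stop("movement offset must follow onset")
  tau <- (t - t0) / (t1 - t0)
  v <- (p1 - p0) / (t1 - t0) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  v[tau < 0 | tau > 1] <- 0
  v
}
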