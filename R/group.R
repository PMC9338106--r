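#' Aggregate per-participant results across the group
#'
#' Computes the across-participant mean and standard error (SD / sqrt(n)) of
#' the window-mean response magnitudes per condition, and optionally of the
#' response curves per lag, together with the per-participant frame-vs-tile
#' pairing used for the magnitude scatter.
#'
#' @param magnitudes Data frame with columns `participant`, `kind`,
#'   `side_cm`, `value_cm_s` (one row per participant x condition).
#' @param curves Optional long data frame with columns `participant`, `kind`,
#'   `side_cm`, `lag_s`, `value_cm_s`.
#' @return An `mfr_group_summary`: list with `magnitudes` (kind, side_cm,
#'   mean_cm_s, sem_cm_s, n_participants), `pairing` (participant, side_cm,
#'   frame_cm_s, tile_cm_s, diff_cm_s) and, when curves are given, `curves`
#'   (kind, side_cm, lag_s, mean_cm_s, sem_cm_s).
#' @export
group_summary <- function(magnitudes, curves = NULL) {
  n_part <- length(unique(magnitudes$participant))
  if (n_part < 2) {
    stop("group summary needs at least two participants (SEM undefined for n < 2)")
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  agg_mean <- stats::aggregate(value_cm_s ~ kind + side_cm, magnitudes, mean)
  agg_sem <- stats::aggregate(value_cm_s ~ kind + side_cm, magnitudes, sem)
  mag <- data.frame(kind = agg_mean$kind, side_cm = agg_mean$side_cm,
                    mean_cm_s = agg_mean$value_cm_s,
                    sem_cm_s = agg_sem$value_cm_s,
                    n_participants = n_part)
  wide <- stats::reshape(magnitudes, direction = "wide",
                         idvar = c("participant", "side_cm"),
                         timevar = "kind")
  pairing <- data.frame(participant = wide$participant,
                        side_cm = wide$side_cm,
                        frame_cm_s = wide$value_cm_s.frame,
                        tile_cm_s = wide$value_cm_s.tile)
  pairing$diff_cm_s <- pairing$tile_cm_s - pairing$frame_cm_s
  out <- list(magnitudes = mag, pairing = pairing, n_participants = n_part)
  if (!is.null(curves)) {
    cm <- stats::aggregate(value_cm_s ~ kind + side_cm + lag_s, curves, mean)
    cs <- stats::aggregate(value_cm_s ~ kind + side_cm + lag_s, curves, sem)
    out$curves <- data.frame(kind = cm$kind, side_cm = cm$side_cm,
                             lag_s = cm$lag_s, mean_cm_s = cm$value_cm_s,
                             sem_cm_s = cs$value_cm_s)
  }
  class(out) <- "mfr_group_summary"
  out
}

#' @export
print.mfr_group_summary <- function(x, ...) {
  cat(sprintf("Group summary across %d participants\n", x$n_participants))
  print(x$magnitudes)
  invisible(x)
}

#' Tile-vs-frame pairing slope with bootstrap interval
#'
#' Slope of the per-participant tile magnitudes against the frame magnitudes
#' (pooled over square sizes), estimated by standardized major-axis
#' regression (`sign(r) * sd(tile) / sd(frame)`), which is unbiased when both
#' axes carry comparable noise — ordinary least squares would be attenuated.
#' The confidence interval bootstraps participants.
#'
#' @param pairing The `pairing` element of a [group_summary()].
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return A list with `slope`, `ci` (length-2) and `n_boot`.
#' @export
pairing_slope <- function(pairing, n_boot = 2000, conf = 0.95, seed = 1L) {
  sma <- function(df) {
    r <- stats::cor(df$frame_cm_s, df$tile_cm_s)
    sign(r) * stats::sd(df$tile_cm_s) / stats::sd(df$frame_cm_s)
  }
  participants <- unique(pairing$participant)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    take <- sample(participants, replace = TRUE)
    sma(do.call(rbind, lapply(take, function(p) {
      pairing[pairing$participant == p, , drop = FALSE]
    })))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(slope = sma(pairing),
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
       n_boot = n_boot)
}
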