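#' Plot group response curves
#'
#' Direction-difference velocity time courses (mean +/- SEM band across
#' participants), one panel per square size, colored by square kind.
#'
#' @param group An [group_summary()] with curves.
#' @return A ggplot object.
#' @export
plot_response_curves <- function(group) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  d <- group$curves
  d$size <- factor(paste0(d$side_cm, " cm"),
                   levels = paste0(sort(unique(d$side_cm)), " cm"))
  ggplot2::ggplot(d, ggplot2::aes(x = 1000 * .data$lag_s, y = .data$mean_cm_s,
                                  color = .data$kind, fill = .data$kind)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_cm_s - .data$sem_cm_s,
                                      ymax = .data$mean_cm_s + .data$sem_cm_s),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~size) +
    ggplot2::labs(x = "Time after square-motion onset (ms)",
                  y = "Response (cm/s)", color = "Square", fill = "Square") +
    ggplot2::theme_minimal()
}

#' Plot response magnitudes
#'
#' Panel A: window-mean magnitude against square size with lines connecting
#' each participant's values per square kind. Panel B: each participant's
#' tile magnitude against their frame magnitude with the identity line.
#'
#' @param magnitudes The per-participant magnitude table
#'   (`participant`, `kind`, `side_cm`, `value_cm_s`).
#' @param pairing The `pairing` element of a [group_summary()].
#' @return A list of two ggplot objects, `size` and `scatter`.
#' @export
plot_magnitudes <- function(magnitudes, pairing) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  p_size <- ggplot2::ggplot(magnitudes,
                            ggplot2::aes(x = .data$side_cm, y = .data$value_cm_s,
                                         color = .data$kind,
                                         group = interaction(.data$participant,
                                                             .data$kind))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Square side (cm)", y = "Response magnitude (cm/s)",
                  color = "Square") +
    ggplot2::theme_minimal()
  lim <- range(c(pairing$frame_cm_s, pairing$tile_cm_s))
  p_scatter <- ggplot2::ggplot(pairing,
                               ggplot2::aes(x = .data$frame_cm_s,
                                            y = .data$tile_cm_s,
                                            color = factor(.data$side_cm))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "Frame response (cm/s)", y = "Tile response (cm/s)",
                  color = "Side (cm)") +
    ggplot2::theme_minimal()
  list(size = p_size, scatter = p_scatter)
}
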