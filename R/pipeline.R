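#' Run the full pipeline end to end
#'
#' Schedule, simulation, kinematics and response analysis for a group of
#' simulated participants, followed by the across-participant summary. Each
#' participant gets their own randomized schedule and session seed, derived
#' deterministically from the configuration seed. When
#' `calibration.miscalibrate` is set, every session is pushed through a fixed
#' marker-to-screen miscalibration and recovered with the four-point
#' calibration before analysis, exercising that stage end to end.
#'
#' @param config A (possibly partial) configuration; see [default_config()].
#' @param out_dir Optional directory; when given, the magnitude, curve,
#'   group, pairing and exclusion tables plus a run manifest are written
#'   there as delimited text.
#' @param quiet Suppress per-stage progress messages.
#' @return A result bundle: list with `config`, `magnitudes`, `curves`,
#'   `group` (an [group_summary()]), `exclusions`, `hit_rates`, `manifest`.
#' @export
run_end_to_end <- function(config = list(), out_dir = NULL, quiet = TRUE) {
  config <- validate_config(config)
  n_part <- as.integer(config$participants)
  if (n_part < 1) stop("stage config: participants must be >= 1")

  geom <- mfr_geometry()
  resp <- response_model(
    latency = config$response.latency,
    kernel_width = config$response.kernel_width,
    gain_by_size = c("7" = config$response.gain_7,
                     "37" = config$response.gain_37,
                     "67" = config$response.gain_67),
    gain_by_kind = c(frame = config$response.kind_gain_frame,
                     tile = config$response.kind_gain_tile))
  noise <- noise_model(position_sd = config$noise.position_sd,
                       endpoint_sd = config$noise.endpoint_sd,
                       missing_rate = config$noise.missing_rate,
                       timing_issue_rate = config$noise.timing_issue_rate)
  reach <- reach_model(contact_mean = config$reach.contact_mean,
                       contact_sd = config$reach.contact_sd,
                       onset = config$reach.onset,
                       lift_height = config$reach.lift_height)
  window <- c(config$analysis.window_start, config$analysis.window_end)

  set.seed(as.integer(config$seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_part),
                  ncol = 2)

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  miscal <- if (config$calibration.miscalibrate != 0) miscalibration_map() else NULL

  magnitudes <- list()
  curves <- list()
  exclusions <- list()
  hit_rates <- numeric(n_part)
  for (p in seq_len(n_part)) {
    id <- sprintf("P%02d", p)
    schedule <- with_stage("schedule", build_schedule(
      config$schedule.reps_per_cell, config$schedule.n_blocks,
      seed = seeds[p, 1]))
    session <- with_stage("simulate", simulate_session(
      schedule, resp, noise, geom, seed = seeds[p, 2], reach = reach))
    if (!is.null(miscal)) {
      session <- with_stage("calibrate", {
        raw <- lapply(session, apply_miscalibration, map = miscal)
        pts <- calibration_points(miscal, geom)
        cal <- fit_calibration(pts$raw, pts$screen, front_point = pts$front)
        out <- lapply(raw, calibrate_trajectory, cal = cal)
        class(out) <- "mfr_session"
        out
      })
    }
    res <- with_stage("analyze", analyze_session(
      session, participant = id, geom = geom, window = window,
      frame_s = config$analysis.frame_s))
    magnitudes[[p]] <- res$magnitudes
    curves[[p]] <- res$curves
    exclusions[[p]] <- res$exclusions
    hit_rates[p] <- res$hit_rate
    if (!quiet) {
      message(sprintf(
        "%s: %d trials simulated, %d excluded (%d timing, %d missing), hit rate %.1f%%",
        id, res$exclusions$n_total,
        res$exclusions$n_total - res$exclusions$n_kept,
        res$exclusions$n_timing, res$exclusions$n_missing,
        100 * res$hit_rate))
    }
  }
  magnitudes <- do.call(rbind, magnitudes)
  curves <- do.call(rbind, curves)
  exclusions <- do.call(rbind, exclusions)

  group <- if (n_part >= 2) {
    with_stage("group", group_summary(magnitudes, curves))
  } else {
    with_stage("group", stop("SEM undefined for a single participant"))
  }

  manifest <- data.frame(key = c("seed", "participants", "trials_per_participant",
                                 "excluded_timing", "excluded_missing",
                                 "mean_hit_rate"),
                         value = c(config$seed, n_part,
                                   exclusions$n_total[1],
                                   sum(exclusions$n_timing),
                                   sum(exclusions$n_missing),
                                   round(mean(hit_rates), 4)))

  bundle <- list(config = config, magnitudes = magnitudes, curves = curves,
                 group = group, exclusions = exclusions,
                 hit_rates = hit_rates, manifest = manifest)

  if (!is.null(out_dir)) {
    with_stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(magnitudes, file.path(out_dir, "magnitudes.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(group$magnitudes, file.path(out_dir, "group_magnitudes.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(group$curves, file.path(out_dir, "group_curves.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(group$pairing, file.path(out_dir, "pairing.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(exclusions, file.path(out_dir, "exclusions.csv"),
                       row.names = FALSE, quote = FALSE)
      cfg_path <- file.path(out_dir, "config.txt")
      write_config(config, cfg_path)
      manifest2 <- rbind(manifest,
                         data.frame(key = "config_md5",
                                    value = unname(tools::md5sum(cfg_path))))
      utils::write.csv(manifest2, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE, quote = FALSE)
    })
  }
  bundle
}
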