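#' Default run configuration
#'
#' A flat key-value configuration (dotted namespaces) whose defaults
#' reproduce the paradigm: 12 participants, 2 blocks of 25 repetitions per
#' condition cell, the default response, noise and reach models, the
#' 150-200 ms magnitude window and the one-display-frame timing-exclusion
#' tolerance. Unknown keys are rejected everywhere, so a typo cannot
#' silently corrupt a simulation.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    participants = 12,
    seed = 1,
    schedule.reps_per_cell = 25,
    schedule.n_blocks = 2,
    response.latency = 0.12,
    response.kernel_width = 0.15,
    response.gain_7 = 0.10,
    response.gain_37 = 0.085,
    response.gain_67 = 0.05,
    response.kind_gain_frame = 1,
    response.kind_gain_tile = 1,
    noise.position_sd = 0.01,
    noise.endpoint_sd = 0.62,
    noise.missing_rate = 0.01,
    noise.timing_issue_rate = 0.005,
    reach.contact_mean = 0.662,
    reach.contact_sd = 0.027,
    reach.onset = 0.10,
    reach.lift_height = 15,
    analysis.window_start = 0.15,
    analysis.window_end = 0.20,
    analysis.frame_s = 1 / 120,
    calibration.miscalibrate = 0
  )
}

#' Validate a run configuration
#'
#' Fills unspecified keys with defaults; unknown keys and non-numeric values
#' are errors.
#'
#' @param config A named list of configuration values (possibly partial).
#' @return The completed configuration.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  out <- defaults
  for (k in names(config)) {
    v <- config[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      stop("configuration value for '", k, "' must be a single number")
    }
    out[[k]] <- v
  }
  out
}

#' Write / read a configuration as flat key-value text
#'
#' One `key = value` line per entry; values round-trip at full double
#' precision.
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `read_config()` returns the validated configuration.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  lines <- sprintf("%s = %s", names(config),
                   vapply(config, function(v) sprintf("%.17g", v), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed configuration line: ", lines[bad][1])
  keys <- trimws(vapply(parts, `[`, character(1), 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, character(1), 2))))
  if (anyNA(vals)) {
    stop("non-numeric configuration value for key: ", keys[is.na(vals)][1])
  }
  validate_config(stats::setNames(as.list(vals), keys))
}

#' Write / read a trajectory as delimited text
#'
#' The file carries a `# key: value` header block with the trial metadata
#' followed by a CSV body with columns `t_s`, `x_cm`, `y_cm`, `z_cm`,
#' `missing` (0/1; positions of missing samples are empty).
#'
#' @param traj An `mfr_trajectory`.
#' @param path File path.
#' @return `read_trajectory()` returns the `mfr_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  meta <- c(trial_index = traj$trial$trial_index,
            block = traj$trial$block_index,
            kind = traj$trial$kind,
            side_cm = traj$trial$side,
            direction = traj$trial$direction,
            start_delay_s = traj$trial$start_delay,
            square_onset_s = traj$trial$square_onset,
            recorded_square_onset_s = traj$recorded_square_onset,
            recorded_square_offset_s = traj$recorded_square_offset,
            contact_time_s = traj$contact_time,
            reach_onset_s = traj$reach_onset)
  num <- function(v) {
    ifelse(is.na(v), "", sprintf("%.10g", v))
  }
  body <- paste(sprintf("%.4f", traj$time), num(traj$x), num(traj$y),
                num(traj$z), as.integer(traj$missing), sep = ",")
  writeLines(c(sprintf("# %s: %s", names(meta), as.character(meta)),
               "t_s,x_cm,y_cm,z_cm,missing", body), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  meta_lines <- sub("^# ", "", lines[hdr])
  kv <- strsplit(meta_lines, ": ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  body <- utils::read.csv(text = lines[!hdr], stringsAsFactors = FALSE)
  num <- function(k) as.numeric(meta[[k]])
  trial <- list(trial_index = num("trial_index"),
                block_index = num("block"),
                kind = meta[["kind"]],
                side = num("side_cm"),
                direction = meta[["direction"]],
                start_delay = num("start_delay_s"),
                square_onset = num("square_onset_s"))
  structure(list(time = body$t_s, x = body$x_cm, y = body$y_cm, z = body$z_cm,
                 missing = body$missing == 1, trial = trial,
                 recorded_square_onset = num("recorded_square_onset_s"),
                 recorded_square_offset = num("recorded_square_offset_s"),
                 contact_time = num("contact_time_s"),
                 reach_onset = num("reach_onset_s")),
            class = "mfr_trajectory")
}
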