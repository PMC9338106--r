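#' Build a randomized, interleaved trial schedule
#'
#' Each block contains every condition cell (2 kinds x 3 sizes x 2 motion
#' directions) exactly `reps_per_cell` times in a seed-reproducible shuffled
#' order; the default 25 repetitions and 2 blocks give the full 600-trial
#' session (300 per block). Per trial, the delay between finger-on-start and
#' target appearance is drawn uniformly from 0.5-0.7 s and the square's motion
#' onset uniformly from 0.3-0.4 s after target appearance.
#'
#' @param reps_per_cell Repetitions of each of the 12 cells per block (>= 1).
#' @param n_blocks Number of blocks (>= 1).
#' @param seed Integer seed for the shuffle and the timing draws.
#' @return An `mfr_schedule`: a data frame with columns `trial_index`,
#'   `block_index`, `kind`, `side`, `direction`, `start_delay`, `square_onset`
#'   and a `seed` attribute.
#' @examples
#' sched <- build_schedule(1, 1, seed = 0)
#' nrow(sched)  # 12, one trial per cell
#' @export
build_schedule <- function(reps_per_cell = 25, n_blocks = 2, seed = 1L) {
  if (!is.numeric(reps_per_cell) || reps_per_cell < 1) {
    stop("reps_per_cell must be a positive integer")
  }
  if (!is.numeric(n_blocks) || n_blocks < 1) {
    stop("n_blocks must be a positive integer")
  }
  reps_per_cell <- as.integer(reps_per_cell)
  n_blocks <- as.integer(n_blocks)
  cells <- condition_cells()
  set.seed(seed)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    idx <- sample(rep(seq_len(nrow(cells)), reps_per_cell))
    out <- cells[idx, , drop = FALSE]
    out$block_index <- b
    out
  })
  sched <- do.call(rbind, blocks)
  n <- nrow(sched)
  sched$trial_index <- seq_len(n)
  sched$start_delay <- stats::runif(n, 0.5, 0.7)
  sched$square_onset <- stats::runif(n, 0.3, 0.4)
  rownames(sched) <- NULL
  sched <- sched[, c("trial_index", "block_index", "kind", "side", "direction",
                     "start_delay", "square_onset")]
  attr(sched, "seed") <- seed
  class(sched) <- c("mfr_schedule", "data.frame")
  sched
}

#' Tabulate condition-cell counts of a schedule
#'
#' @param schedule An [build_schedule()] result.
#' @param by_block Count per block (default) or over the whole schedule.
#' @return A contingency table of kind x side x direction (x block).
#' @export
schedule_counts <- function(schedule, by_block = TRUE) {
  if (by_block) {
    table(kind = schedule$kind, side = schedule$side,
          direction = schedule$direction, block = schedule$block_index)
  } else {
    table(kind = schedule$kind, side = schedule$side,
          direction = schedule$direction)
  }
}

#' Write / read a schedule as delimited text
#'
#' Columns are written with unit-suffixed names (`side_cm`, `start_delay_s`,
#' `square_onset_s`).
#'
#' @param schedule An `mfr_schedule`.
#' @param path File path.
#' @return `read_schedule()` returns the schedule as an `mfr_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  out <- data.frame(trial_index = schedule$trial_index,
                    block = schedule$block_index,
                    kind = schedule$kind,
                    side_cm = schedule$side,
                    direction = schedule$direction,
                    start_delay_s = schedule$start_delay,
                    square_onset_s = schedule$square_onset)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "block", "kind", "side_cm", "direction",
            "start_delay_s", "square_onset_s")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("schedule file lacks columns: ", paste(missing, collapse = ", "))
  }
  sched <- data.frame(trial_index = raw$trial_index,
                      block_index = raw$block,
                      kind = raw$kind,
                      side = raw$side_cm,
                      direction = raw$direction,
                      start_delay = raw$start_delay_s,
                      square_onset = raw$square_onset_s)
  class(sched) <- c("mfr_schedule", "data.frame")
  sched
}
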