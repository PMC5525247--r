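# Antenna-read log parsing and occupancy reconstruction.
#
# Eight ring antennae, two per tube (one on the central-cage side, one on
# the satellite side). Location follows the nearest-side rule: after a read
# at the satellite-side antenna of tube k the animal is in satellite cage k;
# after any central-side read it is in the central cage. The rule needs no
# lookahead and is robust to missed reads; tube transit time is attributed
# to the origin cage.

#' Default run window of the standard schedule
#'
#' The standard experimental schedule starts around 16:00 on a Thursday and
#' ends the following Wednesday around 08:00, i.e. five days and six nights
#' (136 h).
#'
#' @param start Run start (POSIXct); defaults to a Thursday 16:00.
#' @return List with POSIXct `start` and `end` (start + 136 h).
#' @export
default_run_window <- function(start = as.POSIXct("2015-10-01 16:00:00", tz = "UTC")) {
  list(start = start, end = start + 136 * 3600)
}

#' Arena antenna layout
#'
#' Maps the eight antenna ids to (tube, side) and carries the run window.
#' The default numbering puts the central-side antenna of tube k at id
#' `2k - 1` and the satellite-side antenna at id `2k`.
#'
#' @param map Tibble with columns `antenna_id`, `tube` (1..4) and `side`
#'   (`"central"`/`"satellite"`); each (tube, side) pair must appear exactly
#'   once.
#' @param run_start,run_end Absolute run window (POSIXct). Default: the
#'   standard 136 h schedule.
#' @param focal_id Optional focal-animal identifier carried as metadata.
#'
#' @return An object of class `antenna_layout`.
#' @export
antenna_layout <- function(map = NULL,
                           run_start = default_run_window()$start,
                           run_end = default_run_window()$end,
                           focal_id = NA_character_) {
  if (is.null(map)) {
    map <- tibble(
      antenna_id = 1:8,
      tube = rep(1:4, each = 2),
      side = rep(c("central", "satellite"), 4)
    )
  }
  map <- as_tibble(map)
  if (nrow(map) != 8) abort("layout must describe exactly 8 antennae")
  if (anyDuplicated(map$antenna_id)) abort("duplicate antenna ids in layout")
  key <- paste(map$tube, map$side)
  need <- paste(rep(1:4, each = 2), rep(c("central", "satellite"), 4))
  if (!setequal(key, need) || anyDuplicated(key)) {
    abort("each (tube, side) pair must appear exactly once in the layout")
  }
  if (run_end <= run_start) abort("`run_end` must be after `run_start`")
  structure(list(map = map, run_start = run_start, run_end = run_end,
                 focal_id = focal_id),
            class = "antenna_layout")
}

# antenna id for (tube, side) vectors
antenna_id_for <- function(layout, tube, side) {
  key <- paste(layout$map$tube, layout$map$side)
  layout$map$antenna_id[match(paste(tube, side), key)]
}

#' Write an antenna-read event log
#'
#' Tab-separated, two columns: ISO 8601 timestamp with milliseconds and the
#' antenna id.
#'
#' @param reads Tibble with `timestamp` (POSIXct) and `antenna_id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(reads, path) {
  out <- tibble(
    timestamp = format(reads$timestamp, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
    antenna_id = reads$antenna_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an antenna-read event log
#'
#' Parses a two-column TSV (timestamp, antenna id), sorts reads by time,
#' drops reads at antenna ids not present in the layout, and collapses exact
#' duplicates (same timestamp and antenna). Counts of dropped/collapsed
#' records are attached as the `"anomalies"` attribute.
#'
#' @param path Path to the log file.
#' @param layout An [antenna_layout()] used to validate antenna ids.
#' @return Tibble of reads (`timestamp`, `antenna_id`) sorted by time, with
#'   attribute `anomalies` (list with `unknown_antenna`, `duplicates`).
#' @export
read_event_log <- function(path, layout = antenna_layout()) {
  if (!file.exists(path)) abort(sprintf("event log not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  empty <- tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                  antenna_id = integer())
  if (nrow(raw) == 0) {
    attr(empty, "anomalies") <- list(unknown_antenna = 0L, duplicates = 0L)
    return(empty)
  }
  if (ncol(raw) < 2) abort("event log must have two columns (timestamp, antenna_id)")
  ts <- as.POSIXct(raw[[1]], tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    abort(sprintf("unparseable timestamp at data line %d: '%s'", bad[1], raw[[1]][bad[1]]))
  }
  ant <- suppressWarnings(as.integer(raw[[2]]))
  known <- ant %in% layout$map$antenna_id
  n_unknown <- sum(!known)
  reads <- tibble(timestamp = ts[known], antenna_id = ant[known]) |>
    arrange(.data$timestamp)
  dup <- duplicated(paste(format(reads$timestamp, "%Y%m%d%H%M%OS6"), reads$antenna_id))
  n_dup <- sum(dup)
  if (n_dup > 0) reads <- reads[!dup, ]
  attr(reads, "anomalies") <- list(unknown_antenna = n_unknown, duplicates = n_dup)
  reads
}

#' Reconstruct cage occupancy from antenna reads
#'
#' Applies the nearest-side rule: the animal starts in the central cage at
#' the run start; after each read its location is the cage on that read's
#' side of the tube (satellite-side read at tube k puts it in Sk, any
#' central-side read puts it in the central cage), changing at the read's
#' timestamp. The final interval extends to the run end. The resulting
#' intervals tile the run window exactly.
#'
#' Anomalies reported (attribute `"anomalies"`): reads outside the run
#' window (rejected), and physically impossible jumps (a satellite-side
#' read at tube j while located in satellite k != j with no intervening
#' central-side read).
#'
#' @param reads Tibble of reads sorted by time (`timestamp`, `antenna_id`).
#' @param layout An [antenna_layout()].
#' @return Tibble of occupancy intervals (`cage`, `t_start`, `t_end`;
#'   POSIXct) with attribute `anomalies` (list with `outside_window`,
#'   `impossible_jumps`).
#' @export
reconstruct_occupancy <- function(reads, layout = antenna_layout()) {
  t0 <- layout$run_start
  t1 <- layout$run_end
  inside <- reads$timestamp >= t0 & reads$timestamp <= t1
  n_outside <- sum(!inside)
  reads <- reads[inside, , drop = FALSE]

  idx <- match(reads$antenna_id, layout$map$antenna_id)
  tube <- layout$map$tube[idx]
  sat <- layout$map$side[idx] == "satellite"
  loc <- ifelse(sat, tube, 0L)              # location after each read

  # impossible jump: satellite read at tube j while located in satellite k != j
  prev <- c(0L, loc[-length(loc)])
  n_jump <- sum(sat & prev > 0L & prev != tube)

  seq_loc <- c(0L, loc)                     # start central at run start
  seq_t <- c(t0, reads$timestamp)
  changed <- c(TRUE, seq_loc[-1] != seq_loc[-length(seq_loc)])
  cage <- seq_loc[changed]
  t_start <- seq_t[changed]
  occ <- tibble(
    cage = factor(CAGES[cage + 1L], levels = CAGES),
    t_start = t_start,
    t_end = c(t_start[-1], t1)
  )
  occ <- occ[as.numeric(occ$t_end) > as.numeric(occ$t_start), , drop = FALSE]
  stopifnot(nrow(occ) >= 1,
            all(abs(as.numeric(occ$t_end[-nrow(occ)]) -
                      as.numeric(occ$t_start[-1])) < 1e-9))
  attr(occ, "anomalies") <- list(outside_window = n_outside,
                                 impossible_jumps = n_jump)
  occ
}

#' Per-cage dwell totals and social time share
#'
#' @param occupancy Occupancy intervals (`cage`, `t_start`, `t_end`), times
#'   as POSIXct or numeric hours.
#' @return Tibble with one row per cage (`cage`, `hours`) over all five
#'   cages, with attribute `social_share` = satellite time / total time.
#' @export
cage_durations <- function(occupancy) {
  h <- time_to_hours(occupancy$t_end, origin = occupancy$t_start[1]) -
    time_to_hours(occupancy$t_start, origin = occupancy$t_start[1])
  cage <- factor(as.character(occupancy$cage), levels = CAGES)
  out <- tibble(cage = cage, hours = h) |>
    group_by(.data$cage, .drop = FALSE) |>
    summarise(hours = sum(.data$hours), .groups = "drop")
  total <- sum(out$hours)
  attr(out, "social_share") <-
    if (total > 0) sum(out$hours[out$cage != "central"]) / total else NA_real_
  out
}

#' Fraction of time spent in any satellite cage
#'
#' @inheritParams cage_durations
#' @return Social time share in \[0, 1\].
#' @export
social_time_share <- function(occupancy) {
  attr(cage_durations(occupancy), "social_share")
}

#' Antenna reads per clock hour
#'
#' Counts reads in half-open clock-hour bins `[h, h + 1)`; a read exactly on
#' an hour boundary is counted in the later bin. Bins with no reads are 0.
#'
#' @param reads Tibble of reads (`timestamp`, `antenna_id`).
#' @param window Optional list with `start`/`end` (POSIXct); defaults to the
#'   span of the reads.
#' @return Tibble with `hour_start` (POSIXct, whole hours) and `n_reads`.
#' @export
activity_per_hour <- function(reads, window = NULL) {
  if (nrow(reads) == 0 && is.null(window)) {
    return(tibble(hour_start = as.POSIXct(character(), tz = "UTC"),
                  n_reads = integer()))
  }
  start <- window$start %||% min(reads$timestamp)
  end <- window$end %||% max(reads$timestamp)
  h0 <- trunc(start, units = "hours")
  bins <- seq(from = h0, to = trunc(end, units = "hours"), by = 3600)
  i <- findInterval(as.numeric(reads$timestamp), as.numeric(bins))
  i <- i[i >= 1 & i <= length(bins)]
  counts <- tabulate(i, nbins = length(bins))
  tibble(hour_start = as.POSIXct(bins, tz = "UTC"), n_reads = counts)
}

#' Flag truncated recordings
#'
#' A recording whose read span covers less than `min_span_frac` of the
#' nominal run window (for example after a power failure) is flagged for
#' review rather than silently dropped.
#'
#' @param reads Tibble of reads.
#' @param layout An [antenna_layout()] giving the nominal window.
#' @param min_span_frac Minimum acceptable fraction of the nominal span.
#' @return Logical: `TRUE` if the recording is truncated.
#' @export
is_truncated_recording <- function(reads, layout = antenna_layout(),
                                   min_span_frac = 0.9) {
  nominal <- as.numeric(difftime(layout$run_end, layout$run_start, units = "hours"))
  if (nrow(reads) == 0) return(TRUE)
  span <- as.numeric(difftime(max(reads$timestamp), layout$run_start, units = "hours"))
  span < min_span_frac * nominal
}
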