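# Event-log parsing, occupancy reconstruction and activity series.

lay0 <- function(start = "2015-10-01 16:00:00", hours = 2) {
  t0 <- as.POSIXct(start, tz = "UTC")
  antenna_layout(run_start = t0, run_end = t0 + hours * 3600)
}

write_log_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("timestamp\tantenna_id", lines), path)
  path
}

test_that("well-formed logs parse sorted; unknown antennae are dropped and counted", {
  path <- write_log_lines(c(
    "2015-10-01T16:30:00.000\t3",
    "2015-10-01T16:10:00.500\t1",
    "2015-10-01T16:20:00.250\t99",
    "2015-10-01T16:20:00.250\t4"
  ))
  rd <- read_event_log(path, lay0())
  expect_equal(nrow(rd), 3)
  expect_false(is.unsorted(rd$timestamp))
  expect_equal(rd$antenna_id, c(1L, 4L, 3L))
  expect_equal(attr(rd, "anomalies")$unknown_antenna, 1L)
})

test_that("duplicate reads collapse with a counter; bad timestamps fail loudly", {
  path <- write_log_lines(c(
    "2015-10-01T16:10:00.500\t1",
    "2015-10-01T16:10:00.500\t1"
  ))
  rd <- read_event_log(path, lay0())
  expect_equal(nrow(rd), 1)
  expect_equal(attr(rd, "anomalies")$duplicates, 1L)

  bad <- write_log_lines(c("2015-10-01T16:10:00.500\t1", "not-a-time\t2"))
  expect_error(read_event_log(bad, lay0()), "line 2")

  empty <- write_log_lines(character())
  expect_equal(nrow(read_event_log(empty, lay0())), 0)
})

test_that("emitted reads round-trip through the log file unchanged", {
  p <- movement_params()
  tr <- simulate_trajectory(p, duration = 6, seed = 4)
  lay <- antenna_layout(run_start = as.POSIXct("2015-10-01 16:00:00", tz = "UTC"),
                        run_end = as.POSIXct("2015-10-01 22:00:00", tz = "UTC"))
  rd <- emit_reads(tr, p, lay, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_event_log(rd, path)
  back <- read_event_log(path, lay)
  expect_equal(nrow(back), nrow(rd))
  expect_equal(as.numeric(back$timestamp), as.numeric(rd$timestamp),
               tolerance = 1e-9)
  expect_equal(back$antenna_id, rd$antenna_id)
})

test_that("no reads means the whole window is central occupancy", {
  lay <- lay0()
  occ <- reconstruct_occupancy(
    tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                   antenna_id = integer()), lay)
  expect_equal(nrow(occ), 1)
  expect_identical(as.character(occ$cage), "central")
  expect_equal(occ$t_start, lay$run_start)
  expect_equal(occ$t_end, lay$run_end)
})

test_that("nearest-side rule: hand-traced example with a lingering read", {
  lay <- lay0(hours = 1)
  t0 <- lay$run_start
  # tube 2: central side antenna 3, satellite side antenna 4
  rd <- tibble::tibble(
    timestamp = t0 + c(60, 120, 180, 240),
    antenna_id = c(3L, 4L, 4L, 3L)
  )
  occ <- reconstruct_occupancy(rd, lay)
  expect_identical(as.character(occ$cage), c("central", "S2", "central"))
  expect_equal(as.numeric(occ$t_start - t0, units = "secs"), c(0, 120, 240))
  expect_equal(as.numeric(occ$t_end - t0, units = "secs"), c(120, 240, 3600))
  expect_equal(attr(occ, "anomalies")$impossible_jumps, 0L)
})

test_that("physically impossible jumps are counted; outside-window reads rejected", {
  lay <- lay0(hours = 1)
  t0 <- lay$run_start
  rd <- tibble::tibble(
    timestamp = t0 + c(-10, 60, 120, 3700),
    antenna_id = c(1L, 2L, 4L, 1L)   # S1 then S2 with no central read between
  )
  occ <- reconstruct_occupancy(rd, lay)
  expect_equal(attr(occ, "anomalies")$outside_window, 2L)
  expect_equal(attr(occ, "anomalies")$impossible_jumps, 1L)
  expect_identical(as.character(occ$cage), c("central", "S1", "S2"))
})

test_that("durations: totals sum to the window and social share is correct", {
  occ <- make_occupancy(c("central"), c(0, 10))
  d <- cage_durations(occ)
  expect_equal(sum(d$hours), 10)
  expect_equal(attr(d, "social_share"), 0)

  occ2 <- make_occupancy(
    c("central", "S1", "central", "S2", "central", "S3", "central", "S4"),
    c(0, 24, 34, 58, 68, 92, 102, 126, 136))
  d2 <- cage_durations(occ2)
  expect_equal(d2$hours[d2$cage == "central"], 96)
  expect_equal(sum(d2$hours[d2$cage != "central"]), 40)
  expect_equal(social_time_share(occ2), 40 / 136)

  # conservation under splitting an interval in two
  occ3 <- make_occupancy(
    c("central", "S1", "S1", "central", "S2", "central", "S3", "central", "S4"),
    c(0, 24, 29, 34, 58, 68, 92, 102, 126, 136))
  expect_equal(cage_durations(occ3)$hours, d2$hours)
})

test_that("reconstruction reproduces simulated ground truth exactly at ideal settings", {
  p <- fast_params()
  lay <- antenna_layout()
  for (s in 1:3) {
    tr <- simulate_trajectory(p, duration = 136, seed = s)
    rd <- emit_reads(tr, p, lay, seed = s + 100)
    occ <- reconstruct_occupancy(rd, lay)
    d <- cage_durations(occ)
    truth <- tr$dwell$hours[match(as.character(d$cage), as.character(tr$dwell$cage))]
    expect_equal(d$hours, truth, tolerance = 1e-9)
  }
})

test_that("deleting a single read perturbs durations only locally", {
  p <- movement_params(lingering_rate = 0.2)
  lay <- antenna_layout()
  tr <- simulate_trajectory(p, duration = 24, seed = 6)
  rd <- emit_reads(tr, p, lay, seed = 6)
  base <- cage_durations(reconstruct_occupancy(rd, lay))$hours
  set.seed(1)
  for (i in sample(nrow(rd), 15)) {
    pruned <- rd[-i, ]
    pert <- cage_durations(reconstruct_occupancy(pruned, lay))$hours
    t_prev <- if (i > 1) rd$timestamp[i - 1] else lay$run_start
    t_next <- if (i < nrow(rd)) rd$timestamp[i + 1] else lay$run_end
    span <- as.numeric(t_next - t_prev, units = "hours")
    expect_lte(max(abs(pert - base)), span + 1e-9)
  }
})

test_that("activity bins are half-open clock hours that conserve the read count", {
  t0 <- as.POSIXct("2015-10-01 16:00:00", tz = "UTC")
  rd <- tibble::tibble(
    timestamp = t0 + c(runif(86, 1, 3599), 3600),  # 86 in hour 1, 1 on boundary
    antenna_id = 1L
  ) |> dplyr::arrange(timestamp)
  act <- activity_per_hour(rd)
  expect_equal(act$n_reads[1], 86)
  expect_equal(act$n_reads[2], 1)   # boundary read counts in the later bin
  expect_equal(sum(act$n_reads), nrow(rd))
})

test_that("truncated recordings are flagged, not dropped", {
  lay <- antenna_layout()
  rd <- tibble::tibble(timestamp = lay$run_start + c(60, 3 * 24 * 3600),
                       antenna_id = c(1L, 2L))
  expect_true(is_truncated_recording(rd, lay))
  rd2 <- tibble::tibble(timestamp = lay$run_start + c(60, 135 * 3600),
                        antenna_id = c(1L, 2L))
  expect_false(is_truncated_recording(rd2, lay))
})
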