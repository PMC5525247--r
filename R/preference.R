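# Preferred-cage dynamics: which satellite cage holds the cumulative-dwell
# maximum at each 10-minute grid point, how often that preference changes
# ("preference blocks"), when it stabilizes, and whether early preferences
# match the final choice more often than expected by chance.

#' Preferred cage at each grid time
#'
#' At each cumulative 10-minute evaluation time, the preferred cage is the
#' satellite with the largest cumulative dwell. Ties keep the previous grid
#' point's preference when it is among the tied maxima, otherwise the
#' lowest cage index wins. The preference is undefined (`NA`) until the
#' first satellite visit.
#'
#' @inheritParams si_series
#' @return Tibble with `t_hours` and `preferred` (factor `S1`..`S4`, `NA`
#'   while undefined).
#' @export
preferred_cage_series <- function(occupancy, step_min = 10) {
  if (nrow(occupancy) == 0) abort("`occupancy` is empty")
  span <- time_to_hours(occupancy$t_end[nrow(occupancy)], occupancy$t_start[1])
  step_h <- step_min / 60
  grid_h <- seq(step_h, span + 1e-12, by = step_h)
  cum <- cumulative_satellite_durations(occupancy, grid_h)
  pref <- integer(length(grid_h))
  prev <- NA_integer_
  for (i in seq_along(grid_h)) {
    d <- cum[i, ]
    if (sum(d) == 0) {
      pref[i] <- NA_integer_
      next
    }
    top <- which(d == max(d))
    prev <- if (!is.na(prev) && prev %in% top) prev else top[1]
    pref[i] <- prev
  }
  tibble(t_hours = grid_h,
         preferred = factor(SATELLITES[pref], levels = SATELLITES))
}

#' Preference-block summary
#'
#' Segments the preferred-cage series into maximal runs of constant
#' preference ("preference blocks"). Few long blocks indicate a stable
#' choice; many short blocks an unstable one.
#'
#' @param series Tibble from [preferred_cage_series()].
#' @return One-row tibble: `n_blocks` (1 + number of preference changes
#'   between consecutive defined grid points), `last_block_fraction`
#'   (percentage of defined grid points in the final run) and
#'   `stabilization_time` (grid time, hours, at which the final block
#'   begins). All `NA` when no point is defined.
#' @export
segment_blocks <- function(series) {
  def <- !is.na(series$preferred)
  if (!any(def)) {
    return(tibble(n_blocks = NA_integer_, last_block_fraction = NA_real_,
                  stabilization_time = NA_real_))
  }
  p <- as.integer(series$preferred[def])
  t <- series$t_hours[def]
  changes <- sum(p[-1] != p[-length(p)])
  r <- rle(p)
  last_len <- r$lengths[length(r$lengths)]
  tibble(
    n_blocks = changes + 1L,
    last_block_fraction = 100 * last_len / length(p),
    stabilization_time = t[length(p) - last_len + 1]
  )
}

#' Final preference over the full run
#'
#' The satellite cage with the maximal total dwell over the whole run; ties
#' go to the lowest cage index with a tie flag.
#'
#' @param occupancy Occupancy intervals.
#' @return One-row tibble: `preferred` (factor, `NA` if no satellite time),
#'   `hours` in that cage, `share_of_social` (fraction of social time) and
#'   `tied` flag.
#' @export
final_preference <- function(occupancy) {
  d <- cage_durations(occupancy)
  sat <- d$hours[match(SATELLITES, as.character(d$cage))]
  if (sum(sat) == 0) {
    return(tibble(preferred = factor(NA_character_, levels = SATELLITES),
                  hours = NA_real_, share_of_social = NA_real_, tied = NA))
  }
  top <- which(sat == max(sat))
  tibble(
    preferred = factor(SATELLITES[top[1]], levels = SATELLITES),
    hours = sat[top[1]],
    share_of_social = sat[top[1]] / sum(sat),
    tied = length(top) > 1
  )
}

#' Match between early and final preference
#'
#' Compares the preferred cage at each checkpoint (defaults: after 10 min,
#' 90 min and 24 h) with the final preference over the whole run. An
#' undefined preference at a checkpoint counts as a non-match and is
#' flagged.
#'
#' @param series Tibble from [preferred_cage_series()].
#' @param occupancy Occupancy intervals (for the final preference).
#' @param checkpoints_h Checkpoint times in hours (must lie on the grid).
#' @return Tibble with `checkpoint_h`, `early` (preference then), `final`,
#'   `matched` and `undefined_at_checkpoint`.
#' @export
match_at <- function(series, occupancy, checkpoints_h = c(1 / 6, 1.5, 24)) {
  if (any(checkpoints_h > max(series$t_hours) + 1e-9)) {
    abort("checkpoints must lie within the run")
  }
  fin <- final_preference(occupancy)$preferred
  i <- vapply(checkpoints_h, function(ck) {
    which.min(abs(series$t_hours - ck))
  }, integer(1))
  early <- series$preferred[i]
  tibble(
    checkpoint_h = checkpoints_h,
    early = early,
    final = rep(fin, length(checkpoints_h)),
    matched = !is.na(early) & !is.na(fin) & early == fin,
    undefined_at_checkpoint = is.na(early)
  )
}

#' Chi-square test of matches against chance
#'
#' Goodness-of-fit test of the observed number of early/final preference
#' matches against the chance expectation `n_total / k_options`, on the
#' (matched, unmatched) pair with 1 degree of freedom. With the Yates
#' continuity correction (default), each `|O - E|` is reduced by 0.5
#' (floored at 0) before squaring.
#'
#' @param n_matched Observed matches.
#' @param n_total Number of animals tested.
#' @param k_options Number of equally likely options (default 4).
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return An object of class `chance_match_test`.
#' @export
chance_match_test <- function(n_matched, n_total, k_options = 4, yates = TRUE) {
  if (!is_count(n_matched) || !is_count(n_total) || n_total < 1) {
    abort("`n_matched` and `n_total` must be counts, n_total >= 1")
  }
  if (n_matched > n_total) abort("`n_matched` cannot exceed `n_total`")
  expected <- n_total / k_options
  obs <- c(n_matched, n_total - n_matched)
  exp <- c(expected, n_total - expected)
  dev <- abs(obs - exp)
  if (yates) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / exp)
  p <- pchisq(statistic, df = 1, lower.tail = FALSE)
  structure(list(n_matched = n_matched, n_total = n_total,
                 k_options = k_options, expected = expected,
                 statistic = statistic, df = 1L, p.value = p,
                 yates = yates),
            class = "chance_match_test")
}

#' @export
print.chance_match_test <- function(x, ...) {
  cat(sprintf("Chance-match chi-square test (%s)\n",
              if (x$yates) "Yates-corrected" else "uncorrected"))
  cat(sprintf("  matched %d of %d (expected by chance: %.2f)\n",
              x$n_matched, x$n_total, x$expected))
  cat(sprintf("  X-squared(%d) = %.4f, p = %.4g\n", x$df, x$statistic, x$p.value))
  invisible(x)
}

#' @method tidy chance_match_test
#' @export
tidy.chance_match_test <- function(x, ...) {
  tibble(n_matched = x$n_matched, n_total = x$n_total,
         expected = x$expected, statistic = x$statistic, df = x$df,
         p.value = x$p.value, yates = x$yates)
}

#' @method glance chance_match_test
#' @export
glance.chance_match_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}
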