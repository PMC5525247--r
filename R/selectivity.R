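# Selectivity index SI = SD / SD(max): the sample standard deviation of the
# four percentage dwell shares, divided by 50 (the maximal standard
# deviation with four options: sample SD of (100, 0, 0, 0)). SI is 0 for
# equal use of all four satellite cages and 1 for exclusive use of one.

#' Proportional satellite durations
#'
#' Converts four satellite dwell totals into percentages of total satellite
#' time.
#'
#' @param d Numeric vector of 4 nonnegative dwell totals (hours).
#' @return Numeric vector of 4 percentages summing to 100, or all-`NA` when
#'   no satellite time has accrued yet (undefined, not an error).
#' @export
proportional_durations <- function(d) {
  if (length(d) != 4 || any(is.na(d)) || any(d < 0)) {
    abort("`d` must be 4 nonnegative durations")
  }
  s <- sum(d)
  if (s == 0) return(rep(NA_real_, 4))
  100 * d / s
}

#' Selectivity index
#'
#' `SI = SD / 50`, where SD is the sample (n - 1 denominator) standard
#' deviation of the four percentage dwell shares and 50 is the maximal
#' standard deviation possible with four options (the sample SD of
#' (100, 0, 0, 0) is exactly 50).
#'
#' @param p Numeric vector of 4 percentages summing to 100 (tolerance 1e-6),
#'   or all-`NA` (undefined input propagates).
#' @return SI in \[0, 1\], or `NA` for undefined input.
#' @export
selectivity_index <- function(p) {
  if (length(p) != 4) abort("`p` must have 4 elements")
  if (all(is.na(p))) return(NA_real_)
  if (any(is.na(p)) || any(p < -1e-9) || abs(sum(p) - 100) > 1e-6) {
    abort("`p` must be 4 nonnegative percentages summing to 100")
  }
  sd(p) / 50
}

# cumulative dwell (hours) per satellite cage at each grid time, computed
# from the piecewise-linear cumulative occupancy function of each cage
cumulative_satellite_durations <- function(occupancy, grid_h) {
  origin <- occupancy$t_start[1]
  st <- time_to_hours(occupancy$t_start, origin)
  en <- time_to_hours(occupancy$t_end, origin)
  out <- matrix(0, nrow = length(grid_h), ncol = 4,
                dimnames = list(NULL, SATELLITES))
  for (k in seq_along(SATELLITES)) {
    sel <- occupancy$cage == SATELLITES[k]
    if (!any(sel)) next
    s <- st[sel]; e <- en[sel]
    cum_end <- cumsum(e - s)
    x <- as.vector(rbind(s, e))
    y <- as.vector(rbind(cum_end - (e - s), cum_end))
    x <- c(0, x); y <- c(0, y)
    out[, k] <- approx(x, y, xout = grid_h, method = "linear",
                       rule = 2, ties = "ordered")$y
  }
  out
}

#' Cumulative selectivity series on a 10-minute grid
#'
#' Evaluates SI on expanding windows: at grid time `t_i = i * step` the four
#' dwell percentages are computed from the cumulative satellite durations
#' over `[start, t_i]` (the first window is 10 minutes, the second
#' 20 minutes, and so forth). SI is undefined (`NA`) until the first
#' satellite visit; early undefined values are never coerced to 0.
#'
#' @param occupancy Occupancy intervals (`cage`, `t_start`, `t_end`).
#' @param step_min Grid step in minutes (default 10).
#' @return Tibble with `t_hours`, cumulative satellite hours `S1`..`S4`,
#'   `total_social_h` and `si`.
#' @export
si_series <- function(occupancy, step_min = 10) {
  if (nrow(occupancy) == 0) abort("`occupancy` is empty")
  span <- time_to_hours(occupancy$t_end[nrow(occupancy)], occupancy$t_start[1])
  step_h <- step_min / 60
  grid_h <- seq(step_h, span + 1e-12, by = step_h)
  cum <- cumulative_satellite_durations(occupancy, grid_h)
  total <- rowSums(cum)
  si <- rep(NA_real_, length(grid_h))
  pos <- total > 0
  if (any(pos)) {
    pct <- 100 * cum[pos, , drop = FALSE] / total[pos]
    si[pos] <- apply(pct, 1, sd) / 50
  }
  tibble(t_hours = grid_h, S1 = cum[, 1], S2 = cum[, 2], S3 = cum[, 3],
         S4 = cum[, 4], total_social_h = total, si = si)
}

#' Group mean SI with 95% confidence band
#'
#' Averages SI over individuals at each grid time within each group,
#' excluding undefined values, with a symmetric t-based 95% confidence
#' interval (computed when at least two defined values are present).
#'
#' @param data Tibble with one row per (individual, grid time): columns
#'   `group`, `t_hours` and `si` (`NA` for undefined).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `group`, `t_hours`, `n` (defined values), `mean_si`,
#'   `ci_lo`, `ci_hi`.
#' @export
group_mean_si <- function(data, conf_level = 0.95) {
  need <- c("group", "t_hours", "si")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns group, t_hours, si")
  }
  alpha <- 1 - conf_level
  data |>
    group_by(.data$group, .data$t_hours) |>
    summarise(
      n = sum(!is.na(.data$si)),
      mean_si = if (n[1] > 0) mean(.data$si, na.rm = TRUE) else NA_real_,
      se = if (n[1] > 1) sd(.data$si, na.rm = TRUE) / sqrt(n[1]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      tcrit = ifelse(.data$n > 1, qt(1 - alpha / 2, pmax(.data$n - 1, 1)), NA_real_),
      ci_lo = .data$mean_si - .data$tcrit * .data$se,
      ci_hi = .data$mean_si + .data$tcrit * .data$se
    ) |>
    select(-"tcrit") |>
    select(-"se")
}
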