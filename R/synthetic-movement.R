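# Continuous-time star-topology movement and antenna-read emission.
#
# The focal animal alternates between the central cage and the four
# satellites (an alternating renewal process): it leaves the central cage
# with an exponential hazard modulated by a piecewise-constant diurnal
# multiplier, picks satellite k with probability proportional to
# w_k * exp(beta * x_k), and stays there for an exponential time with mean
# dwell_mean * w_k.

#' Movement-model parameters
#'
#' Parameters of the continuous-time movement simulator and of antenna-read
#' emission. Defaults are calibrated to the long-running four-choice setup
#' they emulate: a 10-minute mean central stay and a 0.36 h mean satellite
#' stay give roughly 68% social time, and the lingering re-read rate brings
#' the total read rate to roughly 86 reads per hour.
#'
#' @param leave_central_hazard Baseline rate of leaving the central cage,
#'   events/hour (exponential hazard before diurnal modulation).
#' @param satellite_dwell_mean Mean satellite stay in hours at weight 1.
#' @param weights Positive preference weights `w_k`, one per satellite;
#'   they scale both the choice probability and the dwell mean.
#' @param beta Effect of a standardized dyadic covariate (e.g. MHCpat) on
#'   the log choice weight; 0 disables the effect.
#' @param lights_on,lights_off Clock hours of the 12:12 light cycle.
#' @param siesta Two clock hours bounding the midday activity trough.
#' @param mult_night,mult_day,mult_siesta Diurnal multipliers applied to the
#'   leave-central hazard during darkness, daylight and the midday trough.
#' @param transit_time Tube transit time in seconds between the paired
#'   antenna reads of one crossing.
#' @param detection_prob Probability that an antenna pass is detected.
#' @param lingering_rate Rate (reads/minute) of extra re-reads at the
#'   current cage's tube antenna while the animal stays put.
#'
#' @return An object of class `movement_params`.
#' @export
movement_params <- function(leave_central_hazard = 6, satellite_dwell_mean = 0.36,
                            weights = c(1, 1, 1, 1), beta = 0,
                            lights_on = 7, lights_off = 19,
                            siesta = c(12, 15),
                            mult_night = 1.4, mult_day = 0.8, mult_siesta = 0.25,
                            transit_time = 1, detection_prob = 0.95,
                            lingering_rate = 1.3) {
  if (leave_central_hazard < 0) abort("`leave_central_hazard` must be >= 0")
  if (satellite_dwell_mean <= 0) abort("`satellite_dwell_mean` must be > 0")
  if (length(weights) != 4 || any(weights <= 0)) abort("`weights` must be 4 positive values")
  if (any(c(mult_night, mult_day, mult_siesta) <= 0)) abort("diurnal multipliers must be > 0")
  stop_if_not_scalar_prob(detection_prob, "detection_prob")
  if (transit_time < 0) abort("`transit_time` must be >= 0")
  if (lingering_rate < 0) abort("`lingering_rate` must be >= 0")
  structure(list(
    leave_central_hazard = leave_central_hazard,
    satellite_dwell_mean = satellite_dwell_mean,
    weights = weights, beta = beta,
    lights_on = lights_on, lights_off = lights_off, siesta = siesta,
    mult_night = mult_night, mult_day = mult_day, mult_siesta = mult_siesta,
    transit_time = transit_time, detection_prob = detection_prob,
    lingering_rate = lingering_rate
  ), class = "movement_params")
}

# diurnal multiplier at a clock hour in [0, 24)
diurnal_multiplier <- function(clock, params) {
  night <- clock >= params$lights_off | clock < params$lights_on
  siesta <- clock >= params$siesta[1] & clock < params$siesta[2]
  ifelse(night, params$mult_night,
         ifelse(siesta, params$mult_siesta, params$mult_day))
}

# hours until the next diurnal breakpoint after clock hour `clock`
hours_to_next_break <- function(clock, params) {
  breaks <- sort(c(params$lights_on, params$siesta, params$lights_off))
  d <- (breaks - clock) %% 24
  d[d < 1e-12] <- 24
  min(d)
}

# waiting time (hours) for an exponential event with piecewise-constant
# hazard `hazard * m(clock)`, starting at absolute hour t0
pwc_exp_wait <- function(t0, hazard, start_clock, params) {
  e <- rexp(1)
  t <- t0
  repeat {
    clock <- (start_clock + t) %% 24
    rate <- hazard * diurnal_multiplier(clock, params)
    seg <- hours_to_next_break(clock, params)
    if (rate * seg >= e) return(t + e / rate - t0)
    e <- e - rate * seg
    t <- t + seg
  }
}

#' Simulate a focal-animal trajectory with known ground truth
#'
#' Runs the alternating renewal movement process for `duration` hours,
#' starting in the central cage at clock time `start_clock`.
#'
#' @param params A [movement_params()].
#' @param duration Run length in hours (default 136, the standard schedule).
#' @param covariates Optional numeric vector of 4 standardized dyadic
#'   covariate values (e.g. MHCpat), tilting the satellite choice
#'   probability by `exp(beta * covariate)`.
#' @param seed Optional integer seed for reproducibility.
#' @param start_clock Clock hour at which the run starts (default 16).
#'
#' @return An object of class `simulation_truth`: list with `trajectory`
#'   (tibble `cage`, `t_enter`, `t_exit` in hours from start), `dwell`
#'   (tibble `cage`, `hours` totals over all five cages), `duration`,
#'   `start_clock` and the generating `params`.
#' @export
simulate_trajectory <- function(params, duration = 136, covariates = NULL,
                                seed = NULL, start_clock = 16) {
  if (!inherits(params, "movement_params")) abort("`params` must be `movement_params`")
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be > 0")
  if (!is.null(covariates) && length(covariates) != 4) {
    abort("`covariates` must be NULL or length 4 (exactly 4 satellites)")
  }
  run <- function() {
    tilt <- if (is.null(covariates)) rep(0, 4) else params$beta * covariates
    p_choice <- params$weights * exp(tilt)
    p_choice <- p_choice / sum(p_choice)
    dwell_mean <- params$satellite_dwell_mean * params$weights

    cap <- max(16L, 4L * as.integer(ceiling(
      duration / (1 / max(params$leave_central_hazard, 0.01) +
                    min(dwell_mean)))))
    cage_i <- integer(cap); t_en <- numeric(cap); t_ex <- numeric(cap)
    n <- 0L
    push <- function(cg, a, b) {
      n <<- n + 1L
      if (n > length(cage_i)) {
        cage_i <<- c(cage_i, integer(length(cage_i)))
        t_en <<- c(t_en, numeric(length(t_en)))
        t_ex <<- c(t_ex, numeric(length(t_ex)))
      }
      cage_i[n] <<- cg; t_en[n] <<- a; t_ex[n] <<- b
    }

    t <- 0
    while (t < duration) {
      if (params$leave_central_hazard <= 0) {
        push(0L, t, duration)
        break
      }
      wait <- pwc_exp_wait(t, params$leave_central_hazard, start_clock, params)
      t_leave <- min(t + wait, duration)
      push(0L, t, t_leave)
      t <- t_leave
      if (t >= duration) break
      k <- sample.int(4L, 1L, prob = p_choice)
      stay <- rexp(1, rate = 1 / dwell_mean[k])
      t_back <- min(t + stay, duration)
      push(k, t, t_back)
      t <- t_back
    }

    # align interior transition times to the millisecond resolution of the
    # emitted timestamps, keeping boundaries strictly increasing
    if (n > 1) {
      dur_s <- duration * 3600
      bs <- round(t_en[2:n] * 3600, 3)
      for (i in seq_along(bs)) {
        lo <- if (i == 1) 0 else bs[i - 1]
        if (bs[i] <= lo) bs[i] <- lo + 0.001
      }
      bs <- pmin(bs, dur_s - 0.001)
      if (length(bs) > 1) {
        for (i in rev(seq_along(bs))[-1]) {
          if (bs[i] >= bs[i + 1]) bs[i] <- bs[i + 1] - 0.001
        }
      }
      t_en[2:n] <- bs / 3600
      t_ex[1:(n - 1)] <- bs / 3600
    }

    traj <- tibble(
      cage = factor(CAGES[cage_i[seq_len(n)] + 1L], levels = CAGES),
      t_enter = t_en[seq_len(n)], t_exit = t_ex[seq_len(n)]
    )
    dwell <- traj |>
      group_by(.data$cage, .drop = FALSE) |>
      summarise(hours = sum(.data$t_exit - .data$t_enter), .groups = "drop")
    structure(list(trajectory = traj, dwell = dwell, duration = duration,
                   start_clock = start_clock, params = params),
              class = "simulation_truth")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Emit antenna reads from a ground-truth trajectory
#'
#' Each cage transition through tube k emits a read at the origin-side
#' antenna followed, one transit time later, by a read at the
#' destination-side antenna; each read is retained with the detection
#' probability. While the animal stays in a cage, extra "lingering" re-reads
#' are emitted at the corresponding antenna (current tube's satellite-side
#' antenna in a satellite cage; a random tube's central-side antenna in the
#' central cage) as a Poisson process. Timestamps have millisecond
#' resolution.
#'
#' @param truth A `simulation_truth` from [simulate_trajectory()].
#' @param params A [movement_params()] (detection, transit, lingering).
#' @param layout An [antenna_layout()]; supplies the antenna-id mapping and
#'   the absolute run start time.
#' @param seed Optional integer seed.
#'
#' @return A tibble of reads with columns `timestamp` (POSIXct, ms
#'   resolution) and `antenna_id`, sorted by time.
#' @export
emit_reads <- function(truth, params = truth$params, layout = antenna_layout(),
                       seed = NULL) {
  if (!inherits(truth, "simulation_truth")) abort("`truth` must be a `simulation_truth`")
  run <- function() {
    traj <- truth$trajectory
    n <- nrow(traj)
    empty <- tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                    antenna_id = integer())
    if (n == 0) return(empty)
    cage_idx <- as.integer(traj$cage) - 1L  # 0 = central, 1..4 = satellites

    # transition reads
    tr_time <- double(0); tr_ant <- integer(0); tr_ord <- double(0)
    if (n > 1) {
      from <- cage_idx[-n]; to <- cage_idx[-1]
      t0 <- traj$t_enter[-1]
      tube <- pmax(from, to)               # star topology: one of the two is 0
      origin_sat <- from > 0               # origin side of the crossing
      tau <- params$transit_time / 3600
      a1 <- antenna_id_for(layout, tube, ifelse(origin_sat, "satellite", "central"))
      a2 <- antenna_id_for(layout, tube, ifelse(origin_sat, "central", "satellite"))
      tr_time <- c(t0, t0 + tau)
      tr_ant <- c(a1, a2)
      # origin read sorts before destination read on ties (zero transit)
      tr_ord <- c(seq_along(t0) * 2, seq_along(t0) * 2 + 1)
    }

    # lingering re-reads
    li_time <- double(0); li_ant <- integer(0)
    if (params$lingering_rate > 0) {
      dur_min <- (traj$t_exit - traj$t_enter) * 60
      counts <- rpois(n, params$lingering_rate * dur_min)
      # keep lingering reads strictly inside their interval even after
      # millisecond rounding, so they can never shadow a transition read
      margin <- 0.002 / 3600
      counts[(traj$t_exit - traj$t_enter) <= 2 * margin] <- 0L
      if (sum(counts) > 0) {
        idx <- rep.int(seq_len(n), counts)
        len <- traj$t_exit[idx] - traj$t_enter[idx]
        li_time <- traj$t_enter[idx] + margin +
          runif(length(idx)) * (len - 2 * margin)
        tube <- cage_idx[idx]
        side <- ifelse(tube > 0, "satellite", "central")
        tube[tube == 0] <- sample.int(4L, sum(tube == 0), replace = TRUE)
        li_ant <- antenna_id_for(layout, tube, side)
      }
    }

    time_h <- c(tr_time, li_time)
    ant <- c(tr_ant, li_ant)
    ord <- c(tr_ord, rep(Inf, length(li_time)))
    keep <- runif(length(time_h)) < params$detection_prob
    time_h <- time_h[keep]; ant <- ant[keep]; ord <- ord[keep]
    if (length(time_h) == 0) return(empty)

    o <- order(time_h, ord)
    ts <- layout$run_start + round(time_h[o] * 3600, 3)
    tibble(timestamp = ts, antenna_id = as.integer(ant[o]))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
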