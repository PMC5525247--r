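# Fixtures and independent oracles used across test files.

# Occupancy tibble from cage labels and boundary times (numeric hours).
make_occupancy <- function(cages, bounds) {
  stopifnot(length(bounds) == length(cages) + 1)
  tibble::tibble(
    cage = factor(cages, levels = c("central", "S1", "S2", "S3", "S4")),
    t_start = bounds[-length(bounds)],
    t_end = bounds[-1]
  )
}

# Random valid occupancy (alternating central/satellite) over [0, span_h].
random_occupancy <- function(span_h = 24, seed = 1) {
  set.seed(seed)
  bounds <- sort(runif(30, 0, span_h))
  bounds <- unique(c(0, bounds, span_h))
  n <- length(bounds) - 1
  cages <- character(n)
  for (i in seq_len(n)) {
    cages[i] <- if (i %% 2 == 1) "central" else sample(paste0("S", 1:4), 1)
  }
  make_occupancy(cages, bounds)
}

# Brute-force cumulative satellite dwell at time t (hours) by looping over
# intervals; independent of the package's interpolation-based computation.
brute_cum_dwell <- function(occupancy, t) {
  out <- setNames(numeric(4), paste0("S", 1:4))
  st <- arenapref:::time_to_hours(occupancy$t_start, occupancy$t_start[1])
  en <- arenapref:::time_to_hours(occupancy$t_end, occupancy$t_start[1])
  for (i in seq_len(nrow(occupancy))) {
    cg <- as.character(occupancy$cage[i])
    if (cg == "central") next
    out[cg] <- out[cg] + max(0, min(en[i], t) - st[i]) * (st[i] < t)
  }
  out
}

# Small fast movement setup for simulation-based tests.
fast_params <- function(...) {
  movement_params(transit_time = 0, detection_prob = 1, lingering_rate = 0, ...)
}

small_cohort <- function(seed = 1) {
  simulate_cohort(
    population_model(n_loci = 5, alleles_per_locus = 4, seed = seed),
    pedigree_spec(pairs_per_cross = 1, offspring_per_sex_per_pair = 1),
    seed = seed
  )
}
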