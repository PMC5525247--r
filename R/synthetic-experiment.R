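# Cohort-level synthetic experiments: genotyped mice, satellite assignment,
# dyadic covariates, ground-truth trajectories and (optionally) emitted
# antenna-read logs.

#' Simulate a complete multi-choice experiment
#'
#' Builds a genotyped cohort, assigns each focal animal four opposite-sex
#' satellites (one per cross type), computes dyadic covariates, draws
#' per-focal preference weights, and simulates a ground-truth trajectory per
#' focal animal. When `beta` is nonzero the standardized MHCpat covariate
#' tilts the satellite choice probability by `exp(beta * z)`.
#'
#' Every focal animal's trajectory uses an RNG stream derived from the
#' master seed and its id.
#'
#' @param pop_model A [population_model()].
#' @param pedigree A [pedigree_spec()].
#' @param params A [movement_params()].
#' @param n_focal Number of focal animals (default: all offspring, 48 under
#'   the default design).
#' @param duration Run length in hours.
#' @param beta Effect of standardized MHCpat on the log choice weight
#'   (overrides `params$beta`).
#' @param weight_sdlog Log-sd of the lognormal per-focal preference weights
#'   (0 gives equal weights).
#' @param emit Also emit antenna reads per focal animal.
#' @param seed Master seed.
#'
#' @return List of class `arena_experiment`: `cohort`, `focal_ids`,
#'   `dyads` (focal_id, satellite_id, cage, covariates, standardized
#'   `mhc_pat_std`, true dwell `hours`), `truths` (named list of
#'   `simulation_truth`), `reads` (named list of read tibbles, if `emit`),
#'   `layout`, `params`.
#' @export
simulate_experiment <- function(pop_model = population_model(),
                                pedigree = pedigree_spec(),
                                params = movement_params(),
                                n_focal = NULL, duration = 136,
                                beta = params$beta, weight_sdlog = 1,
                                emit = FALSE, seed = 1L) {
  cohort <- simulate_cohort(pop_model, pedigree, seed = seed)
  offspring <- cohort[cohort$role == "offspring", ]
  n_focal <- n_focal %||% nrow(offspring)
  if (n_focal > nrow(offspring)) abort("`n_focal` exceeds available offspring")

  params$beta <- beta
  layout <- antenna_layout()
  start_clock <- as.numeric(format(layout$run_start, "%H")) +
    as.numeric(format(layout$run_start, "%M")) / 60

  assign <- with_seed(hash_seed(seed, "focal_assignment"), {
    focal_ids <- if (n_focal == nrow(offspring)) offspring$id else
      sample(offspring$id, n_focal)
    sat_tbl <- purrr::map_dfr(focal_ids, function(fid) {
      f <- offspring[offspring$id == fid, ]
      opp <- offspring[offspring$sex != f$sex, ]
      sats <- vapply(CROSS_CODES, function(cc) {
        pool <- opp$id[opp$cross == cc]
        if (length(pool) == 0) abort("no opposite-sex animal of cross " %+% cc)
        pool[sample.int(length(pool), 1)]
      }, character(1))
      tibble(focal_id = fid, satellite_id = unname(sats),
             cage = factor(SATELLITES, levels = SATELLITES))
    })
    list(focal_ids = focal_ids, sat_tbl = sat_tbl)
  })

  dyads <- purrr::map_dfr(assign$focal_ids, function(fid) {
    sids <- assign$sat_tbl$satellite_id[assign$sat_tbl$focal_id == fid]
    cov <- dyadic_covariates(cohort, fid, sids)
    cov$cage <- factor(SATELLITES, levels = SATELLITES)
    cov
  })
  mu <- mean(dyads$mhc_pat, na.rm = TRUE)
  sg <- sd(dyads$mhc_pat, na.rm = TRUE)
  dyads$mhc_pat_std <- if (!is.na(sg) && sg > 0) (dyads$mhc_pat - mu) / sg else 0

  truths <- setNames(vector("list", length(assign$focal_ids)), assign$focal_ids)
  reads <- if (emit) truths else NULL
  hours <- numeric(nrow(dyads))
  for (fid in assign$focal_ids) {
    rows <- which(dyads$focal_id == fid)
    w <- with_seed(hash_seed(seed, paste0("weights_", fid)),
                   stats::rlnorm(4, 0, weight_sdlog))
    p_f <- params
    p_f$weights <- w
    z <- dyads$mhc_pat_std[rows]
    z[is.na(z)] <- 0
    truth <- simulate_trajectory(p_f, duration = duration, covariates = z,
                                 seed = hash_seed(seed, paste0("traj_", fid)),
                                 start_clock = start_clock)
    truths[[fid]] <- truth
    hours[rows] <- truth$dwell$hours[match(SATELLITES, as.character(truth$dwell$cage))]
    if (emit) {
      reads[[fid]] <- emit_reads(truth, p_f, layout,
                                 seed = hash_seed(seed, paste0("reads_", fid)))
    }
  }
  dyads$hours <- hours

  structure(list(cohort = cohort, focal_ids = assign$focal_ids,
                 dyads = dyads, truths = truths, reads = reads,
                 layout = layout, params = params, seed = seed),
            class = "arena_experiment")
}

`%+%` <- function(a, b) paste0(a, b)

#' Export a synthetic experiment to disk
#'
#' Writes one event-log TSV per focal animal, the cohort genotype CSV, the
#' phased haplotype FASTA and a ground-truth JSON (per-focal true dwell
#' totals and generative parameters).
#'
#' @param exp An `arena_experiment` simulated with `emit = TRUE`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  if (!inherits(exp, "arena_experiment")) abort("`exp` must be an `arena_experiment`")
  if (is.null(exp$reads)) abort("experiment was simulated without `emit = TRUE`")
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("writing the ground-truth JSON requires the 'jsonlite' package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fid in exp$focal_ids) {
    write_event_log(exp$reads[[fid]], file.path(dir, paste0(fid, "_reads.tsv")))
  }
  write_genotype_table(exp$cohort, file.path(dir, "cohort_genotypes.csv"))
  write_haplotype_fasta(exp$cohort, file.path(dir, "haplotypes.fasta"))
  truth <- lapply(exp$truths, function(tr) {
    as.list(setNames(tr$dwell$hours, as.character(tr$dwell$cage)))
  })
  json <- list(seed = exp$seed, duration = exp$truths[[1]]$duration,
               params = unclass(exp$params), true_dwell_hours = truth)
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}
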