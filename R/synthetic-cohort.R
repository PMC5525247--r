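# Synthetic genotyped cohorts: two weakly diverged source populations,
# reciprocal F1 crosses, 13 microsatellite loci and a shared MHC haplotype
# pool.

# default marker panel (13 unlinked microsatellites)
MICROSAT_LOCI <- c(
  "Chr3_24R", "Chr16_21R", "Chr12_05R", "Chr10_45R", "Chr01_25R",
  "Chr17_09R", "Chr05_45R", "Chr13_22R", "Chr19_08R", "Chr14_16R",
  "Chr09_20R", "Chr01_23", "Chr02_02R"
)

CROSS_CODES <- c("FF", "GG", "FG", "GF")

rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

# non-stop codons of the standard nuclear code
non_stop_codons <- function() {
  b <- c("a", "c", "g", "t")
  cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cod, c("taa", "tag", "tga"))
}

#' Population model for synthetic cohorts
#'
#' Defines the allele-frequency structure of two source populations (F and G)
#' over a microsatellite panel, and a shared pool of aligned in-frame MHC
#' haplotype sequences with per-population pool frequencies. Divergence
#' between the populations is controlled by mixing population-specific
#' Dirichlet draws toward a common base frequency vector, so the two
#' populations stay separable but only weakly so.
#'
#' @param n_loci Number of microsatellite loci (default 13, the standard
#'   panel; loci are then named after the panel markers).
#' @param alleles_per_locus Number of distinct alleles segregating per locus.
#' @param divergence Weight in \[0, 1\] of the population-specific frequency
#'   component at microsatellite loci; 0 gives identical populations.
#' @param n_haplotypes Size of the shared MHC haplotype pool.
#' @param hap_length Haplotype length in nucleotides; must be divisible by 3.
#' @param mhc_divergence Divergence weight for MHC pool frequencies
#'   (kept low by default: the locus is not differentiated between
#'   populations).
#' @param mhc_mutation_rate Per-codon probability that a pool haplotype
#'   differs from the pool founder sequence; controls the typical
#'   amino-acid p-distance between haplotypes (default 0.11 gives mean dyadic
#'   p-distances around 0.155).
#' @param seed Integer seed controlling frequency and pool generation.
#'
#' @return An object of class `population_model`: a list with elements
#'   `loci`, `alleles` (per-locus integer allele labels), `pop_freqs`
#'   (per population, per locus), `mhc_pool` (named character vector of
#'   nucleotide sequences) and `mhc_pool_freqs`.
#' @export
population_model <- function(n_loci = 13, alleles_per_locus = 8,
                             divergence = 0.3, n_haplotypes = 12,
                             hap_length = 270, mhc_divergence = 0.1,
                             mhc_mutation_rate = 0.11, seed = 1L) {
  if (!is_count(n_loci) || n_loci < 1) abort("`n_loci` must be a positive count")
  if (!is_count(alleles_per_locus) || alleles_per_locus < 1) {
    abort("`alleles_per_locus` must be a positive count (empty allele pools are not allowed)")
  }
  if (hap_length %% 3 != 0) abort("`hap_length` must be divisible by 3 (in-frame coding sequence)")
  if (!is_count(n_haplotypes) || n_haplotypes < 1) abort("`n_haplotypes` must be >= 1")

  loci <- if (n_loci == 13) MICROSAT_LOCI else sprintf("L%02d", seq_len(n_loci))

  with_seed(seed, {
    alleles <- lapply(seq_len(n_loci), function(l) {
      as.integer(100L + 10L * l + 2L * (seq_len(alleles_per_locus) - 1L))
    })
    names(alleles) <- loci

    freq_pair <- function(k, w) {
      base <- rdirichlet1(k)
      lapply(c(F = 1, G = 2), function(i) (1 - w) * base + w * rdirichlet1(k))
    }
    per_locus <- lapply(seq_len(n_loci), function(l) freq_pair(alleles_per_locus, divergence))
    pop_freqs <- list(
      F = lapply(per_locus, `[[`, "F"),
      G = lapply(per_locus, `[[`, "G")
    )
    names(pop_freqs$F) <- names(pop_freqs$G) <- loci

    codons <- non_stop_codons()
    n_codon <- hap_length %/% 3
    founder <- sample(codons, n_codon, replace = TRUE)
    mhc_pool <- vapply(seq_len(n_haplotypes), function(i) {
      hap <- founder
      mut <- runif(n_codon) < mhc_mutation_rate
      hap[mut] <- sample(codons, sum(mut), replace = TRUE)
      paste(hap, collapse = "")
    }, character(1))
    names(mhc_pool) <- sprintf("H%02d", seq_len(n_haplotypes))

    pool_fp <- freq_pair(n_haplotypes, mhc_divergence)
    structure(list(
      loci = loci, alleles = alleles, pop_freqs = pop_freqs,
      mhc_pool = mhc_pool,
      mhc_pool_freqs = list(F = pool_fp$F, G = pool_fp$G)
    ), class = "population_model")
  })
}

#' Pedigree specification for a crossed cohort
#'
#' Describes the breeding design: how many independent breeding pairs are set
#' up per cross type and how many offspring of each sex every pair
#' contributes. Cross codes give the maternal population first (`GF` = German
#' mother, French father).
#'
#' @param crosses Character vector of cross codes, a subset of
#'   `c("FF", "GG", "FG", "GF")`.
#' @param pairs_per_cross Breeding pairs per cross type.
#' @param offspring_per_sex_per_pair Offspring of each sex per pair. The
#'   default design (4 crosses x 3 pairs x 2 per sex) yields 24 female and
#'   24 male focal-eligible mice.
#'
#' @return An object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(crosses = CROSS_CODES, pairs_per_cross = 3,
                          offspring_per_sex_per_pair = 2) {
  bad <- setdiff(crosses, CROSS_CODES)
  if (length(bad) > 0) {
    abort(sprintf("invalid cross code(s): %s (valid: %s)",
                  paste(bad, collapse = ", "), paste(CROSS_CODES, collapse = ", ")))
  }
  if (!is_count(pairs_per_cross) || pairs_per_cross < 1) {
    abort("`pairs_per_cross` must be a positive count")
  }
  if (!is_count(offspring_per_sex_per_pair) || offspring_per_sex_per_pair < 1) {
    abort("`offspring_per_sex_per_pair` must be a positive count")
  }
  structure(list(crosses = crosses, pairs_per_cross = pairs_per_cross,
                 offspring_per_sex_per_pair = offspring_per_sex_per_pair),
            class = "pedigree_spec")
}

draw_genotype <- function(pm, pop) {
  vapply(seq_along(pm$loci), function(l) {
    pool <- pm$alleles[[l]]
    a <- pool[sample.int(length(pool), 2, replace = TRUE,
                         prob = pm$pop_freqs[[pop]][[l]])]
    paste(sort(a), collapse = "/")
  }, character(1))
}

mendel_genotype <- function(gm, gf) {
  vapply(seq_along(gm), function(l) {
    am <- as.integer(strsplit(gm[l], "/", fixed = TRUE)[[1]])
    af <- as.integer(strsplit(gf[l], "/", fixed = TRUE)[[1]])
    a <- c(sample(am, 1), sample(af, 1))
    paste(sort(a), collapse = "/")
  }, character(1))
}

#' Simulate a genotyped, pedigreed cohort
#'
#' Draws founder parents from the two source populations according to the
#' pedigree's cross design, then generates offspring by Mendelian inheritance
#' at every microsatellite locus and at the MHC locus (one haplotype from
#' each parent). Every animal's random draws use an RNG stream derived from
#' the master seed and its id, so edits elsewhere in the cohort leave an
#' animal's genotype unchanged.
#'
#' @param pop_model A [population_model()].
#' @param pedigree A [pedigree_spec()].
#' @param seed Integer master seed.
#'
#' @return A tibble with one row per animal: `id`, `sex` (`"F"`/`"M"`),
#'   `role` (`"founder"`/`"offspring"`), `cross` (maternal letter first),
#'   `mother_id`, `father_id` (`NA` for founders), one `"a/b"` column per
#'   microsatellite locus, and nucleotide haplotypes `hap1`, `hap2`.
#' @export
simulate_cohort <- function(pop_model, pedigree = pedigree_spec(), seed = 1L) {
  if (!inherits(pop_model, "population_model")) abort("`pop_model` must be a `population_model`")
  if (!inherits(pedigree, "pedigree_spec")) abort("`pedigree` must be a `pedigree_spec`")

  rows <- list()
  for (cross in pedigree$crosses) {
    pop_m <- substr(cross, 1, 1)
    pop_f <- substr(cross, 2, 2)
    kid_idx <- c(F = 0L, M = 0L)
    for (pair in seq_len(pedigree$pairs_per_cross)) {
      dam_id <- sprintf("DAM_%s_%d", cross, pair)
      sire_id <- sprintf("SIRE_%s_%d", cross, pair)
      dam <- with_seed(hash_seed(seed, dam_id), list(
        g = draw_genotype(pop_model, pop_m),
        h = sample(names(pop_model$mhc_pool), 2, replace = TRUE,
                   prob = pop_model$mhc_pool_freqs[[pop_m]])
      ))
      sire <- with_seed(hash_seed(seed, sire_id), list(
        g = draw_genotype(pop_model, pop_f),
        h = sample(names(pop_model$mhc_pool), 2, replace = TRUE,
                   prob = pop_model$mhc_pool_freqs[[pop_f]])
      ))
      rows[[dam_id]] <- list(id = dam_id, sex = "F", role = "founder",
                             cross = paste0(pop_m, pop_m),
                             mother_id = NA_character_, father_id = NA_character_,
                             g = dam$g, h = dam$h)
      rows[[sire_id]] <- list(id = sire_id, sex = "M", role = "founder",
                              cross = paste0(pop_f, pop_f),
                              mother_id = NA_character_, father_id = NA_character_,
                              g = sire$g, h = sire$h)
      for (sex in c("F", "M")) {
        for (k in seq_len(pedigree$offspring_per_sex_per_pair)) {
          kid_idx[sex] <- kid_idx[sex] + 1L
          kid_id <- sprintf("%s_%s%02d", cross, sex, kid_idx[sex])
          kid <- with_seed(hash_seed(seed, kid_id), list(
            g = mendel_genotype(rows[[dam_id]]$g, rows[[sire_id]]$g),
            h = c(sample(rows[[dam_id]]$h, 1), sample(rows[[sire_id]]$h, 1))
          ))
          rows[[kid_id]] <- list(id = kid_id, sex = sex, role = "offspring",
                                 cross = cross, mother_id = dam_id,
                                 father_id = sire_id, g = kid$g, h = kid$h)
        }
      }
    }
  }

  geno <- do.call(rbind, lapply(rows, function(r) r$g))
  colnames(geno) <- pop_model$loci
  pull <- function(f) unname(vapply(rows, `[[`, character(1), f))
  out <- tibble(
    id = pull("id"), sex = pull("sex"), role = pull("role"),
    cross = pull("cross"), mother_id = pull("mother_id"),
    father_id = pull("father_id")
  )
  out <- dplyr::bind_cols(out, as_tibble(geno))
  out$hap1 <- unname(pop_model$mhc_pool[vapply(rows, function(r) r$h[1], character(1))])
  out$hap2 <- unname(pop_model$mhc_pool[vapply(rows, function(r) r$h[2], character(1))])
  attr(out, "pop_model") <- pop_model
  attr(out, "loci") <- pop_model$loci
  out
}
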