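# Individual-level genetic distances: proportion of shared microsatellite
# alleles, Cavalli-Sforza & Edwards chord distance, amino-acid p-distances
# at the MHC locus (including parent-referenced variants), and
# neighbor-joining trees from distance matrices.

parse_allele_pair <- function(x) {
  if (is.na(x) || x == "" || x == ".") return(NULL)
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(NA)
  a <- suppressWarnings(as.integer(parts))
  if (any(is.na(a))) {
    if (any(parts == ".")) return(NULL)  # partially missing -> locus missing
    return(NA)                           # malformed
  }
  a
}

genotype_loci <- function(tbl) {
  attr(tbl, "loci") %||%
    setdiff(names(tbl), c("id", "sex", "role", "cross", "mother_id",
                          "father_id", "hap1", "hap2"))
}

#' Write / read a cohort genotype table
#'
#' CSV schema: `id`, `sex`, `cross` (maternal letter first), `mother_id`,
#' `father_id`, then one `"a/b"` column per microsatellite locus (`"."` or
#' an empty field marks a missing locus). Haplotype columns, if present in
#' the cohort, are not written (sequences travel in FASTA).
#'
#' @param cohort Cohort tibble (as from [simulate_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(cohort, path) {
  loci <- genotype_loci(cohort)
  out <- cohort[, c("id", "sex", "cross", "mother_id", "father_id", loci)]
  readr::write_csv(out, path, progress = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_genotype_table
#'
#' @details `read_genotype_table()` validates every allele pair (errors name
#'   the offending row and locus), rejects duplicate ids, and flags parents
#'   referenced by id but absent from the table as external (attribute
#'   `"external_parents"`).
#' @return For the reader: a cohort tibble with attribute `loci`.
#' @export
read_genotype_table <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  need <- c("id", "sex", "cross", "mother_id", "father_id")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("genotype table must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tbl$id)) {
    abort(sprintf("duplicate id in genotype table: %s",
                  tbl$id[duplicated(tbl$id)][1]))
  }
  loci <- setdiff(names(tbl), need)
  for (l in loci) {
    for (r in seq_len(nrow(tbl))) {
      v <- parse_allele_pair(tbl[[l]][r])
      if (length(v) == 1 && is.na(v)) {
        abort(sprintf("malformed allele pair at row %d (id %s), locus %s: '%s'",
                      r, tbl$id[r], l, tbl[[l]][r]))
      }
    }
  }
  tbl$mother_id[tbl$mother_id %in% c("", ".", "NA")] <- NA_character_
  tbl$father_id[tbl$father_id %in% c("", ".", "NA")] <- NA_character_
  parents <- unique(stats::na.omit(c(tbl$mother_id, tbl$father_id)))
  attr(tbl, "external_parents") <- setdiff(parents, tbl$id)
  attr(tbl, "loci") <- loci
  tbl
}

#' Proportion-of-shared-alleles distance
#'
#' `Dps = 1 - (shared alleles) / (2 * typed loci)`, where sharing at a locus
#' is the size of the multiset intersection of the two allele pairs (0, 1 or
#' 2). Loci missing in either individual are excluded (pairwise deletion).
#'
#' @param g1,g2 Named character vectors of `"a/b"` allele pairs (`NA` or
#'   `"."` for missing loci).
#' @return Distance in \[0, 1\], or `NA` when no locus is typed in both.
#' @export
proportion_shared_alleles_distance <- function(g1, g2) {
  shared <- 0L
  typed <- 0L
  for (l in seq_along(g1)) {
    a <- parse_allele_pair(g1[l]); b <- parse_allele_pair(g2[l])
    if (is.null(a) || is.null(b) || anyNA(a) || anyNA(b)) next
    typed <- typed + 1L
    for (x in a) {
      j <- match(x, b)
      if (!is.na(j)) {
        shared <- shared + 1L
        b <- b[-j]
      }
    }
  }
  if (typed == 0L) return(NA_real_)
  1 - shared / (2 * typed)
}

#' Cavalli-Sforza & Edwards chord distance between individuals
#'
#' Each individual's genotype at a locus is read as an allele-frequency
#' vector (homozygote: 1; heterozygote: 0.5/0.5). With
#' `cos(theta) = sum_a sqrt(p_a * q_a)`, the per-locus chord is
#' `(2/pi) * sqrt(2 * (1 - cos(theta)))`; the distance is the mean chord
#' over loci typed in both individuals.
#'
#' @inheritParams proportion_shared_alleles_distance
#' @return Nonnegative distance, or `NA` when no locus is typed in both.
#' @export
cavalli_sforza_distance <- function(g1, g2) {
  d <- double(0)
  for (l in seq_along(g1)) {
    a <- parse_allele_pair(g1[l]); b <- parse_allele_pair(g2[l])
    if (is.null(a) || is.null(b) || anyNA(a) || anyNA(b)) next
    alleles <- union(a, b)
    p <- tabulate(match(a, alleles), length(alleles)) / 2
    q <- tabulate(match(b, alleles), length(alleles)) / 2
    cos_t <- min(sum(sqrt(p * q)), 1)
    d <- c(d, (2 / pi) * sqrt(2 * (1 - cos_t)))
  }
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

#' Translate an in-frame nucleotide sequence
#'
#' Standard nuclear code; stop codons are reported with a warning and
#' rendered as `"*"` (excluded from p-distance comparisons), ambiguous
#' codons as `"X"`.
#'
#' @param nt Nucleotide sequence (string), length divisible by 3 after the
#'   frame offset.
#' @param frame Frame offset (0, 1 or 2).
#' @return Character vector of amino acids.
#' @export
translate_sequence <- function(nt, frame = 0) {
  if ((nchar(nt) - frame) %% 3 != 0) {
    abort("sequence length (after frame offset) must be divisible by 3")
  }
  aa <- seqinr::translate(seqinr::s2c(tolower(nt)), frame = frame,
                          ambiguous = FALSE)
  if (any(aa == "*")) warn("stop codon(s) in translated sequence")
  aa
}

#' Amino-acid p-distance between aligned sequences
#'
#' Proportion of differing amino-acid sites among comparable sites. Sites
#' with `X`, a gap or a stop in either sequence are excluded (pairwise
#' deletion).
#'
#' @param a,b Aligned amino-acid sequences (strings or character vectors of
#'   equal length).
#' @return p-distance in \[0, 1\], or `NA` if no site is comparable.
#' @export
aa_p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) abort("sequences must be aligned (equal length)")
  excluded <- c("X", "x", "-", "*")
  ok <- !(a %in% excluded) & !(b %in% excluded) & !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  mean(toupper(a[ok]) != toupper(b[ok]))
}

# p-distance between two individuals given pre-translated haplotypes
ind_pdist_aa <- function(aa_a, aa_b) {
  mean(c(aa_p_distance(aa_a[[1]], aa_b[[1]]),
         aa_p_distance(aa_a[[1]], aa_b[[2]]),
         aa_p_distance(aa_a[[2]], aa_b[[1]]),
         aa_p_distance(aa_a[[2]], aa_b[[2]])))
}

#' Individual-to-individual MHC p-distance
#'
#' Mean amino-acid p-distance over the four inter-individual haplotype
#' pairings (a1-b1, a1-b2, a2-b1, a2-b2) of the translated sequences.
#'
#' @param a,b Character vectors of two nucleotide haplotypes each.
#' @param frame Reading-frame offset passed to [translate_sequence()].
#' @return p-distance in \[0, 1\].
#' @export
individual_pdist <- function(a, b, frame = 0) {
  if (length(a) != 2 || length(b) != 2) abort("each individual needs 2 haplotypes")
  ind_pdist_aa(lapply(a, translate_sequence, frame = frame),
               lapply(b, translate_sequence, frame = frame))
}

#' Within-individual MHC diversity
#'
#' Amino-acid p-distance between an individual's own two translated
#' haplotypes.
#'
#' @param pair Character vector of the individual's two nucleotide
#'   haplotypes.
#' @inheritParams individual_pdist
#' @return p-distance in \[0, 1\] (0 for a homozygote).
#' @export
mhc_diversity <- function(pair, frame = 0) {
  if (length(pair) != 2) abort("`pair` must hold 2 haplotypes")
  aa_p_distance(translate_sequence(pair[1], frame),
                translate_sequence(pair[2], frame))
}

# population-background match category between two cross codes
match_category <- function(focal_cross, satellite_cross) {
  if (is.na(focal_cross) || is.na(satellite_cross)) return(NA_character_)
  if (focal_cross == satellite_cross) return("exact")
  if (substr(focal_cross, 2, 2) == substr(satellite_cross, 2, 2)) return("paternal")
  if (substr(focal_cross, 1, 1) == substr(satellite_cross, 1, 1)) return("maternal")
  "none"
}

#' Dyadic genetic covariates for one focal animal
#'
#' For each focal-satellite pair: MHC amino-acid p-distances of the
#' satellite to the focal animal (`mhc`), to its mother (`mhc_mat`) and to
#' its father (`mhc_pat`); the satellite's own MHC diversity; chord
#' distances `cas`, `cas_mat`, `cas_pat` and the shared-allele distance
#' `dps`; the population-background match category (exact, paternal,
#' maternal, none); and pure/mixed flags. Covariates that need a missing
#' parent record are `NA`, never zero.
#'
#' @param cohort Cohort tibble with genotype columns and haplotypes `hap1`,
#'   `hap2`.
#' @param focal_id Id of the focal animal.
#' @param satellite_ids Ids of the four satellite animals.
#' @return Tibble with one row per (focal, satellite) pair.
#' @export
dyadic_covariates <- function(cohort, focal_id, satellite_ids) {
  loci <- genotype_loci(cohort)
  row_of <- function(id) {
    i <- match(id, cohort$id)
    if (is.na(i)) NULL else cohort[i, ]
  }
  focal <- row_of(focal_id)
  if (is.null(focal)) abort(sprintf("focal id %s not in cohort", focal_id))
  mother <- if (!is.na(focal$mother_id)) row_of(focal$mother_id) else NULL
  father <- if (!is.na(focal$father_id)) row_of(focal$father_id) else NULL

  # translate each distinct haplotype once
  haps <- unique(stats::na.omit(c(
    t(as.matrix(cohort[cohort$id %in% c(focal_id, focal$mother_id,
                                        focal$father_id, satellite_ids),
                       c("hap1", "hap2")]))
  )))
  aa_cache <- lapply(setNames(haps, haps), translate_sequence)
  aa_of <- function(r) list(aa_cache[[r$hap1]], aa_cache[[r$hap2]])
  geno_of <- function(r) unlist(r[1, loci])

  g_f <- geno_of(focal)
  aa_f <- aa_of(focal)
  aa_m <- if (is.null(mother)) NULL else aa_of(mother)
  aa_p <- if (is.null(father)) NULL else aa_of(father)
  g_m <- if (is.null(mother)) NULL else geno_of(mother)
  g_p <- if (is.null(father)) NULL else geno_of(father)

  ns <- length(satellite_ids)
  col <- function() rep(NA_real_, ns)
  mhc <- col(); mhc_mat <- col(); mhc_pat <- col(); div <- col()
  cas <- col(); cas_mat <- col(); cas_pat <- col(); dps <- col()
  mc <- character(ns); sp <- logical(ns)
  for (j in seq_len(ns)) {
    s <- row_of(satellite_ids[j])
    if (is.null(s)) abort(sprintf("satellite id %s not in cohort", satellite_ids[j]))
    g_s <- geno_of(s)
    aa_s <- aa_of(s)
    mhc[j] <- ind_pdist_aa(aa_f, aa_s)
    if (!is.null(aa_m)) mhc_mat[j] <- ind_pdist_aa(aa_m, aa_s)
    if (!is.null(aa_p)) mhc_pat[j] <- ind_pdist_aa(aa_p, aa_s)
    div[j] <- aa_p_distance(aa_s[[1]], aa_s[[2]])
    cas[j] <- cavalli_sforza_distance(g_f, g_s)
    if (!is.null(g_m)) cas_mat[j] <- cavalli_sforza_distance(g_m, g_s)
    if (!is.null(g_p)) cas_pat[j] <- cavalli_sforza_distance(g_p, g_s)
    dps[j] <- proportion_shared_alleles_distance(g_f, g_s)
    mc[j] <- match_category(focal$cross, s$cross)
    sp[j] <- s$cross %in% c("FF", "GG")
  }
  tibble(
    focal_id = focal_id, satellite_id = satellite_ids,
    mhc = mhc, mhc_mat = mhc_mat, mhc_pat = mhc_pat, mhc_diversity = div,
    cas = cas, cas_mat = cas_mat, cas_pat = cas_pat, dps = dps,
    match_category = mc,
    focal_pure = focal$cross %in% c("FF", "GG"),
    satellite_pure = sp
  )
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration; negative branch lengths are
#' clamped to 0 (count reported in attribute `"n_clamped"`). Two-taxon
#' input yields the single edge split at its midpoint.
#'
#' @param d Symmetric distance matrix with zero diagonal and row names.
#' @return An `ape::phylo` tree with attribute `n_clamped`; serialize with
#'   [tree_newick()].
#' @export
neighbor_joining_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-9 || any(diag(d) != 0)) {
    abort("`d` must be a symmetric matrix with zero diagonal")
  }
  labs <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  if (nrow(d) < 2) abort("need at least 2 taxa")
  if (nrow(d) == 2) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "n_clamped") <- 0L
    return(tr)
  }
  rownames(d) <- colnames(d) <- labs
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "n_clamped") <- sum(neg)
  tr
}

#' Serialize a tree to Newick text
#'
#' @param tree An `ape::phylo` object.
#' @return Single Newick string.
#' @export
tree_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Write / read phased haplotype FASTA
#'
#' Headers are `>{id}|hap1` and `>{id}|hap2`.
#'
#' @param cohort Cohort tibble with `id`, `hap1`, `hap2`.
#' @param path FASTA path.
#' @return `path` invisibly; the reader returns a tibble (`id`, `hap1`,
#'   `hap2`).
#' @export
write_haplotype_fasta <- function(cohort, path) {
  seqs <- c(rbind(cohort$hap1, cohort$hap2))
  names(seqs) <- c(rbind(paste0(cohort$id, "|hap1"), paste0(cohort$id, "|hap2")))
  seqinr::write.fasta(as.list(seqs), names(seqs), file.out = path, nbchar = 80)
  invisible(path)
}

#' @rdname write_haplotype_fasta
#' @export
read_haplotype_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = TRUE)
  nm <- names(fa)
  parts <- strsplit(nm, "|", fixed = TRUE)
  ids <- unname(vapply(parts, `[[`, character(1), 1))
  hap <- unname(vapply(parts, `[[`, character(1), 2))
  seqs <- unname(vapply(fa, function(x) as.character(x)[1], character(1)))
  tibble(id = ids, hap = hap, seq = seqs) |>
    tidyr::pivot_wider(names_from = "hap", values_from = "seq")
}
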