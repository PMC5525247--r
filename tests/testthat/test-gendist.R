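# Microsatellite and MHC distance computations, dyadic covariates, NJ trees.

toy_genotype <- function(alleles) {
  setNames(vapply(alleles, function(a) paste(sort(a), collapse = "/"),
                  character(1)),
           sprintf("L%02d", seq_along(alleles)))
}

test_that("genotype tables round-trip and malformed input fails with context", {
  co <- small_cohort(seed = 4)
  path <- tempfile(fileext = ".csv")
  write_genotype_table(co, path)
  back <- read_genotype_table(path)
  loci <- attr(co, "loci")
  expect_equal(as.data.frame(back[, c("id", "sex", "cross", loci)]),
               as.data.frame(co[, c("id", "sex", "cross", loci)]),
               ignore_attr = TRUE)
  expect_length(attr(back, "external_parents"), 0)

  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,sex,cross,mother_id,father_id,L01",
               "m1,F,FF,.,.,212/216",
               "m2,M,GG,.,.,212/x"), tmp)
  expect_error(read_genotype_table(tmp), "row 2.*L01")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("id,sex,cross,mother_id,father_id,L01",
               "m1,F,FF,.,.,212/216",
               "m1,M,GG,.,.,212/212"), dup)
  expect_error(read_genotype_table(dup), "duplicate id")
})

test_that("partially missing allele pairs mark the locus missing", {
  g1 <- c(L01 = "212/.", L02 = "100/102")
  g2 <- c(L01 = "212/212", L02 = "100/102")
  expect_equal(proportion_shared_alleles_distance(g1, g2), 0)  # only L02 typed
  g3 <- c(L01 = NA, L02 = ".")
  expect_true(is.na(proportion_shared_alleles_distance(g1, g3)))
})

test_that("shared-allele distance: identical 0, disjoint 1, half-sharing 0.5", {
  ident <- toy_genotype(replicate(13, c(100, 102), simplify = FALSE))
  expect_equal(proportion_shared_alleles_distance(ident, ident), 0)

  a <- toy_genotype(replicate(13, c(100, 102), simplify = FALSE))
  b <- toy_genotype(replicate(13, c(104, 106), simplify = FALSE))
  expect_equal(proportion_shared_alleles_distance(a, b), 1)

  # heterozygotes sharing exactly one allele at each of 13 loci
  c1 <- toy_genotype(replicate(13, c(100, 102), simplify = FALSE))
  c2 <- toy_genotype(replicate(13, c(102, 104), simplify = FALSE))
  expect_equal(proportion_shared_alleles_distance(c1, c2), 0.5)
})

test_that("chord distance: zero on identity, (2/pi)*sqrt(2) on disjoint loci, symmetric", {
  ident <- toy_genotype(replicate(5, c(100, 102), simplify = FALSE))
  expect_equal(cavalli_sforza_distance(ident, ident), 0)

  a <- toy_genotype(list(c(100, 100)))
  b <- toy_genotype(list(c(104, 106)))
  expect_equal(cavalli_sforza_distance(a, b), (2 / pi) * sqrt(2), tolerance = 1e-12)

  # homozygote vs heterozygote sharing that allele: cos = sqrt(0.5)
  h1 <- toy_genotype(list(c(100, 100)))
  h2 <- toy_genotype(list(c(100, 102)))
  expect_equal(cavalli_sforza_distance(h1, h2),
               (2 / pi) * sqrt(2 * (1 - sqrt(0.5))), tolerance = 1e-12)

  co <- small_cohort(seed = 8)
  loci <- attr(co, "loci")
  set.seed(3)
  for (i in 1:20) {
    pair <- sample(nrow(co), 2)
    g1 <- unlist(co[pair[1], loci]); g2 <- unlist(co[pair[2], loci])
    expect_equal(cavalli_sforza_distance(g1, g2),
                 cavalli_sforza_distance(g2, g1))
    expect_gte(cavalli_sforza_distance(g1, g2), 0)
  }
})

test_that("populations separate weakly at microsatellites under divergence > 0", {
  pm <- population_model(divergence = 0.4, seed = 6)
  co <- simulate_cohort(pm, pedigree_spec(), seed = 6)
  loci <- attr(co, "loci")
  founders <- co[co$role == "founder", ]
  ff <- founders[founders$cross == "FF", ]
  gg <- founders[founders$cross == "GG", ]
  gmat <- function(tbl) lapply(seq_len(nrow(tbl)), function(i) unlist(tbl[i, loci]))
  gf <- gmat(ff); gg2 <- gmat(gg)
  between <- outer(seq_along(gf), seq_along(gg2), Vectorize(function(i, j)
    cavalli_sforza_distance(gf[[i]], gg2[[j]])))
  within_f <- utils::combn(seq_along(gf), 2, function(ij)
    cavalli_sforza_distance(gf[[ij[1]]], gf[[ij[2]]]))
  within_g <- utils::combn(seq_along(gg2), 2, function(ij)
    cavalli_sforza_distance(gg2[[ij[1]]], gg2[[ij[2]]]))
  expect_gt(mean(between), mean(c(within_f, within_g)))
})

test_that("amino-acid p-distance uses pairwise deletion", {
  expect_equal(aa_p_distance("MKTA", "MKTA"), 0)
  expect_equal(aa_p_distance(strrep("A", 20),
                             paste0(strrep("A", 18), "RR")), 0.1)
  expect_equal(aa_p_distance("AAAA", "RRRR"), 1)
  # X and gaps excluded from the comparison: only sites 1 and 3 count
  expect_equal(aa_p_distance("AXA-", "AARR"), 0.5)
  expect_true(is.na(aa_p_distance("XX", "AA")))
})

test_that("individual-level p-distance averages the four haplotype pairings", {
  h1 <- "atggctgctgct"   # M A A A
  h2 <- "atgcgtgctgct"   # M R A A
  h3 <- "atgcgtcgtgct"   # M R R A
  expect_equal(individual_pdist(c(h1, h1), c(h1, h1)), 0)
  expect_equal(individual_pdist(c(h1, h1), c(h2, h2)), aa_p_distance("MAAA", "MRAA"))
  # mixed case against a brute-force average
  brute <- mean(c(aa_p_distance("MAAA", "MRAA"), aa_p_distance("MAAA", "MRRA"),
                  aa_p_distance("MRAA", "MRAA"), aa_p_distance("MRAA", "MRRA")))
  expect_equal(individual_pdist(c(h1, h2), c(h2, h3)), brute)
})

test_that("MHC diversity is the within-individual haplotype p-distance", {
  h <- strrep("gct", 90)
  expect_equal(mhc_diversity(c(h, h)), 0)
  # 9 of 90 codons changed to a different amino acid
  h2 <- paste0(strrep("cgt", 9), strrep("gct", 81))
  expect_equal(mhc_diversity(c(h, h2)), 0.1)
  expect_equal(mhc_diversity(c(h, h2)),
               individual_pdist(c(h, h2), c(h, h2)) * 2)  # off-diagonal mean = 2x
})

test_that("population-background match categories follow the cross codes", {
  co <- small_cohort(seed = 2)
  off <- co[co$role == "offspring", ]
  pick <- function(cross, sex) off$id[off$cross == cross & off$sex == sex][1]
  focal <- pick("GF", "F")
  sats <- c(pick("GF", "M"), pick("FG", "M"), pick("GG", "M"), pick("FF", "M"))
  cov <- dyadic_covariates(co, focal, sats)
  expect_equal(cov$match_category, c("exact", "none", "maternal", "paternal"))
  expect_false(cov$focal_pure[1])

  focal2 <- pick("FG", "F")
  cov2 <- dyadic_covariates(co, focal2, c(pick("GG", "M")))
  expect_equal(cov2$match_category, "paternal")
})

test_that("missing parent records yield NA covariates, never zero", {
  co <- small_cohort(seed = 2)
  founder <- co$id[co$role == "founder"][1]
  sats <- co$id[co$role == "offspring"][1:4]
  cov <- dyadic_covariates(co, founder, sats)
  expect_true(all(is.na(cov$mhc_mat)))
  expect_true(all(is.na(cov$cas_pat)))
  expect_false(anyNA(cov$mhc))
})

test_that("neighbor joining: two- and three-taxon closed forms", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- neighbor_joining_tree(d2)
  expect_equal(sort(tr2$edge.length), c(0.2, 0.2))

  # three taxa: pendant lengths from the three-point formulas
  dab <- 0.3; dac <- 0.5; dbc <- 0.6
  d3 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  d3["A", "B"] <- d3["B", "A"] <- dab
  d3["A", "C"] <- d3["C", "A"] <- dac
  d3["B", "C"] <- d3["C", "B"] <- dbc
  tr3 <- neighbor_joining_tree(d3)
  lens <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(lens[["A"]], (dab + dac - dbc) / 2, tolerance = 1e-12)
  expect_equal(lens[["B"]], (dab + dbc - dac) / 2, tolerance = 1e-12)
  expect_equal(lens[["C"]], (dac + dbc - dab) / 2, tolerance = 1e-12)

  expect_error(neighbor_joining_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("neighbor joining recovers an additive four-taxon tree exactly", {
  # tree ((A:1,B:2),(C:3,D:4)) with internal edge 1
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- neighbor_joining_tree(d)
  expect_equal(attr(tr, "n_clamped"), 0L)
  path <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(path, d, tolerance = 1e-12)
  expect_match(tree_newick(tr), "^\\(.*\\);$")
})

test_that("haplotype FASTA round-trips with id|hap headers", {
  co <- small_cohort(seed = 3)
  path <- tempfile(fileext = ".fasta")
  write_haplotype_fasta(co, path)
  back <- read_haplotype_fasta(path)
  expect_equal(back$id, co$id)
  expect_equal(back$hap1, co$hap1)
  expect_equal(back$hap2, co$hap2)
})
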