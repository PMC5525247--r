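---
title: "Methods: occupancy, selectivity and dyadic correlates in four-choice preference arenas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy, selectivity and dyadic correlates in four-choice preference arenas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arenapref)
```

## The experimental design this package analyses

A single tagged focal animal lives for several days in a star-shaped arena:
one central cage connected by four tubes to four satellite cages, each
holding a stimulus animal behind a grid. Every tube carries two RFID ring
antennae (one at the central end, one at the satellite end), and every pass
of the focal animal is logged as a timestamped antenna read. The standard
schedule runs from Thursday 16:00 to the following Wednesday 08:00 — 136
hours — under a 12:12 light cycle (lights on 07:00, off 19:00).

From the raw read log the package reconstructs where the animal was at every
instant, how its preference for particular neighbours developed, and whether
dyadic genetic covariates — microsatellite distances and MHC amino-acid
distances, including distances referenced to the focal animal's mother and
father — predict where it spent its time.

## Occupancy reconstruction

**Nearest-side rule.** After a read at the satellite-side antenna of tube
*k* the animal's location is satellite cage *k*; after any central-side read
it is the central cage. The location changes at the read's timestamp, the
animal starts central (where it is placed at the beginning of a run), and
the last interval extends to the end of the run window.

This rule was chosen over explicit pairing of the two reads of each tube
crossing because it needs no lookahead and degrades gracefully: a missed
read causes a bounded, local attribution error that the next read at the
true location repairs, whereas a pairing automaton can desynchronise. The
consequences are:

* tube transit time is attributed to the origin cage (error at most one
  transit time per crossing, with opposite signs on entry and exit);
* lingering re-reads at the current cage's antenna are harmless — they
  re-assert the current location;
* a missed satellite-side read is repaired by the first lingering re-read
  in that satellite cage.

The reconstruction asserts on every output that the intervals tile the run
window with no gaps or overlaps. Physically impossible sequences (a
satellite-side read at tube *j* while the animal is located in satellite
*k* with no intervening central-side read) are counted and reported, not
silently patched. Reads outside the run window are rejected with a count.
Recordings whose read span covers less than 90% of the nominal window
(e.g. after a power failure) are flagged for review rather than dropped.

## The selectivity index

With percentage dwell shares $p_1,\dots,p_4$ of the four satellite cages,

$$\mathrm{SI} = \frac{\mathrm{SD}(p_1,\dots,p_4)}{\mathrm{SD}_{max}}, \qquad
\mathrm{SD}_{max} = 50,$$

where SD is the *sample* (n−1 denominator) standard deviation. The sample
convention is forced by the normalizer: the sample SD of $(100,0,0,0)$ is
exactly 50, so SI is 1 exactly when all social time is in one cage and 0
exactly at uniform use. The population SD of the one-hot vector is 43.3 and
would leave SI's maximum below 1.

The temporal series evaluates SI on *expanding* windows anchored at the run
start — the first window is 10 minutes, the second 20, and so forth — not
on sliding windows. SI is undefined until the animal first enters a
satellite cage, and undefined values are propagated as missing rather than
as 0: very early "selectivity" reflects lack of time to explore, not
choice, and coercing it to a number would distort group averages. Group
mean curves exclude missing values pointwise and carry a symmetric t-based
95% confidence band (whether such bands should instead be bootstrapped is
undecidable from the printed record; the t band is the documented choice,
and the per-point n is reported so a user can bootstrap from the per-animal
series if preferred).

## Preference blocks and chance-match tests

The preferred cage at each 10-minute grid point is the argmax of the
cumulative satellite dwell. Ties retain the previous point's preference
when it is among the tied maxima and otherwise take the lowest cage index;
ties have measure zero on real continuous data, so the rule only serves
determinism. A *preference block* is a maximal run of grid points with
constant preference; the block count, the percentage of defined points in
the final block, and the time at which the final block begins summarise
stability.

Whether the preference at a checkpoint (10 min, 90 min, 24 h) matches the
final preference is tested against the chance expectation $n/4$ with a
1-df goodness-of-fit chi-square on (matched, unmatched). The Yates
continuity correction is applied by default — with observed 12 of 47 and
expected 11.75 it yields the statistic 0.0000 and p = 1, which the
uncorrected statistic (0.0071) does not — and both variants are exposed.
An undefined preference at a checkpoint counts conservatively as a
non-match and is flagged separately.

## Genetic distances

* **Dps** (proportion of shared alleles): per locus, the multiset
  intersection of the two allele pairs (0, 1 or 2 shared); distance
  $1 - \sum \text{shared} / (2 L_{typed})$.
* **Chord distance (CAS)**: each individual's genotype is read as an
  allele-frequency vector (homozygote 1, heterozygote 0.5/0.5); with
  $\cos\theta_\ell = \sum_a \sqrt{p_a q_a}$ the per-locus chord is
  $(2/\pi)\sqrt{2(1-\cos\theta_\ell)}$, averaged over typed loci. The exact
  normalization used by legacy microsatellite-analysis programs is
  undocumented, so the formula is pinned here and covered by unit tests
  rather than by matching any particular tool.
* **MHC amino-acid p-distance**: proportion of differing amino acids among
  comparable sites of translated exon sequences. Individual-to-individual
  distance averages the four inter-individual haplotype pairings
  (a1b1, a1b2, a2b1, a2b2); the within-individual version of the same
  quantity is the animal's MHC diversity. Parent-referenced variants
  (MHCmat, MHCpat, CASmat, CASpat) replace the focal animal with its mother
  or father.

Missing data are handled by pairwise deletion everywhere — loci untyped in
either member of a pair, and amino-acid sites with X, a gap or a stop in
either sequence, are dropped for that pair only; nothing is imputed, and
covariates that would need a missing parent record are reported missing,
never zero. Translation uses the standard nuclear code with a configurable
frame offset; stop codons trigger a warning and are excluded from
comparisons.

Neighbor-joining trees (for cohort-level visualisation of either distance)
are delegated to `ape::nj`, with negative branch lengths clamped to zero
and counted; trees serialize to Newick.

## The grouped correlation procedure

Each focal animal contributes four dyad records (one per satellite). Within
a grouping — all animals; pure (FF, GG) versus mixed (FG, GF) background;
or sex × paternal background (xF/xG = paternal letter) — the Spearman rank
correlation between the square-root-transformed dwell duration and MHCpat
is reported together with the t-approximation
$t = r\sqrt{(n-2)/(1-r^2)}$ and its two-sided p from the central t
distribution. This t-approximation reproduces, at printed precision, every
(r, t, df, p) row of the reference analysis this procedure follows, which
is why it is adopted over an exact permutation null.

The square-root transform is retained for output fidelity even though
Spearman r, being rank-based, is unchanged by any strictly monotone
transform (a property the test suite asserts). Groups with fewer than five
usable records (configurable) yield an explicit undefined row rather than a
fragile estimate, and exclusion counts for missing covariates are reported
per group rather than guessed around.

## The synthetic experiment generator

No generative model of mouse movement is given in the printed record; the
generator is therefore a documented stand-in whose purpose is to make every
downstream stage testable against known ground truth, not to model mouse
cognition.

**Movement** is a continuous-time alternating renewal process — not a
discrete-time chain — because event-driven RFID data are continuous-time
and because dwell shares stay analytically controllable: the animal leaves
the central cage with exponential hazard modulated by a piecewise-constant
diurnal multiplier, chooses satellite *k* with probability proportional to
$w_k e^{\beta z_k}$ (with $z_k$ a standardized dyadic covariate such as
MHCpat), and stays an exponential time with mean proportional to $w_k$.
The covariate effect $\beta$ acts on the choice probability only; the dwell
mean scales with the base weight.

Defaults were fixed once to the study conditions the generator emulates:

| parameter | default | rationale |
|---|---|---|
| run length | 136 h | Thursday 16:00 → Wednesday 08:00 |
| leave-central hazard | 6 /h | 10-min mean central stay |
| satellite dwell mean | 0.36 h | gives ≈68% social time, matching the reported average |
| diurnal multipliers | night 1.4, day 0.8, siesta 0.25 | lights 07/19 h; early-afternoon trough (12:00–15:00); ≈1.0 average |
| transit time | 1 s | tube crossing between paired reads |
| detection probability | 0.95 | per antenna pass |
| lingering re-reads | 1.3 /min | brings the total to ≈86 reads/h, the reported average |
| per-focal weights | lognormal, sdlog 1 | heterogeneous but not exclusive preferences |

A piecewise-constant three-level diurnal multiplier was preferred to a
smooth sinusoid because its integrated hazard is exactly invertible, which
keeps the sampler verifiable. Interior transition times are aligned to the
millisecond resolution of emitted timestamps so that, at perfect detection
and zero transit, reconstructed dwell totals equal ground truth exactly
rather than approximately.

**Genetics.** Two source populations draw microsatellite frequencies from
a symmetric Dirichlet mixed toward a common base with a divergence weight
(default 0.3), keeping FF and GG separable but weakly so; the MHC pool is
shared between populations (divergence weight 0.1) with haplotypes derived
from a common founder sequence by per-codon mutation (rate 0.11, giving
mean dyadic amino-acid p-distances near 0.155, the reported scale).
Offspring are Mendelian draws from simulated parents. Each animal's
random draws use an RNG stream derived from the master seed and its id by
stable hashing, so editing one animal never perturbs another's genotype or
trajectory.

**What the generator does not emulate:** oestrus cycling, t-haplotype
effects, habituation (declining activity over days), satellite-animal
behaviour (satellites are static stimuli, as in the physical setup), and
any spatial structure beyond the star topology. Passing tests therefore
demonstrate correctness of the *analysis* under a plausible event-stream
model, not fidelity of any biological conclusion drawn from real data.

## Numerical choices and degenerate inputs

* Undefined SI / preference (no social time yet) propagates as `NA`.
* Zero total satellite time makes proportional durations undefined, not an
  error; an all-central run is a valid (if dull) experiment.
* Percentage vectors are validated to sum to 100 within 1e-6.
* `|r| = 1` yields an infinite-t marker rather than an error; zero rank
  variance yields `NA`.
* Duplicate reads (same timestamp and antenna) collapse with a counter;
  unknown antenna ids are dropped with a counter; an unparseable timestamp
  is an error naming the line.
* Negative NJ branch lengths are clamped to zero with a count.

## Problem sizes used in the test suite

The simulation-based checks run at deliberately moderate sizes chosen to
make sampling noise negligible relative to the asserted margins: 50
replicate single-animal experiments per acquisition regime for the
reconstruction-oracle check; 100 replicate 12-focal cohorts for the
effect-recovery check and 1000 for the null-calibration check of the
grouped Spearman procedure; 10,000 simulated cohorts for the size of the
chance-match test; 100 random additive matrices for neighbor joining.

## Known limitations

* The occupancy rule is a documented choice, not a reconstruction of the
  undocumented rule used by the original acquisition scripts; with real
  logs the two can differ by up to one transit time per crossing.
* Cohort-level headline statistics (mean SI curves, block counts, social
  time) depend on real behaviour; the synthetic defaults reproduce their
  order of magnitude, not their values.
* The grouped Spearman procedure treats the four dyads of one focal animal
  as independent records, as the reference analysis does; the dyadic
  clustering (shared father in MHCpat, a shared time budget in durations)
  is inherited by design. The null-calibration test shows the pooled test
  holds its nominal size under the generator's conditions, but this is a
  property of those conditions, not a general guarantee.
* Timestamps are timezone-naive local clock times; daylight-saving shifts
  are out of contract.
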