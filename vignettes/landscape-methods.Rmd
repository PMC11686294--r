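---
title: "Methods: scoring, topography and adaptive walks on sort-seq landscapes"
author: "SortScape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, topography and adaptive walks on sort-seq landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SortScape)
```

This vignette documents the models, parameter choices and numerical
conventions behind SortScape, in the spirit of a methods section: what each
stage assumes, which knobs matter, and where genuinely open design choices
were settled.

## From bin counts to repression scores

Sort-seq assigns each binding-site variant a read-count vector over
fluorescence bins. Because mis-sorting and expression noise spread a
clonal population over several gates, the expression of a variant is
estimated as the read-weighted mean bin index
$e = \sum_i x_i w_i / \sum_i x_i$ with integer weights $w_i = 1,\dots,13$,
then reversed, $r = e_{max} + 1 - e$, so that strong repression scores
high, and finally divided by the wild-type repression so the reference
operator sits at exactly 1.

Three replicate filters precede scoring, applied in order: presence in
every replicate, a minimum read count, and a cap of 0.5 on the coefficient
of variation of $r$ across replicates. Two readings of the read threshold
are defensible — a minimum per *bin* or a minimum *total* per replicate.
A per-bin minimum of 30 reads would discard essentially every variant at
realistic depth (13 bins would require 390 well-placed reads per variant
per replicate, and most variants concentrate in a few gates), so the
default applies the threshold to the per-replicate total; `perBin = TRUE`
selects the stricter reading. The CV is computed on raw $r$ (normalising
every replicate by one shared constant leaves a CV unchanged), whereas the
per-genotype noise value $\tau$ — used later by the noise-aware landscape —
is the replicate standard deviation on the *normalised* scale, since the
noise conditions compare normalised scores.

## The synthetic experiment

The generator exists so that every downstream stage can be validated
against a known truth. It emulates, per replicate:

* a monotone decreasing repression-to-fluorescence map, log-linear with
  saturation: $F(S) = \max(F_{floor},\ F_{max}\, 2^{-kS})$. Defaults
  $F_{max} = 10^5$ a.u., $F_{floor} = 100$ a.u. (the autofluorescence
  median of a promoterless control) and $k = 8$ spread the score range
  $[0, 1.25]$ over the full dynamic range of the gates;
* log-normal single-cell noise (`cellNoiseSd`, default 0.8 on the log2
  scale) and a per genotype-by-replicate log-normal factor
  (`replicateNoiseSd`) emulating between-replicate dispersion — day
  effects, copy-number variation, sorting drift. The default 0.9 was
  calibrated once so that between-replicate score correlations land in the
  0.84–0.92 band typical of replicated sort-seq screens, while still
  letting the scoring pipeline recover true ranks with Spearman ≳ 0.95;
* gates mirroring the described protocol structurally: the lowest gate is
  bounded above by the autofluorescence median, the top gate starts at the
  95th percentile of the recorded population, and interior boundaries are
  log2-equidistant between the two. Explicit `gateBoundaries` override the
  derivation (used by the noiseless unit tests);
* multinomial read sampling from the gate-occupancy matrix, with exactly
  `readsTotal` reads per replicate (default 100 per genotype, so the
  30-read filter bites but does not dominate).

What the generator does *not* emulate: sequencing-read artefacts (PCR
bias, barcode errors), instrument physics beyond gates-plus-noise, and —
by default — post-sort dropout of genotypes (`dropoutRate` exposes it; the
default of 0 keeps parameter-recovery experiments interpretable). Passing
tests on synthetic data therefore demonstrate correctness of the
*computations*, not robustness to every artefact of real libraries.

Three ground-truth models span the ruggedness spectrum: **additive**
(independent per-position weights; with distinct best-allele margins the
landscape has exactly one local maximum and every shortest path to it is
accessible), **NK** (each site interacts with its $K$ circular neighbours;
$K = 0$ reduces to additive, $K = L-1$ behaves like House-of-Cards), and
**House-of-Cards** (i.i.d. scores; expected peak count $4^L/(3L+1)$ on the
complete 4-allele Hamming graph — the tests verify this by Monte Carlo).

## Landscape annotation

Edges connect observed genotypes at Hamming distance 1 over the variable
positions; the canonical orientation is uphill (low to high score)
everywhere. Noise-free ties are neutral edges under exact floating-point
equality by default (`epsilon` widens this; replicate-averaged bin means
*can* tie exactly, so the option matters in principle but rarely in
practice).

With a noise model, genotype A counts as distinguishably higher than
neighbour B only when $S_A > S_B + \tau_B$ **and**
$S_A - \tau_A > S_B + \tau_B$ (with $\tau \ge 0$ the second condition
implies the first; both are evaluated). Indistinguishable pairs become
neutral edges traversable in both directions. One subtlety is settled
here: the per-pair conditions decide only *distinguishability and
direction*; the orientation convention stays uphill, so every downstream
algorithm (basins, walks, accessibility) works identically with and
without noise.

Peaks are defined as local maxima: no distinguishably higher neighbour.
Connected peaks joined by neutral edges form plateaus, each member still
counting as a peak, with breadth = peaks per plateau. Under this rule,
raising the noise scale can only *remove* strictly-uphill edges, so the
local-maximum set grows monotonically and peaks merge into plateaus. A
second, stricter notion — distinguishably above *all* neighbours — shrinks
with noise; `findPeaks()` reports both (`peakCount`, `strictPeakCount`)
because "number of peaks" in noisy-landscape discussions can mean either.
Mean plateau breadth is *not* monotone in the noise scale: freshly created
local maxima enter as singleton plateaus and can lower the average even as
existing peaks merge; only in the large-noise limit does everything
collapse into one landscape-wide plateau, and the tests assert exactly
these directions.

## Topography

**Basins** are computed by reverse reachability over the directed uphill
edges (with a noise model, neutral edges count as permitted
non-decreasing steps; without one, accessibility demands a strict increase
at every step). Basin sizes exclude peak-labelled nodes, and one common
denominator — non-peak genotypes in the landscape — is used for all
fractions. Overlap between basins is the Jaccard index.

**Path census.** Accessibility "of all lengths" is answered by
reachability (that is what a basin is); explicit counting is restricted to
*minimum-length* paths, where totals are finite and meaningful. The census
uses dynamic programming over breadth-first-search layers rather than path
listing, so the $d!$ direct paths between genotypes at distance $d$ on a
complete landscape (40,320 at $d = 8$) are counted in milliseconds, and
the accessible subset is counted by the same recursion restricted to
score-increasing layer edges. Tests cross-check both counts against
explicit `igraph` path enumeration on small graphs.

**Epistasis squares.** Every quadruple {background, two single mutants,
double mutant} with all four members observed is enumerated by grouping
genotypes on their residues outside a position pair; candidates with
missing corners are skipped and counted. Each square is re-oriented so its
highest-scoring corner is the double mutant (ties broken by a fixed corner
order), after which the class is determined by how many single mutants
fall strictly below the background: both (reciprocal sign), exactly one
(simple sign), none (no sign — magnitude epistasis and additivity pooled,
since neither constrains accessibility). On an additive landscape this
yields no sign epistasis of either kind, and multi-peaked complete
landscapes always contain reciprocal-sign squares — both asserted in the
tests.

**One-hot PCA** embeds genotypes as $4L$ binary indicators and runs
`prcomp()`. In combinatorially complete spaces each component explains
little variance; the embedding is a coarse map, not a metric
reconstruction, and duplicated-genotype inputs (zero variance) are
rejected.

## Adaptive walks

Three engines share the strict-uphill adjacency. **Greedy** walks step to
the neighbour with the largest gain — a proxy for clonal interference —
and are deterministic; equal maximal gains are broken lexicographically by
default (a `tieBreak = "random"` flag exists) so that repeated runs are
bit-identical. **Uniform** (SSWM) walks choose uphill neighbours with
equal probability; their endpoint support provably equals basin
reachability, which the tests verify against an exact dynamic-programming
endpoint distribution. **Kimura** walks run a fixed number of proposal
steps (default 1000); each step proposes one neighbour of the current
genotype — uniformly, or weighted by a user-supplied 4×4 relative
mutation-rate matrix (no specific organism's bias values are built in) —
and fixes it with probability $f = (1-e^{-2s})/(1-e^{-2Ns})$. Neutral and
deleterious fixations are allowed, so walks can leave peaks; every visited
peak is recorded. Numerically, $f$ is evaluated piecewise: the exact
$1/N$ limit at $s = 0$, `expm1` forms for $s > 0$, and log-space for
$s < 0$ so strongly deleterious probabilities underflow cleanly to 0
(never NaN). For $s > 0$ the finite-$N$ value always exceeds the
$N \to \infty$ limit $1 - e^{-2s}$ and approaches it from above.

Walk batches (`runWalks`) support both start-set conventions — every
non-peak genotype, or a seeded random sample — and `noiseSweep()` reruns
Kimura walks with identical starts and seeds on landscapes rebuilt at each
noise scale, so topography and navigability trends are directly
comparable across scales.

## Reproducibility and problem sizes

Every stochastic function takes or derives a seed; `runPipeline()` derives
per-stage seeds from the global seed plus the stage label and stamps every
artifact with a hash of the full configuration, so artifacts from
different runs cannot be mixed silently. The test suite works at sizes
where exhaustive oracles are feasible — complete spaces up to $L = 5$
(1024 genotypes) for brute-force peak scans and path enumeration, $L = 8$
(65,536) for the census checks, 400–1000-genotype simulated libraries for
parameter recovery — and the acceptance script adds a study-density run at
27% coverage of the complete 8-position space. These sizes were chosen as
the smallest at which each property is non-trivially exercised.

## Known limitations

* The pipeline starts from count tables; read preprocessing (trimming,
  merging, demultiplexing) is upstream and out of scope.
* Polymorphic population genetics (clonal interference beyond the greedy
  proxy, recombination, standing variation) is not modelled.
* The shuffled null preserves the score distribution but not any
  mutational-distance correlation structure; it answers "how many peaks
  would an uncorrelated landscape of the same score distribution have",
  nothing subtler.
* Statistical hypothesis testing on the resulting distributions
  (rank-sum, KS and the like) is left to the user; the package exposes the
  raw distributions instead.
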