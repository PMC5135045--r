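---
title: "Modelling larval dispersal and genetic connectivity with larvaConn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling larval dispersal and genetic connectivity with larvaConn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaConn)
```

## The problem

Many coastal fishes are site-attached as adults: whatever demographic and
genetic exchange happens between their populations happens while their
larvae drift. Two very different instruments measure that exchange. A
biophysical model advects virtual larvae through ocean currents and counts
who could get where; population genetics measures who actually did, through
allele-frequency differentiation, assignment and parentage. larvaConn
implements both instruments end to end, together with synthetic-data
generators that provide gridded currents, coastal habitat and
microsatellite genotypes with known ground truth, so that every stage of
the pipeline can be verified without any external dataset.

## The dispersal model

Each virtual larva carries a position (longitude, latitude), an age in
days, a developmental stage (competent to settle or not) and a status
(alive, settled, dead, lost). Larvae are released from every habitat cell
every `releaseIntervalHours` (default 6 h) on each day of a spawning
season of `seasonLengthDays` (default 180, six 30-day months — with 11
years this gives 7,920 releases per cell), and drift for at most
`pldMax = 18` days, the species' maximum pelagic larval duration.
Settlement becomes possible at `competenceDay = 10`: from that age on, the
first recorded position inside any habitat cell terminates the trajectory
as a settlement (first-contact rule). A larva that never finds habitat is
dead at day 18; one that leaves the model domain is lost and takes no
further part in the statistics.

Positions are recorded hourly (`stepsPerDay = 24`). Between recordings the
path equation dx/dt = v(x, t) is integrated with the classical fourth-order
Runge--Kutta scheme; velocities come from bilinear interpolation over the
four surrounding grid nodes, with land nodes carrying zero weight and the
remaining weights renormalized, and linear interpolation in time between
daily snapshots (clamped at the ends of the series). Because flow speed
varies by orders of magnitude between an upwelling jet and the inner
shelf, each hourly macro-step is split adaptively into substeps such that
no substep displaces a particle by more than `cflFraction` (default 0.5)
of a grid cell; only the hourly endpoint is recorded. On a solid-body
rotation field the integrator closes an orbit to within $10^{-3}$ of the
radius and exhibits the expected fourth-order error decay (Richardson
ratio near 16 when the step is halved); both properties are asserted in
the test suite.

Three depth-use behaviours are supported: `surface` larvae stay in the 0 m
velocity layer for their whole pelagic phase, `deep` larvae in the 10 m
layer, and `migration` larvae use the surface until competence and the
deep layer from day 10.0 on (the boundary age belongs to the deep layer).

### Numerical choices at the coast and the domain edge

A land cell must be unreachable, but *how* it is unreachable matters.
Rejecting any substep that ends on land turns the coastline into a sticky
wall: a larva pressed onshore loses its alongshore motion too, sits in
its natal cell indefinitely and inflates retention. larvaConn therefore
uses a free-slip coastline: a substep that would beach keeps the
along-coast component of its displacement (each axis is tried in turn)
and only the shoreward component is cancelled. Particles whose endpoint
leaves the grid are flagged lost at the following recorded step; their
release still counts in the default denominators. Cells are half-open
boxes ([lon, lon+res) x [lat, lat+res)), so any point lies in exactly one
cell and settlement assignment is unambiguous.

### From trajectories to connectivity

The paired probability from cell i to cell j is a *residence* measure:
for each particle released in i, the number of recorded hourly steps
spent inside j, divided by the maximum possible number of steps
(18 x 24 = 432), averaged over the particles released from i. The release
position itself is not a step — with it, a stationary particle could
accumulate 433 counts and the probability could exceed one — and counting
stops at settlement, consistent with first-contact termination. A
stationary particle in an all-habitat cell therefore scores
240/432 on the diagonal (steps 1..240, settling at the first competent
step); the test suite pins this value by enumeration. For sensitivity
analyses `settledResidence = TRUE` additionally credits a settled particle
with its settlement cell for the remaining steps, and both denominator
conventions (`all_released`, the default, and `excluding_lost`) are
available because the treatment of offshore-advected particles is a
genuine analytical choice.

Per-cell retention (settling back into the natal cell) and effective
settlement (settling anywhere), dispersal distances along the shore
(least-cost paths through sea cells on an 8-connected graph with
great-circle edge lengths), Kruskal--Wallis comparisons of behaviours
followed by all-pairs Nemenyi tests (chi-square approximation, which
accommodates unequal group sizes), exponential distance-decay fits and
focal-region source/sink ratios complete the summaries. The decay
P = a e^{-bd} is fitted by least squares on log-transformed positive
off-diagonal entries; zeros are excluded because they carry no
information about the decay *rate* on the log scale (a weighted variant
is available).

## The synthetic ocean

The generator emulates the circulation of an eastern-boundary upwelling
shelf in two seasonal phases. During upwelling, an alongshore jet flows
in the initial direction, ramping up away from the frictional inner shelf
over `jetOffshoreKm` (default 15 km), while surface-trapped Ekman
transport (`offshoreSurface`, default 0.02 m/s) pushes the surface layer
offshore. After `seasonReversalDay` the flow relaxes into a weaker
(`counterFraction`) counter-current trapped within `coastalTrapKm` of the
coast, with weak onshore return flow. Mesoscale eddies are a sum of
random plane-wave streamfunction modes — divergence-free by construction —
whose patterns propagate at a few km/day (`eddyPropKmDay`), as real
eddies do; early versions with quasi-standing modes trapped particles in
stagnation cells, a numerically induced artifact rather than physics.
The 10 m layer receives the mean flow and an independent eddy realization
both scaled by `depthAttenuation`, and the Ekman component scaled by its
square, since wind-driven transport decays fastest with depth. Yearly
mean speeds are perturbed by `interannualJitter`. Defaults sit in the
0.05--0.2 m/s range typical of temperate shelf currents; no site-specific
measurements are assumed, and all of it is user-configurable.

What the generator does *not* contain: real bathymetry or coastline
geometry, three-dimensional velocities and vertical advection, tides,
wave- or storm-driven transport, and biological mortality. Tests passing
on these fields show that the pipeline's mechanics are correct and that
the qualitative behaviour contrasts emerge for the stated physical
reasons; they do not validate any quantitative prediction for a real
coastline.

### The packaged behaviour experiment

`runBehaviorExperiment()` is the package's scaled-down in silico study:
20 habitat cells in the middle of a 2-degree coast (sandy gaps on either
side), one 36-day release season spanning the seasonal reversal, releases
every 6 h (2,880 particles per behaviour), deep attenuation 0.5. At this
scale one CPU completes all three behaviours in well under a minute,
and the acceptance tests check the orderings the biology predicts: deep
larvae are retained more (Nemenyi p below 0.001 against surface and
migration at the packaged seed), settle more, stay closer to home, and
their connectivity decays faster with distance, while surface and
migration larvae are statistically indistinguishable from each other.
The season length (36 days rather than 180) and domain size were chosen
as the smallest configuration in which those contrasts are statistically
resolvable per run; the orderings themselves are stable across an
independent panel of seeds, while the significance of single-season runs
naturally fluctuates with the year's realized circulation.

## The genetics suite

Genotypes live in a `GenotypeTable`: two integer allele codes per
individual and locus with population and year labels, read and written in
GENEPOP format (2- and 3-digit dialects, `000000` missing).

Diversity per population: mean allele count A; allelic richness rarefied
to g individuals by the hypergeometric formula (the expected number of
alleles in 2g gene copies — the packaged examples rarefy to the smallest
common sample); Nei's unbiased expected heterozygosity with the
2n/(2n-1) correction; observed heterozygosity; and the Weir--Cockerham
within-population f (F_IS) as a ratio of variance components summed over
alleles and loci, with a one-sided permutation p-value for heterozygote
deficit obtained by shuffling alleles among the population's individuals
(the permutation unit is a documented choice). Monomorphic loci
contribute zero heterozygosity and are uninformative for f.

Differentiation: Weir--Cockerham theta per locus and as a multilocus
ratio of summed components, pairwise matrices with permutation p-values
(population labels shuffled over individuals) and a bootstrap-over-loci
95% confidence interval for the global estimate; and Jost's D with
Nei--Chesser sample-size-corrected heterozygosities (harmonic-mean sample
size, the r/(r-1) factor), averaged over loci, with p-values from
resampling individuals with replacement from the pooled pair into the
original group sizes — a panmixia null. Isolation by distance couples the
pairwise matrices to shoreline distances through a Mantel test (Pearson
correlation of off-diagonal entries, one-sided permutation p, delegated
to vegan). Multiple testing is controlled with Benjamini--Hochberg
q-values; this is a step-up FDR procedure, slightly more conservative
than empirical-null q-value estimation.

Assignment follows the partial-exclusion logic: each recruit's genotype
likelihood under a reference population's allele frequencies (unobserved
alleles floored at 1/(2n+1) so a foreign allele excludes softly) is
ranked within the likelihoods of 10,000 genotypes simulated from those
frequencies under Hardy--Weinberg; a recruit is assigned if its rank
probability exceeds 0.05 in exactly one population and is an immigrant if
it falls below 0.05 everywhere.

Parentage replaces a full-likelihood sibship reconstruction with
error-tolerant Mendelian exclusion: a locus mismatches when the candidate
shares no allele with the offspring, and a pair survives the screen if
its mismatch count does not exceed a tolerance derived from the
genotyping error model — the 95% binomial quantile of the per-locus
incompatibility implied by per-allele dropout (an allele replaced by its
homologue, the classic false homozygote) plus other error (a random
allele substitution). At the study rates (0.05 and 0.01) over 12 loci
this tolerance is 2; a tolerance of 1 would, by the same arithmetic,
already reject over a tenth of true pairs. Surviving pairs receive a
confidence equal to one minus the fraction of simulated unrelated
candidates (drawn from the candidate pool's allele frequencies) that
reach as few mismatches, and are accepted above 0.95. On the packaged
fixtures this recovers all pairs without error when genotyping is clean,
and with the study error model it meets a 90% recovery floor while
accepting a negligible fraction of the unrelated pairs screened; because
the null confidence is a per-pair quantity, a large candidate pool can
still let a handful of coincidental 2-mismatch pairs through, which is
the price of the exclusion design and is measured, not hidden, by the
truth-table tests. Self-recruitment is then simply the proportion of
recruits at a focal site with at least one accepted local parent.

### The synthetic genotypes

Ancestral allele frequencies per locus are drawn from a skewed symmetric
Dirichlet (alpha = 0.35 over 9--41 alleles, giving microsatellite-like
expected heterozygosities around 0.7--0.9); K latent gene pools diverge
from the ancestor following a Balding--Nichols parameterization with
divergence F (`poolDivergence`); sampled populations mix the pools
through ancestry weights. With `mixing = "allele"` every allele is an
independent draw from the mixed frequencies, so populations are in exact
Hardy--Weinberg proportions; with `mixing = "individual"` each individual
first draws a pool of origin, which creates the Wahlund heterozygote
deficit (positive F_IS) that admixed samples show in practice. Year
effects are emulated by shifting the ancestry weights between year
labels. The packaged calibration dataset (`demoGenotypeDataset()`, seven
admixed populations over K = 3 pools, divergence 0.2) was calibrated once
so that realized global theta lands in the weak-structure band around
0.02. Families (`makeFamilies()`) draw disjoint parent pairs, transmit
one Mendelian allele per parent per locus, and corrupt the observed
offspring genotypes allele-wise with the dropout/error model above; the
truth tables they return drive all parentage benchmarks.

## Reproducibility

Every generator and every resampling routine takes an explicit seed, and
the umbrella `runPipeline()` derives an independent stream per stage from
one master seed, so toggling a stage never changes another stage's draws.
Each run directory carries a manifest with the seed, a canonical
configuration hash and md5 checksums of every artifact; re-running a
configuration reproduces the checksums. Statistical test sizes follow the
study's settings (10,000 permutations for theta and Mantel, 1,000
resamples for D) but are reduced in the automated tests (99--199
permutations, 500 replicate datasets for the type-I-error checks), sizes
at which the exact validity of the (1 + k)/(B + 1) permutation p-value
keeps the nominal level.

## Known limitations

The two prongs remain descriptive side by side, as in the study design
they implement: no joint inference couples the connectivity matrices to
the genetic differentiation. The circulation is a two-layer cartoon; the
least-cost shoreline distance uses cell-centre great-circle steps, which
overestimates smooth-coast distances by up to the usual 8-connectivity
factor (~8%); and the exclusion-based parentage, by design, trades the
resolution of full-likelihood methods for transparency and testability.
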