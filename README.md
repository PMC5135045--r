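# larvaConn

Marine fish populations that look isolated on a map can be demographically
and genetically connected through their drifting larvae. **larvaConn**
implements the two standard instruments for measuring that connectivity in
one tested R package:

* an **individual-based Lagrangian dispersal model** — virtual larvae
  advected hourly through gridded two-layer (0 m / 10 m) ocean velocity
  fields with fourth-order Runge–Kutta integration, masked bilinear
  interpolation, behaviour-dependent depth use (surface, deep, vertical
  migration at competence), an 18-day pelagic larval duration, competence
  from day 10, first-contact settlement into 0.05° coastal habitat cells,
  and cell-by-cell connectivity matrices built from step counts;
* a **microsatellite population-genetics suite** — allelic richness by
  rarefaction, unbiased heterozygosities, Weir–Cockerham *F*~IS~ and
  *F*~ST~ (θ) with permutation tests and bootstrap-over-loci confidence
  intervals, Jost's *D* with sample-size-corrected heterozygosities,
  Mantel isolation-by-distance against least-cost shoreline distances,
  Monte-Carlo partial-exclusion population assignment, error-tolerant
  Mendelian parentage (allele dropout 0.05, other error 0.01), and
  self-recruitment.

Because the data such studies rest on (ocean hindcasts, genotype tables)
are rarely shippable, the package includes first-class synthetic
generators: a coastal domain builder, a two-phase upwelling-shelf
circulation with propagating mesoscale eddies, and a gene-pool admixture
genotype simulator with known truth — every downstream statistic is tested
against ground truth or an independent oracle.

The central quantity of the dispersal prong is the paired probability

P(i→j) = E[ #hourly steps of a larva from cell *i* spent in cell *j* ] / (18 × 24),

whose diagonal measures retention; the genetics prong centres on
Weir–Cockerham θ = Σa / Σ(a+b+c) over alleles and loci and on
D = (H~T~ − H~S~)/(1 − H~S~) · r/(r−1).

## Worked example

```r
library(larvaConn)

## dispersal prong: the packaged 20-cell behaviour experiment, deep layer
habitat <- behaviorExperimentDomain()
regime  <- behaviorExperimentRegime()
fields  <- makeVelocitySeries(habitat, regime, years = 1, daysPerYear = 60, seed = 1)
pars    <- simParams(seasonLengthDays = 36, releaseIntervalHours = 6, behavior = "deep")
rec     <- simulateDispersal(fields, habitat, pars)
rec
#> ParticleRecords: 2880 particles; behavior = deep
#>    dead settled
#>     519    2361

connectivityMatrix(rec, habitat)
#> ConnectivityMatrix: 20 cells; year = 1 ; behavior = deep ; denominator = all_released
#>   mean retention (diagonal): 0.2691

settlementSummary(rec, habitat)
#> SettlementSummary: mean retention 0.259 | mean effective settlement 0.82 |
#>   dispersal 4.34 +/- 3.355 km (max 11.13 km)
```

2,880 larvae were released (20 cells × 36 days × 4 releases/day); in this
realization none were advected out of the domain in the deep layer, 82%
found habitat within their larval duration, and a quarter settled back
into their natal cell, dispersing 4.3 ± 3.4 km on average. Re-running with
`behavior = "surface"` shows the contrast the model is built to expose:
surface larvae are exported offshore by the upwelling circulation, retain
far less, and disperse farther.

```r
## genetics prong: the calibrated seven-population demo dataset
gd  <- demoGenotypeDataset(seed = 1)
round(fstWC(gd$genotypes)$global, 4)
#> [1] 0.0287
round(jostD(gd$genotypes, nBoot = 0)$mean, 4)
#> [1] 0.1001
s <- summarizePopulation(gd$genotypes, "ARR", g = 24, nPerm = 199)
unlist(lapply(s[c("A", "Arich", "He", "Ho", "Fis", "FisP")], round, 3))
#>      A  Arich     He     Ho    Fis   FisP
#>  9.667  8.583  0.752  0.761 -0.012  0.730
```

Global θ ≈ 0.03 with per-population expected heterozygosity ≈ 0.75 and
allelic richness ≈ 8.6 (rarefied to 24 individuals): weak spatial
structure over diverse microsatellites, the regime the calibration
targets. *F*~IS~ is near zero here because the demo populations are
generated in Hardy–Weinberg proportions; the `mixing = "individual"`
generator option produces the Wahlund-style heterozygote deficits seen in
admixed field samples.

`runPipeline(runConfig(seed = 1))` chains synthesis, simulation,
connectivity and genetics into one run directory with a seed- and
checksum-carrying manifest.

## Vignette

`vignettes/larval-connectivity.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generators emulate (and deliberately do not), the numerical
choices at the coastline and in the statistics, and known limitations.
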