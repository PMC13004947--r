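# polclust

Quantitative analysis of RNA Polymerase II (RNAPII) clustering and
kinetics in early embryos, from single-molecule tracking (SMT) and
volumetric light-sheet imaging.

During zygotic genome activation, the fraction of chromatin-engaged
RNAPII rises sharply and the properties of RNAPII clusters change with
it. `polclust` implements the full computational pipeline needed to
measure this from microscopy-derived inputs, for researchers analysing
fast SMT trajectory tables and 4D (T×Z×Y×X) nuclear image stacks:

* **Diffusion-state inference.** Per-trajectory squared jumps are
  modelled as exponential with mean `4(D·Δt + σ_loc²)`; occupancies over
  a fixed grid of 100 log-spaced coefficients on [0.001, 100] µm²/s are
  estimated by finite-mixture EM. States (bound / intermediate / fast)
  are delimited at occupancy minima, and per-field kinetic fractions are
  the occupancy mass per state (`estimateOccupancy()`,
  `findStateBoundaries()`, `computeOccupancyFractions()`).
* **Bound-fraction decomposition.** With `b` the bound fraction under
  vehicle, α-amanitin (elongation block) and triptolide (initiation
  block): `nonspecific = b_TRI`, `initiating = b_AMA − b_TRI`,
  `elongating = b_VEH − b_AMA`, with standard error propagation and
  fold changes (`decomposeBoundFraction()`, `foldChange()`), plus
  centered log-ratio compositional testing (`clrTransform()`,
  `compareFractions()`).
* **Anisotropy.** Turning angles between consecutive jumps ≥0.2 µm;
  fold-anisotropy `P(150–180°)/P(0–30°)` with subsampling uncertainty
  (`computeAngles()`, `foldAnisotropy()`, `bootstrapAnisotropy()`).
* **Cluster analysis.** Density-based clustering of trajectory mean
  positions with size-matched control spots
  (`densityCluster()`, `placeControlSpots()`); volumetric segmentation
  of nuclear clusters by top-hat + seeded watershed, HLB detection,
  the 1.65 enrichment filter, lifetime tracking with the 600-nm axial
  gate, and a two-state lifetime Gaussian mixture
  (`segmentClusters()`, `detectHlbs()`, `trackLifetimes()`,
  `fitLifetimeMixture()`).
* **Burst analysis.** MS2 spot tracking, paired MCP/RNAPII traces in a
  1.2 µm disc, burst segmentation (>30 s), loading rates, and normalized
  cross-correlation whose lag-0 value is the Pearson coefficient
  (`segmentMs2Spot()`, `extractTraces()`, `segmentBursts()`,
  `crossCorrelate()`, `controlSphereCC()`).
* **Promoter-loading simulator.** Stochastic loading (`k_on`),
  dissociation (`k_off`) and elongation (2.5 kb/min over 2.8 kb) during
  a 15-min ON window, rendered with a 400-nm-FWHM PSF over the ~50,000
  nuclear molecules scaled to a 3-slice slab
  (`simulateGene()`, `simulateTrace()`, `renderFrame()`, `sweepKon()`).
* **Synthetic data with ground truth** for every stage
  (`simulateTrajectories()`, `simulateNucleusMovie()`,
  `generateCoupledTraces()`), so the entire pipeline is testable without
  raw imaging data.

## Worked example

Simulate a late-cycle-like trajectory set, infer states, and decompose
the bound fraction from the study's published inputs:

```r
library(polclust)

cfg <- smtSimConfig(nTrajectories = 3000, stateFractions = c(0.37, 0.33, 0.30),
                    stateD = c(0.002, 0.2, 8), seed = 1)
sim <- simulateTrajectories(cfg)
prof <- estimateOccupancy(sim$tracks, sigmaLoc = 0.030, frameInterval = 0.01)
bins <- findStateBoundaries(prof)
bins
#> KineticBins: 3 states
#>   bound        [0.001, 0.0231013] um^2/s
#>   intermediate [0.0231013, 1.2045] um^2/s
#>   fast         [1.2045, 100] um^2/s

round(occupancyFractions(prof, bins), 3)
#>        bound intermediate         fast
#>        0.368        0.334        0.298
```

The generating fractions (0.37/0.33/0.30) are recovered to ~0.01. The
decomposition arithmetic on the published cycle-14 numbers (vehicle
bound fraction 0.51 ± 0.08; 2.3-fold decrease under α-amanitin; 3.6-fold
under triptolide):

```r
decomposeBoundFraction(0.51, 0.51 / 2.3, 0.51 / 3.6, sdVehicle = 0.08)
#>     component   fraction   sd flagged
#> 1 nonspecific 0.14166667 0.00   FALSE
#> 2  initiating 0.08007246 0.00   FALSE
#> 3  elongating 0.28826087 0.08   FALSE

fc <- foldChange(0.51, 0.37, 0.08, 0.05)
sprintf("bound-fraction fold change: %.2f +- %.2f", fc$estimate, fc$sd)
#> [1] "bound-fraction fold change: 1.38 +- 0.29"
```

So 14% of molecules remain non-specifically bound after initiation
inhibition, ~29% of all molecules are elongating in cycle 14, and the
bound fraction rises 1.4 ± 0.3-fold across genome activation.

A thin command-line wrapper over the same functions lives at
`inst/scripts/polclust-cli.R`
(`simulate`, `fit-kinetics`, `decompose`, `anisotropy`, `run`).

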