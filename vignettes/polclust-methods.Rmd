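---
title: "Methods: quantifying RNA Polymerase II clustering and kinetics"
author: "polclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying RNA Polymerase II clustering and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polclust)
```

# Scope

`polclust` implements the computational pipeline behind a single-molecule
and volumetric-imaging study of RNA Polymerase II (RNAPII) clustering in
early fly embryos, where transcription rises sharply at zygotic genome
activation. The package covers five analysis families — diffusion-state
inference from single-molecule tracking (SMT), decomposition of the
chromatin-bound fraction under transcription inhibitors, displacement-angle
anisotropy, cluster detection (from trajectories and from volumetric
movies, including lifetime mixture modelling), and MS2/MCP transcription
burst analysis — plus a stochastic promoter-loading simulator and a
synthetic-data module that generates every input with known ground truth.
Raw microscopy data are not required anywhere: all tests and the
acceptance analysis run on synthetic inputs.

# Diffusion-state inference

## Model

A trajectory is a time-ordered sequence of 2D localizations at a fixed
frame interval $\Delta t$ (default 0.01 s). Each trajectory is assumed to
stay in one diffusive state with coefficient $D$; with per-axis
localization noise of sd $\sigma_{loc}$ (default 0.030 µm, estimated
separately), the squared length of one jump is modelled as exponential
with mean $4(D\Delta t + \sigma_{loc}^2)$, and jumps within a trajectory
are treated as independent. This "jumps-independent" likelihood neglects
the negative correlation between successive displacements induced by the
shared localization of adjacent jumps; the full blurred/correlated
treatment is a possible extension, and the consequences of the
approximation are discussed below.

Occupancies are estimated over a fixed grid of 100 log-spaced diffusion
coefficients on $[0.001, 100]$ µm²/s by finite-mixture
expectation–maximization: starting from uniform weights, responsibilities
and weights alternate for at most 200 iterations (stopping earlier when
the log-likelihood gain falls below $10^{-8}$). Because the likelihood
depends on a trajectory only through its jump count and summed squared
jump length, the E-step is a single matrix operation and $10^4$
trajectories fit in seconds. The log-likelihood is non-decreasing across
iterations (tested), and the occupancy vector sums to one after every
update.

## State boundaries

Kinetic states (bound, intermediate, fast) are delimited by local minima
of the occupancy curve, smoothed with a discrete Gaussian kernel of 3
grid points; minima must have a prominence of at least 1% of the curve
maximum. Two numerical details matter in practice:

* **One boundary per valley.** The finite-mixture EM concentrates weight
  near the modes and leaves ragged, near-zero weights across the valley
  between them, so a raw minima scan can return several "minima" inside
  one wide valley. Successive minima with no intervening ridge (a peak
  exceeding both by the prominence) are therefore merged into one valley.
* **Flat-valley tie-break.** Within a valley whose floor is flat, every
  point is an equally good minimum. The boundary is placed at the midpoint
  of the valley floor (the contiguous run within one prominence of the
  floor level), i.e. at maximum margin from both neighbouring modes. This
  choice is made on symmetry grounds, not fitted to any outcome.

A unimodal profile yields a single state; three states are labelled
bound / intermediate / fast. When perturbation conditions are compared,
boundaries are frozen on the vehicle profile and applied unchanged to the
drug conditions (`runPipeline()` does this).

## Fractions: occupancy mass, not track counts

Two estimators of the per-field kinetic fractions are provided.
`computeOccupancyFractions()` fits an occupancy profile per field (with
frozen boundaries) and reports the occupancy mass within each bin — the
state-array notion of a bound fraction. `computeFractions()` instead
counts trajectories whose assigned coefficient (the geometric mean of the
grid weighted by the trajectory's posterior, `assignTrajectoryD()`) falls
in each bin.

The two disagree systematically for short tracks. A 2–4-jump trajectory
has a posterior spread over decades of the grid; taking its geometric
mean shrinks the assignment toward the slow modes, so count-based
fractions overestimate the bound state when it carries the largest
weight (by about +0.03 under the three-state recovery conditions below).
Occupancy mass does not suffer from this shrinkage and recovers
generating fractions of (0.50, 0.20, 0.30) to within 0.03 at $10^4$
trajectories, which is the estimator used for headline fractions and in
`scripts/acceptance.R`. The count-based estimator is retained because
per-trajectory assignments are still needed downstream (anisotropy
filtering, cluster kinetics).

A related resolution limit is worth stating: with
$\sigma_{loc} = 0.03$ µm and $\Delta t = 0.01$ s, the localization floor
is $\sigma_{loc}^2/\Delta t = 0.09$ µm²/s, and diffusion coefficients
well below it (e.g. 0.01) cannot be pinpointed on the grid — the
likelihood is nearly flat over the slow plateau, and the EM leaves mass
spread across it. Slow-state *mass* is still recovered; the *location* of
mass within the sub-floor region is not meaningful.

## Localization error

The localization error is estimated from the slowest tracks: the mean
consecutive displacement $m$ of an immobile emitter is Rayleigh with mean
$\sigma_{loc}\sqrt{\pi}$, giving $\hat\sigma_{loc} = m/\sqrt{\pi}$.
Selecting the slowest 5% of tracks by a statistic computed from the same
displacements that are subsequently averaged would bias the estimate low
by ~30% (the selected tracks are those whose noise happened to be small
— and alternating even/odd jumps does not decouple selection from
measurement because adjacent jumps share a localization). The estimator
therefore splits each trajectory's jumps into a leading half used only
for ranking and a trailing half used only for the mean displacement,
skipping one jump in between so the halves share no localization. With
4,000 immobile emitters at $\sigma_{loc} = 30$ nm the estimate is
recovered to within 2 nm (tested).

# Bound-fraction decomposition and compositional statistics

The bound fraction measured after initiation inhibition (triptolide) is
interpreted as non-specific chromatin binding; the additional binding
surviving elongation inhibition (α-amanitin) as initiating molecules; the
remainder of the vehicle bound fraction as elongating molecules:

$$\text{nonspecific} = b_{TRI},\quad
  \text{initiating} = b_{AMA} - b_{TRI},\quad
  \text{elongating} = b_{VEH} - b_{AMA}.$$

Standard deviations of differences propagate as
$\sqrt{sd_1^2 + sd_2^2}$ and of ratios as
$r\sqrt{(sd_a/a)^2 + (sd_b/b)^2}$. The components always reassemble to
the vehicle bound fraction exactly; a negative component (possible when
drug-condition fractions cross) is flagged with a warning, never
clipped. The first-order ratio propagation is accurate to within 5% of a
Monte-Carlo reference for relative errors up to ~15%; at 20% relative
error on the denominator the exact sd exceeds the first-order value by
about $3(sd_b/b)^2 \approx 12\%$, so propagated errors on noisy ratios
should be read as lower bounds.

Because (bound, intermediate, fast) live on the simplex, group
comparisons of full compositions use the centered log-ratio transform
$clr_i = \log(x_i/g(x))$ before a two-sided rank-sum test per component;
single components (e.g. bound fractions inside clusters) are compared on
the raw values. Zero parts are only admitted with multiplicative
replacement (half the smallest nonzero part). Groups of at most 10 fields
are tested exactly by enumerating all assignments of the pooled ranks —
valid under ties, unlike the classical exact rank-sum distribution —
and larger groups use the normal approximation with tie correction.

# Displacement anisotropy

Turning angles between consecutive jumps are computed from the clamped
normalized dot product; pairs with either jump below 0.2 µm are skipped
and chromatin-bound trajectories are removed first, since immobile
molecules produce noise-dominated, backward-biased angles. The
fold-anisotropy is
$f = P(\theta \in [150°, 180°]) / P(\theta \in [0°, 30°])$, with both
windows closed; $f = 1$ for free diffusion and $f > 1$ under confinement.
A zero forward count makes $f$ undefined and it is reported as `NA`, not
infinity. Uncertainty is estimated by recomputing $f$ on 20 random
half-samples drawn without replacement (the protocol's "bootstrap" is
subsampling, and it is implemented as such). At $4\times10^5$ angles from
an isotropic walk, $f$ is 1.00 within 0.02 (tested); at $10^5$ angles the
sampling sd of $f$ is already ≈1%, so larger angle sets are used where
the check must be tight.

# Trajectory clustering and control spots

Clusters of trajectories are found by density-based clustering of
trajectory mean positions (a core point has ≥15 neighbours within
0.2 µm, including itself; clusters are connected core points plus border
points). The implementation is deterministic in point order; border
points reachable from two clusters join the cluster expanded first. A
brute-force density-reachability oracle verifies the partition on ≤100
points over 50 random fields (tested). `epsElbowScan()` tabulates
cluster count against the radius for elbow inspection; no automatic knee
selection is attempted. Clusters extreme in both member count and radius
(above the 95th percentile of each) can be dropped as likely
histone-locus bodies or random accumulations; the cutoff is configurable
because no printed value exists.

Each cluster gets 30 size-matched control spots, rejection-sampled
inside the circular nuclear mask so that they overlap neither any
cluster nor each other ("size" = the cluster's maximal member distance to
its centroid). Placement is seeded and reproducible; an over-constrained
nucleus yields a partial list with a warning. Inside/outside/control
bound fractions are computed per field, and enrichment folds carry
propagated sds. A trajectory is "inside" when its mean position falls in
any cluster disc, which also decides angles near a cluster edge (the
angle belongs to the zone of its central localization).

# Volumetric cluster analysis

Nuclear volumes are divided by their in-mask mean intensity, giving
enrichment over nuclear background (mean exactly 1 inside the mask).
Segmentation then runs: per-slice 3×3 median filter → grayscale erosion
(Euclidean ball, radius 2 voxels) → reconstruction by dilation
(6-connected geodesic dilation to convergence) → subtraction of the
reconstruction from the median-filtered image (a top-hat residue that
removes the smooth nuclear background) → binarization (Otsu on the
positive residue by default; a fixed threshold can be supplied, which is
preferable when a few very bright objects dominate the residue
histogram) → local-maxima markers (≥3 voxels apart) → seeded watershed
(voxels join labelled 6-neighbours in decreasing-intensity passes) →
per-label region properties. Kernel sizes are configurable; the defaults
above are the package's own, as the operator chain is standard but its
parameters are not printed anywhere authoritative.

HLBs — at most two per nucleus — are the clusters overlapping a
thresholded per-slice difference-of-Gaussians response (sigmas 1 and 5
pixels, 99.95th percentile) with the highest mean enrichment; they are
flagged and removed before cluster statistics. Clusters with mean
enrichment below 1.65 are discarded; the filter is monotone in the
threshold. Cluster density is count over nuclear volume (µm⁻³).

Lifetimes come from frame-to-frame nearest-neighbour linking with an
axial gate of 0.6 µm (two 300-nm z-slices) and a lateral gate of 0.5 µm
(the axial rule is prescribed; the lateral gate is the package's, set
below typical inter-cluster spacing, and configurable). A track ends at
the first frame without a link. On noise-free synthetic movies with
separated clusters, track count and every lifetime are recovered exactly
(tested). Lifetimes (minutes, raw not log) are then fit with a
two-component maximum-likelihood Gaussian mixture (`mclust`, unequal
variances, equal-variance fallback on degeneracy), components ordered by
mean, and the weight uncertainty reported as the binomial
$\sqrt{w(1-w)/n}$ with $n$ the number of clusters fit. A two-component
*exponential* lifetime mixture — what the movie generator draws, matching
memoryless dissolution — has a monotone density, and a Gaussian mixture
fit on such data does not recover the generating weights; mixture
recovery is therefore validated on the Gaussian family
(`sampleLifetimes(..., family = "gaussian")`, sds 0.8 and 2 min), where
weights (0.33/0.67) and means (2/7 min) are recovered within 0.05 and
15% at $n = 300$ (tested). On unimodal data the two fitted components
collapse onto the same population rather than inventing separated modes.

# Transcription-burst analysis

The MS2 spot is segmented per volume by a per-slice
difference-of-Gaussians (sigmas 1.5 and 6 px), a percentile threshold
(default 99.9, configurable since the original thresholds were checked
by eye), removal of objects under 6 voxels and of objects whose centroid
lies outside the nuclear labels; the brightest surviving object per
nucleus is tracked by its intensity-weighted centroid. Traces use a
3-slice max-projection around the spot's z: RNAPII is the integrated
intensity in an 11-px (1.2 µm) diameter disc normalized to the nuclear
mean (enrichment), MCP is the brightest 2×2 square in the disc window.
Gaps of up to 2 frames are linearly interpolated; longer gaps split the
trace. Both channels are smoothed with a centered 3-sample (27 s) moving
average — kept shorter than the minimal burst.

Bursts are segmented on the smoothed MCP trace: boundaries at local
minima with prominence ≥5% of the trace range (endpoints count), each
candidate segment trimmed to its contiguous run above the baseline
(trace minimum plus the prominence), and kept only if strictly longer
than 30 s. The trimming matters: a trace that returns to baseline after
a burst would otherwise stretch the burst to the trace end. The loading
rate is the least-squares slope of the RNAPII enrichment from burst
start to its maximum — the rising-phase definition; the duration of a
triangular 180-s test burst is recovered within one 9-s sample, and the
deterministic simulator burst (see below) within two.

Cross-correlation is the full discrete linear correlation of the
mean-centered traces normalized by $n\,\sigma_a\sigma_b$ (population
sds), so the lag-0 value equals the Pearson coefficient (verified
against `cor()` to $10^{-9}$), and $cc(a,b)[k] = cc(b,a)[-k]$. Control
regions of the locus-disc size, placed in the same nucleus away from the
spot and from each other, provide the null. One caveat the synthetic
tests make explicit: because the RNAPII trace is normalized to the
nuclear mean *including* the locus, a strong locus signal leaks weak
negative correlation into control traces; controls therefore scatter at
or below zero rather than exactly at it, and the meaningful comparison
is locus versus control, not control versus zero.

# Promoter-loading simulator

While the promoter is ON (first `tOn` = 15 min), one polymerase loads
with probability `kOn` per 0.1 s step; engaged polymerases advance at
2.5 kb/min along a 2.8 kb gene, dissociate with probability `kOff` per
step (default 0.001 — the dissociation constant is not printed and is
configurable), and run off the end after ON. The event ledger
(loaded = completed + dissociated + engaged) balances at every step.
With `kOff = 0`, the steady-state mean engaged count obeys Little's law,
`kOn/dt` × (gene length / elongation rate) — e.g. 134.4 at `kOn` = 0.2 —
and 1,000 replicates match it within 5% (tested).

Rendering places the slab-scaled background (the 50,000 nuclear
molecules scaled by the exact spherical-cap volume fraction of the
central 3 × 0.3 µm slab of a 5 µm nucleus, ≈ 27%) uniformly in the
projected nuclear disc and the engaged molecules at the locus, each as a
2D Gaussian of 400 nm FWHM with unit flux at 0.108 µm pixels; the frame
is padded by 4 PSF sigmas so flux is conserved to 0.5% and a fitted
FWHM matches 400 nm within 5% (tested). Enrichment traces avoid full
rendering: each molecule contributes its analytic PSF mass inside the
1 µm gene-region disc (a noncentral-χ² expression), background molecules
are re-placed per 9-s sample (no background diffusion dynamics — only
the static enrichment contrast matters for detectability), and the disc
integral is divided by the expected background integral. A sweep over
`kOn` records per burst the loading rate, duration and maximal
enrichment, with detectability defined as enrichment ≥1.65 to match the
imaging filter; mean maximal enrichment is monotone in `kOn` (tested).

# Synthetic data: what it does and does not emulate

The trajectory generator draws per-track states from the configured
fractions (no within-track switching, matching the one-coefficient-per-
trajectory analysis), reflects walks at a circular nuclear boundary,
adds independent Gaussian localization noise to every localization
(reflected back inside, so all positions stay in the mask), and
truncates track lengths geometrically (memoryless photobleaching) with
a minimum of 3 localizations (needed for angles) and mean 8 frames — a
typical track duration for fast SMT of a photoconvertible tag. Bound
tracks can be seeded in circular hotspots to create ground-truth
clusters. The movie generator paints an ellipsoidal nuclear baseline,
transient isotropic Gaussian clusters with exponential-mixture
lifetimes, up to two persistent bright HLBs, and additive Gaussian
noise — additive, not Poisson, because the emulated data are
deconvolved, which already distorts shot statistics. Coupled traces wrap
the loading simulator.

None of the generators emulate camera noise physics, axial PSF
anisotropy, drift, chromatic registration, nuclear import/export, or
state switching within tracks. Passing recovery tests therefore show
that the estimators invert the stated generative models at realistic
sizes and noise levels — not that they are robust to every artefact of
real microscopy data.

# Problem sizes and reproducibility

The test-suite and acceptance runs use: $10^4$ trajectories (10 fields)
for three-state recovery; 4,000 immobile emitters for the localization
error; 300 lifetimes for the mixture; 1,000 replicates for the
steady-state occupancy; ≈$4\times10^5$ angles for the isotropy null; 50
random ≤100-point fields for the clustering oracle; movies of
$\le 10 \times 12 \times 56 \times 56$ voxels for segmentation and
lifetime round-trips. These sizes put sampling error well inside each
check's tolerance while keeping a full run in minutes. Every stochastic
stage takes a seed, and pipeline stages derive their seeds from one
global seed (`deriveSeed()`), so reruns are bit-identical; the pipeline
manifest records parameters, seeds and output hashes.

# Known limitations

* The jumps-independent likelihood ignores localization-induced jump
  correlations; sub-floor diffusion coefficients are identifiable only
  as aggregate slow mass.
* Count-based fractions are shrinkage-biased for very short tracks; use
  occupancy-mass fractions for headline numbers.
* The triptolide residual is *labelled* non-specific binding; incomplete
  drug action is not modelled, and the label is interpretation, not
  logic.
* Cluster segmentation defaults (kernel sizes, Otsu) are package
  choices; on data whose residue histogram is dominated by a few bright
  objects, supply a fixed threshold.
* The burst "loading rate" uses the RNAPII rising slope; the original
  definition is not printed, and other conventions would scale results.
* Control-region correlations inherit a weak negative coupling from
  nuclear-mean normalization (see above).
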