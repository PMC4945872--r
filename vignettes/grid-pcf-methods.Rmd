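---
title: "Grid-based pair-correlation analysis of algal colonization: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based pair-correlation analysis of algal colonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralPCF)
```

## The question and the statistic

Algae colonizing a bleached coral surface form a binary spatial pattern:
each small patch of surface either carries algae or does not. The
scientific questions — do algae cluster? is there an exclusion zone
around polyps? at what scales? — are questions about the *second-order*
structure of that pattern, and the natural tool is the pair-correlation
function. For a categorical raster (cells of side $c$ μm, occupied
fraction $p$), the grid-based O-ring estimator used here is

$$\hat g(r) \;=\; \frac{1}{p}\;\cdot\;
  \frac{\sum_{i \in F_r} n_i(r)}{\sum_{i \in F_r} A(r)},$$

where $F_r$ is the set of *focal* cells (occupied cells whose whole
annulus fits inside the map), $n_i(r)$ the number of occupied cells in
the annulus of mean radius $r$ around focal cell $i$, and $A(r)$ the
number of grid cells in that annulus. $\hat g(r)$ is the relative
density of neighbours at distance $r$: 1 under complete spatial
randomness (CSR), above 1 for aggregation, below 1 for regularity. It is
non-cumulative, so mixed patterns (clustering at one scale, exclusion at
another) appear as distinct features rather than being integrated away
as in Ripley's $K$.

## The processing chain and its parameters

**Pixel averaging** (`binPixels`, factor 2). Each 2 × 2 neighbourhood is
replaced by its per-channel mean before any colour conversion; trailing
pixels that do not fill a block are dropped. Averaging precedes the HSV
conversion because that is the order of the standard chain this package
reproduces, and because averaging RGB then converting is not the same
operation as converting then averaging saturations.

**Saturation segmentation** (`rgbToSaturation`, `thresholdSaturation`).
Saturation is the standard HSV quantity $S = (\max - \min)/\max$ over
the RGB channels ($S = 0$ when $\max = 0$). Bleached tissue reflects
roughly evenly (low $S$); pigmented algae absorb preferentially (high
$S$). The global threshold defaults to 0.25 with 0.22/0.28 as
conventional sensitivity alternatives (`thresholdSensitivity` runs the
whole chain per threshold and reports mean relative change in $g$).
The comparison is strict ($S > t$): 0.25 is a round value that synthetic
images hit exactly, so the tie rule is part of the contract, and strict
inequality makes the mask monotone in $t$ (lowering the threshold can
only add pixels).

**Rasterization** (`rasterizeMask`). Cells are `cellPx` = 16 original
camera pixels on a side — with the default optics (3.45 μm pitch, 3×
magnification) that is $16 \times 3.45 / 3 = 18.4$ μm, chosen to match
the smallest algal filaments, i.e. the minimum feature the analysis
should resolve. A 2,448 × 2,050 frame therefore yields
$\lfloor 2448/16 \rfloor \times \lfloor 2050/16 \rfloor = 153 \times 128$
cells; trailing partial cells are dropped. How segmented *pixels* map to
cell *presence* is genuinely open (the chain this reproduces does not
state it); the default is the majority rule (`occupancyFraction = 0.5`),
on the rationale that a cell sized to the minimum feature should be
called occupied when a feature substantially covers it. The fraction is
configurable, and the comparison is done on integer pixel counts so the
boundary case is exact in floating point.

**Ring geometry** (`ringOffsets`, `PcfConfig`). Annuli are
non-overlapping half-open distance classes $[kw, (k+1)w)$ in cell units
with $w = 2$ cells, labelled by their midpoints $w/2, 3w/2, \dots$ — so
the first class is the 8-neighbourhood and, at $w = 2$, the "first class
at one cell" and "midpoint at half-width" conventions coincide.
Distances are centre-to-centre Euclidean; membership is evaluated on
squared distances in integer arithmetic, so pairs at exactly an integer
boundary (e.g. distance 2) fall deterministically into exactly one ring.
The focal cell itself is never counted.

**Edge correction** (`bufferValidFocals`). A focal cell contributes to a
distance class only if every cell of its annulus lies inside the map
(buffer-zone correction); because each used annulus is complete, the
grid cell count $A(r)$ is exact and no area approximation enters. Radii
with fewer than `minFocalCells` = 100 usable focal cells are reported
but flagged invalid — transparency for plots rather than silent
dropping. On the 153 × 128 grid at moderate density every valid radius
also accumulates well over 8,000 point-to-point neighbour counts
(exposed as `n_pairs`).

**Normalization.** The density $p$ in the denominator is computed over
the *entire* map by default, following the usual grid-based convention;
`densityScope = "buffer_interior"` recomputes it per radius over the
buffer-eroded interior instead. The default is also what the brute-force
oracle asserts.

**Resampling intervals** (`resampleCI`, `ciOrderRanks`). Each draw takes
$\lfloor N/2 \rfloor$ of the $N$ occupied cells uniformly without
replacement and recomputes the full curve under identical settings; 999
draws at $\alpha = 0.05$ bound the interval with the order statistics at
ranks $\mathrm{round}(\alpha/2 \cdot (B+1)) = 25$ and $B+1-25 = 975$.
That rank formula is used precisely because it reproduces the 25th
lowest/25th highest convention at $B = 999$. Two details are ambiguous
in the source chain and are therefore explicit switches:

* *Shared versus per-radius draws.* One draw yields one full $g(r)$
  curve shared across radii (default); per-radius independent draws are
  statistically equivalent radius-by-radius and ~$K$-fold more
  expensive. Both are implemented (`sharedDraws`).
* *Subsample density.* Each draw's curve is normalized by the
  subsample's own density (default): since $g$ is density-normalized,
  halving the density leaves its expectation unchanged, which is what
  makes half-population resampling a dispersion estimate for $g$ itself.
  Normalizing by the full-map density instead is available
  (`densityFrom = "full"`).

A radius is classified *clustered* when its whole interval lies above 1,
*regular* below 1, *csr_consistent* otherwise. The half-sample interval
is a dispersion estimate, not an exact null test, so no exact 5% error
rate is claimed; on CSR ensembles the observed misclassification rate is
small (the test suite checks ≤ 10%).

**Critical scales** (`summarizeScales`). The aggregation extent is the
largest radius of the unbroken run of clustered classes from the
smallest valid radius; the dip is the $g$ minimum beyond that run
(ties to the smallest radius), reported only when the minimum is itself
classified regular — under CSR the shallow sample minimum is not a
"dip"; the return radius is the smallest radius beyond the dip
consistent with CSR. Homogeneity (`homogeneityCheck`) asks whether $g$
trends to 1 at large scales: mean $|g - 1|$ over the largest quarter
(`windowFraction = 0.25`) of valid radii below `tolerance = 0.15`. The
source chain gives only the qualitative criterion; the window and
tolerance are package defaults, exposed in the configuration, and the
diagnostic is indeterminate (`NA`) when fewer than three valid radii lie
in the window.

## The synthetic-scene generator

`generateRaster` produces patterns whose structure is known exactly, so
segmentation and statistics can be validated end to end:

* **csr** — every cell occupied independently with probability
  `density` (default 0.3): the null reference.
* **thomas** — Poisson parents (default $3 \times 10^{-5}$/μm², drawn on
  a window padded by $4\sigma$ to avoid edge deficits), Poisson(40)
  offspring displaced by an isotropic Gaussian ($\sigma = 50$ μm), cells
  occupied when at least one point falls inside — the simplest faithful
  discretization for categorical raster semantics. This gives clustered
  patterns with a known ~100 μm scale and ~0.27 occupancy.
* **polyp_lattice** — polyp centres on a hexagonal lattice
  (centre-to-centre spacing 600 μm; corallites pack hexagonally, hence
  hexagonal rather than square), jittered with a 20 μm isotropic sd
  because real corallites are not a perfect crystal; cells within the
  exclusion radius (250 μm) of a centre are never occupied; remaining
  "ridge" cells are thinned, Matérn-style, to clustered micro-patches
  (kept only within 100 μm of a sparse Poisson seed set) and then
  occupied with probability 0.6. The spacing and radius are *plausible*
  scales for a massive *Porites* surface chosen to produce the
  qualitative three-phase pattern — aggregation at small $r$, a dip near
  the polyp scale, return toward 1 — and are not measured values.
* **full / empty** — degenerate references with exact expectations.

All randomness comes from one seeded generator per call, and the
caller's RNG state is restored afterwards; identical parameters give
bit-identical scenes.

`renderScene` draws a raster as an RGB image: occupied cells get a
high-saturation colour (default mean 0.6), background a low one (0.05),
with per-pixel Gaussian saturation spread, additive RGB noise, and a
configurable rendered feature radius. The HSV→RGB arithmetic is exact
(no 8-bit quantization), so at zero noise the segmentation chain
recovers the input raster cell-for-cell — the round-trip identity the
tests rely on. What the renderer deliberately does **not** emulate:
uneven illumination and vignetting, white-balance drift, chromatic
blur, focus stacking artefacts, partially pigmented (recovering) tissue,
or 3-D surface relief. Passing the synthetic round trips therefore
validates the *arithmetic* of the chain, not its robustness to optical
artefacts of real imagery — the threshold-sensitivity operation is the
tool for probing the latter on real frames.

## Numerical and engineering choices

* Counting kernels (per-ring offset counts; resampled pair counts over a
  precomputed neighbour-pair list) are small C++ routines; their
  contract is fixed by `bruteForcePCF`, an independent pure-R pairwise
  oracle that re-derives ring geometry by exhaustive enumeration and is
  asserted equal to the kernel to $10^{-9}$ on randomized rasters.
* Grid dimensions derived from physical windows use
  $\lfloor x/c + 10^{-9} \rfloor$ so exact multiples are not floored
  away by one ulp (18.4 μm is not binary-exact).
* Subsample draws are generated in R (`sample.int`) and passed to the
  kernel, keeping all randomness under R's RNG and seed.
* Degenerate inputs: an empty raster is an error for the estimator; a
  single occupied cell yields zero counts, $g = 0$, and is flagged
  invalid by the focal-cell rule; rings with no valid focal cell give
  `NA` bounds and no classification.
* Validation problem sizes: the suites use the native 153 × 128 frame
  geometry for calibration (200 CSR replicates; 20 polyp-lattice scenes
  with the full 999-draw resampling) and 40–60-cell grids for oracle
  and property checks — sizes at which the whole suite runs in about a
  minute on one core.

## Known limitations

* The pattern is assumed isotropic and first-order homogeneous;
  inhomogeneity induces *virtual aggregation* in second-order
  statistics. The homogeneity diagnostic flags it but no correction is
  applied. The polyp-lattice scenes themselves show the effect mildly
  (their $g$ tail sits slightly below 1, so `homogeneous` is often
  `FALSE` for them).
* Scale estimates are quantized to ring midpoints: with 18.4 μm cells
  and width-2 annuli, dip and return radii move in 36.8 μm steps, and a
  continuum feature near a class boundary can land in either adjacent
  ring. Recovered scales should be read with ±1 annulus width in mind.
* The half-population resampling interval inherits the pattern's own
  spatial dependence; it is a variability band around $\hat g$, not a
  CSR Monte-Carlo envelope, and the package deliberately does not
  provide envelope tests.
* The segmentation is a single global threshold; it has no notion of
  colour constancy, and images with strong illumination gradients will
  need external flat-fielding before entering the chain.
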