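# coralPCF

Micro-scale spatial statistics for algal colonization of bleached coral,
from *in situ* reflectance microscopy images.

When corals bleach, filamentous turf algae and benthic diatoms begin to
colonize the tissue surface. Whether that colonization is random or
structured — e.g. algae clustering on the ridges between polyps while
being excluded from the polyps themselves — is an ecological question
that can be answered from single microscope images with second-order
spatial statistics. `coralPCF` implements the full analysis chain:

1. **Segmentation.** Raw RGB frames are denoised by averaging 2 × 2
   pixel neighbourhoods, converted to HSV, and thresholded on
   saturation (default 0.25, strictly `S > t`): bleached tissue reflects
   light evenly (low saturation) while algae absorb preferentially
   (high saturation). The binary mask is rasterized into a categorical
   presence/absence grid whose cell side matches the smallest algal
   filaments — 16 camera pixels, i.e. 18.4 μm with a 3.45 μm pixel
   pitch behind a 3× objective, so a 2,448 × 2,050 frame becomes a
   153 × 128 grid.

2. **Pair-correlation function.** The grid-based (O-ring) estimator of
   the pair-correlation function

   *g*(*r*) = [mean occupied-neighbour density in the annulus at
   distance *r* around an occupied focal cell] / *p*,

   where *p* is the overall occupied fraction of the map. Annuli are
   non-overlapping distance classes two cells wide; distances are
   centre-to-centre Euclidean in cell units with half-open binning.
   Edge effects are removed with a buffer zone (a focal cell counts
   only when its entire annulus lies inside the map) and radii with
   fewer than 100 usable focal cells are flagged invalid.
   *g*(*r*) = 1 is the reference under complete spatial randomness
   (CSR, a homogeneous Poisson process); *g* > 1 indicates clustering,
   *g* < 1 regularity.

3. **Inference.** Confidence intervals come from 999 resampling draws
   of half the occupied cells without replacement; the 95% interval is
   bounded by the 25th-lowest and 25th-highest resampled *g*(*r*)
   values. A radius is *clustered* if the whole interval lies above 1,
   *regular* below 1, otherwise *csr_consistent*; two distance classes
   differ when their intervals are disjoint. `summarizeScales()`
   condenses the classified curve into the critical scales of the
   colonization pattern (aggregation extent, exclusion dip, return to
   randomness) and a large-radius homogeneity diagnostic.

4. **Synthetic scenes.** Because every stage must be testable without
   external data, `generateRaster()` produces point patterns with
   known structure — CSR, Thomas cluster processes, and a hexagonal
   "polyp lattice" with an exclusion radius and clustered micro-patches
   of algae on the inter-polyp ridges — and `renderScene()` draws them
   as RGB images for end-to-end validation of the segmentation chain.

## Worked example

Simulate a partially colonized *Porites*-like surface (polyps ~500 μm
across, centres 600 μm apart, algal micro-patches on the ridges), then
run the full analysis:

```r
library(coralPCF)

scene  <- SceneParams(patternKind = "polyp_lattice",
                      polypSpacingUm = 600, polypRadiusUm = 250, seed = 3)
raster <- generateRaster(scene)
raster
#> RasterMap: 128 x 153 cells (18.4 um/cell), 2653 occupied (13.5%)

ci <- resampleCI(raster, PcfConfig(), ResamplingConfig(seed = 3))
head(as.data.frame(ci)[, c("r_um", "g", "ci_lo", "ci_hi", "classification")], 8)
#>    r_um         g     ci_lo     ci_hi classification
#> 1  18.4 3.6729919 3.5397683 3.8187369      clustered
#> 2  55.2 2.8310612 2.7346965 2.9138195      clustered
#> 3  92.0 1.9891211 1.9201540 2.0571190      clustered
#> 4 128.8 1.4194108 1.3632037 1.4736658      clustered
#> 5 165.6 1.0755903 1.0319871 1.1225206      clustered
#> 6 202.4 0.8841519 0.8465706 0.9225926        regular
#> 7 239.2 0.7809564 0.7450868 0.8174597        regular
#> 8 276.0 0.7267474 0.6949971 0.7570215        regular

summarizeScales(ci)
#> ScaleSummary:
#>   aggregation extent: 165.6 um
#>   dip radius:         312.8 um (g = 0.725)
#>   return radius:      496.8 um
#>   homogeneous:        FALSE
```

Reading: algae are significantly aggregated out to ~166 μm (patch
growth), significantly *under*-dense around 310 μm (the exclusion zone
just outside the 250 μm polyp radius), and indistinguishable from
randomness beyond ~500 μm. `plot(ci)` draws the curve with its
intervals, red where a radius is consistent with CSR.

Real images enter the same chain through `readImageRGB()`,
`segmentImage()` and `rasterizeMask()` with your `OpticalGeometry`, or
in one step through `runPipeline()`, which also writes the raster,
g(r) and CI tables, scale summary, and a manifest that reproduces the
run byte-for-byte (`inst/scripts/run-pipeline.R` wraps it for the
shell).

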