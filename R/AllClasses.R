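#' Optical geometry of the imaging system
#'
#' Describes the camera/objective combination needed to convert sensor
#' pixels to object-space micrometres.  Defaults correspond to a 2/3"
#' machine-vision CCD (2,448 x 2,050 pixels, 3.45 um pixel pitch) behind a
#' 3x long-working-distance objective, which maps 16 camera pixels to an
#' 18.4 um object-space length.
#'
#' @slot pixelPitchUm sensor pixel pitch in micrometres.
#' @slot magnification objective magnification (dimensionless).
#' @slot sensorWidthPx,sensorHeightPx sensor dimensions in pixels.
#' @export
setClass("OpticalGeometry", representation(
  pixelPitchUm = "numeric",
  magnification = "numeric",
  sensorWidthPx = "integer",
  sensorHeightPx = "integer"
))

setValidity("OpticalGeometry", function(object) {
  msg <- character()
  for (s in c("pixelPitchUm", "magnification", "sensorWidthPx", "sensorHeightPx")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0) {
      msg <- c(msg, sprintf("'%s' must be a single positive value", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param pixelPitchUm,magnification,sensorWidthPx,sensorHeightPx see slots.
#' @rdname OpticalGeometry-class
#' @export
OpticalGeometry <- function(pixelPitchUm = 3.45, magnification = 3,
                            sensorWidthPx = 2448L, sensorHeightPx = 2050L) {
  new("OpticalGeometry",
      pixelPitchUm = pixelPitchUm, magnification = magnification,
      sensorWidthPx = as.integer(sensorWidthPx),
      sensorHeightPx = as.integer(sensorHeightPx))
}

#' Segmentation configuration
#'
#' Parameters of the image-to-raster stage: pixel binning factor, the
#' global HSV saturation threshold separating algae from bleached coral
#' tissue, the raster cell side in original camera pixels, and the
#' fraction of algae pixels required to call a raster cell occupied.
#'
#' The defaults (2 x 2 binning, threshold 0.25, 16 x 16 pixel cells,
#' majority occupancy) reproduce the standard processing chain for
#' bleached-coral reflectance images; thresholds 0.22 and 0.28 are
#' conventional sensitivity alternatives (see [thresholdSensitivity()]).
#'
#' @slot binFactor integer pixel-averaging factor (>= 1).
#' @slot saturationThreshold saturation cut in (0,1); pixels with
#'   S > threshold (strictly) are algae.
#' @slot cellPx raster cell side in *original* camera pixels; must be a
#'   multiple of `binFactor`.
#' @slot occupancyFraction fraction of algae pixels within a cell needed
#'   to mark it occupied, in (0,1].
#' @export
setClass("SegmentationConfig", representation(
  binFactor = "integer",
  saturationThreshold = "numeric",
  cellPx = "integer",
  occupancyFraction = "numeric"
))

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  if (!is_count(object@binFactor)) msg <- c(msg, "'binFactor' must be an integer >= 1")
  t <- object@saturationThreshold
  if (!is_scalar_num(t) || t <= 0 || t >= 1) {
    msg <- c(msg, "'saturationThreshold' must lie in (0, 1)")
  }
  if (!is_count(object@cellPx)) msg <- c(msg, "'cellPx' must be an integer >= 1")
  if (is_count(object@binFactor) && is_count(object@cellPx) &&
      object@cellPx %% object@binFactor != 0L) {
    msg <- c(msg, "'cellPx' must be divisible by 'binFactor'")
  }
  f <- object@occupancyFraction
  if (!is_scalar_num(f) || f <= 0 || f > 1) {
    msg <- c(msg, "'occupancyFraction' must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @param binFactor,saturationThreshold,cellPx,occupancyFraction see slots.
#' @rdname SegmentationConfig-class
#' @export
SegmentationConfig <- function(binFactor = 2L, saturationThreshold = 0.25,
                               cellPx = 16L, occupancyFraction = 0.5) {
  new("SegmentationConfig", binFactor = as.integer(binFactor),
      saturationThreshold = saturationThreshold, cellPx = as.integer(cellPx),
      occupancyFraction = occupancyFraction)
}

#' Pair-correlation configuration
#'
#' Controls the grid-based g(r) estimator: annulus width in cells, the
#' largest ring midpoint evaluated, the minimum number of usable focal
#' cells for a radius to be reported as valid, and which region the
#' normalizing density is computed over.
#'
#' Ring midpoints sit at odd multiples of half the annulus width, so with
#' the default width of two cells the annuli are the non-overlapping
#' distance classes \[0,2), \[2,4), ... in cell units and the first ring is
#' the 8-neighbourhood.
#'
#' @slot annulusWidthCells ring width in cells (>= 1).
#' @slot maxRadiusCells largest ring midpoint evaluated, in cell units.
#' @slot minFocalCells minimum focal cells for a radius to be valid.
#' @slot densityScope `"full_map"` (default; the whole-map occupied
#'   fraction normalizes every radius) or `"buffer_interior"` (per-radius
#'   density over the buffer-eroded interior).
#' @export
setClass("PcfConfig", representation(
  annulusWidthCells = "numeric",
  maxRadiusCells = "numeric",
  minFocalCells = "integer",
  densityScope = "character"
))

setValidity("PcfConfig", function(object) {
  msg <- character()
  if (!is_scalar_num(object@annulusWidthCells) || object@annulusWidthCells < 1) {
    msg <- c(msg, "'annulusWidthCells' must be >= 1")
  }
  if (!is_scalar_num(object@maxRadiusCells) || object@maxRadiusCells <= 0) {
    msg <- c(msg, "'maxRadiusCells' must be > 0")
  }
  if (!is_count(object@minFocalCells)) msg <- c(msg, "'minFocalCells' must be an integer >= 1")
  if (length(object@densityScope) != 1L ||
      !object@densityScope %in% c("full_map", "buffer_interior")) {
    msg <- c(msg, "'densityScope' must be \"full_map\" or \"buffer_interior\"")
  }
  if (length(msg)) msg else TRUE
})

#' @param annulusWidthCells,maxRadiusCells,minFocalCells,densityScope see slots.
#' @rdname PcfConfig-class
#' @export
PcfConfig <- function(annulusWidthCells = 2, maxRadiusCells = 50,
                      minFocalCells = 100L, densityScope = "full_map") {
  new("PcfConfig", annulusWidthCells = annulusWidthCells,
      maxRadiusCells = maxRadiusCells, minFocalCells = as.integer(minFocalCells),
      densityScope = densityScope)
}

#' Resampling configuration for g(r) confidence intervals
#'
#' Parameters of the half-population resampling scheme: number of draws,
#' the fraction of occupied cells per draw (without replacement), the
#' two-sided confidence level complement, and the seed.  The defaults (999
#' draws of half the population at alpha = 0.05) place the interval at the
#' 25th-lowest and 25th-highest resampled g(r) values.
#'
#' @slot nDraws number of resampling draws (>= 1).
#' @slot sampleFraction fraction of occupied cells per draw, in (0,1).
#' @slot alpha two-sided confidence-level complement in (0,1).
#' @slot seed integer seed for the draws.
#' @slot sharedDraws if `TRUE` (default) one draw yields one full g(r)
#'   curve shared across radii; if `FALSE` independent draws are made per
#'   radius.
#' @slot densityFrom `"subsample"` (default; each draw's g is normalized
#'   by the subsample's own density) or `"full"` (the full-map density).
#' @export
setClass("ResamplingConfig", representation(
  nDraws = "integer",
  sampleFraction = "numeric",
  alpha = "numeric",
  seed = "integer",
  sharedDraws = "logical",
  densityFrom = "character"
))

setValidity("ResamplingConfig", function(object) {
  msg <- character()
  if (!is_count(object@nDraws)) msg <- c(msg, "'nDraws' must be an integer >= 1")
  f <- object@sampleFraction
  if (!is_scalar_num(f) || f <= 0 || f >= 1) {
    msg <- c(msg, "'sampleFraction' must lie in (0, 1)")
  }
  a <- object@alpha
  if (!is_scalar_num(a) || a <= 0 || a >= 1) msg <- c(msg, "'alpha' must lie in (0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed)) msg <- c(msg, "'seed' must be an integer")
  if (length(object@sharedDraws) != 1L || is.na(object@sharedDraws)) {
    msg <- c(msg, "'sharedDraws' must be TRUE or FALSE")
  }
  if (length(object@densityFrom) != 1L ||
      !object@densityFrom %in% c("subsample", "full")) {
    msg <- c(msg, "'densityFrom' must be \"subsample\" or \"full\"")
  }
  if (length(msg)) msg else TRUE
})

#' @param nDraws,sampleFraction,alpha,seed,sharedDraws,densityFrom see slots.
#' @rdname ResamplingConfig-class
#' @export
ResamplingConfig <- function(nDraws = 999L, sampleFraction = 0.5, alpha = 0.05,
                             seed = 1L, sharedDraws = TRUE,
                             densityFrom = "subsample") {
  new("ResamplingConfig", nDraws = as.integer(nDraws),
      sampleFraction = sampleFraction, alpha = alpha, seed = as.integer(seed),
      sharedDraws = sharedDraws, densityFrom = densityFrom)
}

#' Ground-truth parameters of a synthetic colonization scene
#'
#' Describes a point pattern on a physical window.  Pattern kinds:
#' \describe{
#'   \item{`csr`}{complete spatial randomness: each raster cell occupied
#'     independently with probability `density`.}
#'   \item{`thomas`}{Thomas cluster process: Poisson parents at
#'     `clusterParentIntensity` per um^2, each with a Poisson
#'     (`clusterOffspringMean`) number of offspring displaced by an
#'     isotropic Gaussian of sd `clusterSigmaUm`; a cell is occupied if at
#'     least one point falls in it.}
#'   \item{`polyp_lattice`}{hexagonal lattice of polyp centres with
#'     spacing `polypSpacingUm` (optionally jittered by `polypJitterUm`);
#'     cells whose centre lies within `polypRadiusUm` of a polyp centre
#'     are never occupied; ridge cells (beyond the exclusion radius) are
#'     occupied with probability `ridgeOccupancy`, thinned to clustered
#'     micro-patches (kept only within 2 x `clusterSigmaUm` of a sparse
#'     Poisson set of patch seeds at `clusterParentIntensity`).}
#'   \item{`full` / `empty`}{all cells occupied / none occupied.}
#' }
#'
#' Defaults emulate a 2.8 x 2.4 mm field of view of bleached *Porites*
#' with polyps ~500 um across spaced ~600 um apart and algal micro-patches
#' ~100 um in size on the ridges between polyps.
#'
#' @slot windowWidthUm,windowHeightUm physical extent of the scene.
#' @slot patternKind one of `"csr"`, `"thomas"`, `"polyp_lattice"`,
#'   `"full"`, `"empty"`.
#' @slot density expected occupied fraction in (0,1] (csr).
#' @slot clusterParentIntensity parents (or patch seeds) per um^2.
#' @slot clusterOffspringMean expected points per parent (thomas).
#' @slot clusterSigmaUm Gaussian offspring spread / half patch radius, um.
#' @slot polypSpacingUm centre-to-centre lattice spacing, um.
#' @slot polypRadiusUm exclusion radius around each polyp centre, um;
#'   must be less than half the spacing.
#' @slot polypJitterUm sd of isotropic jitter applied to lattice centres.
#' @slot ridgeOccupancy probability of algae on (patch-covered) ridge cells.
#' @slot seed integer seed.
#' @export
setClass("SceneParams", representation(
  windowWidthUm = "numeric",
  windowHeightUm = "numeric",
  patternKind = "character",
  density = "numeric",
  clusterParentIntensity = "numeric",
  clusterOffspringMean = "numeric",
  clusterSigmaUm = "numeric",
  polypSpacingUm = "numeric",
  polypRadiusUm = "numeric",
  polypJitterUm = "numeric",
  ridgeOccupancy = "numeric",
  seed = "integer"
))

setValidity("SceneParams", function(object) {
  msg <- character()
  kinds <- c("csr", "thomas", "polyp_lattice", "full", "empty")
  if (length(object@patternKind) != 1L || !object@patternKind %in% kinds) {
    msg <- c(msg, sprintf("'patternKind' must be one of: %s",
                          paste(kinds, collapse = ", ")))
  }
  for (s in c("windowWidthUm", "windowHeightUm", "clusterSigmaUm",
              "polypSpacingUm", "polypRadiusUm")) {
    v <- slot(object, s)
    if (!is_scalar_num(v) || v <= 0) {
      msg <- c(msg, sprintf("'%s' must be a single positive length", s))
    }
  }
  if (!is_scalar_num(object@density) || object@density <= 0 || object@density > 1) {
    msg <- c(msg, "'density' must lie in (0, 1]")
  }
  if (is_scalar_num(object@polypRadiusUm) && is_scalar_num(object@polypSpacingUm) &&
      object@polypRadiusUm >= object@polypSpacingUm / 2) {
    msg <- c(msg, "'polypRadiusUm' must be less than polypSpacingUm / 2")
  }
  if (!is_scalar_num(object@polypJitterUm) || object@polypJitterUm < 0) {
    msg <- c(msg, "'polypJitterUm' must be >= 0")
  }
  r <- object@ridgeOccupancy
  if (!is_scalar_num(r) || r < 0 || r > 1) {
    msg <- c(msg, "'ridgeOccupancy' must lie in [0, 1]")
  }
  if (!is_scalar_num(object@clusterParentIntensity) || object@clusterParentIntensity <= 0) {
    msg <- c(msg, "'clusterParentIntensity' must be > 0")
  }
  if (!is_scalar_num(object@clusterOffspringMean) || object@clusterOffspringMean <= 0) {
    msg <- c(msg, "'clusterOffspringMean' must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param windowWidthUm,windowHeightUm,patternKind,density see slots.
#' @param clusterParentIntensity,clusterOffspringMean,clusterSigmaUm see slots.
#' @param polypSpacingUm,polypRadiusUm,polypJitterUm,ridgeOccupancy,seed see slots.
#' @rdname SceneParams-class
#' @export
SceneParams <- function(windowWidthUm = 2815.2, windowHeightUm = 2355.2,
                        patternKind = "csr", density = 0.3,
                        clusterParentIntensity = 3e-5,
                        clusterOffspringMean = 40, clusterSigmaUm = 50,
                        polypSpacingUm = 600, polypRadiusUm = 250,
                        polypJitterUm = 20, ridgeOccupancy = 0.6,
                        seed = 1L) {
  new("SceneParams", windowWidthUm = windowWidthUm,
      windowHeightUm = windowHeightUm, patternKind = patternKind,
      density = density, clusterParentIntensity = clusterParentIntensity,
      clusterOffspringMean = clusterOffspringMean,
      clusterSigmaUm = clusterSigmaUm, polypSpacingUm = polypSpacingUm,
      polypRadiusUm = polypRadiusUm, polypJitterUm = polypJitterUm,
      ridgeOccupancy = ridgeOccupancy, seed = as.integer(seed))
}

#' Rendering parameters for synthetic scenes
#'
#' Controls how a presence/absence raster is drawn as an RGB image:
#' bleached coral tissue reflects light nearly evenly (low saturation)
#' while algae absorb preferentially (high saturation), so occupied cells
#' are rendered with a higher-saturation colour than the background, plus
#' additive per-channel pixel noise.
#'
#' @slot backgroundSaturationMean,backgroundSaturationSd background
#'   saturation distribution, values in \[0,1\].
#' @slot algaeSaturationMean,algaeSaturationSd algal saturation
#'   distribution; the mean must exceed the background mean.
#' @slot pixelNoiseSd sd of additive Gaussian RGB noise.
#' @slot filamentRadiusPx half-width of the rendered algal feature, in
#'   rendered pixels: pixels within this Euclidean distance of an occupied
#'   cell's centre are drawn as algae.
#' @slot seed integer seed.
#' @export
setClass("RenderParams", representation(
  backgroundSaturationMean = "numeric",
  backgroundSaturationSd = "numeric",
  algaeSaturationMean = "numeric",
  algaeSaturationSd = "numeric",
  pixelNoiseSd = "numeric",
  filamentRadiusPx = "numeric",
  seed = "integer"
))

setValidity("RenderParams", function(object) {
  msg <- character()
  for (s in c("backgroundSaturationMean", "backgroundSaturationSd",
              "algaeSaturationMean", "algaeSaturationSd")) {
    v <- slot(object, s)
    if (!is_scalar_num(v) || v < 0 || v > 1) {
      msg <- c(msg, sprintf("'%s' must lie in [0, 1]", s))
    }
  }
  if (is_scalar_num(object@backgroundSaturationMean) &&
      is_scalar_num(object@algaeSaturationMean) &&
      object@backgroundSaturationMean >= object@algaeSaturationMean) {
    msg <- c(msg, "'backgroundSaturationMean' must be below 'algaeSaturationMean'")
  }
  if (!is_scalar_num(object@pixelNoiseSd) || object@pixelNoiseSd < 0) {
    msg <- c(msg, "'pixelNoiseSd' must be >= 0")
  }
  if (!is_scalar_num(object@filamentRadiusPx) || object@filamentRadiusPx <= 0) {
    msg <- c(msg, "'filamentRadiusPx' must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param backgroundSaturationMean,backgroundSaturationSd see slots.
#' @param algaeSaturationMean,algaeSaturationSd,pixelNoiseSd see slots.
#' @param filamentRadiusPx,seed see slots.
#' @rdname RenderParams-class
#' @export
RenderParams <- function(backgroundSaturationMean = 0.05,
                         backgroundSaturationSd = 0.02,
                         algaeSaturationMean = 0.6,
                         algaeSaturationSd = 0.05,
                         pixelNoiseSd = 0.01, filamentRadiusPx = 12,
                         seed = 1L) {
  new("RenderParams",
      backgroundSaturationMean = backgroundSaturationMean,
      backgroundSaturationSd = backgroundSaturationSd,
      algaeSaturationMean = algaeSaturationMean,
      algaeSaturationSd = algaeSaturationSd,
      pixelNoiseSd = pixelNoiseSd, filamentRadiusPx = filamentRadiusPx,
      seed = as.integer(seed))
}

#' Categorical presence/absence raster map
#'
#' The central data object of the pipeline: a logical matrix marking which
#' grid cells contain algae, together with the physical cell side in
#' micrometres.  Rows run from the top of the image down; cell centres lie
#' at (row - 0.5, col - 0.5) in cell units.
#'
#' @slot occupancy logical matrix (rows x cols), no missing values.
#' @slot cellSizeUm physical cell side, um (> 0).
#' @export
setClass("RasterMap", representation(
  occupancy = "matrix",
  cellSizeUm = "numeric"
))

setValidity("RasterMap", function(object) {
  msg <- character()
  occ <- object@occupancy
  if (!is.logical(occ)) msg <- c(msg, "'occupancy' must be a logical matrix")
  if (anyNA(occ)) msg <- c(msg, "'occupancy' must not contain NA")
  if (nrow(occ) < 1L || ncol(occ) < 1L) msg <- c(msg, "'occupancy' must be non-empty")
  if (!is_scalar_num(object@cellSizeUm) || object@cellSizeUm <= 0) {
    msg <- c(msg, "'cellSizeUm' must be a single positive value")
  }
  if (length(msg)) msg else TRUE
})

#' @param occupancy,cellSizeUm see slots.
#' @rdname RasterMap-class
#' @export
RasterMap <- function(occupancy, cellSizeUm = 18.4) {
  if (is.numeric(occupancy)) {
    if (!all(occupancy %in% c(0, 1))) {
      stop("numeric 'occupancy' must contain only 0 and 1", call. = FALSE)
    }
    occupancy <- matrix(as.logical(occupancy), nrow(occupancy), ncol(occupancy))
  }
  new("RasterMap", occupancy = occupancy, cellSizeUm = cellSizeUm)
}

#' Pair-correlation function estimate
#'
#' Holds the grid-based g(r) curve: one row per distance class with the
#' ring midpoint in cell units and micrometres, the relative neighbourhood
#' density g, the number of buffer-valid focal cells, the total
#' point-to-point neighbour count accumulated, and a validity flag
#' (n_focal at or above the minimum-focal-cell rule).
#'
#' @slot table data.frame with columns `r_cells`, `r_um`, `g`, `n_focal`,
#'   `n_pairs`, `valid`.
#' @slot ringCells integer vector: number of grid cells per annulus.
#' @slot overallDensity occupied fraction p used to normalize (full map
#'   unless `densityScope = "buffer_interior"`, in which case per-radius
#'   densities are used and this slot stores the full-map p for reference).
#' @slot annulusWidthCells,minFocalCells,cellSizeUm estimator settings.
#' @export
setClass("PcfResult", representation(
  table = "data.frame",
  ringCells = "integer",
  overallDensity = "numeric",
  annulusWidthCells = "numeric",
  minFocalCells = "integer",
  cellSizeUm = "numeric"
))

setValidity("PcfResult", function(object) {
  msg <- character()
  tb <- object@table
  need <- c("r_cells", "r_um", "g", "n_focal", "n_pairs", "valid")
  if (!all(need %in% names(tb))) {
    msg <- c(msg, sprintf("table must have columns: %s", paste(need, collapse = ", ")))
  } else {
    if (nrow(tb) > 1 && any(diff(tb$r_cells) <= 0)) {
      msg <- c(msg, "radii must be strictly increasing")
    }
    if (any(!is.na(tb$g) & tb$g < 0)) msg <- c(msg, "g must be >= 0")
    if (length(object@ringCells) == nrow(tb) &&
        any(tb$n_pairs > as.numeric(tb$n_focal) * object@ringCells)) {
      msg <- c(msg, "n_pairs cannot exceed n_focal x annulus cell count")
    }
  }
  if (length(msg)) msg else TRUE
})

#' g(r) with resampling confidence intervals and CSR classification
#'
#' Wraps a point-estimate [PcfResult-class] with per-radius confidence
#' bounds from order statistics of the resampled g(r) values and a
#' three-way classification: `"clustered"` when the whole interval lies
#' above 1, `"regular"` when it lies below 1, `"csr_consistent"`
#' otherwise; radii invalid in the point estimate are `NA`.
#'
#' @slot pcf the point-estimate [PcfResult-class].
#' @slot ciLo,ciHi per-radius confidence bounds.
#' @slot classification character vector per radius.
#' @slot config the [ResamplingConfig-class] used.
#' @export
setClass("CiResult", representation(
  pcf = "PcfResult",
  ciLo = "numeric",
  ciHi = "numeric",
  classification = "character",
  config = "ResamplingConfig"
))

setValidity("CiResult", function(object) {
  msg <- character()
  n <- nrow(object@pcf@table)
  if (length(object@ciLo) != n || length(object@ciHi) != n ||
      length(object@classification) != n) {
    msg <- c(msg, "ciLo, ciHi and classification must have one entry per radius")
  }
  bad <- !is.na(object@ciLo) & !is.na(object@ciHi) & object@ciLo > object@ciHi
  if (any(bad)) msg <- c(msg, "ciLo must not exceed ciHi")
  cls <- object@classification
  ok <- is.na(cls) | cls %in% c("clustered", "regular", "csr_consistent")
  if (!all(ok)) msg <- c(msg, "invalid classification label")
  if (length(msg)) msg else TRUE
})

#' Critical-scale summary of a classified g(r) curve
#'
#' Condenses the classified pair-correlation curve into the three critical
#' scales of the colonization pattern: the extent of small-scale
#' aggregation, the location and depth of the intermediate-scale exclusion
#' dip, and the radius at which the pattern returns to CSR, plus a
#' large-scale homogeneity flag.  Fields are `NA` when the corresponding
#' feature is absent.
#'
#' @slot aggregationExtentUm largest radius of the unbroken run of
#'   clustered classes from the smallest valid radius.
#' @slot dipRadiusUm,dipG location and value of the g minimum (the dip is
#'   only reported when the minimum is classified regular).
#' @slot returnRadiusUm smallest radius beyond the dip classified
#'   csr_consistent.
#' @slot homogeneous large-radius homogeneity diagnostic (g trending to 1).
#' @export
setClass("ScaleSummary", representation(
  aggregationExtentUm = "numeric",
  dipRadiusUm = "numeric",
  dipG = "numeric",
  returnRadiusUm = "numeric",
  homogeneous = "logical"
))

setValidity("ScaleSummary", function(object) {
  if (!is.na(object@aggregationExtentUm) && !is.na(object@dipRadiusUm) &&
      object@dipRadiusUm < object@aggregationExtentUm) {
    "dipRadiusUm must be >= aggregationExtentUm when both are defined"
  } else TRUE
})
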