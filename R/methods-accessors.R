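#' @rdname RasterMap-class
#' @export
setMethod("occupancy", "RasterMap", function(object) object@occupancy)

#' @rdname RasterMap-class
#' @export
setMethod("cellSizeUm", "RasterMap", function(object) object@cellSizeUm)

#' @rdname PcfResult-class
#' @export
setMethod("cellSizeUm", "PcfResult", function(object) object@cellSizeUm)

#' @rdname RasterMap-class
#' @export
setMethod("dim", "RasterMap", function(x) dim(x@occupancy))

#' Number of occupied cells
#' @param raster a [RasterMap-class].
#' @return integer count of occupied cells.
#' @export
nOccupied <- function(raster) sum(raster@occupancy)

#' @rdname PcfResult-class
#' @export
setMethod("pcfTable", "PcfResult", function(object) object@table)

#' @rdname PcfResult-class
#' @export
setMethod("overallDensity", "PcfResult", function(object) object@overallDensity)

#' @rdname CiResult-class
#' @export
setMethod("pcfTable", "CiResult", function(object) object@pcf@table)

#' @rdname CiResult-class
#' @export
setMethod("classifications", "CiResult", function(object) object@classification)

#' @rdname CiResult-class
#' @export
setMethod("ciBounds", "CiResult", function(object) {
  data.frame(r_um = object@pcf@table$r_um,
             ci_lo = object@ciLo, ci_hi = object@ciHi)
})

#' @rdname CiResult-class
#' @param ... unused.
#' @export
setMethod("as.data.frame", "CiResult", function(x, ...) {
  tb <- x@pcf@table
  data.frame(r_cells = tb$r_cells, r_um = tb$r_um, g = tb$g,
             ci_lo = x@ciLo, ci_hi = x@ciHi,
             n_focal = tb$n_focal, n_pairs = tb$n_pairs, valid = tb$valid,
             classification = x@classification,
             stringsAsFactors = FALSE)
})

#' @rdname PcfResult-class
#' @param x,... object and unused arguments.
#' @export
setMethod("as.data.frame", "PcfResult", function(x, ...) x@table)

#' @rdname ScaleSummary-class
#' @export
setMethod("as.data.frame", "ScaleSummary", function(x, ...) {
  data.frame(aggregation_extent_um = x@aggregationExtentUm,
             dip_radius_um = x@dipRadiusUm, dip_g = x@dipG,
             return_radius_um = x@returnRadiusUm, homogeneous = x@homogeneous)
})

setMethod("show", "RasterMap", function(object) {
  d <- dim(object@occupancy)
  n <- sum(object@occupancy)
  cat(sprintf("RasterMap: %d x %d cells (%.4g um/cell), %d occupied (%.1f%%)\n",
              d[1], d[2], object@cellSizeUm, n, 100 * n / prod(d)))
})

setMethod("show", "PcfResult", function(object) {
  tb <- object@table
  cat(sprintf("PcfResult: %d distance classes (annulus width %g cells, cell %.4g um)\n",
              nrow(tb), object@annulusWidthCells, object@cellSizeUm))
  cat(sprintf("  overall density p = %.4f; %d/%d radii valid (>= %d focal cells)\n",
              object@overallDensity, sum(tb$valid), nrow(tb), object@minFocalCells))
  print(head(tb, 6), row.names = FALSE)
  if (nrow(tb) > 6) cat(sprintf("  ... %d more radii\n", nrow(tb) - 6))
})

setMethod("show", "CiResult", function(object) {
  cls <- object@classification
  cat(sprintf("CiResult: %d radii, %d draws of fraction %.2f (alpha %.3g)\n",
              length(cls), object@config@nDraws, object@config@sampleFraction,
              object@config@alpha))
  tab <- table(factor(cls, levels = c("clustered", "regular", "csr_consistent")))
  cat(sprintf("  clustered %d | regular %d | csr_consistent %d | unclassified %d\n",
              tab[1], tab[2], tab[3], sum(is.na(cls))))
})

setMethod("show", "ScaleSummary", function(object) {
  fmt <- function(v, unit = " um") if (is.na(v)) "undefined" else sprintf("%.1f%s", v, unit)
  cat("ScaleSummary:\n")
  cat("  aggregation extent:", fmt(object@aggregationExtentUm), "\n")
  cat("  dip radius:        ", fmt(object@dipRadiusUm),
      if (!is.na(object@dipG)) sprintf("(g = %.3f)", object@dipG) else "", "\n")
  cat("  return radius:     ", fmt(object@returnRadiusUm), "\n")
  cat("  homogeneous:       ",
      if (is.na(object@homogeneous)) "indeterminate" else object@homogeneous, "\n")
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf("SceneParams: %s pattern on %.4g x %.4g um window (seed %d)\n",
              object@patternKind, object@windowWidthUm, object@windowHeightUm,
              object@seed))
})
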