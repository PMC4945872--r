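# Grid-based (O-ring) pair-correlation function with buffer-zone edge
# correction, after the Wiegand-Moloney neighbourhood-density estimator.

# Ring midpoints for a config: odd multiples of w/2 up to maxRadiusCells,
# i.e. the non-overlapping distance classes [0,w), [w,2w), ...
ring_midpoints <- function(cfg) {
  w <- cfg@annulusWidthCells
  K <- floor(cfg@maxRadiusCells / w + 0.5)
  if (K < 1L) stop("'maxRadiusCells' admits no ring", call. = FALSE)
  (2 * seq_len(K) - 1) * w / 2
}

#' Integer cell offsets forming an annulus
#'
#' All cell offsets `(di, dj) != (0, 0)` whose centre-to-centre Euclidean
#' distance falls in the half-open class
#' `[rCells - width/2, rCells + width/2)`.  Comparisons are made on
#' squared distances so integer boundaries (e.g. distance exactly 2) bin
#' deterministically: each pair of cells falls in exactly one ring.
#'
#' @param rCells ring midpoint in cell units (> 0).
#' @param widthCells ring width in cell units (>= 1).
#' @return integer matrix with columns `di`, `dj`.
#' @examples
#' nrow(ringOffsets(1, 2))  # the 8-neighbourhood
#' @export
ringOffsets <- function(rCells, widthCells = 2) {
  if (!is_scalar_num(rCells) || rCells <= 0) stop("'rCells' must be > 0", call. = FALSE)
  lo <- max(0, rCells - widthCells / 2)
  hi <- rCells + widthCells / 2
  rmax <- ceiling(hi)
  dd <- seq.int(-rmax, rmax)
  di <- rep(dd, times = length(dd))
  dj <- rep(dd, each = length(dd))
  d2 <- di^2 + dj^2
  keep <- d2 >= lo * lo & d2 < hi * hi & d2 > 0
  cbind(di = as.integer(di[keep]), dj = as.integer(dj[keep]))
}

#' Occupied focal cells whose annulus fits inside the grid
#'
#' Buffer-zone edge correction: a focal cell contributes to a distance
#' class only if its entire annulus lies within the imaged area.  Returns
#' the occupied cells for which every ring offset lands inside the grid.
#'
#' @param raster a [RasterMap-class].
#' @param rCells,widthCells ring midpoint and width in cell units.
#' @return integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
bufferValidFocals <- function(raster, rCells, widthCells = 2) {
  stopifnot(is(raster, "RasterMap"))
  occ <- raster@occupancy
  off <- ringOffsets(rCells, widthCells)
  m <- if (nrow(off)) max(abs(off)) else 0L
  nr <- nrow(occ); nc <- ncol(occ)
  if (2 * m >= nr || 2 * m >= nc) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  idx <- which(occ, arr.ind = TRUE)
  keep <- idx[, 1] > m & idx[, 1] <= nr - m & idx[, 2] > m & idx[, 2] <= nc - m
  out <- idx[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

# Shared assembly of a PcfResult from per-ring counts.
build_pcf_result <- function(r_cells, counts, nfocal, ringcells, margins,
                             raster, cfg) {
  nr <- nrow(raster@occupancy); nc <- ncol(raster@occupancy)
  n_occ <- sum(raster@occupancy)
  p_full <- n_occ / (nr * nc)
  if (cfg@densityScope == "buffer_interior") {
    p <- vapply(seq_along(r_cells), function(k) {
      m <- margins[k]
      if (2 * m >= nr || 2 * m >= nc) return(NA_real_)
      sum(raster@occupancy[(m + 1):(nr - m), (m + 1):(nc - m)]) /
        ((nr - 2 * m) * (nc - 2 * m))
    }, numeric(1))
  } else {
    p <- rep(p_full, length(r_cells))
  }
  denom <- as.numeric(nfocal) * ringcells
  g <- ifelse(nfocal > 0 & !is.na(p) & p > 0, (counts / denom) / p, NA_real_)
  tb <- data.frame(
    r_cells = r_cells,
    r_um = r_cells * raster@cellSizeUm,
    g = g,
    n_focal = as.integer(nfocal),
    n_pairs = counts,
    valid = nfocal >= cfg@minFocalCells & !is.na(g)
  )
  new("PcfResult", table = tb, ringCells = as.integer(ringcells),
      overallDensity = p_full, annulusWidthCells = cfg@annulusWidthCells,
      minFocalCells = cfg@minFocalCells, cellSizeUm = raster@cellSizeUm)
}

#' Grid-based pair-correlation function g(r)
#'
#' For each distance class the estimator counts, around every buffer-valid
#' occupied focal cell, the occupied cells in the annulus; divides the
#' summed counts by the summed annulus cell counts (the grid analogue of
#' annulus area); and normalizes by the overall occupied fraction p of the
#' map.  `g = 1` is the complete-spatial-randomness reference, `g > 1`
#' aggregation, `g < 1` regularity.  Radii with fewer than
#' `minFocalCells` usable focal cells are reported but flagged invalid.
#'
#' @param raster a [RasterMap-class] with at least one occupied cell.
#' @param cfg a [PcfConfig-class].
#' @return a [PcfResult-class].
#' @examples
#' r <- generateRaster(SceneParams(patternKind = "csr", density = 0.3, seed = 1))
#' head(pcfTable(gridPCF(r, PcfConfig(maxRadiusCells = 10))))
#' @export
gridPCF <- function(raster, cfg = PcfConfig()) {
  stopifnot(is(raster, "RasterMap"), is(cfg, "PcfConfig"))
  validObject(cfg)
  if (!any(raster@occupancy)) stop("raster has no occupied cells", call. = FALSE)
  r_cells <- ring_midpoints(cfg)
  w <- cfg@annulusWidthCells
  offs <- lapply(r_cells, ringOffsets, widthCells = w)
  res <- cpp_ring_counts(raster@occupancy, offs)
  ringcells <- vapply(offs, nrow, integer(1))
  margins <- vapply(offs, function(o) if (nrow(o)) max(abs(o)) else 0L, integer(1))
  build_pcf_result(r_cells, res$count, res$n_focal, ringcells, margins,
                   raster, cfg)
}
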