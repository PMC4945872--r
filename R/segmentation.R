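# Image -> saturation -> mask -> raster, plus imaging-geometry arithmetic.

# Block-average a matrix by an integer factor, dropping trailing rows and
# columns that do not fill a block.
bin_matrix <- function(m, factor) {
  nr <- (nrow(m) %/% factor) * factor
  nc <- (ncol(m) %/% factor) * factor
  if (nr < factor || nc < factor) {
    stop("binning factor exceeds image dimensions", call. = FALSE)
  }
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  m1 <- colMeans(array(m, dim = c(factor, nr / factor, nc)), dims = 1)
  t(colMeans(array(t(m1), dim = c(factor, nc / factor, nr / factor)), dims = 1))
}

#' Object-space length imaged onto a run of sensor pixels
#'
#' The physical size (in micrometres) of the object region imaged onto
#' `nPx` contiguous sensor pixels: `nPx * pixelPitchUm / magnification`.
#' With a 3.45 um pitch and a 3x objective, 16 pixels correspond to
#' 18.4 um and the full 2,448-pixel sensor width to 2,815.2 um (2.82 mm).
#'
#' @param geom an [OpticalGeometry-class].
#' @param nPx number of sensor pixels (>= 1).
#' @return length in micrometres.
#' @examples
#' objectSpaceLength(OpticalGeometry(), 16)   # 18.4
#' @export
objectSpaceLength <- function(geom, nPx) {
  stopifnot(is(geom, "OpticalGeometry"))
  if (!is.numeric(nPx) || any(nPx < 1)) stop("'nPx' must be >= 1", call. = FALSE)
  nPx * geom@pixelPitchUm / geom@magnification
}

#' Average pixel neighbourhoods to reduce noise
#'
#' Replaces each `factor` x `factor` block with its per-channel arithmetic
#' mean; trailing rows/columns that do not fill a block are dropped, so
#' the output dimensions are `floor(dim / factor)`.  `factor = 1` is the
#' identity.
#'
#' @param image numeric array (height, width, 3) with intensities in
#'   \[0,1\], or a single-channel matrix.
#' @param factor integer averaging factor >= 1.
#' @return binned image of the same kind as the input.
#' @export
binPixels <- function(image, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be >= 1", call. = FALSE)
  if (factor == 1L) return(image)
  if (is.matrix(image)) return(bin_matrix(image, factor))
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  ch <- lapply(1:3, function(k) bin_matrix(image[, , k], factor))
  out <- array(0, dim = c(nrow(ch[[1]]), ncol(ch[[1]]), 3))
  for (k in 1:3) out[, , k] <- ch[[k]]
  out
}

#' Per-pixel HSV saturation of an RGB image
#'
#' Standard HSV saturation: `S = (max(R,G,B) - min(R,G,B)) / max(R,G,B)`,
#' defined as 0 where the maximum channel is 0.  Bleached coral tissue
#' reflects nearly evenly (equal channels, S near 0), while algae absorb
#' preferentially and show high S, which is what the downstream threshold
#' exploits.
#'
#' @param image numeric array (height, width, 3), intensities in \[0,1\].
#' @return matrix of saturations in \[0,1\].
#' @export
rgbToSaturation <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (min(image) < 0 || max(image) > 1) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- matrix(image[, , 1], h, w)
  g <- matrix(image[, , 2], h, w)
  b <- matrix(image[, , 3], h, w)
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  s <- matrix(0, h, w)
  pos <- mx > 0
  s[pos] <- (mx[pos] - mn[pos]) / mx[pos]
  s
}

#' Threshold a saturation map into an algae mask
#'
#' A pixel is flagged as algae iff its saturation strictly exceeds the
#' threshold (`S > t`); pixels exactly at the threshold are background.
#' Lowering the threshold can therefore only add algae pixels, never
#' remove them.
#'
#' @param s saturation matrix in \[0,1\].
#' @param threshold saturation cut in (0,1); 0.25 is the conventional
#'   value, with 0.22 and 0.28 as sensitivity alternatives.
#' @return logical matrix, `TRUE` = algae.
#' @export
thresholdSaturation <- function(s, threshold = 0.25) {
  if (!is_scalar_num(threshold) || threshold <= 0 || threshold >= 1) {
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  }
  s > threshold
}

#' Segment an RGB image into an algae pixel mask
#'
#' The full pixel chain in the conventional order: average `binFactor` x
#' `binFactor` pixel neighbourhoods, convert to HSV saturation, apply the
#' global threshold.
#'
#' @param image numeric array (height, width, 3).
#' @param cfg a [SegmentationConfig-class].
#' @return logical matrix in binned-pixel coordinates.
#' @export
segmentImage <- function(image, cfg = SegmentationConfig()) {
  stopifnot(is(cfg, "SegmentationConfig"))
  validObject(cfg)
  binned <- binPixels(image, cfg@binFactor)
  thresholdSaturation(rgbToSaturation(binned), cfg@saturationThreshold)
}

#' Rasterize an algae mask to a categorical presence/absence grid
#'
#' Divides the (binned-pixel) mask into cells of `cellPx / binFactor`
#' binned pixels on a side and marks a cell occupied iff the fraction of
#' algae pixels inside it is at least `occupancyFraction`.  Trailing
#' partial cells are dropped, so a 2,448 x 2,050 pixel frame with 16-pixel
#' cells yields a 153 x 128 grid.  The physical cell side comes from the
#' optical geometry (`cellPx` sensor pixels in object space).
#'
#' @param mask logical matrix from [segmentImage()] (binned pixels).
#' @param cfg a [SegmentationConfig-class].
#' @param geom an [OpticalGeometry-class], used for the physical cell
#'   size; alternatively pass `cellSizeUm` directly.
#' @param cellSizeUm physical cell side override (um).
#' @return a [RasterMap-class].
#' @export
rasterizeMask <- function(mask, cfg = SegmentationConfig(),
                          geom = OpticalGeometry(), cellSizeUm = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask), is(cfg, "SegmentationConfig"))
  validObject(cfg)
  if (cfg@cellPx %% cfg@binFactor != 0L) {
    stop("cell size in post-binning pixels (cellPx / binFactor) must be an integer",
         call. = FALSE)
  }
  cell_bp <- cfg@cellPx %/% cfg@binFactor
  n_rows <- nrow(mask) %/% cell_bp
  n_cols <- ncol(mask) %/% cell_bp
  if (n_rows < 1L || n_cols < 1L) {
    stop("mask smaller than one raster cell", call. = FALSE)
  }
  frac <- bin_matrix(matrix(as.numeric(mask), nrow(mask), ncol(mask)), cell_bp)
  # compare via counts to keep the boundary exact in floating point
  counts <- round(frac * cell_bp^2)
  occ <- counts >= cfg@occupancyFraction * cell_bp^2 - 1e-9
  if (is.null(cellSizeUm)) {
    cellSizeUm <- objectSpaceLength(geom, cfg@cellPx)
  }
  RasterMap(occ, cellSizeUm = cellSizeUm)
}

#' Full image-to-raster convenience wrapper
#'
#' @inheritParams rasterizeMask
#' @param image numeric array (height, width, 3).
#' @return a [RasterMap-class].
#' @export
imageToRaster <- function(image, cfg = SegmentationConfig(),
                          geom = OpticalGeometry(), cellSizeUm = NULL) {
  rasterizeMask(segmentImage(image, cfg), cfg, geom, cellSizeUm)
}
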