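# Synthetic colonization scenes with known ground truth.

# Hexagonal lattice of polyp centres covering the window plus one spacing
# of margin on every side; optional isotropic Gaussian jitter.
hex_lattice <- function(width_um, height_um, spacing_um, jitter_um = 0) {
  row_h <- spacing_um * sqrt(3) / 2
  rows <- seq(-1, ceiling(height_um / row_h) + 1)
  centres <- do.call(rbind, lapply(rows, function(j) {
    xoff <- if (j %% 2 == 0) 0 else spacing_um / 2
    xs <- seq(-spacing_um, width_um + spacing_um, by = spacing_um) + xoff
    cbind(x = xs, y = j * row_h)
  }))
  if (jitter_um > 0) {
    centres[, 1] <- centres[, 1] + rnorm(nrow(centres), sd = jitter_um)
    centres[, 2] <- centres[, 2] + rnorm(nrow(centres), sd = jitter_um)
  }
  centres
}

# Minimum distance from each query point (n x 2 matrix of x,y) to a set of
# reference points; loops over references, which are few.
min_dist_to <- function(px, py, refs) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(refs))) {
    d2 <- pmin(d2, (px - refs[i, 1])^2 + (py - refs[i, 2])^2)
  }
  sqrt(d2)
}

# Rasterize continuous points: a cell is occupied if at least one point
# falls inside it.
points_to_raster <- function(x, y, n_rows, n_cols, cell_um) {
  occ <- matrix(FALSE, n_rows, n_cols)
  keep <- x >= 0 & x < n_cols * cell_um & y >= 0 & y < n_rows * cell_um
  if (any(keep)) {
    col <- pmin(floor(x[keep] / cell_um) + 1L, n_cols)
    row <- pmin(floor(y[keep] / cell_um) + 1L, n_rows)
    occ[cbind(row, col)] <- TRUE
  }
  occ
}

#' Generate a synthetic presence/absence raster
#'
#' Draws a point pattern with the spatial structure requested in `params`
#' and rasterizes it onto a grid of `gridDims` cells.  Patterns: `"csr"`
#' (homogeneous Poisson reference: each cell occupied independently with
#' probability `density`), `"thomas"` (Poisson cluster process rasterized
#' by marking any cell containing at least one point), `"polyp_lattice"`
#' (hexagonal polyp exclusion with clustered micro-patches of algae on the
#' inter-polyp ridges), `"full"` and `"empty"`.
#'
#' Identical `params` (including the seed) give bit-identical rasters, and
#' the caller's RNG state is left untouched.
#'
#' @param params a [SceneParams-class].
#' @param gridDims integer vector `c(n_rows, n_cols)`; defaults to the
#'   window extent divided by `cellSizeUm`, floored.
#' @param cellSizeUm physical cell side; defaults to the window width
#'   divided by the number of columns when `gridDims` is given, else 18.4.
#' @return a [RasterMap-class].
#' @examples
#' r <- generateRaster(SceneParams(patternKind = "csr", density = 0.3, seed = 7))
#' dim(r)
#' @export
generateRaster <- function(params, gridDims = NULL, cellSizeUm = NULL) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  if (is.null(gridDims)) {
    if (is.null(cellSizeUm)) cellSizeUm <- 18.4
    # tolerance so an exact multiple is not floored away by the last ulp
    gridDims <- c(floor(params@windowHeightUm / cellSizeUm + 1e-9),
                  floor(params@windowWidthUm / cellSizeUm + 1e-9))
  } else if (is.null(cellSizeUm)) {
    cellSizeUm <- params@windowWidthUm / gridDims[2]
  }
  n_rows <- as.integer(gridDims[1])
  n_cols <- as.integer(gridDims[2])
  if (n_rows < 1L || n_cols < 1L) stop("'gridDims' must be positive", call. = FALSE)
  W <- n_cols * cellSizeUm
  H <- n_rows * cellSizeUm

  occ <- switch(params@patternKind,
    full = matrix(TRUE, n_rows, n_cols),
    empty = matrix(FALSE, n_rows, n_cols),
    csr = with_seed(params@seed, {
      matrix(runif(n_rows * n_cols) < params@density, n_rows, n_cols)
    }),
    thomas = with_seed(params@seed, {
      sig <- params@clusterSigmaUm
      margin <- 4 * sig
      area <- (W + 2 * margin) * (H + 2 * margin)
      n_par <- rpois(1, params@clusterParentIntensity * area)
      if (n_par == 0) {
        matrix(FALSE, n_rows, n_cols)
      } else {
        px <- runif(n_par, -margin, W + margin)
        py <- runif(n_par, -margin, H + margin)
        n_off <- rpois(n_par, params@clusterOffspringMean)
        x <- rep(px, n_off) + rnorm(sum(n_off), sd = sig)
        y <- rep(py, n_off) + rnorm(sum(n_off), sd = sig)
        points_to_raster(x, y, n_rows, n_cols, cellSizeUm)
      }
    }),
    polyp_lattice = with_seed(params@seed, {
      centres <- hex_lattice(W, H, params@polypSpacingUm, params@polypJitterUm)
      cx <- (rep(seq_len(n_cols), each = n_rows) - 0.5) * cellSizeUm
      cy <- (rep(seq_len(n_rows), times = n_cols) - 0.5) * cellSizeUm
      d_polyp <- min_dist_to(cx, cy, centres)
      ridge <- d_polyp >= params@polypRadiusUm
      # Matern-style micro-patch thinning: ridge cells survive only near a
      # sparse Poisson set of patch seeds, then occupy independently.
      n_seed <- rpois(1, params@clusterParentIntensity * W * H)
      patch_r <- 2 * params@clusterSigmaUm
      covered <- if (n_seed > 0) {
        seeds <- cbind(runif(n_seed, 0, W), runif(n_seed, 0, H))
        min_dist_to(cx, cy, seeds) <= patch_r
      } else {
        rep(FALSE, length(cx))
      }
      u <- runif(length(cx))
      matrix(ridge & covered & (u < params@ridgeOccupancy), n_rows, n_cols)
    }),
    stop(sprintf("unknown pattern kind '%s'", params@patternKind), call. = FALSE)
  )
  RasterMap(occ, cellSizeUm = cellSizeUm)
}

#' Render a raster as a synthetic RGB reflectance image
#'
#' Draws each raster cell as a `cellPx` x `cellPx` block of pixels.
#' Pixels within `filamentRadiusPx` of an occupied cell's centre take a
#' high-saturation algal colour; everything else takes the low-saturation
#' bleached-tissue background.  Saturations are drawn per pixel from
#' clamped Gaussians and additive RGB noise is applied last, so at zero
#' noise and zero saturation sd the segmentation chain recovers the input
#' raster exactly.
#'
#' @param raster a [RasterMap-class].
#' @param render a [RenderParams-class].
#' @param cellPx rendered pixels per raster cell side (default 16).
#' @return numeric array (height, width, 3) of RGB intensities in \[0,1\].
#' @export
renderScene <- function(raster, render, cellPx = 16L) {
  stopifnot(is(raster, "RasterMap"), is(render, "RenderParams"))
  validObject(render)
  occ <- raster@occupancy
  cellPx <- as.integer(cellPx)
  if (cellPx < 1L) stop("'cellPx' must be >= 1", call. = FALSE)
  h <- nrow(occ) * cellPx
  w <- ncol(occ) * cellPx
  # Per-cell filament template: pixel centres within filamentRadiusPx of
  # the cell centre (radius >= cellPx * sqrt(2)/2 fills the whole cell).
  u <- seq_len(cellPx) - 0.5 - cellPx / 2
  template <- outer(u^2, u^2, "+") <= render@filamentRadiusPx^2
  algae <- kronecker(occ, template) > 0 # h x w logical

  with_seed(render@seed, {
    n <- h * w
    s <- ifelse(algae,
                rnorm(n, render@algaeSaturationMean, render@algaeSaturationSd),
                rnorm(n, render@backgroundSaturationMean, render@backgroundSaturationSd))
    s <- clamp01(s)
    hue <- ifelse(algae, 1 / 3, 0.09)       # green algae on warm-grey coral
    val <- ifelse(algae, 0.55, 0.9)         # bleached tissue is bright
    rgb <- hsv_to_rgb(hue, s, val)
    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- rgb$r
    img[, , 2] <- rgb$g
    img[, , 3] <- rgb$b
    if (render@pixelNoiseSd > 0) {
      img <- img + array(rnorm(length(img), sd = render@pixelNoiseSd), dim = dim(img))
    }
    clamp01(img)
  })
}
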