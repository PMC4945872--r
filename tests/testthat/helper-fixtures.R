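# Shared fixtures built in code.

# Noise-free render settings for exact raster round trips.
exact_render <- function(seed = 1L) {
  RenderParams(backgroundSaturationSd = 0, algaeSaturationSd = 0,
               pixelNoiseSd = 0, seed = seed)
}

# A small PcfConfig suitable for hand-checkable rasters.
small_pcf <- function(maxRadiusCells = 8, minFocalCells = 1L, ...) {
  PcfConfig(maxRadiusCells = maxRadiusCells,
            minFocalCells = as.integer(minFocalCells), ...)
}

# Random raster for oracle-equivalence checks.
random_raster <- function(seed, max_dim = 40) {
  set.seed(seed)
  nr <- sample(10:max_dim, 1)
  nc <- sample(10:max_dim, 1)
  p <- runif(1, 0.05, 0.6)
  RasterMap(matrix(runif(nr * nc) < p, nr, nc), cellSizeUm = 18.4)
}

# Hand-built classified curve for summary/comparison tests.
manual_ci <- function(g, ci_lo, ci_hi, cell_um = 18.4,
                      valid = rep(TRUE, length(g))) {
  r_cells <- 2 * seq_along(g) - 1
  tb <- data.frame(r_cells = r_cells, r_um = r_cells * cell_um, g = g,
                   n_focal = rep(500L, length(g)),
                   n_pairs = rep(1000, length(g)), valid = valid)
  pcf <- new("PcfResult", table = tb, ringCells = rep(100L, length(g)),
             overallDensity = 0.3, annulusWidthCells = 2,
             minFocalCells = 100L, cellSizeUm = cell_um)
  cls <- rep(NA_character_, length(g))
  ok <- valid
  cls[ok & ci_lo > 1] <- "clustered"
  cls[ok & ci_hi < 1] <- "regular"
  cls[ok & is.na(cls)] <- "csr_consistent"
  new("CiResult", pcf = pcf, ciLo = ci_lo, ciHi = ci_hi,
      classification = cls, config = ResamplingConfig(nDraws = 999L))
}
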