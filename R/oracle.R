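# Brute-force pairwise oracle for the grid PCF, used to verify the
# counting kernel.  Same contract as gridPCF, computed from explicit
# ordered-pair centre distances rather than per-ring offset shifts.

#' Brute-force pair-correlation oracle
#'
#' Computes the identical quantity to [gridPCF()] by looping over ordered
#' pairs of occupied cells, binning their centre-to-centre Euclidean
#' distances into the half-open classes `[(k-1)w, kw)`, and honouring the
#' same buffer rule (a focal cell counts for a class only if the whole
#' annulus fits in the grid).  Annulus cell counts and buffer margins are
#' re-derived here by exhaustive enumeration of integer offsets, so the
#' two code paths share no counting logic.  Intended for verification on
#' small rasters; refuses more than 10,000 occupied cells.
#'
#' @inheritParams gridPCF
#' @return a [PcfResult-class], equal to `gridPCF(raster, cfg)` to within
#'   floating-point tolerance.
#' @export
bruteForcePCF <- function(raster, cfg = PcfConfig()) {
  stopifnot(is(raster, "RasterMap"), is(cfg, "PcfConfig"))
  validObject(cfg)
  occ_idx <- which(raster@occupancy, arr.ind = TRUE)
  n <- nrow(occ_idx)
  if (n == 0) stop("raster has no occupied cells", call. = FALSE)
  if (n > 1e4) stop("oracle refuses rasters with more than 10,000 occupied cells",
                    call. = FALSE)
  nr <- nrow(raster@occupancy); nc <- ncol(raster@occupancy)
  w <- cfg@annulusWidthCells
  K <- floor(cfg@maxRadiusCells / w + 0.5)
  if (K < 1L) stop("'maxRadiusCells' admits no ring", call. = FALSE)
  r_cells <- (2 * seq_len(K) - 1) * w / 2

  # ring geometry by exhaustive enumeration of integer offsets
  rmax <- ceiling(K * w)
  dd <- seq.int(-rmax, rmax)
  di <- rep(dd, times = length(dd))
  dj <- rep(dd, each = length(dd))
  dist_off <- sqrt(di^2 + dj^2)
  ringcells <- integer(K)
  margins <- integer(K)
  for (k in seq_len(K)) {
    sel <- dist_off >= (k - 1) * w & dist_off < k * w & !(di == 0 & dj == 0)
    ringcells[k] <- sum(sel)
    margins[k] <- if (any(sel)) max(abs(c(di[sel], dj[sel]))) else 0L
  }

  counts <- numeric(K)
  nfocal <- integer(K)
  for (a in seq_len(n)) {
    i <- occ_idx[a, 1]; j <- occ_idx[a, 2]
    # which rings is this focal cell buffer-valid for?
    ok <- i > margins & i <= nr - margins & j > margins & j <= nc - margins
    nfocal <- nfocal + ok
    d <- sqrt((occ_idx[, 1] - i)^2 + (occ_idx[, 2] - j)^2)[-a]
    kk <- floor(d / w) + 1
    kk <- kk[kk <= K]
    kk <- kk[ok[kk]]
    if (length(kk)) counts <- counts + tabulate(kk, nbins = K)
  }

  # independent assembly of the normalized curve
  p_full <- n / (nr * nc)
  if (cfg@densityScope == "buffer_interior") {
    p <- vapply(seq_len(K), function(k) {
      m <- margins[k]
      if (2 * m >= nr || 2 * m >= nc) return(NA_real_)
      inside <- occ_idx[, 1] > m & occ_idx[, 1] <= nr - m &
        occ_idx[, 2] > m & occ_idx[, 2] <= nc - m
      sum(inside) / ((nr - 2 * m) * (nc - 2 * m))
    }, numeric(1))
  } else {
    p <- rep(p_full, K)
  }
  g <- ifelse(nfocal > 0 & !is.na(p) & p > 0,
              (counts / (as.numeric(nfocal) * ringcells)) / p, NA_real_)
  tb <- data.frame(r_cells = r_cells, r_um = r_cells * raster@cellSizeUm,
                   g = g, n_focal = as.integer(nfocal), n_pairs = counts,
                   valid = nfocal >= cfg@minFocalCells & !is.na(g))
  new("PcfResult", table = tb, ringCells = as.integer(ringcells),
      overallDensity = p_full, annulusWidthCells = cfg@annulusWidthCells,
      minFocalCells = cfg@minFocalCells, cellSizeUm = raster@cellSizeUm)
}
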