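# Resampling confidence intervals, CSR classification, distance-class
# comparison, threshold sensitivity, homogeneity, and critical scales.

#' Order-statistic ranks for a resampling confidence interval
#'
#' For `nDraws` resampled values and a two-sided level `1 - alpha`, the
#' interval is bounded by the k-th lowest and k-th highest values with
#' `k = round(alpha/2 * (nDraws + 1))` (1-based).  For the conventional
#' 999 draws at alpha = 0.05 this selects the 25th lowest and 25th
#' highest resampled g(r) values.
#'
#' @param nDraws number of resampling draws.
#' @param alpha confidence-level complement in (0,1).
#' @return integer vector `c(lower, upper)` of 1-based ranks.
#' @examples
#' ciOrderRanks(999, 0.05)  # 25, 975
#' @export
ciOrderRanks <- function(nDraws, alpha = 0.05) {
  if (!is_count(nDraws)) stop("'nDraws' must be a positive integer", call. = FALSE)
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  k <- round(alpha / 2 * (nDraws + 1))
  if (k < 1) {
    stop(sprintf("nDraws = %d is too small to support alpha = %g", nDraws, alpha),
         call. = FALSE)
  }
  c(lower = as.integer(k), upper = as.integer(nDraws + 1 - k))
}

#' Resampling confidence intervals and CSR classification for g(r)
#'
#' Repeatedly draws a random sample of `sampleFraction` of the occupied
#' cells without replacement, recomputes g(r) on the subsampled raster
#' under the identical PCF configuration (by default normalizing by the
#' subsample's own density, which leaves the expectation of g unchanged),
#' and takes per-radius order statistics of the resampled curves as
#' confidence bounds.  A radius is classified `"clustered"` when the
#' interval lies entirely above 1, `"regular"` entirely below 1, and
#' `"csr_consistent"` otherwise; radii flagged invalid in the point
#' estimate are left unclassified (`NA`).
#'
#' @param raster a [RasterMap-class].
#' @param pcfCfg a [PcfConfig-class].
#' @param rsCfg a [ResamplingConfig-class].
#' @return a [CiResult-class].
#' @export
resampleCI <- function(raster, pcfCfg = PcfConfig(), rsCfg = ResamplingConfig()) {
  stopifnot(is(raster, "RasterMap"), is(pcfCfg, "PcfConfig"),
            is(rsCfg, "ResamplingConfig"))
  validObject(pcfCfg); validObject(rsCfg)
  point <- gridPCF(raster, pcfCfg)
  occ_idx <- which(raster@occupancy, arr.ind = TRUE)
  N <- nrow(occ_idx)
  if (N < 2 / rsCfg@sampleFraction) {
    stop("too few occupied cells to resample", call. = FALSE)
  }
  m <- floor(rsCfg@sampleFraction * N)
  nr <- nrow(raster@occupancy); nc <- ncol(raster@occupancy)
  r_cells <- ring_midpoints(pcfCfg)
  K <- length(r_cells)
  offs <- lapply(r_cells, ringOffsets, widthCells = pcfCfg@annulusWidthCells)
  margins <- vapply(offs, function(o) if (nrow(o)) max(abs(o)) else 0L, integer(1))
  interior <- pmax(0, (nr - 2 * margins)) * pmax(0, (nc - 2 * margins))

  density_mode <- if (pcfCfg@densityScope == "buffer_interior") 1L else 0L
  p_fixed <- if (rsCfg@densityFrom == "subsample") m / (nr * nc) else N / (nr * nc)

  g_mat <- with_seed(rsCfg@seed, {
    if (rsCfg@sharedDraws) {
      draws <- t(vapply(seq_len(rsCfg@nDraws),
                        function(d) sample.int(N, m), integer(m)))
      cpp_resample_g(occ_idx[, 1] - 1L, occ_idx[, 2] - 1L, nr, nc, offs,
                     draws, p_fixed, density_mode, as.numeric(interior))
    } else {
      # independent draws per radius: one column at a time
      cols <- lapply(seq_len(K), function(k) {
        draws_k <- t(vapply(seq_len(rsCfg@nDraws),
                            function(d) sample.int(N, m), integer(m)))
        cpp_resample_g(occ_idx[, 1] - 1L, occ_idx[, 2] - 1L, nr, nc,
                       offs[k], draws_k, p_fixed, density_mode,
                       as.numeric(interior[k]))[, 1]
      })
      do.call(cbind, cols)
    }
  })

  ranks <- ciOrderRanks(rsCfg@nDraws, rsCfg@alpha)
  ci_lo <- ci_hi <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    gs <- g_mat[, k]
    if (anyNA(gs)) next
    gs <- sort(gs)
    ci_lo[k] <- gs[ranks["lower"]]
    ci_hi[k] <- gs[ranks["upper"]]
  }
  cls <- rep(NA_character_, K)
  ok <- point@table$valid & !is.na(ci_lo) & !is.na(ci_hi)
  cls[ok & ci_lo > 1] <- "clustered"
  cls[ok & ci_hi < 1] <- "regular"
  cls[ok & is.na(cls)] <- "csr_consistent"
  new("CiResult", pcf = point, ciLo = ci_lo, ciHi = ci_hi,
      classification = cls, config = rsCfg)
}

#' Are two distance classes different?
#'
#' Two radii are judged different when their confidence intervals are
#' disjoint.  Radii are matched against `r_um` in the result table (or
#' `r_cells` with `units = "cells"`).
#'
#' @param ci a [CiResult-class].
#' @param rA,rB the two radii to compare.
#' @param units `"um"` (default) or `"cells"`.
#' @return `TRUE` iff the intervals do not overlap.
#' @export
compareDistanceClasses <- function(ci, rA, rB, units = c("um", "cells")) {
  stopifnot(is(ci, "CiResult"))
  units <- match.arg(units)
  rr <- if (units == "um") ci@pcf@table$r_um else ci@pcf@table$r_cells
  find <- function(r) {
    k <- which(abs(rr - r) < 1e-6 * max(1, abs(r)))
    if (length(k) != 1L) {
      stop(sprintf("radius %g does not match a distance class", r), call. = FALSE)
    }
    if (!ci@pcf@table$valid[k] || is.na(ci@ciLo[k])) {
      stop(sprintf("radius %g is not a valid distance class", r), call. = FALSE)
    }
    k
  }
  a <- find(rA); b <- find(rB)
  ci@ciLo[a] > ci@ciHi[b] || ci@ciLo[b] > ci@ciHi[a]
}

#' Sensitivity of g(r) to the saturation threshold
#'
#' Runs the full segment-rasterize-PCF chain once at the reference
#' threshold and once per alternative threshold, and reports for each
#' alternative the mean over jointly valid radii of
#' `|g_t(r) - g_ref(r)| / g_ref(r)`, in percent.  Thresholds that yield an
#' empty raster are flagged and excluded with a warning.
#'
#' @param image numeric RGB array.
#' @param thresholds alternative thresholds to evaluate.
#' @param reference reference threshold (default 0.25).
#' @param cfg a [SegmentationConfig-class] (its threshold slot is
#'   overridden per run).
#' @param geom an [OpticalGeometry-class].
#' @param pcfCfg a [PcfConfig-class].
#' @param cellSizeUm optional physical cell-size override.
#' @return data.frame with columns `threshold`, `mean_rel_dev_pct`,
#'   `n_radii`, `empty`.
#' @export
thresholdSensitivity <- function(image, thresholds = c(0.22, 0.28),
                                 reference = 0.25,
                                 cfg = SegmentationConfig(),
                                 geom = OpticalGeometry(),
                                 pcfCfg = PcfConfig(), cellSizeUm = NULL) {
  if (any(thresholds <= 0 | thresholds >= 1) || reference <= 0 || reference >= 1) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  run_one <- function(t) {
    cfg@saturationThreshold <- t
    r <- rasterizeMask(segmentImage(image, cfg), cfg, geom, cellSizeUm)
    if (!any(r@occupancy)) return(NULL)
    gridPCF(r, pcfCfg)
  }
  ref <- run_one(reference)
  if (is.null(ref)) stop("reference threshold yields an empty raster", call. = FALSE)
  out <- data.frame(threshold = thresholds, mean_rel_dev_pct = NA_real_,
                    n_radii = 0L, empty = FALSE)
  for (i in seq_along(thresholds)) {
    alt <- run_one(thresholds[i])
    if (is.null(alt)) {
      warning(sprintf("threshold %g yields an empty raster; excluded",
                      thresholds[i]), call. = FALSE)
      out$empty[i] <- TRUE
      next
    }
    both <- ref@table$valid & alt@table$valid
    if (!any(both)) next
    dev <- abs(alt@table$g[both] - ref@table$g[both]) / ref@table$g[both]
    out$mean_rel_dev_pct[i] <- 100 * mean(dev)
    out$n_radii[i] <- sum(both)
  }
  out
}

#' Large-scale homogeneity diagnostic
#'
#' A pattern is homogeneous at the map scale when g(r) trends to 1 at
#' large radii.  Operationally: the mean of `|g(r) - 1|` over the largest
#' `windowFraction` of valid radii must fall below `tolerance`.  Returns
#' `NA` (with a warning) when fewer than three valid radii lie in the
#' window.
#'
#' @param pcf a [PcfResult-class].
#' @param windowFraction fraction of the largest valid radii to inspect.
#' @param tolerance acceptance band on the mean deviation from 1.
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate).
#' @export
homogeneityCheck <- function(pcf, windowFraction = 0.25, tolerance = 0.15) {
  stopifnot(is(pcf, "PcfResult"))
  tb <- pcf@table[pcf@table$valid, , drop = FALSE]
  nw <- ceiling(windowFraction * nrow(tb))
  if (nw < 3) {
    warning("fewer than 3 valid radii in the inspection window; homogeneity indeterminate",
            call. = FALSE)
    return(NA)
  }
  tail_g <- tail(tb$g[order(tb$r_cells)], nw)
  mean(abs(tail_g - 1)) < tolerance
}

#' Critical-scale summary of a classified g(r) curve
#'
#' Extracts the three critical scales of the colonization pattern from a
#' classified curve: the aggregation extent (largest radius of the
#' unbroken run of clustered classes starting at the smallest valid
#' radius), the exclusion dip (the g minimum beyond the aggregation run,
#' reported only when that minimum is itself classified regular), and the
#' return radius (smallest radius beyond the dip consistent with CSR),
#' plus the large-scale homogeneity flag.  Absent features are `NA`.
#'
#' @param ci a [CiResult-class] with at least five valid radii.
#' @param windowFraction,tolerance passed to [homogeneityCheck()].
#' @return a [ScaleSummary-class].
#' @export
summarizeScales <- function(ci, windowFraction = 0.25, tolerance = 0.15) {
  stopifnot(is(ci, "CiResult"))
  tb <- ci@pcf@table
  ok <- tb$valid & !is.na(ci@classification)
  if (sum(ok) < 5) stop("need at least 5 valid classified radii", call. = FALSE)
  r_um <- tb$r_um[ok]
  g <- tb$g[ok]
  cls <- ci@classification[ok]
  o <- order(r_um)
  r_um <- r_um[o]; g <- g[o]; cls <- cls[o]

  agg_um <- NA_real_
  run_end <- 0L
  if (cls[1] == "clustered") {
    run_end <- which.max(cumsum(cls != "clustered") > 0) - 1L
    if (all(cls == "clustered")) run_end <- length(cls)
    agg_um <- r_um[run_end]
  }

  dip_um <- dip_g <- ret_um <- NA_real_
  cand <- seq_along(g) > run_end
  if (any(cand)) {
    k <- which(cand)[which.min(g[cand])] # ties resolve to the smallest r
    if (cls[k] == "regular") {
      dip_um <- r_um[k]
      dip_g <- g[k]
      beyond <- which(seq_along(g) > k & cls == "csr_consistent")
      if (length(beyond)) ret_um <- r_um[beyond[1]]
    }
  }

  hom <- suppressWarnings(homogeneityCheck(ci@pcf, windowFraction, tolerance))
  new("ScaleSummary", aggregationExtentUm = agg_um, dipRadiusUm = dip_um,
      dipG = dip_g, returnRadiusUm = ret_um, homogeneous = as.logical(hom))
}
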