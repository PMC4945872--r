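test_that("ring offsets enumerate the documented annuli", {
  o1 <- ringOffsets(1, 2)
  expect_equal(nrow(o1), 8)
  expect_setequal(paste(o1[, 1], o1[, 2]),
                  c("-1 -1", "-1 0", "-1 1", "0 -1", "0 1", "1 -1", "1 0", "1 1"))
  # third ring: integer lattice points with distance in [2, 4)
  o3 <- ringOffsets(3, 2)
  d2 <- o3[, 1]^2 + o3[, 2]^2
  expect_true(all(d2 >= 4 & d2 < 16))
  n_expected <- 0L
  for (di in -4:4) for (dj in -4:4) {
    dd <- di * di + dj * dj
    if (dd >= 4 && dd < 16) n_expected <- n_expected + 1L
  }
  expect_equal(nrow(o3), n_expected)
  # symmetry under negation
  for (r in c(1, 3, 5, 9)) {
    o <- ringOffsets(r, 2)
    expect_setequal(paste(o[, 1], o[, 2]), paste(-o[, 1], -o[, 2]))
  }
  expect_error(ringOffsets(0, 2), "rCells")
})

test_that("buffer rule keeps only focal cells with fully contained annuli", {
  r <- RasterMap(matrix(TRUE, 10, 10), 18.4)
  f1 <- bufferValidFocals(r, 1, 2)
  expect_equal(nrow(f1), 64)  # 8 x 8 interior
  expect_true(all(f1 > 1 & f1 < 10))
  expect_equal(nrow(bufferValidFocals(r, 9, 2)), 0)  # no annulus fits
  empty <- RasterMap(matrix(c(FALSE, rep(FALSE, 99)), 10, 10), 18.4)
  expect_equal(nrow(bufferValidFocals(empty, 1, 2)), 0)
})

test_that("the fully occupied raster gives g = 1 exactly", {
  r <- RasterMap(matrix(TRUE, 30, 30), 18.4)
  tb <- pcfTable(gridPCF(r, small_pcf(maxRadiusCells = 13)))
  expect_true(any(tb$valid))
  expect_identical(tb$g[tb$valid], rep(1, sum(tb$valid)))
})

test_that("grid counting equals the brute-force pairwise oracle", {
  for (seed in 1:25) {
    r <- random_raster(seed)
    w <- sample(c(2, 3), 1)
    cfg <- PcfConfig(annulusWidthCells = w,
                     maxRadiusCells = sample(5:12, 1), minFocalCells = 1L)
    a <- pcfTable(gridPCF(r, cfg))
    b <- pcfTable(bruteForcePCF(r, cfg))
    expect_equal(a$n_focal, b$n_focal)
    expect_equal(a$n_pairs, b$n_pairs)
    expect_equal(a$g, b$g, tolerance = 1e-9)
  }
  # buffer-interior normalization agrees too
  r <- random_raster(99)
  cfg <- PcfConfig(maxRadiusCells = 9, minFocalCells = 1L,
                   densityScope = "buffer_interior")
  expect_equal(pcfTable(gridPCF(r, cfg))$g, pcfTable(bruteForcePCF(r, cfg))$g,
               tolerance = 1e-9)
})

test_that("the oracle refuses rasters beyond its guard", {
  big <- RasterMap(matrix(TRUE, 120, 120), 18.4)
  expect_error(bruteForcePCF(big), "10,000")
})

test_that("g is invariant under rigid translation away from the edges", {
  set.seed(17)
  block <- matrix(runif(100) < 0.5, 10, 10)
  place <- function(at) {
    occ <- matrix(FALSE, 40, 40)
    occ[at[1]:(at[1] + 9), at[2]:(at[2] + 9)] <- block
    RasterMap(occ, 18.4)
  }
  cfg <- small_pcf(maxRadiusCells = 7)
  a <- pcfTable(gridPCF(place(c(12, 12)), cfg))
  b <- pcfTable(gridPCF(place(c(14, 17)), cfg))
  expect_equal(a$g, b$g)
  expect_equal(a$n_pairs, b$n_pairs)
})

test_that("isolated pairs land in the ring containing their distance", {
  occ <- matrix(FALSE, 20, 20)
  occ[10, 8] <- TRUE
  occ[10, 11] <- TRUE  # centre distance exactly 3
  tb <- pcfTable(gridPCF(RasterMap(occ, 18.4), small_pcf(maxRadiusCells = 7)))
  expect_equal(tb$n_pairs, c(0, 2, 0, 0))  # both ordered pairs in [2, 4)
  single <- matrix(FALSE, 20, 20); single[10, 10] <- TRUE
  tb1 <- pcfTable(gridPCF(RasterMap(single, 18.4), PcfConfig(maxRadiusCells = 7)))
  expect_true(all(tb1$n_pairs == 0))
  expect_false(any(tb1$valid))  # below the minimum-focal-cell rule
})

test_that("CSR ensembles are centred on g = 1", {
  gs <- vapply(1:50, function(s) {
    r <- generateRaster(SceneParams(patternKind = "csr", density = 0.3,
                                    seed = 300 + s), gridDims = c(60, 60))
    pcfTable(gridPCF(r, small_pcf(maxRadiusCells = 9, minFocalCells = 50)))$g
  }, numeric(5))
  m <- rowMeans(gs)
  se <- apply(gs, 1, sd) / sqrt(ncol(gs))
  expect_true(all(abs(m - 1) < 3 * se))
})

test_that("Thomas clustering is strong at small r and decays toward 1", {
  gs <- vapply(1:5, function(s) {
    pcfTable(gridPCF(generateRaster(SceneParams(patternKind = "thomas",
                                                seed = s))))$g
  }, numeric(25))
  m <- rowMeans(gs)
  expect_gt(m[1], 1.5)
  expect_true(all(diff(m[1:5]) < 0))       # declining through the cluster scale
  expect_lt(max(abs(m[15:25] - 1)), 0.1)   # back to CSR beyond the clusters
})

test_that("the full-frame raster accumulates enough focal cells and pairs", {
  r <- generateRaster(SceneParams(patternKind = "csr", density = 0.3, seed = 77L))
  tb <- pcfTable(gridPCF(r))
  expect_true(all(tb$valid))
  expect_true(all(tb$n_focal >= 100))
  expect_true(all(tb$n_pairs >= 8000))
})

test_that("degenerate inputs are rejected", {
  none <- RasterMap(matrix(FALSE, 5, 5), 18.4)
  expect_error(gridPCF(none), "no occupied")
  expect_error(bruteForcePCF(none), "no occupied")
})
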