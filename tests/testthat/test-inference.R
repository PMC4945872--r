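test_that("order-statistic ranks match the half-population convention", {
  expect_equal(unname(ciOrderRanks(999, 0.05)), c(25, 975))
  expect_equal(unname(ciOrderRanks(39, 0.05)), c(1, 39))
  r <- ciOrderRanks(999, 0.998)
  expect_equal(unname(r), c(499, 501))  # degenerate, median-adjacent interval
  expect_error(ciOrderRanks(19, 0.05), "too small")
  expect_error(ciOrderRanks(999, 1.2), "alpha")
})

test_that("resampling is reproducible and leaves the RNG untouched", {
  r <- generateRaster(SceneParams(patternKind = "csr", density = 0.4, seed = 2L),
                      gridDims = c(40, 40))
  cfg <- small_pcf(maxRadiusCells = 7, minFocalCells = 20)
  set.seed(123); state <- .Random.seed
  a <- resampleCI(r, cfg, ResamplingConfig(nDraws = 99L, seed = 5L))
  expect_identical(.Random.seed, state)
  b <- resampleCI(r, cfg, ResamplingConfig(nDraws = 99L, seed = 5L))
  expect_identical(ciBounds(a), ciBounds(b))
  expect_identical(classifications(a), classifications(b))
  c <- resampleCI(r, cfg, ResamplingConfig(nDraws = 99L, seed = 6L))
  expect_false(identical(ciBounds(a), ciBounds(c)))
})

test_that("a fully occupied raster is consistent with CSR at every radius", {
  r <- RasterMap(matrix(TRUE, 30, 30), 18.4)
  ci <- resampleCI(r, small_pcf(maxRadiusCells = 9, minFocalCells = 20),
                   ResamplingConfig(nDraws = 199L, seed = 1L))
  cls <- classifications(ci)
  expect_true(all(cls[!is.na(cls)] == "csr_consistent"))
  bounds <- ciBounds(ci)
  ok <- !is.na(bounds$ci_lo)
  expect_true(all(bounds$ci_lo[ok] <= 1 & bounds$ci_hi[ok] >= 1))
})

test_that("known structured patterns classify as expected", {
  thomas <- generateRaster(SceneParams(patternKind = "thomas", seed = 4L))
  ci_t <- resampleCI(thomas, PcfConfig(maxRadiusCells = 20),
                     ResamplingConfig(nDraws = 199L, seed = 4L))
  expect_equal(classifications(ci_t)[1], "clustered")

  polyp <- generateRaster(SceneParams(patternKind = "polyp_lattice", seed = 3L))
  ci_p <- resampleCI(polyp, PcfConfig(), ResamplingConfig(nDraws = 199L, seed = 3L))
  tb <- pcfTable(ci_p)
  dip_zone <- tb$r_um >= 200 & tb$r_um <= 450
  expect_true(any(classifications(ci_p)[dip_zone] == "regular", na.rm = TRUE))
})

test_that("per-radius draws give the same calibration as shared draws", {
  r <- generateRaster(SceneParams(patternKind = "csr", density = 0.4, seed = 9L),
                      gridDims = c(40, 40))
  cfg <- small_pcf(maxRadiusCells = 5, minFocalCells = 20)
  sh <- resampleCI(r, cfg, ResamplingConfig(nDraws = 199L, seed = 7L))
  pr <- resampleCI(r, cfg, ResamplingConfig(nDraws = 199L, seed = 7L,
                                            sharedDraws = FALSE))
  b1 <- ciBounds(sh); b2 <- ciBounds(pr)
  expect_equal(b1$ci_lo, b2$ci_lo, tolerance = 0.15)
  expect_identical(classifications(sh), classifications(pr))
})

test_that("distance classes differ exactly when their intervals are disjoint", {
  ci <- manual_ci(g = c(1.45, 1.0, 0.8, 1.0, 1.1),
                  ci_lo = c(1.3, 0.9, 0.7, 0.9, 1.0),
                  ci_hi = c(1.6, 1.1, 0.9, 1.2, 1.2),
                  valid = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  r_um <- pcfTable(ci)$r_um
  expect_true(compareDistanceClasses(ci, r_um[1], r_um[3]))
  expect_false(compareDistanceClasses(ci, r_um[2], r_um[4]))
  expect_false(compareDistanceClasses(ci, r_um[2], r_um[2]))
  expect_error(compareDistanceClasses(ci, r_um[5], r_um[1]), "not a valid")
  expect_error(compareDistanceClasses(ci, 123.4, r_um[1]), "does not match")
})

test_that("threshold sensitivity is zero for identical masks, positive when straddling", {
  scene <- generateRaster(SceneParams(patternKind = "thomas", seed = 2L,
                                      windowWidthUm = 736, windowHeightUm = 736))
  pcf_cfg <- small_pcf(maxRadiusCells = 9, minFocalCells = 10)

  clear <- renderScene(scene, RenderParams(algaeSaturationMean = 0.6,
                                           algaeSaturationSd = 0.02,
                                           pixelNoiseSd = 0.005, seed = 1L))
  dev <- thresholdSensitivity(clear, thresholds = c(0.22, 0.25, 0.28),
                              pcfCfg = pcf_cfg, cellSizeUm = 18.4)
  expect_equal(dev$mean_rel_dev_pct, c(0, 0, 0))

  straddle <- renderScene(scene, RenderParams(algaeSaturationMean = 0.28,
                                              algaeSaturationSd = 0.30,
                                              pixelNoiseSd = 0.005, seed = 1L))
  dev2 <- thresholdSensitivity(straddle, pcfCfg = pcf_cfg, cellSizeUm = 18.4)
  expect_true(all(!dev2$empty))
  expect_true(all(dev2$mean_rel_dev_pct > 0))
})

test_that("empty-raster thresholds are flagged and excluded with a warning", {
  occ1 <- RasterMap(matrix(c(TRUE, rep(c(FALSE, TRUE), 49), FALSE), 10, 10), 18.4)
  img <- renderScene(occ1, RenderParams(algaeSaturationMean = 0.26,
                                        algaeSaturationSd = 0, pixelNoiseSd = 0,
                                        seed = 1L))
  # at threshold 0.28 nothing survives; at 0.25 the algae do
  out <- NULL
  expect_warning(
    out <- thresholdSensitivity(img, thresholds = c(0.28), reference = 0.25,
                                pcfCfg = small_pcf(maxRadiusCells = 3,
                                                   minFocalCells = 1),
                                cellSizeUm = 18.4),
    "empty")
  expect_true(out$empty[1])
})

test_that("homogeneity diagnostic reads the large-radius tail", {
  flat <- manual_ci(g = rep(1, 12), ci_lo = rep(0.9, 12), ci_hi = rep(1.1, 12))
  expect_true(homogeneityCheck(flat@pcf))
  shifted <- manual_ci(g = c(rep(1, 9), rep(1.5, 3)),
                       ci_lo = rep(1.4, 12), ci_hi = rep(1.6, 12))
  expect_false(homogeneityCheck(shifted@pcf, tolerance = 0.15))
  few <- manual_ci(g = rep(1, 4), ci_lo = rep(0.9, 4), ci_hi = rep(1.1, 4))
  expect_warning(res <- homogeneityCheck(few@pcf), "indeterminate")
  expect_true(is.na(res))
})

test_that("CSR replicates are homogeneous in at least 95% of cases", {
  hom <- vapply(1:40, function(s) {
    r <- generateRaster(SceneParams(patternKind = "csr", density = 0.3,
                                    seed = 400 + s))
    homogeneityCheck(gridPCF(r))
  }, logical(1))
  expect_gte(mean(hom), 0.95)
})

test_that("scale summary reads the three-phase curve correctly", {
  ci <- manual_ci(g = c(2, 1.5, 0.6, 0.9, 1.0, 1.02, 1.0),
                  ci_lo = c(1.8, 1.3, 0.5, 0.8, 0.92, 0.95, 0.93),
                  ci_hi = c(2.2, 1.7, 0.7, 0.95, 1.08, 1.09, 1.07))
  sm <- summarizeScales(ci)
  r_um <- pcfTable(ci)$r_um
  expect_equal(sm@aggregationExtentUm, r_um[2])
  expect_equal(sm@dipRadiusUm, r_um[3])
  expect_equal(sm@dipG, 0.6)
  expect_equal(sm@returnRadiusUm, r_um[5])
})

test_that("CSR patterns yield no aggregation extent and no dip", {
  r <- generateRaster(SceneParams(patternKind = "csr", density = 0.3, seed = 55L))
  ci <- resampleCI(r, PcfConfig(), ResamplingConfig(nDraws = 199L, seed = 55L))
  sm <- summarizeScales(ci)
  expect_true(is.na(sm@dipRadiusUm))
  expect_true(sm@homogeneous)
  few <- manual_ci(g = rep(1, 4), ci_lo = rep(0.9, 4), ci_hi = rep(1.1, 4))
  expect_error(summarizeScales(few), "at least 5")
})

test_that("misclassification under CSR stays rare", {
  frac <- vapply(1:8, function(s) {
    r <- generateRaster(SceneParams(patternKind = "csr", density = 0.3,
                                    seed = 500 + s))
    ci <- resampleCI(r, PcfConfig(), ResamplingConfig(nDraws = 199L, seed = s))
    cls <- classifications(ci)
    v <- pcfTable(ci)$valid
    mean(cls[v] != "csr_consistent")
  }, numeric(1))
  expect_lte(mean(frac), 0.10)
})
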