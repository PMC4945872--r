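test_that("pixel binning averages blocks and floors trailing pixels", {
  m <- matrix(c(0, 4, 0, 8) / 8, 2, 2)
  expect_equal(binPixels(m, 2), matrix(3 / 8, 1, 1))
  img <- array(runif(12 * 9 * 3), dim = c(12, 9, 3))
  expect_identical(binPixels(img, 1), img)
  b <- binPixels(img, 2)
  expect_equal(dim(b), c(6, 4, 3))
  expect_equal(b[1, 1, 2], mean(img[1:2, 1:2, 2]))
  big <- matrix(0, 2448, 2050)
  expect_equal(dim(binPixels(big, 2)), c(1224, 1025))
  expect_error(binPixels(matrix(0, 3, 3), 4), "exceeds")
})

test_that("saturation follows the standard HSV definition", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(rgbToSaturation(px(0.4, 0.4, 0.4))[1, 1], 0)
  expect_equal(rgbToSaturation(px(1, 0, 0))[1, 1], 1)
  expect_equal(rgbToSaturation(px(0.5, 0.25, 0.25))[1, 1], 0.5)
  expect_equal(rgbToSaturation(px(0, 0, 0))[1, 1], 0)
  # cross-check against the reference converter on random colours
  set.seed(4)
  rgb <- matrix(runif(300), 3, 100)
  img <- array(t(rgb), dim = c(100, 1, 3))
  expect_equal(as.vector(rgbToSaturation(img)),
               unname(grDevices::rgb2hsv(rgb, maxColorValue = 1)["s", ]),
               tolerance = 1e-12)
})

test_that("thresholding is strict and monotone in the threshold", {
  s <- matrix(c(0.3, 0.25, 0.1, 0.26), 2, 2)
  expect_identical(thresholdSaturation(s, 0.25),
                   matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_false(any(thresholdSaturation(matrix(0, 4, 4), 0.25)))
  set.seed(3)
  img <- array(runif(40 * 40 * 3), dim = c(40, 40, 3))
  s2 <- rgbToSaturation(img)
  lo <- thresholdSaturation(s2, 0.22)
  hi <- thresholdSaturation(s2, 0.28)
  expect_true(all(lo[hi]))  # 0.22 mask contains the 0.28 mask
  expect_error(thresholdSaturation(s, 1.2), "threshold")
})

test_that("rasterization yields the documented grid and occupancy rule", {
  # full-frame geometry: 2448 x 2050 px binned 2x, 16-px cells -> 153 x 128
  mask <- matrix(TRUE, 1025, 1224)  # binned pixels (rows x cols)
  r <- rasterizeMask(mask, SegmentationConfig())
  expect_equal(dim(r), c(128, 153))          # rows x cols
  expect_true(all(occupancy(r)))
  expect_equal(cellSizeUm(r), 18.4)

  # a single algae pixel occupies exactly one cell at fraction 1/256
  cfg1 <- SegmentationConfig(binFactor = 1L, cellPx = 16L,
                             occupancyFraction = 1 / 256)
  m1 <- matrix(FALSE, 32, 32); m1[20, 7] <- TRUE
  r1 <- rasterizeMask(m1, cfg1, cellSizeUm = 18.4)
  expect_equal(sum(occupancy(r1)), 1)
  expect_true(occupancy(r1)[2, 1])

  # majority rule boundary: exactly half the cell is occupied
  cfg2 <- SegmentationConfig(binFactor = 1L, cellPx = 4L, occupancyFraction = 0.5)
  m2 <- matrix(FALSE, 4, 4); m2[1:2, ] <- TRUE
  expect_true(occupancy(rasterizeMask(m2, cfg2, cellSizeUm = 4.6))[1, 1])
  m3 <- matrix(FALSE, 4, 4); m3[1, ] <- TRUE; m3[2, 1:3] <- TRUE
  expect_false(occupancy(rasterizeMask(m3, cfg2, cellSizeUm = 4.6))[1, 1])

  expect_error(SegmentationConfig(binFactor = 3L, cellPx = 16L), "divisible")
})

test_that("object-space arithmetic reproduces the optical worked examples", {
  g <- OpticalGeometry(pixelPitchUm = 3.45, magnification = 3)
  expect_equal(objectSpaceLength(g, 16), 18.4)
  expect_equal(objectSpaceLength(g, 2448), 2815.2)  # 2.82 mm field width
  expect_equal(objectSpaceLength(OpticalGeometry(magnification = 1), 1), 3.45)
  expect_error(objectSpaceLength(g, 0), "nPx")
})

test_that("rasterization commutes with image flips on exact multiples", {
  set.seed(21)
  img <- array(runif(64 * 96 * 3), dim = c(64, 96, 3))
  cfg <- SegmentationConfig(binFactor = 2L, cellPx = 16L)
  r <- occupancy(imageToRaster(img, cfg, cellSizeUm = 18.4))
  flip_v <- img[rev(seq_len(64)), , , drop = FALSE]
  r_v <- occupancy(imageToRaster(flip_v, cfg, cellSizeUm = 18.4))
  expect_identical(r_v, r[rev(seq_len(nrow(r))), , drop = FALSE])
  flip_h <- img[, rev(seq_len(96)), , drop = FALSE]
  r_h <- occupancy(imageToRaster(flip_h, cfg, cellSizeUm = 18.4))
  expect_identical(r_h, r[, rev(seq_len(ncol(r))), drop = FALSE])
})
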