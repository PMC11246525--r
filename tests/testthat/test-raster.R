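test_that("GridSpec validates its fields and compares by full equality", {
  expect_error(gridSpec(0, 4), "nRows")
  expect_error(gridSpec(4, 4, pixelWidth = -1), "pixelWidth")
  a <- gridSpec(4, 4, originX = 10, originY = 20, pixelWidth = 2)
  expect_true(sameSpec(a, gridSpec(4, 4, originX = 10, originY = 20,
                                   pixelWidth = 2)))
  expect_false(sameSpec(a, gridSpec(4, 4, originX = 11, originY = 20,
                                    pixelWidth = 2)))
  expect_false(sameSpec(a, gridSpec(4, 4, originX = 10, originY = 20,
                                    pixelWidth = 2, crs = "other")))
})

test_that("ASCII grid round-trips values, validity and georeference", {
  d <- withr::local_tempdir()
  m <- matrix(c(1.5, -2.25, 1 / 3, 4, NA, 6, 7, 8, 9, 10, 11, 12, 13, 14,
                15, 16), 4, 4)
  g <- rasterGrid(m, gridSpec(4, 4, originX = 100, originY = 200,
                              pixelWidth = 30, crs = "EPSG:32650"))
  p <- file.path(d, "g.asc")
  writeRaster(g, p)
  r <- readRaster(p)
  expect_identical(gridValid(r), gridValid(g))
  expect_equal(gridValues(r), gridValues(g), tolerance = 0)
  expect_true(sameSpec(gridSpecOf(r), gridSpecOf(g)))

  # overwrite replaces the content
  writeRaster(rasterGrid(matrix(0, 4, 4), gridSpecOf(g)), p)
  expect_true(all(gridValues(readRaster(p)) == 0))

  # all-invalid grid: a file of pure nodata
  writeRaster(rasterGrid(matrix(NA_real_, 2, 2)), file.path(d, "na.asc"))
  rn <- readRaster(file.path(d, "na.asc"))
  expect_false(any(gridValid(rn)))

  expect_error(readRaster(file.path(d, "missing.asc")), "exist")
})

test_that("a declared nodata sentinel maps to invalid cells", {
  d <- withr::local_tempdir()
  p <- file.path(d, "s.asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "-9999 2", "3 4"), p)
  r <- readRaster(p)
  expect_false(gridValid(r)[1, 1])
  expect_true(all(gridValid(r)[cbind(c(1, 2, 2), c(2, 1, 2))]))
  expect_equal(gridValues(r)[2, 2], 4)
})

test_that("cube directory layout round-trips through the manifest", {
  d <- withr::local_tempdir()
  spec <- gridSpec(3, 3)
  cube <- rasterCube(list(rasterGrid(matrix(1:9, 3, 3), spec),
                          rasterGrid(matrix(9:1, 3, 3), spec)),
                     as.Date(c("2020-03-01", "2020-03-17")))
  writeCube(cube, file.path(d, "cube"))
  back <- readCube(file.path(d, "cube"))
  expect_equal(cubeDates(back), cubeDates(cube))
  expect_equal(gridValues(cubeLayer(back, 2)), gridValues(cubeLayer(cube, 2)))
})

test_that("bilinear resampling interpolates pixel centers exactly", {
  # identity
  src <- rasterGrid(matrix(rnorm(16), 4, 4))
  expect_equal(gridValues(resampleBilinear(src, gridSpecOf(src))),
               gridValues(src))

  # 1 x 2 source (0, 2); target center midway between the two centers -> 1
  src2 <- rasterGrid(matrix(c(0, 2), 1, 2), gridSpec(1, 2))
  tgt <- gridSpec(1, 1, originX = 0.5, originY = 1)
  expect_equal(gridValues(resampleBilinear(src2, tgt))[1, 1], 1)

  # affine surfaces are reproduced exactly at interior target centers
  spec <- gridSpec(10, 10, pixelWidth = 2)
  xs <- cropcast:::pixelCenterX(spec, 1:10)
  ys <- cropcast:::pixelCenterY(spec, 1:10)
  affine <- function(x, y) 3 + 0.25 * x - 0.5 * y
  src3 <- rasterGrid(outer(ys, xs, function(y, x) affine(x, y)), spec)
  tgt3 <- gridSpec(7, 7, originX = 3, originY = 17, pixelWidth = 1.5)
  out <- resampleBilinear(src3, tgt3)
  expX <- cropcast:::pixelCenterX(tgt3, 1:7)
  expY <- cropcast:::pixelCenterY(tgt3, 1:7)
  expect_equal(gridValues(out), outer(expY, expX, function(y, x) affine(x, y)),
               tolerance = 1e-12)
})

test_that("bilinear output is bounded by its contributing source values", {
  withr::with_seed(7, {
    src <- rasterGrid(matrix(runif(64), 8, 8))
    tgt <- gridSpec(13, 13, originX = 0.7, originY = 7.6,
                    pixelWidth = 0.45)
    out <- resampleBilinear(src, tgt)
    ok <- gridValid(out)
    expect_true(all(gridValues(out)[ok] >= min(gridValues(src)) - 1e-12))
    expect_true(all(gridValues(out)[ok] <= max(gridValues(src)) + 1e-12))
  })
})

test_that("invalid source neighbors and out-of-hull centers invalidate output", {
  m <- matrix(1, 4, 4); m[2, 2] <- NA
  src <- rasterGrid(m, gridSpec(4, 4))
  # half-pixel-shifted target: every interior cell touches 4 source cells
  tgt <- gridSpec(3, 3, originX = 0.5, originY = 3.5)
  out <- resampleBilinear(src, tgt)
  expect_false(gridValid(out)[1, 1])  # neighborhood includes (2,2)
  expect_false(gridValid(out)[2, 2])
  expect_true(gridValid(out)[3, 3])
  # target beyond the source center hull is invalid
  tgt2 <- gridSpec(1, 1, originX = -5, originY = 4)
  expect_error(resampleBilinear(src, tgt2), "disjoint")
  expect_error(resampleBilinear(src, gridSpec(4, 4, crs = "other")), "CRS")
})

test_that("maskWhere keeps values only where the mask is true", {
  g <- rasterGrid(matrix(rnorm(16), 4, 4))
  allTrue <- rasterGrid(matrix(1, 4, 4))
  expect_equal(gridValues(maskWhere(g, allTrue)), gridValues(g))
  allFalse <- rasterGrid(matrix(0, 4, 4))
  expect_false(any(gridValid(maskWhere(g, allFalse))))
  chk <- rasterGrid(matrix(rep(c(1, 0), 8), 4, 4))
  expect_equal(sum(gridValid(maskWhere(g, chk))), sum(gridValues(chk) != 0))
  expect_error(maskWhere(g, rasterGrid(matrix(1, 2, 2))), "share")
})
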