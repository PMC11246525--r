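# small 4 x 4 world with two counties (left/right halves) shared by the
# feature-assembly tests
twoCountyWorld <- function() {
  spec <- gridSpec(4, 4)
  labels <- rasterGrid(matrix(rep(c(1, 1, 2, 2), each = 4), 4, 4), spec)
  list(spec = spec, counties = countyMap(labels),
       mask = rasterGrid(matrix(1, 4, 4), spec))
}

constClimate <- function(spec, years, value = 1) {
  entries <- list()
  for (y in years) {
    slots <- seasonSlots(seasonSpec(y))
    for (s in 1:8) {
      key <- cropcast:::climateKey(slots$year[s], slots$month[s])
      if (is.null(entries[[key]]))
        entries[[key]] <- setNames(lapply(CLIMATE_VARS, function(v)
          rasterGrid(value, spec)), CLIMATE_VARS)
    }
  }
  climateStack(entries)
}

test_that("zonal means average masked valid pixels per county", {
  w <- twoCountyWorld()
  g <- rasterGrid(matrix(7, 4, 4), w$spec)
  zm <- zonalMean(g, w$counties, w$mask)
  expect_equal(zm$mean, c(7, 7))

  # county 2 covering two masked pixels valued 2 and 4 -> 3
  vals <- matrix(NA_real_, 4, 4)
  vals[, 1:2] <- 5
  vals[1, 3] <- 2; vals[2, 3] <- 4
  zm2 <- zonalMean(rasterGrid(vals, w$spec), w$counties, w$mask)
  expect_equal(zm2$mean[zm2$unit_id == 2], 3)
  expect_equal(zm2$n_pixels[zm2$unit_id == 2], 2L)

  # county fully outside the crop mask is omitted and reported
  halfMask <- rasterGrid(matrix(rep(c(1, 1, 0, 0), each = 4), 4, 4), w$spec)
  zm3 <- zonalMean(g, w$counties, halfMask)
  expect_equal(zm3$unit_id, 1L)
  expect_equal(attr(zm3, "omitted"), 2L)
  expect_error(zonalMean(rasterGrid(matrix(1, 2, 2)), w$counties, w$mask),
               "share")
})

test_that("zonal means conserve the masked total", {
  for (seed in 1:20) {
    w <- twoCountyWorld()
    dat <- withr::with_seed(seed, {
      list(v = matrix(runif(16), 4, 4),
           lab = matrix(sample(0:3, 16, TRUE), 4, 4),
           msk = matrix(rbinom(16, 1, 0.7), 4, 4))
    })
    g <- rasterGrid(dat$v, w$spec)
    cm <- countyMap(rasterGrid(dat$lab, w$spec))
    msk <- rasterGrid(dat$msk, w$spec)
    zm <- zonalMean(g, cm, msk)
    lhs <- sum(zm$mean * zm$n_pixels)
    rhs <- sum(dat$v[dat$msk == 1 & dat$lab > 0])
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("climate resampling is identity on-target and exact for affine
           fields", {
  spec <- gridSpec(6, 6, pixelWidth = 4, originY = 30, originX = -3)
  xs <- cropcast:::pixelCenterX(spec, 1:6)
  ys <- cropcast:::pixelCenterY(spec, 1:6)
  affine <- outer(ys, xs, function(y, x) 2 + 0.1 * x + 0.3 * y)
  entries <- list("2020-05" = setNames(lapply(CLIMATE_VARS, function(v)
    rasterGrid(affine, spec)), CLIMATE_VARS))
  st <- climateStack(entries)
  expect_equal(gridValues(climateGrid(resampleClimate(st, spec),
                                      2020, 5, "Pr")), affine)
  fine <- gridSpec(10, 10, originX = 1, originY = 25, pixelWidth = 1.7)
  out <- climateGrid(resampleClimate(st, fine), 2020, 5, "Tmin")
  fx <- cropcast:::pixelCenterX(fine, 1:10)
  fy <- cropcast:::pixelCenterY(fine, 1:10)
  expect_equal(gridValues(out),
               outer(fy, fx, function(y, x) 2 + 0.1 * x + 0.3 * y),
               tolerance = 1e-12)
})

test_that("the county feature matrix joins 48 features with yields and drops
           incomplete rows", {
  w <- twoCountyWorld()
  years <- 2019:2021
  cubes <- setNames(lapply(years, function(y)
    constSlotCube(seq(0.1, 0.8, by = 0.1), w$spec, seasonSpec(y))),
    as.character(years))
  clim <- constClimate(w$spec, years)
  yields <- data.frame(unit_id = rep(1:2, 3), year = rep(years, each = 2),
                       yield_kg_ha = 5000 + 1:6, level = "county")
  fm <- buildFeatureMatrix(cubes, clim, w$counties, w$mask, yields)
  expect_equal(nrow(fm), 6L)
  expect_identical(names(fm), c("unit_id", "year", featureColumns(), "yield"))
  expect_equal(fm$VI_Oct, rep(0.1, 6))
  expect_equal(fm$VI_May, rep(0.8, 6))

  # county missing from the yield table for one year -> that row dropped
  fm2 <- buildFeatureMatrix(cubes, clim, w$counties, w$mask, yields[-1, ])
  expect_equal(nrow(fm2), 5L)
  expect_equal(attr(fm2, "n_dropped_yield"), 1L)

  # all-invalid VI for one season -> both its rows dropped and counted
  cubes3 <- cubes
  cubes3[["2020"]] <- constSlotCube(rep(NA_real_, 8), w$spec,
                                    seasonSpec(2020))
  fm3 <- buildFeatureMatrix(cubes3, clim, w$counties, w$mask, yields)
  expect_equal(nrow(fm3), 4L)
  expect_false(2020L %in% fm3$year)
})

test_that("pixel feature tables share the county schema byte for byte", {
  w <- twoCountyWorld()
  cube <- constSlotCube(seq(0.1, 0.8, by = 0.1), w$spec, seasonSpec(2020))
  clim <- constClimate(w$spec, 2020)
  mask10 <- rasterGrid(matrix(c(rep(1, 10), rep(0, 6)), 4, 4), w$spec)
  pfm <- pixelFeatureTable(cube, clim, mask10, 2020)
  expect_equal(nrow(pfm), 10L)
  expect_identical(names(pfm), c("row", "col", "year", featureColumns()))
  yields <- data.frame(unit_id = 1:2, year = 2020L,
                       yield_kg_ha = c(5000, 6000), level = "county")
  fm <- buildFeatureMatrix(list("2020" = cube), clim, w$counties, w$mask,
                           yields)
  expect_identical(setdiff(names(fm), c("unit_id", "year", "yield")),
                   setdiff(names(pfm), c("row", "col", "year")))
  # masked-out pixels never appear
  expect_true(all(gridValues(mask10)[cbind(pfm$row, pfm$col)] == 1))
})

test_that("forward-month truncation keeps exactly the slots seen so far", {
  fm <- linearFm(12)
  expect_equal(ncol(truncateToMonth(fm, "May")),
               ncol(fm))
  expect_identical(truncateToMonth(fm, "May")[, names(fm)], fm)
  expect_equal(sum(names(truncateToMonth(fm, "Oct")) %in% featureColumns()),
               6L)
  expect_equal(sum(names(truncateToMonth(fm, "Apr")) %in% featureColumns()),
               42L)
  expect_true("yield" %in% names(truncateToMonth(fm, "Oct")))
  expect_error(truncateToMonth(fm, "Jun"), "unknown")
})
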