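test_that("metrics compute R2, RMSE and relative errors as defined", {
  perfect <- yieldMetrics(c(1000, 2000, 3000), c(1000, 2000, 3000))
  expect_equal(reportR2(perfect), 1)
  expect_equal(reportRMSE(perfect), 0)
  expect_true(all(reportRecords(perfect)$re_percent == 0))

  obs <- c(1000, 2000, 1500, 2500)
  atMean <- yieldMetrics(obs, rep(mean(obs), 4))
  expect_equal(reportR2(atMean), 0)

  r <- yieldMetrics(c(1000, 2000), c(1200, 2400))
  expect_equal(reportRecords(r)$re_percent, c(20, 20))
  expect_equal(reportRMSE(r), sqrt((200^2 + 400^2) / 2))

  expect_error(yieldMetrics(1:3, 1:2), "lengths")
  expect_warning(z <- yieldMetrics(c(5, 5), c(4, 6)), "zero variance")
  expect_true(is.na(reportR2(z)))
})

test_that("metrics agree with a scalar brute-force implementation", {
  for (seed in 1:10) {
    v <- withr::with_seed(seed, list(o = runif(50, 1000, 9000),
                                     p = runif(50, 1000, 9000)))
    r <- yieldMetrics(v$o, v$p)
    sse <- 0; sst <- 0
    for (i in 1:50) {
      sse <- sse + (v$p[i] - v$o[i])^2
      sst <- sst + (v$o[i] - mean(v$o))^2
    }
    expect_equal(reportRMSE(r), sqrt(sse / 50), tolerance = 1e-10)
    expect_equal(reportR2(r), 1 - sse / sst, tolerance = 1e-10)
  }
})

test_that("leave-one-year-out partitions records by year", {
  fm <- linearFm(48, seed = 13, sigma = 100, years = 2001:2004)
  spec <- modelSpec("gbm", list(num_leaves = 4L), seed = 2)
  loyo <- leaveOneYearOut(fm, spec)
  reps <- loyoReports(loyo)
  expect_setequal(as.integer(names(reps)), 2001:2004)
  allRecs <- do.call(rbind, lapply(reps, reportRecords))
  expect_equal(nrow(allRecs), 48L)
  for (y in names(reps))
    expect_true(all(reportRecords(reps[[y]])$year == as.integer(y)))
  expect_setequal(paste(allRecs$unit_id, allRecs$year),
                  paste(fm$unit_id, fm$year))

  # a year with a single row is skipped and logged
  fm1 <- rbind(fm, fm[1, ])
  fm1$year[nrow(fm1)] <- 2005L
  fm1$unit_id[nrow(fm1)] <- 999L
  loyo1 <- leaveOneYearOut(fm1, spec)
  expect_false("2005" %in% names(loyoReports(loyo1)))
  expect_equal(attr(loyo1, "skipped_years"), 2005L)
  expect_error(leaveOneYearOut(fm[fm$year < 2003, ], spec), "3 distinct")
})

test_that("relative errors band at +/-20% with a closed inner interval", {
  rep1 <- new("EvalReport", r2 = 1, rmse = 0, n = 5L,
              records = data.frame(unit_id = 1:5, year = 2001L,
                                   observed = rep(1000, 5),
                                   predicted = c(750, 800, 1000, 1200, 1300),
                                   re_percent = c(-25, -20, 0, 20, 30)))
  loyo <- new("LoyoResult", reports = list("2001" = rep1))
  re <- reByUnit(loyo)
  expect_equal(as.character(re$band),
               c("< -20%", "-20..20%", "-20..20%", "-20..20%", "> 20%"))
  expect_equal(nrow(re), 5L)
})

test_that("yield maps place clipped predictions at their pixels", {
  w <- gridSpec(4, 4)
  cube <- constSlotCube(seq(0.1, 0.8, by = 0.1), w, seasonSpec(2020))
  entries <- list()
  slots <- seasonSlots(seasonSpec(2020))
  for (s in 1:8)
    entries[[cropcast:::climateKey(slots$year[s], slots$month[s])]] <-
      setNames(lapply(CLIMATE_VARS, function(v) rasterGrid(1, w)),
               CLIMATE_VARS)
  clim <- climateStack(entries)
  mask <- rasterGrid(matrix(c(rep(1, 10), rep(0, 6)), 4, 4), w)
  pfm <- pixelFeatureTable(cube, clim, mask, 2020)

  fmTrain <- linearFm(30, seed = 2)
  fmTrain$yield <- rep(4200, 30)          # constant-yield model
  fit <- trainModel(fmTrain, modelSpec("gbm", seed = 1))
  map <- yieldMap(fit, pfm, w)
  expect_equal(sum(gridValid(map)), nrow(pfm))
  expect_true(all(abs(gridValues(map)[gridValid(map)] - 4200) < 42))

  # negative predictions are clipped to zero and counted
  fmNeg <- fmTrain; fmNeg$yield <- rep(-500, 30)
  mapNeg <- yieldMap(trainModel(fmNeg, modelSpec("gbm", seed = 1)), pfm, w)
  expect_true(all(gridValues(mapNeg)[gridValid(mapNeg)] == 0))
  expect_equal(attr(mapNeg, "n_clipped"), nrow(pfm))
})

test_that("map validation compares zonal means and site pixels", {
  w <- gridSpec(4, 4)
  labels <- rasterGrid(matrix(rep(c(1, 1, 2, 2), each = 4), 4, 4), w)
  counties <- countyMap(labels)
  mask <- rasterGrid(matrix(1, 4, 4), w)
  vals <- matrix(rep(c(4000, 4000, 6000, 6000), each = 4), 4, 4)
  map <- rasterGrid(vals, w)
  cy <- data.frame(unit_id = 1:2, year = 2020L,
                   yield_kg_ha = c(4000, 6000), level = "county",
                   x = NA, y = NA)
  sy <- data.frame(unit_id = 1:3, year = 2020L,
                   yield_kg_ha = c(4000, 6000, 5000), level = "site",
                   x = c(0.5, 3.5, 99), y = c(3.5, 0.5, 99))
  val <- validateMap(map, counties, mask, cy, sy, 2020)
  expect_equal(reportR2(val$county), 1)
  expect_equal(reportRMSE(val$county), 0)
  expect_equal(reportRecords(val$site)$re_percent, c(0, 0))
  expect_equal(attr(val, "n_sites_skipped"), 1L)  # site outside the grid
})

test_that("forward-month analysis spans Oct..May and matches the full
           evaluation in May", {
  fm <- linearFm(60, seed = 17, sigma = 200)
  grid1 <- list(list(num_leaves = 7L, learning_rate = 0.2))
  tm <- forwardMonthAnalysis(fm, "gbm", grid1, seed = 4)
  expect_equal(nrow(tm), 8L)
  expect_equal(as.character(tm$last_month), SEASON_MONTHS)
  expect_equal(tm$n_features, 6 * (1:8))
  full <- evaluateRandomSplit(fm, "gbm", grid1, seed = 4)
  expect_equal(tm$r2[8], reportR2(full$report))
  expect_equal(tm$rmse[8], reportRMSE(full$report))
})
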