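smallCfg <- function(...) {
  sceneConfig(nRows = 24, nCols = 24, coarseFactor = 6, climateFactor = 12,
              nYears = 2, nCounties = 4, nSites = 3, ...)
}

test_that("the whole scene is a pure function of its config", {
  cfg <- smallCfg(seed = 5)
  t1 <- genTruthVI(cfg, 2001)
  t2 <- genTruthVI(cfg, 2001)
  expect_equal(cropcast:::cubeMatrix(t1), cropcast:::cubeMatrix(t2))
  c1 <- genClimate(cfg, 2001); c2 <- genClimate(cfg, 2001)
  expect_equal(gridValues(climateGrid(c1, 2001, 4, "Pr")),
               gridValues(climateGrid(c2, 2001, 4, "Pr")))
  o1 <- genObservations(t1, cfg); o2 <- genObservations(t2, cfg)
  expect_equal(cropcast:::cubeMatrix(o1$fine), cropcast:::cubeMatrix(o2$fine))
  # a different year gives different fields
  expect_gt(max(abs(cropcast:::cubeMatrix(t1) -
                      cropcast:::cubeMatrix(genTruthVI(cfg, 2002)))), 0.01)
})

test_that("truth phenology stays in range and degenerates to one shared
           curve without spatial variation", {
  cfg <- smallCfg(seed = 2)
  t1 <- genTruthVI(cfg, 2001)
  m <- cropcast:::cubeMatrix(t1)
  expect_true(all(m >= 0.02 & m <= 0.98))
  flat <- smallCfg(seed = 2, phenology = list(pixelSd = 0, shiftSd = 0))
  mf <- cropcast:::cubeMatrix(genTruthVI(flat, 2001))
  expect_true(all(apply(mf, 1, sd) == 0))
})

test_that("fine observations lose the configured cloud fraction, coarse
           observations are exact block means when noiseless", {
  cfg <- sceneConfig(nRows = 48, nCols = 48, coarseFactor = 8,
                     climateFactor = 16, nYears = 1, nCounties = 4,
                     noiseSd = 0, cloudFraction = 0.25, seed = 6)
  truth <- genTruthVI(cfg, 2001)
  obs <- genObservations(truth, cfg)
  fracs <- vapply(obs$fine@layers, function(l) mean(!gridValid(l)),
                  numeric(1))
  expect_true(all(abs(fracs - 0.25) < 0.05))
  # noiseless fine observations equal the truth where not clouded
  i <- match(cubeDates(obs$fine)[3], cubeDates(truth))
  fv <- cubeLayer(obs$fine, 3)
  expect_equal(gridValues(fv)[gridValid(fv)],
               gridValues(cubeLayer(truth, i))[gridValid(fv)])
  # coarse = explicit block average (independent loop oracle)
  j <- match(cubeDates(obs$coarse)[5], cubeDates(truth))
  tv <- gridValues(cubeLayer(truth, j))
  cv <- gridValues(cubeLayer(obs$coarse, 5))
  ref <- matrix(NA_real_, 6, 6)
  for (r in 1:6) for (c in 1:6)
    ref[r, c] <- mean(tv[(8 * r - 7):(8 * r), (8 * c - 7):(8 * c)])
  expect_equal(cv, ref, tolerance = 1e-12)
})

test_that("county tiling partitions every pixel and keeps crop in each
           county", {
  cfg <- smallCfg(seed = 3)
  g <- genCounties(cfg)
  lab <- gridValues(countyLabels(g$counties))
  expect_true(all(lab %in% 1:4))
  expect_equal(sort(unique(as.vector(lab))), 1:4)
  areas <- table(lab)
  expect_true(max(areas) - min(areas) <= 24 * 2)
  for (id in 1:4)
    expect_gt(sum(gridValues(g$cropMask)[lab == id]), 0)
  expect_true(abs(mean(gridValues(g$cropMask)) - cfg@cropFraction) < 0.1)
  sites <- genSites(cfg, g$cropMask)
  expect_equal(nrow(sites), 3L)
  expect_true(all(gridValues(g$cropMask)[cbind(sites$row, sites$col)] == 1))
})

test_that("climate stacks order the temperatures and carry all variables", {
  cfg <- smallCfg(seed = 8)
  st <- genClimate(cfg, 2001)
  expect_length(st@entries, 8L)
  for (e in st@entries) {
    expect_setequal(names(e), CLIMATE_VARS)
    expect_true(all(gridValues(e$Tmax) >= gridValues(e$Tmin)))
    expect_true(all(gridValues(e$Pr) >= 0))
  }
})

test_that("yields are the stated linear function of true features", {
  # sigma = 0: ordinary least squares recovers the coefficients
  cfg <- smallCfg(seed = 4, sigmaY = 0)
  n <- 400
  ft <- withr::with_seed(40, {
    ft <- data.frame(unit_id = seq_len(n), year = 2001L)
    for (cn in featureColumns()) ft[[cn]] <- runif(n)
    ft
  })
  ys <- genYields(ft, cfg)
  expect_true(all(ys$level == "county"))
  X <- cbind(as.matrix(ft[, paste0("VI_", SEASON_MONTHS)]),
             vapply(CLIMATE_VARS, function(v)
               rowMeans(ft[, paste(v, SEASON_MONTHS, sep = "_")]),
               numeric(n)))
  co <- lm.fit(cbind(1, X), ys$yield_kg_ha)$coefficients
  expect_equal(unname(co[1]), cfg@beta0, tolerance = 1e-6)
  expect_equal(unname(co[2:9]), unname(cfg@betaVi), tolerance = 1e-6)
  expect_equal(unname(co[10:14]), unname(cfg@gamma), tolerance = 1e-6)

  # all-zero coefficients with intercept 5000: every yield is 5000
  cfg0 <- smallCfg(seed = 4, sigmaY = 0, beta0 = 5000,
                   betaVi = setNames(rep(0, 8), SEASON_MONTHS),
                   gamma = setNames(rep(0, 5), CLIMATE_VARS))
  expect_true(all(genYields(ft, cfg0)$yield_kg_ha == 5000))

  # doubling the VI features shifts yields by the VI contribution
  ft2 <- ft
  for (m in SEASON_MONTHS) ft2[[paste0("VI_", m)]] <-
    2 * ft[[paste0("VI_", m)]]
  d <- genYields(ft2, cfg)$yield_kg_ha - ys$yield_kg_ha
  expected <- as.matrix(ft[, paste0("VI_", SEASON_MONTHS)]) %*% cfg@betaVi
  expect_equal(d, as.numeric(expected), tolerance = 1e-8)

  # site records carry coordinates and independent noise
  sf <- ft[1:5, ]
  sf$x <- 1:5; sf$y <- 5:1
  both <- genYields(ft, smallCfg(seed = 4, sigmaY = 100), siteFeatures = sf)
  expect_equal(sum(both$level == "site"), 5L)
  expect_false(anyNA(both$x[both$level == "site"]))
})
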