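# Shared fixtures, all built in code.

# constant-per-slot monthly cube on a given spec
constSlotCube <- function(vals, spec, season = seasonSpec(2020)) {
  dates <- cropcast:::seasonSlotDates(season)
  rasterCube(lapply(vals, function(v) rasterGrid(v, spec)), dates)
}

# single-pixel cube from a numeric series (NA = invalid)
seriesCube <- function(series, dates = NULL) {
  spec <- gridSpec(1, 1)
  if (is.null(dates))
    dates <- seq(as.Date("2020-01-15"), by = "1 month",
                 length.out = length(series))
  rasterCube(lapply(series, function(v)
    rasterGrid(matrix(v, 1, 1), spec)), dates)
}

seriesOf <- function(cube) as.vector(cropcast:::cubeMatrix(cube))

# feature matrix with independent N(0,1) features and a linear target
linearFm <- function(n, seed = 1, beta = NULL, sigma = 0,
                     years = 2001:2004) {
  cols <- featureColumns()
  withr::with_seed(seed, {
    fm <- data.frame(unit_id = seq_len(n),
                     year = rep_len(years, n))
    for (cn in cols) fm[[cn]] <- rnorm(n)
    if (is.null(beta)) beta <- rnorm(length(cols), 0, 200)
    fm$yield <- 5000 + as.matrix(fm[, cols]) %*% beta + rnorm(n, 0, sigma)
    fm$yield <- as.numeric(fm$yield)
    fm
  })
}

# the default study scene, built once and reused by the acceptance tests
.fixtures <- new.env(parent = emptyenv())

acceptanceScene <- function() {
  if (is.null(.fixtures$scene))
    .fixtures$scene <- synthScene(sceneConfig(seed = 1))
  .fixtures$scene
}

# reduced scene for the timing experiment: yields driven only by April VI,
# with a late-season stress field so April carries information that earlier
# months cannot predict
timingConfig <- function(seed) {
  sceneConfig(nRows = 60, nCols = 60, coarseFactor = 10, climateFactor = 20,
              nYears = 12, nCounties = 25, nSites = 5,
              phenology = list(lateStressSd = 0.2, stressOnsetSlot = 6.5),
              betaVi = c(Oct = 0, Nov = 0, Dec = 0, Jan = 0, Feb = 0,
                         Mar = 0, Apr = 15000, May = 0),
              gamma = c(Pr = 0, Tmax = 0, Tmin = 0, VPD = 0, SM = 0),
              beta0 = 2500, seed = seed)
}

# reduced low-noise scene for map validation
mapsConfig <- function(seed) {
  sceneConfig(nRows = 60, nCols = 60, coarseFactor = 10, climateFactor = 20,
              nYears = 8, nCounties = 25, nSites = 13, noiseSd = 0.005,
              seed = seed)
}
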