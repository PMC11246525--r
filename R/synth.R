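# Deterministic synthetic scenes: seasonal VI phenology with smooth spatial
# parameter fields, paired fine (sparse, cloud-gapped) and coarse (dense,
# block-aggregated) sensors, monthly climate fields on a coarser grid, a
# county partition with a clumpy crop mask, and county/site yields generated
# from a stated linear function of the TRUE (pre-gap, pre-noise) monthly
# features plus noise.  Everything is a pure function of the SceneConfig,
# including its master seed.

#' SceneConfig: all parameters of a synthetic study scene
#'
#' The defaults emulate the study conditions the pipeline targets: a
#' 120 x 120 fine grid with a coarse sensor of 16 x 16-pixel blocks
#' (30 m vs ~500 m), 100 counties observed over 20 harvest years
#' (2001--2020, 2000 county-year records), 2 fine and 4 coarse observations
#' per month, 30\% spatially correlated cloud cover per fine observation,
#' reflectance noise of 0.01, 13 validation sites, and county yields around
#' 4000--8000 kg/ha with residual noise sigmaY = 300 kg/ha.
#'
#' @slot fineSpec fine-sensor [GridSpec-class].
#' @slot coarseFactor coarse pixel edge in fine pixels (>= 2).
#' @slot climateFactor climate pixel edge in fine pixels.
#' @slot nYears,firstYear harvest years `firstYear .. firstYear + nYears - 1`.
#' @slot fineRevisit,coarseRevisit observations per month for each sensor.
#' @slot cloudFraction fraction of fine pixels lost per observation, in
#'   [0, 1].
#' @slot noiseSd reflectance noise sd added to each sensed band.
#' @slot nCounties,cropFraction,nSites county partition, crop-mask share and
#'   validation-site count.
#' @slot phenology named list: `base`, `peak` (VI bounds), `greenupSlot`,
#'   `senescenceSlot` (inflection points in slot coordinates, 1 = mid
#'   October), `greenupRate`, `senescenceRate`, `pixelSd` (spatial sd of the
#'   peak field), `shiftSd` (spatial sd of the green-up timing field, in
#'   slots), `yearAmpSd`, `yearShiftSd` (year effects), `lateStressSd`
#'   (spatial sd of a late-season stress multiplier applied from
#'   `stressOnsetSlot` onward; 0 disables it), `stressOnsetSlot`.
#' @slot beta0,betaVi,gamma,sigmaY yield model: yield = beta0 +
#'   sum(betaVi * VI_slot) + sum(gamma * season-mean climate) + N(0, sigmaY^2),
#'   floored at 100 kg/ha.
#' @slot yieldVi which index the yields are generated from.
#' @slot seed master seed; the entire dataset is a pure function of the
#'   config.
#' @export
setClass("SceneConfig",
  representation(fineSpec = "GridSpec", coarseFactor = "integer",
                 climateFactor = "integer", nYears = "integer",
                 firstYear = "integer", fineRevisit = "integer",
                 coarseRevisit = "integer", cloudFraction = "numeric",
                 noiseSd = "numeric", nCounties = "integer",
                 cropFraction = "numeric", nSites = "integer",
                 phenology = "list", beta0 = "numeric", betaVi = "numeric",
                 gamma = "numeric", sigmaY = "numeric", yieldVi = "character",
                 seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- NULL
  if (object@coarseFactor < 2L) msg <- c(msg, "coarseFactor must be >= 2")
  if (object@cloudFraction < 0 || object@cloudFraction > 1)
    msg <- c(msg, "cloudFraction must lie in [0, 1]")
  ph <- object@phenology
  if (ph$peak > 1) msg <- c(msg, "peak VI must be <= 1")
  if (ph$base >= ph$peak) msg <- c(msg, "base VI must be below peak VI")
  if (length(object@betaVi) != 8L)
    msg <- c(msg, "betaVi must have one coefficient per month slot")
  if (length(object@gamma) != 5L)
    msg <- c(msg, "gamma must have one coefficient per climate variable")
  if (!object@yieldVi %in% c("NDVI", "NIRv", "kNDVI"))
    msg <- c(msg, "yieldVi must be NDVI, NIRv or kNDVI")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SceneConfig
#'
#' @param nRows,nCols fine-grid size (default 120 x 120, pixel 1 unit).
#' @param coarseFactor,climateFactor block sizes of the coarse sensor and
#'   climate grid in fine pixels.
#' @param nYears,firstYear season coverage.
#' @param fineRevisit,coarseRevisit observations per month.
#' @param cloudFraction,noiseSd fine-sensor gap fraction and band noise.
#' @param nCounties,cropFraction,nSites partition, crop share, site count.
#' @param phenology overrides for the phenology list (see
#'   [SceneConfig-class]).
#' @param beta0,betaVi,gamma,sigmaY yield-model coefficients (kg/ha scale;
#'   `betaVi` named Oct..May, `gamma` named after [CLIMATE_VARS]).
#' @param yieldVi index driving the yields (default `"NIRv"`).
#' @param seed master seed.
#' @return A [SceneConfig-class].
#' @export
sceneConfig <- function(nRows = 120L, nCols = 120L, coarseFactor = 16L,
                        climateFactor = 40L, nYears = 20L, firstYear = 2001L,
                        fineRevisit = 2L, coarseRevisit = 4L,
                        cloudFraction = 0.3, noiseSd = 0.01,
                        nCounties = 100L, cropFraction = 0.6, nSites = 13L,
                        phenology = list(), beta0 = 1400,
                        betaVi = c(Oct = 1000, Nov = 800, Dec = 500,
                                   Jan = 400, Feb = 800, Mar = 2500,
                                   Apr = 9000, May = 4000),
                        gamma = c(Pr = 8, Tmax = -60, Tmin = 40,
                                  VPD = -800, SM = 15),
                        sigmaY = 300, yieldVi = "NIRv", seed = 1L) {
  ph <- utils::modifyList(
    list(base = 0.15, peak = 0.85, greenupSlot = 4.5, senescenceSlot = 8.3,
         greenupRate = 1.3, senescenceRate = 2.0, pixelSd = 0.08,
         shiftSd = 0.3, yearAmpSd = 0.05, yearShiftSd = 0.3,
         lateStressSd = 0, stressOnsetSlot = 7), phenology)
  new("SceneConfig",
      fineSpec = gridSpec(nRows, nCols, crs = "synthetic"),
      coarseFactor = as.integer(coarseFactor),
      climateFactor = as.integer(climateFactor), nYears = as.integer(nYears),
      firstYear = as.integer(firstYear), fineRevisit = as.integer(fineRevisit),
      coarseRevisit = as.integer(coarseRevisit),
      cloudFraction = cloudFraction, noiseSd = noiseSd,
      nCounties = as.integer(nCounties), cropFraction = cropFraction,
      nSites = as.integer(nSites), phenology = ph, beta0 = beta0,
      betaVi = betaVi, gamma = gamma, sigmaY = sigmaY, yieldVi = yieldVi,
      seed = as.integer(seed))
}

#' Harvest years of a scene
#' @param config a [SceneConfig-class].
#' @export
sceneYears <- function(config)
  seq(config@firstYear, length.out = config@nYears)

# ---------------------------------------------------------------------------
# building blocks

# smooth random field on a spec: white noise on a lattice of ~`scale`-unit
# cells (extended one cell beyond the grid so the bilinear hull covers it),
# upsampled bilinearly, then demeaned and rescaled to exactly `sdTarget`
smoothField <- function(spec, sdTarget, seed, scale = 15) {
  w <- scale * spec@pixelWidth
  nr <- ceiling(spec@nRows * spec@pixelHeight / w) + 2L
  nc <- ceiling(spec@nCols * spec@pixelWidth / w) + 2L
  latSpec <- gridSpec(nr, nc, originX = spec@originX - w,
                      originY = spec@originY + w, pixelWidth = w,
                      pixelHeight = w, crs = spec@crs)
  noise <- withSeed(seed, matrix(rnorm(nr * nc), nr, nc))
  up <- resampleBilinear(rasterGrid(noise, latSpec), spec)@values
  if (sdTarget == 0) return(up * 0)
  up <- up - mean(up)
  s <- sd(as.vector(up))
  if (s == 0) up else up / s * sdTarget
}

# mean over factor x factor blocks of a value matrix (NA-aware); ragged edge
# blocks average over the pixels that exist
blockMeanMatrix <- function(values, valid, k) {
  rg <- ((seq_len(nrow(values)) - 1L) %/% k) + 1L
  cg <- ((seq_len(ncol(values)) - 1L) %/% k) + 1L
  v <- values; v[!valid] <- 0
  sums <- t(rowsum(t(rowsum(v, rg)), cg))
  cnts <- t(rowsum(t(rowsum(valid + 0, rg)), cg))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  dimnames(out) <- NULL
  out
}

# coarse-sensor GridSpec aligned to the fine grid's top-left corner
coarseSpecOf <- function(config) {
  f <- config@fineSpec
  k <- config@coarseFactor
  gridSpec(ceiling(f@nRows / k), ceiling(f@nCols / k), originX = f@originX,
           originY = f@originY, pixelWidth = k * f@pixelWidth,
           pixelHeight = k * f@pixelHeight, crs = f@crs)
}

#' Block-mean aggregation of a grid to the coarse sensor's spec
#'
#' Each coarse pixel is the arithmetic mean of the valid fine pixels inside
#' its k x k block (edge blocks may be ragged); invalid when the block holds
#' no valid pixel.
#'
#' @param grid a [RasterGrid-class] on the fine grid.
#' @param config a [SceneConfig-class].
#' @return A [RasterGrid-class] on the coarse spec.
#' @export
blockAggregate <- function(grid, config) {
  out <- blockMeanMatrix(grid@values, grid@valid, config@coarseFactor)
  rasterGrid(out, coarseSpecOf(config))
}

# observation days-of-month, evenly placed
revisitDays <- function(nDays, revisit)
  pmax(1L, pmin(nDays, round((seq_len(revisit) - 0.5) * nDays / revisit)))

obsDates <- function(config, year, revisit) {
  slots <- seasonSlots(seasonSpec(year))
  out <- as.Date(character())
  for (s in 1:8) {
    first <- as.Date(sprintf("%d-%02d-01", slots$year[s], slots$month[s]))
    nDays <- as.integer(seq(first, by = "1 month", length.out = 2)[2] - first)
    out <- c(out, first + revisitDays(nDays, revisit) - 1L)
  }
  out
}

# continuous season coordinate of a date (1 = mid October .. 8 = mid May)
seasonCoord <- function(dates, year) {
  slots <- seasonSlots(seasonSpec(year))
  mids <- seasonSlotDates(seasonSpec(year))
  idx <- match(format(dates, "%Y-%m"), sprintf("%d-%02d", slots$year,
                                               slots$month))
  if (anyNA(idx)) stop("date outside the season span")
  idx + as.numeric(dates - mids[idx]) / 30.44
}

# per-year phenology parameter fields (pure function of config and year)
phenologyFields <- function(config, year) {
  ph <- config@phenology
  spec <- config@fineSpec
  yr <- withSeed(childSeed(config@seed, "year", year), {
    list(amp = rnorm(1, 0, ph$yearAmpSd), shift = rnorm(1, 0, ph$yearShiftSd))
  })
  peak <- ph$peak + yr$amp +
    smoothField(spec, ph$pixelSd, childSeed(config@seed, "amp", year))
  peak <- pmin(pmax(peak, ph$base + 0.05), 0.98)
  shift <- yr$shift +
    smoothField(spec, ph$shiftSd, childSeed(config@seed, "shift", year))
  stress <- if (ph$lateStressSd > 0)
    pmin(pmax(smoothField(spec, ph$lateStressSd,
                          childSeed(config@seed, "stress", year)) +
                2 * ph$lateStressSd, 0), 0.9)
  else matrix(0, spec@nRows, spec@nCols)
  list(peak = peak, shift = shift, stress = stress)
}

#' Dense truth VI cube for one season
#'
#' Evaluates, per pixel, a double-logistic seasonal NDVI curve (green-up
#' inflection, senescence decline) whose peak and timing vary through smooth
#' spatial fields plus a common year effect, optionally damped from the
#' stress-onset slot onward by a smooth late-season stress field.  Values
#' are clamped to [0.02, 0.98].  Deterministic per (config seed, year).
#'
#' @param config a [SceneConfig-class].
#' @param year harvest year.
#' @param dates evaluation dates (default: the union of both sensors'
#'   revisit dates).
#' @return A truth NDVI [RasterCube-class] on the fine grid.
#' @export
genTruthVI <- function(config, year, dates = NULL) {
  if (is.null(dates))
    dates <- sort(unique(c(obsDates(config, year, config@fineRevisit),
                           obsDates(config, year, config@coarseRevisit))))
  ph <- config@phenology
  flds <- phenologyFields(config, year)
  s <- seasonCoord(dates, year)
  spec <- config@fineSpec
  layers <- lapply(seq_along(dates), function(i) {
    up <- sigmoid(ph$greenupRate * (s[i] - (ph$greenupSlot + flds$shift)))
    down <- sigmoid(ph$senescenceRate * (s[i] - ph$senescenceSlot))
    vi <- ph$base + (flds$peak - ph$base) * (up - down)
    if (s[i] >= ph$stressOnsetSlot) vi <- vi * (1 - flds$stress)
    rasterGrid(pmin(pmax(vi, 0.02), 0.98), spec)
  })
  rasterCube(layers, dates)
}

# spatially correlated cloud mask (TRUE = cloudy) covering exactly the
# requested fraction of pixels, via quantile-thresholded smooth noise
cloudMask <- function(config, seed) {
  spec <- config@fineSpec
  if (config@cloudFraction <= 0)
    return(matrix(FALSE, spec@nRows, spec@nCols))
  f <- smoothField(spec, 1, seed, scale = 10)
  f >= quantile(f, 1 - config@cloudFraction)
}

#' Sample fine and coarse VI observations from a truth cube
#'
#' The fine cube samples the truth at the fine revisit dates, adds
#' N(0, noiseSd) and invalidates a spatially correlated cloud mask covering
#' `cloudFraction` of pixels per date.  The coarse cube is the k x k block
#' mean of the truth at the coarse revisit dates on the coarse grid, plus
#' noise.  Both are deterministic per config seed.
#'
#' @param truth truth [RasterCube-class] containing all revisit dates (see
#'   [genTruthVI()]).
#' @param config a [SceneConfig-class].
#' @return list with cubes `fine` and `coarse`.
#' @export
genObservations <- function(truth, config) {
  year <- as.integer(format(max(truth@timestamps), "%Y"))
  spec <- config@fineSpec
  sampleDates <- function(revisit) {
    d <- obsDates(config, year, revisit)
    idx <- match(d, truth@timestamps)
    if (anyNA(idx)) stop("truth cube lacks some revisit dates")
    idx
  }
  fineIdx <- sampleDates(config@fineRevisit)
  fineDates <- truth@timestamps[fineIdx]
  fineLayers <- lapply(seq_along(fineIdx), function(j) {
    v <- truth@layers[[fineIdx[j]]]@values
    if (config@noiseSd > 0)
      v <- v + withSeed(childSeed(config@seed, "fnoise", year, j),
                        matrix(rnorm(length(v), 0, config@noiseSd),
                               nrow(v), ncol(v)))
    cl <- cloudMask(config, childSeed(config@seed, "cloud", year, j))
    v[cl] <- NA_real_
    rasterGrid(v, spec, !cl & truth@layers[[fineIdx[j]]]@valid)
  })
  coarseIdx <- sampleDates(config@coarseRevisit)
  coarseDates <- truth@timestamps[coarseIdx]
  cSpec <- coarseSpecOf(config)
  coarseLayers <- lapply(seq_along(coarseIdx), function(j) {
    g <- blockAggregate(truth@layers[[coarseIdx[j]]], config)
    v <- g@values
    if (config@noiseSd > 0)
      v <- v + withSeed(childSeed(config@seed, "cnoise", year, j),
                        matrix(rnorm(length(v), 0, config@noiseSd),
                               nrow(v), ncol(v)))
    rasterGrid(v, cSpec, g@valid)
  })
  list(fine = rasterCube(fineLayers, fineDates),
       coarse = rasterCube(coarseLayers, coarseDates))
}

# NIR reflectance of a canopy as a function of NDVI, and the red band that
# reproduces the NDVI exactly given that NIR
nirFromNdvi <- function(n) 0.12 + 0.45 * n
redFromNdvi <- function(n, nir) nir * (1 - n) / (1 + n)

#' Sample fine and coarse red/NIR band observations
#'
#' Derives red and NIR reflectance from the truth NDVI (a fixed linear
#' canopy NIR relation plus the exact NDVI inversion for red), then applies
#' the same sampling model as [genObservations()]: per-band noise, one
#' shared cloud mask per fine date, block aggregation of the bands (not of
#' the index) for the coarse sensor.
#'
#' @param config a [SceneConfig-class].
#' @param year harvest year.
#' @return nested list: `fine$red`, `fine$nir`, `coarse$red`, `coarse$nir`
#'   ([RasterCube-class]s), plus `truth` (the NDVI truth cube).
#' @export
genBandObservations <- function(config, year) {
  truth <- genTruthVI(config, year)
  spec <- config@fineSpec
  cSpec <- coarseSpecOf(config)
  nirOf <- function(l) nirFromNdvi(l@values)
  redOf <- function(l) redFromNdvi(l@values, nirFromNdvi(l@values))
  noise <- function(tag, year, j, d)
    withSeed(childSeed(config@seed, tag, year, j),
             matrix(rnorm(prod(d), 0, config@noiseSd), d[1], d[2]))
  fineIdx <- match(obsDates(config, year, config@fineRevisit),
                   truth@timestamps)
  fr <- list(); fn <- list()
  for (j in seq_along(fineIdx)) {
    l <- truth@layers[[fineIdx[j]]]
    cl <- cloudMask(config, childSeed(config@seed, "cloud", year, j))
    d <- dim(l@values)
    red <- redOf(l); nir <- nirOf(l)
    if (config@noiseSd > 0) {
      red <- red + noise("fred", year, j, d)
      nir <- nir + noise("fnir", year, j, d)
    }
    red[cl] <- NA_real_; nir[cl] <- NA_real_
    fr[[j]] <- rasterGrid(red, spec, !cl)
    fn[[j]] <- rasterGrid(nir, spec, !cl)
  }
  coarseIdx <- match(obsDates(config, year, config@coarseRevisit),
                     truth@timestamps)
  cr <- list(); cn <- list()
  for (j in seq_along(coarseIdx)) {
    l <- truth@layers[[coarseIdx[j]]]
    red <- blockMeanMatrix(redOf(l), l@valid, config@coarseFactor)
    nir <- blockMeanMatrix(nirOf(l), l@valid, config@coarseFactor)
    d <- dim(red)
    if (config@noiseSd > 0) {
      red <- red + noise("cred", year, j, d)
      nir <- nir + noise("cnir", year, j, d)
    }
    cr[[j]] <- rasterGrid(red, cSpec)
    cn[[j]] <- rasterGrid(nir, cSpec)
  }
  fd <- truth@timestamps[fineIdx]; cd <- truth@timestamps[coarseIdx]
  list(fine = list(red = rasterCube(fr, fd), nir = rasterCube(fn, fd)),
       coarse = list(red = rasterCube(cr, cd), nir = rasterCube(cn, cd)),
       truth = truth)
}

#' Rectangular county partition and clumpy crop mask
#'
#' Tiles the fine grid into near-equal rectangles (the most square factor
#' pair of `nCounties`), so every pixel carries exactly one county id, and
#' draws a spatially clumped crop mask covering `cropFraction` of pixels
#' (quantile-thresholded smooth noise).  Counties left without a crop pixel
#' get their best-scoring pixel forced into the mask.
#'
#' @param config a [SceneConfig-class].
#' @return list with `counties` (a [CountyMap-class]) and `cropMask` (a
#'   boolean [RasterGrid-class]).
#' @export
genCounties <- function(config) {
  spec <- config@fineSpec
  n <- config@nCounties
  r <- floor(sqrt(n))
  while (n %% r != 0L) r <- r - 1L
  cBands <- n %/% r
  if (r > spec@nRows || cBands > spec@nCols)
    stop("cannot tile ", n, " counties onto the grid")
  rowBand <- ceiling(seq_len(spec@nRows) / spec@nRows * r)
  colBand <- ceiling(seq_len(spec@nCols) / spec@nCols * cBands)
  labels <- outer(rowBand, colBand, function(a, b) (a - 1L) * cBands + b)
  f <- smoothField(spec, 1, childSeed(config@seed, "crop"), scale = 12)
  mask <- f >= quantile(f, 1 - config@cropFraction)
  for (id in seq_len(n)) {
    inC <- labels == id
    if (!any(mask[inC])) {
      cand <- which(inC & f == max(f[inC]))[1]
      mask[cand] <- TRUE
    }
  }
  list(counties = countyMap(rasterGrid(labels, spec)),
       cropMask = rasterGrid(mask + 0, spec))
}

#' Validation sites at fixed random crop pixels
#'
#' @param config a [SceneConfig-class].
#' @param cropMask the boolean crop mask from [genCounties()].
#' @return data.frame with columns `unit_id`, `row`, `col`, `x`, `y`.
#' @export
genSites <- function(config, cropMask) {
  spec <- config@fineSpec
  pix <- which(cropMask@values != 0 & cropMask@valid)
  pick <- withSeed(childSeed(config@seed, "sites"),
                   sample(pix, min(config@nSites, length(pix))))
  row <- ((pick - 1L) %% spec@nRows) + 1L
  col <- ((pick - 1L) %/% spec@nRows) + 1L
  data.frame(unit_id = seq_along(pick), row = row, col = col,
             x = pixelCenterX(spec, col), y = pixelCenterY(spec, row))
}

# seasonal monthly means (Oct..May) of the five climate variables, chosen
# for a temperate winter-wheat plain, and the scales of their anomalies
CLIMATE_SEASONAL <- list(
  Pr   = c(18, 12, 6, 4, 6, 12, 25, 35),      # mm
  Tmax = c(20, 12, 5, 3, 6, 13, 21, 27),      # degC
  Tmin = c(8, 0, -6, -8, -5, 1, 9, 15),       # degC
  VPD  = c(0.8, 0.5, 0.3, 0.3, 0.4, 0.7, 1.1, 1.6),  # kPa
  SM   = c(25, 22, 18, 15, 16, 20, 18, 14))   # mm
CLIMATE_ANOM_SD <- c(Pr = 6, Tmax = 1.5, Tmin = 1.5, VPD = 0.15, SM = 4)

# climate GridSpec: coarser than the coarse sensor and extended one pixel
# beyond the fine grid so bilinear resampling covers every fine center
climateSpecOf <- function(config) {
  f <- config@fineSpec
  w <- config@climateFactor * f@pixelWidth
  gridSpec(ceiling(f@nRows * f@pixelHeight / w) + 2L,
           ceiling(f@nCols * f@pixelWidth / w) + 2L,
           originX = f@originX - w, originY = f@originY + w,
           pixelWidth = w, pixelHeight = w, crs = f@crs)
}

#' Monthly climate stack for one season
#'
#' Each variable and month is a smooth spatial gradient plus a seasonal
#' cycle, a common year anomaly and smooth noise, generated on a climate
#' grid coarser than the coarse sensor.  Tmax is built as Tmin plus a
#' positive diurnal range, so Tmax >= Tmin everywhere by construction.
#' Pr and SM are floored at 0.  Deterministic per config seed.
#'
#' @param config a [SceneConfig-class].
#' @param year harvest year.
#' @return A [ClimateStack-class] with the season's 8 month slots.
#' @export
genClimate <- function(config, year) {
  spec <- climateSpecOf(config)
  slots <- seasonSlots(seasonSpec(year))
  xg <- matrix(pixelCenterX(spec, seq_len(spec@nCols)), spec@nRows,
               spec@nCols, byrow = TRUE)
  yg <- matrix(pixelCenterY(spec, seq_len(spec@nRows)), spec@nRows,
               spec@nCols)
  ext <- max(diff(range(xg)), diff(range(yg)), 1)
  entries <- list()
  for (s in 1:8) {
    e <- list()
    made <- list()
    for (v in CLIMATE_VARS) {
      sdv <- CLIMATE_ANOM_SD[[v]]
      base <- CLIMATE_SEASONAL[[v]][s]
      seeds <- childSeed(config@seed, "clim", year, s, v)
      parts <- withSeed(seeds, list(anom = rnorm(1, 0, sdv),
                                    gx = rnorm(1, 0, sdv / ext),
                                    gy = rnorm(1, 0, sdv / ext)))
      fld <- base + parts$anom + parts$gx * (xg - mean(xg)) +
        parts$gy * (yg - mean(yg)) +
        smoothField(spec, sdv / 2, childSeed(seeds, "f"),
                    scale = 2 * spec@pixelWidth / spec@pixelWidth)
      made[[v]] <- fld
    }
    # enforce Tmax >= Tmin via a positive diurnal range
    rng <- abs(made$Tmax - made$Tmin - 10) + 2
    made$Tmax <- made$Tmin + rng
    made$Pr <- pmax(made$Pr, 0)
    made$SM <- pmax(made$SM, 0)
    for (v in CLIMATE_VARS) e[[v]] <- rasterGrid(made[[v]], spec)
    entries[[climateKey(slots$year[s], slots$month[s])]] <- e
  }
  climateStack(entries)
}

#' County and site yields from true features
#'
#' yield = beta0 + sum_slot betaVi[slot] * VI_slot + sum_var gamma[var] *
#' mean_slot(var) + N(0, sigmaY^2), floored at 100 kg/ha.  County yields use
#' the county's true feature row; site yields apply the same formula to the
#' site pixel's features with independent noise.  Deterministic per config
#' seed.
#'
#' @param countyFeatures county feature matrix (true, pre-sensor features;
#'   columns of [featureColumns()] plus `unit_id`, `year`).
#' @param config a [SceneConfig-class].
#' @param siteFeatures optional per-site feature matrix with `unit_id`,
#'   `year` and the same feature columns (e.g. truth-pixel rows).
#' @return data.frame of records: `unit_id`, `year`, `yield_kg_ha`, `level`,
#'   `x`, `y` (NA at county level).
#' @export
genYields <- function(countyFeatures, config, siteFeatures = NULL) {
  linpred <- function(fm) {
    out <- rep(config@beta0, nrow(fm))
    for (m in SEASON_MONTHS)
      out <- out + config@betaVi[[m]] * fm[[paste0("VI_", m)]]
    for (v in CLIMATE_VARS) {
      cols <- paste(v, SEASON_MONTHS, sep = "_")
      out <- out + config@gamma[[v]] * rowMeans(fm[, cols])
    }
    out
  }
  cy <- linpred(countyFeatures)
  cy <- cy + withSeed(childSeed(config@seed, "yield-county"),
                      rnorm(length(cy), 0, config@sigmaY))
  county <- data.frame(unit_id = countyFeatures$unit_id,
                       year = countyFeatures$year,
                       yield_kg_ha = pmax(cy, 100), level = "county",
                       x = NA_real_, y = NA_real_)
  site <- NULL
  if (!is.null(siteFeatures)) {
    sy <- linpred(siteFeatures)
    sy <- sy + withSeed(childSeed(config@seed, "yield-site"),
                        rnorm(length(sy), 0, config@sigmaY))
    site <- data.frame(unit_id = siteFeatures$unit_id,
                       year = siteFeatures$year,
                       yield_kg_ha = pmax(sy, 100), level = "site",
                       x = siteFeatures$x, y = siteFeatures$y)
  }
  rbind(county, site)
}

# derive a VI cube from an NDVI truth cube via the band relations
truthIndexCube <- function(truth, viName) {
  if (viName == "NDVI") return(truth)
  layers <- lapply(truth@layers, function(l) {
    nir <- rasterGrid(nirFromNdvi(l@values), l@spec, l@valid)
    if (viName == "NIRv") computeNIRv(l, nir) else computeKNDVI(l)
  })
  rasterCube(layers, truth@timestamps)
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generative pipeline for every season: truth phenology,
#' band observations, VI computation, reconstruction (compositing,
#' interpolation, smoothing, fusion), climate, zonal features, and yields
#' generated from the TRUE (pre-gap, pre-noise) features so that sensor and
#' reconstruction error stay separable from model error.
#'
#' @param config a [SceneConfig-class].
#' @param viNames indices to reconstruct features for (default: the
#'   config's `yieldVi`).
#' @param sg [SGParams-class] for reconstruction.
#' @param years subset of harvest years (default all).
#' @param keepCubes also return the fused VI cubes (memory permitting).
#' @return list with `config`, `counties`, `cropMask`, `sites`, `climate`
#'   (fine grid), `yields`, `trueFeatures`, `features` (named list per VI,
#'   each a ready feature matrix with target), `sitesTrueFeatures`, and
#'   optionally `cubes`.
#' @export
synthScene <- function(config, viNames = config@yieldVi, sg = sgParams(),
                       years = NULL, keepCubes = FALSE) {
  if (is.null(years)) years <- sceneYears(config)
  cm <- genCounties(config)
  sites <- genSites(config, cm$cropMask)
  fineSpec <- config@fineSpec
  trueRows <- list(); siteRows <- list()
  fused <- lapply(viNames, function(v) list())
  names(fused) <- viNames
  climFine <- list()
  for (yr in years) {
    season <- seasonSpec(yr)
    clim <- resampleClimate(genClimate(config, yr), fineSpec)
    climFine[[as.character(yr)]] <- clim
    bands <- genBandObservations(config, yr)
    truthVi <- truthIndexCube(bands$truth, config@yieldVi)
    truthMonthly <- monthlyMaxComposite(truthVi, season)
    trueRows[[as.character(yr)]] <- countySeasonFeatures(
      truthMonthly, clim, cm$counties, cm$cropMask, season)
    trueRows[[as.character(yr)]]$year <- yr
    pixTruth <- pixelFeatureTable(truthMonthly, clim, cm$cropMask, yr)
    key <- paste(pixTruth$row, pixTruth$col)
    sIdx <- match(paste(sites$row, sites$col), key)
    sr <- pixTruth[sIdx[!is.na(sIdx)], , drop = FALSE]
    sr$unit_id <- sites$unit_id[!is.na(sIdx)]
    sr$x <- sites$x[!is.na(sIdx)]; sr$y <- sites$y[!is.na(sIdx)]
    siteRows[[as.character(yr)]] <- sr
    for (v in viNames) {
      fineVi <- viCube(bands$fine$red, bands$fine$nir, v)
      coarseVi <- viCube(bands$coarse$red, bands$coarse$nir, v)
      fused[[v]][[as.character(yr)]] <-
        reconstructSeason(fineVi, coarseVi, season, sg)
    }
  }
  trueFeatures <- do.call(rbind, trueRows)
  rownames(trueFeatures) <- NULL
  siteTrue <- do.call(rbind, siteRows)
  yields <- genYields(trueFeatures, config, siteTrue)
  mergedClim <- climateStack(do.call(c, unname(lapply(climFine,
                                                      function(s) s@entries))))
  features <- lapply(viNames, function(v)
    buildFeatureMatrix(fused[[v]], mergedClim, cm$counties, cm$cropMask,
                       yields))
  names(features) <- viNames
  out <- list(config = config, counties = cm$counties,
              cropMask = cm$cropMask, sites = sites, climate = mergedClim,
              yields = yields, trueFeatures = trueFeatures,
              sitesTrueFeatures = siteTrue, features = features)
  if (keepCubes) out$cubes <- fused
  out
}
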