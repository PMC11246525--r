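#' @import methods
#' @importFrom stats approx predict rnorm runif sd quantile setNames
#' @importFrom utils head tail read.csv write.csv
NULL

#' Season month order (October through May)
#'
#' The winter-wheat season runs from October of the year before harvest to
#' May of the harvest year.  All monthly cubes and feature matrices use this
#' slot order.
#'
#' @format Character vector of 8 three-letter month labels.
#' @export
SEASON_MONTHS <- c("Oct", "Nov", "Dec", "Jan", "Feb", "Mar", "Apr", "May")

# calendar month numbers for the 8 slots
SEASON_MONTH_NUM <- c(10L, 11L, 12L, 1L, 2L, 3L, 4L, 5L)

#' Climate variable order
#'
#' Monthly climate covariates attached to each season slot: precipitation
#' (Pr, mm), maximum temperature (Tmax, degrees C), minimum temperature
#' (Tmin, degrees C), vapor pressure deficit (VPD, kPa) and soil moisture
#' (SM, mm).
#'
#' @format Character vector of 5 variable names.
#' @export
CLIMATE_VARS <- c("Pr", "Tmax", "Tmin", "VPD", "SM")

# ---------------------------------------------------------------------------
# GridSpec

#' GridSpec: geometry of a georeferenced grid
#'
#' Describes a regular grid by the map coordinates of its top-left corner,
#' the pixel size, the number of rows and columns, and an opaque CRS tag.
#' The convention used throughout the package: row 1 is the top row, pixel
#' (r, c) occupies the half-open extent
#' \eqn{[x0 + (c-1)w, x0 + cw) \times (y0 - rh, y0 - (r-1)h]} and its center
#' is at \eqn{(x0 + (c-1/2)w,\; y0 - (r-1/2)h)}.
#'
#' @slot originX,originY map coordinates of the top-left corner.
#' @slot pixelWidth,pixelHeight positive map units per pixel.
#' @slot nRows,nCols grid dimensions.
#' @slot crs opaque CRS identifier; two grids interoperate only when equal.
#' @export
setClass("GridSpec",
  representation(originX = "numeric", originY = "numeric",
                 pixelWidth = "numeric", pixelHeight = "numeric",
                 nRows = "integer", nCols = "integer", crs = "character"))

setValidity("GridSpec", function(object) {
  msg <- NULL
  if (length(object@pixelWidth) != 1 || !is.finite(object@pixelWidth) ||
      object@pixelWidth <= 0)
    msg <- c(msg, "pixelWidth must be a single positive number")
  if (length(object@pixelHeight) != 1 || !is.finite(object@pixelHeight) ||
      object@pixelHeight <= 0)
    msg <- c(msg, "pixelHeight must be a single positive number")
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (length(object@crs) != 1L)
    msg <- c(msg, "crs must be a single string")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param originX,originY map coordinates of the top-left corner.
#' @param pixelWidth,pixelHeight pixel size in map units (both positive).
#' @param crs CRS tag string; grids only interoperate when tags are equal.
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(4, 4)
#' @export
gridSpec <- function(nRows, nCols, originX = 0, originY = nRows * pixelHeight,
                     pixelWidth = 1, pixelHeight = pixelWidth,
                     crs = "synthetic") {
  new("GridSpec", originX = as.numeric(originX), originY = as.numeric(originY),
      pixelWidth = as.numeric(pixelWidth),
      pixelHeight = as.numeric(pixelHeight),
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      crs = as.character(crs))
}

#' Test two GridSpecs for equality
#'
#' Two specs are equal iff every field (origin, pixel size, dimensions, CRS
#' tag) is equal.
#'
#' @param a,b [GridSpec-class] objects.
#' @return Logical scalar.
#' @export
sameSpec <- function(a, b) {
  isTRUE(a@originX == b@originX) && isTRUE(a@originY == b@originY) &&
    isTRUE(a@pixelWidth == b@pixelWidth) &&
    isTRUE(a@pixelHeight == b@pixelHeight) &&
    a@nRows == b@nRows && a@nCols == b@nCols && a@crs == b@crs
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d pixels of %g x %g, origin (%g, %g), crs '%s'\n",
              object@nRows, object@nCols, object@pixelWidth,
              object@pixelHeight, object@originX, object@originY, object@crs))
})

# map coordinates of pixel centers (1-based row/col)
pixelCenterX <- function(spec, col) spec@originX + (col - 0.5) * spec@pixelWidth
pixelCenterY <- function(spec, row) spec@originY - (row - 0.5) * spec@pixelHeight

# ---------------------------------------------------------------------------
# RasterGrid

#' RasterGrid: a single georeferenced grid with per-pixel validity
#'
#' @slot spec the [GridSpec-class].
#' @slot values numeric matrix (nRows x nCols); finite wherever valid.
#' @slot valid logical matrix of the same shape; FALSE marks nodata/cloud.
#' @export
setClass("RasterGrid",
  representation(spec = "GridSpec", values = "matrix", valid = "matrix"))

setValidity("RasterGrid", function(object) {
  msg <- NULL
  d <- c(object@spec@nRows, object@spec@nCols)
  if (!identical(dim(object@values), d))
    msg <- c(msg, "values shape does not match spec")
  if (!identical(dim(object@valid), d))
    msg <- c(msg, "valid shape does not match spec")
  if (!is.logical(object@valid))
    msg <- c(msg, "valid must be logical")
  else if (anyNA(object@valid))
    msg <- c(msg, "valid must not contain NA")
  else if (length(object@values) &&
           !all(is.finite(object@values[object@valid])))
    msg <- c(msg, "values must be finite wherever valid")
  if (is.null(msg)) TRUE else msg
})

#' Construct a RasterGrid
#'
#' @param values numeric matrix, or a single number recycled over the grid.
#' @param spec a [GridSpec-class]; defaults to a unit grid matching `values`.
#' @param valid logical matrix; defaults to `is.finite(values)`.
#' @return A [RasterGrid-class].
#' @examples
#' rasterGrid(matrix(1:4, 2, 2))
#' @export
rasterGrid <- function(values, spec = NULL, valid = NULL) {
  if (is.null(dim(values)) && length(values) == 1 && !is.null(spec))
    values <- matrix(values, spec@nRows, spec@nCols)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(spec)) spec <- gridSpec(nrow(values), ncol(values))
  if (is.null(valid)) valid <- is.finite(values)
  valid <- matrix(as.logical(valid), nrow(values), ncol(values))
  values[!valid] <- NA_real_
  new("RasterGrid", spec = spec, values = values, valid = valid)
}

#' @describeIn rasterGrid Accessors for the spec, value matrix and validity
#'   mask of a grid.
#' @param x a [RasterGrid-class] or [RasterCube-class].
#' @export
gridSpecOf <- function(x) x@spec

#' Value matrix of a RasterGrid (NA where invalid)
#' @param x a [RasterGrid-class].
#' @return Numeric matrix.
#' @export
gridValues <- function(x) x@values

#' Validity mask of a RasterGrid
#' @param x a [RasterGrid-class].
#' @return Logical matrix.
#' @export
gridValid <- function(x) x@valid

setMethod("show", "RasterGrid", function(object) {
  cat(sprintf("RasterGrid: %d x %d, %d/%d valid, range [%s]\n",
              object@spec@nRows, object@spec@nCols, sum(object@valid),
              length(object@valid),
              if (any(object@valid))
                paste(signif(range(object@values[object@valid]), 4),
                      collapse = ", ")
              else "empty"))
})

# ---------------------------------------------------------------------------
# RasterCube

#' RasterCube: a time-stamped stack of RasterGrids on one GridSpec
#'
#' @slot spec shared [GridSpec-class].
#' @slot timestamps strictly increasing `Date` vector.
#' @slot layers list of [RasterGrid-class], one per timestamp.
#' @export
setClass("RasterCube",
  representation(spec = "GridSpec", timestamps = "Date", layers = "list"))

setValidity("RasterCube", function(object) {
  msg <- NULL
  if (length(object@layers) != length(object@timestamps))
    msg <- c(msg, "one layer per timestamp required")
  if (length(object@timestamps) > 1 &&
      any(diff(as.numeric(object@timestamps)) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  for (l in object@layers)
    if (!is(l, "RasterGrid") || !sameSpec(l@spec, object@spec)) {
      msg <- c(msg, "all layers must be RasterGrids sharing the cube spec")
      break
    }
  if (is.null(msg)) TRUE else msg
})

#' Construct a RasterCube
#'
#' @param layers list of [RasterGrid-class] sharing one spec.
#' @param timestamps `Date` vector (or coercible), strictly increasing.
#' @return A [RasterCube-class].
#' @export
rasterCube <- function(layers, timestamps) {
  timestamps <- as.Date(timestamps)
  o <- order(timestamps)
  layers <- layers[o]
  timestamps <- timestamps[o]
  spec <- if (length(layers)) layers[[1]]@spec else gridSpec(1, 1)
  new("RasterCube", spec = spec, timestamps = timestamps, layers = layers)
}

#' Number of layers in a cube
#' @param x a [RasterCube-class].
#' @export
nLayers <- function(x) length(x@layers)

#' Timestamps of a cube
#' @param x a [RasterCube-class].
#' @return `Date` vector.
#' @export
cubeDates <- function(x) x@timestamps

#' Extract one layer of a cube
#' @param x a [RasterCube-class].
#' @param i layer index.
#' @return A [RasterGrid-class].
#' @export
cubeLayer <- function(x, i) x@layers[[i]]

setMethod("show", "RasterCube", function(object) {
  cat(sprintf("RasterCube: %d layers (%s .. %s) on %d x %d grid\n",
              nLayers(object),
              if (nLayers(object)) format(min(object@timestamps)) else "-",
              if (nLayers(object)) format(max(object@timestamps)) else "-",
              object@spec@nRows, object@spec@nCols))
})

# values of a cube as a (nLayers x nPixels) matrix, NA where invalid;
# pixels are in column-major grid order
cubeMatrix <- function(cube) {
  npix <- cube@spec@nRows * cube@spec@nCols
  m <- vapply(cube@layers, function(l) as.vector(l@values), numeric(npix))
  if (is.null(dim(m))) m <- matrix(m, nrow = npix)   # single-pixel grids
  t(m)
}

# rebuild a cube from a (nLayers x nPixels) matrix (NA -> invalid)
cubeFromMatrix <- function(m, spec, timestamps) {
  layers <- lapply(seq_len(nrow(m)), function(i)
    rasterGrid(matrix(m[i, ], spec@nRows, spec@nCols), spec))
  rasterCube(layers, timestamps)
}

# ---------------------------------------------------------------------------
# SeasonSpec

#' SeasonSpec: the 8 monthly slots of one winter-wheat season
#'
#' A season is identified by its harvest year `y`; it spans October--December
#' of `y - 1` and January--May of `y`.
#'
#' @slot harvestYear integer harvest year.
#' @export
setClass("SeasonSpec", representation(harvestYear = "integer"))

#' Construct a SeasonSpec
#' @param harvestYear integer harvest year (the season ends in May of it).
#' @return A [SeasonSpec-class].
#' @examples
#' seasonSlots(seasonSpec(2020))
#' @export
seasonSpec <- function(harvestYear)
  new("SeasonSpec", harvestYear = as.integer(harvestYear))

#' The (year, month) calendar slots of a season
#' @param season a [SeasonSpec-class].
#' @return data.frame with columns `slot` (1..8), `label`, `year`, `month`.
#' @export
seasonSlots <- function(season) {
  y <- season@harvestYear
  data.frame(slot = 1:8, label = SEASON_MONTHS,
             year = ifelse(SEASON_MONTH_NUM >= 10, y - 1L, y),
             month = SEASON_MONTH_NUM)
}

# nominal mid-month timestamps for the 8 slots
seasonSlotDates <- function(season) {
  s <- seasonSlots(season)
  as.Date(sprintf("%d-%02d-15", s$year, s$month))
}

setMethod("show", "SeasonSpec", function(object) {
  cat(sprintf("SeasonSpec: harvest year %d (Oct %d .. May %d)\n",
              object@harvestYear, object@harvestYear - 1L,
              object@harvestYear))
})

# ---------------------------------------------------------------------------
# SGParams

#' Savitzky-Golay smoothing parameters
#'
#' @slot window odd window length >= 3.
#' @slot polyorder polynomial order, 0 <= polyorder < window.
#' @export
setClass("SGParams", representation(window = "integer", polyorder = "integer"))

setValidity("SGParams", function(object) {
  msg <- NULL
  if (object@window < 3L || object@window %% 2L == 0L)
    msg <- c(msg, "window must be an odd integer >= 3")
  if (object@polyorder < 0L || object@polyorder >= object@window)
    msg <- c(msg, "polyorder must satisfy 0 <= polyorder < window")
  if (is.null(msg)) TRUE else msg
})

#' Construct SGParams
#'
#' The defaults (window 5, order 2) are the largest odd window that still
#' leaves several independent interior positions on the 8-point monthly
#' series.
#'
#' @param window odd integer >= 3.
#' @param polyorder integer, 0 <= polyorder < window.
#' @return An [SGParams-class].
#' @export
sgParams <- function(window = 5L, polyorder = 2L)
  new("SGParams", window = as.integer(window), polyorder = as.integer(polyorder))

# ---------------------------------------------------------------------------
# ClimateStack

#' ClimateStack: monthly climate grids for the five covariates
#'
#' Holds one [RasterGrid-class] per (year, month, variable), all on a shared
#' spec.  Entries are keyed "YYYY-MM".
#'
#' @slot spec shared [GridSpec-class].
#' @slot entries named list; each element is a named list of the 5 variable
#'   grids ([CLIMATE_VARS]).
#' @export
setClass("ClimateStack",
  representation(spec = "GridSpec", entries = "list"))

setValidity("ClimateStack", function(object) {
  for (e in object@entries) {
    if (!all(CLIMATE_VARS %in% names(e)))
      return("every entry must contain all five climate variables")
    for (v in CLIMATE_VARS)
      if (!is(e[[v]], "RasterGrid") || !sameSpec(e[[v]]@spec, object@spec))
        return("all climate grids must share the stack spec")
  }
  TRUE
})

#' Construct a ClimateStack
#' @param entries named list keyed "YYYY-MM", each a named list of the five
#'   variable grids.
#' @return A [ClimateStack-class].
#' @export
climateStack <- function(entries) {
  spec <- if (length(entries)) entries[[1]][[CLIMATE_VARS[1]]]@spec
          else gridSpec(1, 1)
  new("ClimateStack", spec = spec, entries = entries)
}

climateKey <- function(year, month) sprintf("%d-%02d", year, month)

#' Fetch one climate grid
#' @param stack a [ClimateStack-class].
#' @param year,month calendar year and month.
#' @param var one of [CLIMATE_VARS].
#' @return A [RasterGrid-class]; errors if the slot is absent.
#' @export
climateGrid <- function(stack, year, month, var) {
  key <- climateKey(year, month)
  e <- stack@entries[[key]]
  if (is.null(e)) stop("climate stack has no entry for ", key)
  if (!var %in% CLIMATE_VARS) stop("unknown climate variable: ", var)
  e[[var]]
}

setMethod("show", "ClimateStack", function(object) {
  cat(sprintf("ClimateStack: %d month-slots x %d variables on %d x %d grid\n",
              length(object@entries), length(CLIMATE_VARS),
              object@spec@nRows, object@spec@nCols))
})

# ---------------------------------------------------------------------------
# CountyMap

#' CountyMap: county label raster plus id/name table
#'
#' @slot labels [RasterGrid-class] of nonnegative integer county ids on the
#'   fine grid; 0 means "no county".
#' @slot table data.frame with columns `id`, `name`; every nonzero id in the
#'   label grid appears here.
#' @export
setClass("CountyMap",
  representation(labels = "RasterGrid", table = "data.frame"))

setValidity("CountyMap", function(object) {
  ids <- unique(as.vector(object@labels@values[object@labels@valid]))
  ids <- ids[ids != 0]
  if (!all(ids %in% object@table$id))
    return("every nonzero label id must appear in the id/name table")
  TRUE
})

#' Construct a CountyMap
#' @param labels [RasterGrid-class] of county ids (0 = none).
#' @param table data.frame with columns `id`, `name`; defaults to
#'   auto-generated names.
#' @return A [CountyMap-class].
#' @export
countyMap <- function(labels, table = NULL) {
  if (is.null(table)) {
    ids <- sort(unique(as.vector(labels@values[labels@valid])))
    ids <- ids[ids != 0]
    table <- data.frame(id = as.integer(ids),
                        name = sprintf("county_%03d", as.integer(ids)))
  }
  new("CountyMap", labels = labels, table = table)
}

#' County label grid
#' @param x a [CountyMap-class].
#' @export
countyLabels <- function(x) x@labels

#' County id/name table
#' @param x a [CountyMap-class].
#' @export
countyTable <- function(x) x@table

setMethod("show", "CountyMap", function(object) {
  cat(sprintf("CountyMap: %d counties on %d x %d grid\n",
              nrow(object@table), object@labels@spec@nRows,
              object@labels@spec@nCols))
})

# ---------------------------------------------------------------------------
# ModelSpec / FittedModel

#' ModelSpec: algorithm, hyperparameters and seed of a regressor
#'
#' Two algorithms are supported: `"lstm"` (recurrent network over the
#' monthly sequence) and `"gbm"` (leaf-wise gradient-boosted regression
#' trees; the alias `"lgbm"` is accepted).
#'
#' @slot algorithm `"lstm"` or `"gbm"`.
#' @slot hyper named list of hyperparameters (see [defaultGrid()]).
#' @slot seed integer seed for fitting.
#' @slot standardize z-score features (and target) using training statistics.
#' @export
setClass("ModelSpec",
  representation(algorithm = "character", hyper = "list", seed = "integer",
                 standardize = "logical"))

setValidity("ModelSpec", function(object) {
  if (!object@algorithm %in% c("lstm", "gbm"))
    return("algorithm must be 'lstm' or 'gbm'")
  known <- if (object@algorithm == "gbm")
    c("learning_rate", "num_leaves", "n_estimators", "early_stopping",
      "min_data_in_leaf")
  else c("hidden", "epochs", "batch", "learning_rate", "patience",
         "weight_decay", "head", "n_members")
  bad <- setdiff(names(object@hyper), known)
  if (length(bad))
    return(paste0("unknown hyperparameters for ", object@algorithm, ": ",
                  paste(bad, collapse = ", ")))
  TRUE
})

#' Construct a ModelSpec
#' @param algorithm `"lstm"`, `"gbm"` (or its alias `"lgbm"`).
#' @param hyper named list of hyperparameters; unset entries take the
#'   defaults documented in [defaultGrid()].
#' @param seed integer seed used when fitting.
#' @param standardize z-score features/target on training rows (default TRUE).
#' @return A [ModelSpec-class].
#' @export
modelSpec <- function(algorithm = c("gbm", "lstm", "lgbm"), hyper = list(),
                      seed = 1L, standardize = TRUE) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "lgbm") algorithm <- "gbm"
  new("ModelSpec", algorithm = algorithm, hyper = hyper,
      seed = as.integer(seed), standardize = isTRUE(standardize))
}

setMethod("show", "ModelSpec", function(object) {
  h <- if (length(object@hyper))
    paste(names(object@hyper), unlist(object@hyper), sep = "=", collapse = ", ")
  else "defaults"
  cat(sprintf("ModelSpec: %s (%s), seed %d\n", object@algorithm, h,
              object@seed))
})

#' FittedModel: a trained yield regressor
#'
#' Carries the training column schema and standardization statistics so that
#' prediction refuses mismatched matrices and applies the training-time
#' scaling.
#'
#' @slot spec the [ModelSpec-class] it was trained with.
#' @slot schema character vector of feature column names, in order.
#' @slot center,scale per-column standardization statistics.
#' @slot yCenter,yScale target standardization statistics.
#' @slot state opaque fitted state (booster or network weights).
#' @export
setClass("FittedModel",
  representation(spec = "ModelSpec", schema = "character", center = "numeric",
                 scale = "numeric", yCenter = "numeric", yScale = "numeric",
                 state = "list"))

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel: %s over %d features\n", object@spec@algorithm,
              length(object@schema)))
})

# ---------------------------------------------------------------------------
# EvalReport / LoyoResult

#' EvalReport: accuracy metrics plus per-record errors
#'
#' @slot r2 coefficient of determination, 1 - SS_res/SS_tot (NA when the
#'   observed values have zero variance).
#' @slot rmse root mean square error (kg/ha for yields).
#' @slot n number of records.
#' @slot records data.frame with columns `unit_id`, `year`, `observed`,
#'   `predicted`, `re_percent`.
#' @export
setClass("EvalReport",
  representation(r2 = "numeric", rmse = "numeric", n = "integer",
                 records = "data.frame"))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: n = %d, R2 = %s, RMSE = %s\n", object@n,
              if (is.na(object@r2)) "NA" else sprintf("%.3f", object@r2),
              sprintf("%.1f", object@rmse)))
})

#' R-squared of an EvalReport
#' @param x an [EvalReport-class].
#' @export
reportR2 <- function(x) x@r2

#' RMSE of an EvalReport
#' @param x an [EvalReport-class].
#' @export
reportRMSE <- function(x) x@rmse

#' Per-record table of an EvalReport
#' @param x an [EvalReport-class].
#' @export
reportRecords <- function(x) x@records

#' LoyoResult: one EvalReport per held-out year
#'
#' @slot reports named list of [EvalReport-class], keyed by held-out year.
#' @export
setClass("LoyoResult", representation(reports = "list"))

#' Per-year reports of a LoyoResult
#' @param x a [LoyoResult-class].
#' @export
loyoReports <- function(x) x@reports

setMethod("show", "LoyoResult", function(object) {
  cat(sprintf("LoyoResult: %d held-out years\n", length(object@reports)))
})
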