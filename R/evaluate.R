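# Evaluation battery: R2/RMSE/relative-error metrics, leave-one-year-out
# validation, relative-error banding, pixel-level yield mapping and its
# county/site validation, and the forward-month timing analysis.

#' Accuracy metrics between observed and predicted yields
#'
#' RMSE = sqrt(mean((pred - obs)^2)); R2 = 1 - SS_res/SS_tot about the
#' observed mean (the coefficient of determination, which can be negative
#' out of sample); per-record relative error RE = 100 (pred - obs) / obs in
#' percent.  When the observed values have zero variance R2 is undefined
#' and returned as NA with a warning.
#'
#' @param observed,predicted numeric vectors of equal length >= 2; observed
#'   must be positive for RE.
#' @param unit_id,year optional per-record identifiers carried into the
#'   report table.
#' @return An [EvalReport-class].
#' @export
yieldMetrics <- function(observed, predicted, unit_id = NULL, year = NULL) {
  n <- length(observed)
  if (length(predicted) != n) stop("observed and predicted lengths differ")
  if (n < 2L) stop("need at least 2 records")
  rmse <- sqrt(mean((predicted - observed)^2))
  ssTot <- sum((observed - mean(observed))^2)
  r2 <- if (ssTot == 0) {
    warning("observed values have zero variance; R2 undefined")
    NA_real_
  } else 1 - sum((predicted - observed)^2) / ssTot
  re <- 100 * (predicted - observed) / observed
  new("EvalReport", r2 = r2, rmse = rmse, n = as.integer(n),
      records = data.frame(
        unit_id = if (is.null(unit_id)) rep(NA_integer_, n) else unit_id,
        year = if (is.null(year)) rep(NA_integer_, n) else year,
        observed = observed, predicted = predicted, re_percent = re))
}

#' Leave-one-year-out validation
#'
#' For each distinct year y, trains on all rows with year != y and
#' evaluates on year y, so every record is tested exactly once.  Years with
#' fewer than 2 rows are skipped (their count is attached as attribute
#' `skipped_years`).
#'
#' @param fm county feature matrix with `yield` and at least 3 distinct
#'   years.
#' @param spec the [ModelSpec-class] to refit per fold.
#' @return A [LoyoResult-class] keyed by held-out year.
#' @export
leaveOneYearOut <- function(fm, spec) {
  years <- sort(unique(fm$year))
  if (length(years) < 3L) stop("need at least 3 distinct years")
  counts <- table(fm$year)
  skip <- as.integer(names(counts)[counts < 2L])
  reports <- list()
  for (y in setdiff(years, skip)) {
    tr <- fm[fm$year != y, , drop = FALSE]
    te <- fm[fm$year == y, , drop = FALSE]
    foldSpec <- modelSpec(spec@algorithm, spec@hyper,
                          seed = childSeed(spec@seed, "loyo", y),
                          standardize = spec@standardize)
    fit <- trainModel(tr, foldSpec)
    pred <- predictYield(fit, te)
    reports[[as.character(y)]] <- yieldMetrics(te$yield, pred,
                                               unit_id = te$unit_id,
                                               year = te$year)
  }
  out <- new("LoyoResult", reports = reports)
  attr(out, "skipped_years") <- skip
  out
}

#' Relative errors by unit with +/-20\% bands
#'
#' Pools the per-record relative errors of a leave-one-year-out result and
#' classifies each into the bands `"< -20%"` (RE < -20), `"-20..20%"`
#' (-20 <= RE <= 20, inner band closed) and `"> 20%"` (RE > 20), the
#' over-/under-estimation convention used for error mapping.
#'
#' @param loyo a [LoyoResult-class].
#' @return data.frame with columns `unit_id`, `year`, `re_percent`, `band`.
#' @export
reByUnit <- function(loyo) {
  reports <- loyoReports(loyo)
  if (!length(reports)) stop("empty leave-one-year-out result")
  recs <- do.call(rbind, lapply(reports, reportRecords))
  rownames(recs) <- NULL
  band <- ifelse(recs$re_percent < -20, "< -20%",
                 ifelse(recs$re_percent > 20, "> 20%", "-20..20%"))
  data.frame(unit_id = recs$unit_id, year = recs$year,
             re_percent = recs$re_percent,
             band = factor(band, levels = c("< -20%", "-20..20%", "> 20%")))
}

#' Pixel-level yield map from a fitted model
#'
#' Writes per-pixel predictions back to their grid positions; pixels outside
#' the feature table (non-crop or incomplete) are invalid.  Negative
#' predictions are clipped to 0 and counted in attribute `n_clipped`.
#'
#' @param model a [FittedModel-class] (or any object with a
#'   [predictYield()] method).
#' @param pixelFm per-pixel feature table from [pixelFeatureTable()].
#' @param spec the fine [GridSpec-class] of the map.
#' @return A [RasterGrid-class] of predicted yield (kg/ha).
#' @export
yieldMap <- function(model, pixelFm, spec) {
  pred <- predictYield(model, pixelFm)
  nClip <- sum(pred < 0)
  pred <- pmax(pred, 0)
  vals <- matrix(NA_real_, spec@nRows, spec@nCols)
  vals[cbind(pixelFm$row, pixelFm$col)] <- pred
  out <- rasterGrid(vals, spec)
  attr(out, "n_clipped") <- nClip
  out
}

# 1-based pixel index of a map coordinate, NA outside the grid
pixelAt <- function(spec, x, y) {
  col <- floor((x - spec@originX) / spec@pixelWidth) + 1
  row <- floor((spec@originY - y) / spec@pixelHeight) + 1
  bad <- col < 1 | col > spec@nCols | row < 1 | row > spec@nRows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Validate a yield map against county and site records
#'
#' County level: the map is aggregated by [zonalMean()] over the crop mask
#' and compared with county yields of the map's year.  Site level: the map
#' pixel containing each site's coordinates (pixel-center containment) is
#' compared with the site's observed yield; sites outside the grid or on
#' invalid pixels are skipped and counted.
#'
#' @param map yield [RasterGrid-class] for one season.
#' @param counties a [CountyMap-class].
#' @param cropMask boolean [RasterGrid-class].
#' @param countyYields,siteYields yield record data.frames (columns
#'   `unit_id`, `year`, `yield_kg_ha`, `level`, and `x`, `y` for sites).
#' @param year harvest year of the map.
#' @return list with elements `county` and `site`, both [EvalReport-class]
#'   (NULL when fewer than 2 records are available at that level).
#' @export
validateMap <- function(map, counties, cropMask, countyYields, siteYields,
                        year) {
  zm <- zonalMean(map, counties, cropMask)
  cy <- countyYields[countyYields$level == "county" &
                       countyYields$year == year, ]
  cj <- merge(zm, cy, by = "unit_id")
  countyRep <- if (nrow(cj) >= 2L)
    yieldMetrics(cj$yield_kg_ha, cj$mean, unit_id = cj$unit_id,
                 year = rep(year, nrow(cj)))
  else NULL
  sy <- siteYields[siteYields$level == "site" & siteYields$year == year, ]
  siteRep <- NULL
  nSkipped <- 0L
  if (nrow(sy)) {
    rc <- pixelAt(map@spec, sy$x, sy$y)
    ok <- !is.na(rc[, 1])
    ok[ok] <- map@valid[rc[ok, , drop = FALSE]]
    nSkipped <- sum(!ok)
    if (sum(ok) >= 2L)
      siteRep <- yieldMetrics(sy$yield_kg_ha[ok],
                              map@values[rc[ok, , drop = FALSE]],
                              unit_id = sy$unit_id[ok],
                              year = sy$year[ok])
  }
  out <- list(county = countyRep, site = siteRep)
  attr(out, "n_sites_skipped") <- nSkipped
  out
}

#' Shared 70/30 evaluation of one (features, algorithm) cell
#'
#' The canonical evaluation used by the model comparison and the timing
#' analysis: split 70/30 by row, run ten-fold CV hyperparameter selection on
#' the training portion only, fit the winning spec on the full training
#' portion and report metrics on the held-out 30\%.
#'
#' @param fm feature matrix with `yield`.
#' @param algorithm `"gbm"` (alias `"lgbm"`) or `"lstm"`.
#' @param grid hyperparameter grid (default [defaultGrid()]); a grid of one
#'   entry skips the CV search.
#' @param seed integer seed governing split, folds and fit.
#' @param nfolds CV folds (default 10).
#' @return list with `spec`, `model`, `report` (an [EvalReport-class]).
#' @export
evaluateRandomSplit <- function(fm, algorithm = c("gbm", "lstm", "lgbm"),
                                grid = NULL, seed = 1L, nfolds = 10L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "lgbm") algorithm <- "gbm"
  if (is.null(grid)) grid <- defaultGrid(algorithm)
  sp <- randomSplit(fm, 0.7, seed)
  spec <- if (length(grid) == 1L)
    modelSpec(algorithm, grid[[1]], seed = childSeed(seed, "fit"))
  else
    tenfoldCvSelect(sp$train, algorithm, grid, seed, nfolds)
  fit <- trainModel(sp$train, spec)
  pred <- predictYield(fit, sp$test)
  rep <- yieldMetrics(sp$test$yield, pred, unit_id = sp$test$unit_id,
                      year = sp$test$year)
  list(spec = spec, model = fit, report = rep)
}

#' Forward-month prediction timing analysis
#'
#' For each last month from October through May, truncates the features to
#' the slots observed so far, re-runs the full selection + 70/30 evaluation
#' (retraining per truncation rather than masking a full-season model) and
#' records R2 and RMSE.  The May entry coincides exactly with the
#' full-feature evaluation at the same seed.
#'
#' @param fm full-width county feature matrix.
#' @param algorithm `"gbm"` (alias `"lgbm"`) or `"lstm"`.
#' @param grid hyperparameter grid (default [defaultGrid()]).
#' @param seed integer seed.
#' @param nfolds CV folds (default 10).
#' @return data.frame with one row per month (season order): `last_month`,
#'   `n_features`, `r2`, `rmse`.
#' @export
forwardMonthAnalysis <- function(fm, algorithm = c("gbm", "lstm", "lgbm"),
                                 grid = NULL, seed = 1L, nfolds = 10L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "lgbm") algorithm <- "gbm"
  if (!all(featureColumns() %in% names(fm)))
    stop("full-width feature matrix required")
  rows <- lapply(SEASON_MONTHS, function(m) {
    sub <- truncateToMonth(fm, m)
    res <- evaluateRandomSplit(sub, algorithm, grid, seed, nfolds)
    data.frame(last_month = m, n_features = length(featureColumns(m)),
               r2 = reportR2(res$report), rmse = reportRMSE(res$report))
  })
  out <- do.call(rbind, rows)
  out$last_month <- factor(out$last_month, levels = SEASON_MONTHS)
  rownames(out) <- NULL
  out
}
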