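# Feature assembly: zonal statistics over the crop mask and the 48-column
# (8 month slots x (VI + 5 climate variables)) feature matrices at county
# and pixel level.

#' Feature column schema
#'
#' Column names are `<var>_<slot>` with variables in the fixed order VI,
#' Pr, Tmax, Tmin, VPD, SM and month slots Oct through May within each
#' variable.  County- and pixel-level matrices share this schema byte for
#' byte, so a county-trained model applies to pixel rows unchanged.
#'
#' @param lastMonth final slot to retain (default `"May"` = all 8).
#' @return Character vector of feature column names.
#' @examples
#' length(featureColumns())        # 48
#' length(featureColumns("Oct"))   # 6
#' @export
featureColumns <- function(lastMonth = "May") {
  k <- match(lastMonth, SEASON_MONTHS)
  if (is.na(k)) stop("unknown month: ", lastMonth)
  months <- SEASON_MONTHS[seq_len(k)]
  unlist(lapply(c("VI", CLIMATE_VARS), function(v) paste(v, months, sep = "_")))
}

#' Per-county mean of a masked grid
#'
#' Arithmetic mean of valid grid values over crop-mask pixels, by county
#' label.  Counties with zero contributing pixels are omitted (their ids are
#' attached as attribute `omitted`).
#'
#' @param grid a [RasterGrid-class].
#' @param counties a [CountyMap-class] on the same spec.
#' @param cropMask boolean [RasterGrid-class] on the same spec.
#' @return data.frame with columns `unit_id`, `mean`, `n_pixels`.
#' @export
zonalMean <- function(grid, counties, cropMask) {
  lab <- countyLabels(counties)
  if (!sameSpec(grid@spec, lab@spec) || !sameSpec(grid@spec, cropMask@spec))
    stop("grid, counties and crop mask must share one GridSpec")
  use <- grid@valid & lab@valid & cropMask@valid &
    (!is.na(cropMask@values) & cropMask@values != 0) &
    (!is.na(lab@values) & lab@values > 0)
  ids <- as.integer(lab@values[use])
  vals <- grid@values[use]
  if (!length(ids)) {
    res <- data.frame(unit_id = integer(), mean = numeric(),
                      n_pixels = integer())
  } else {
    sums <- rowsum(vals, ids)
    cnts <- rowsum(rep(1L, length(ids)), ids)
    res <- data.frame(unit_id = as.integer(rownames(sums)),
                      mean = as.vector(sums) / as.vector(cnts),
                      n_pixels = as.integer(cnts))
  }
  attr(res, "omitted") <- setdiff(countyTable(counties)$id, res$unit_id)
  res
}

#' Resample a climate stack onto a target grid
#'
#' Bilinearly resamples every variable of every month slot (monthly climate
#' values are used as-is, with no compositing, since the source product is
#' already monthly).
#'
#' @param stack a [ClimateStack-class].
#' @param target a [GridSpec-class].
#' @return A [ClimateStack-class] on `target`.
#' @export
resampleClimate <- function(stack, target) {
  entries <- lapply(stack@entries, function(e)
    lapply(e, resampleBilinear, target = target))
  climateStack(entries)
}

# zonal VI + climate means for one season -> wide one-row-per-county frame
countySeasonFeatures <- function(viMonthly, climate, counties, cropMask,
                                 season) {
  slots <- seasonSlots(season)
  out <- NULL
  for (s in 1:8) {
    zm <- zonalMean(cubeLayer(viMonthly, s), counties, cropMask)
    piece <- setNames(zm[, c("unit_id", "mean")],
                      c("unit_id", paste0("VI_", slots$label[s])))
    for (v in CLIMATE_VARS) {
      g <- climateGrid(climate, slots$year[s], slots$month[s], v)
      zc <- zonalMean(g, counties, cropMask)
      piece <- merge(piece,
                     setNames(zc[, c("unit_id", "mean")],
                              c("unit_id", paste0(v, "_", slots$label[s]))),
                     by = "unit_id", all = TRUE)
    }
    out <- if (is.null(out)) piece else merge(out, piece, by = "unit_id",
                                              all = TRUE)
  }
  out
}

#' Build the county-level feature matrix
#'
#' One row per (county, year) that has all 48 zonal-mean features and a
#' county-level yield record; incomplete rows are dropped and counted in
#' attributes `n_dropped_features` / `n_dropped_yield`.
#'
#' @param viCubes named list of fused monthly [RasterCube-class]s, keyed by
#'   harvest year.
#' @param climate a [ClimateStack-class] on the fine grid (resample first
#'   with [resampleClimate()]).
#' @param counties a [CountyMap-class].
#' @param cropMask boolean [RasterGrid-class].
#' @param yields data.frame of yield records with columns `unit_id`, `year`,
#'   `yield_kg_ha`, `level` (only `"county"` rows are used).
#' @return data.frame with columns `unit_id`, `year`, the 48 features of
#'   [featureColumns()], and `yield`.
#' @export
buildFeatureMatrix <- function(viCubes, climate, counties, cropMask, yields) {
  if (!sameSpec(climate@spec, cropMask@spec))
    stop("climate stack must be resampled to the fine grid first")
  rows <- list()
  for (yr in names(viCubes)) {
    season <- seasonSpec(as.integer(yr))
    ft <- countySeasonFeatures(viCubes[[yr]], climate, counties, cropMask,
                               season)
    ft$year <- as.integer(yr)
    rows[[yr]] <- ft
  }
  fm <- do.call(rbind, rows)
  cols <- featureColumns()
  complete <- stats::complete.cases(fm[, cols])
  nDropFeat <- sum(!complete)
  fm <- fm[complete, , drop = FALSE]
  cy <- yields[yields$level == "county" & yields$yield_kg_ha > 0,
               c("unit_id", "year", "yield_kg_ha")]
  merged <- merge(fm, cy, by = c("unit_id", "year"))
  nDropYield <- nrow(fm) - nrow(merged)
  if (nrow(merged) == 0L) stop("no (county, year) rows survived the joins")
  names(merged)[names(merged) == "yield_kg_ha"] <- "yield"
  out <- merged[order(merged$year, merged$unit_id),
                c("unit_id", "year", cols, "yield")]
  rownames(out) <- NULL
  attr(out, "n_dropped_features") <- nDropFeat
  attr(out, "n_dropped_yield") <- nDropYield
  out
}

#' Per-pixel feature table for one season
#'
#' One row per crop-mask pixel whose VI series is gap-free and whose climate
#' values are all valid, with the same 48-column schema (names and order) as
#' [buildFeatureMatrix()], so a county-trained model predicts on it
#' unchanged.  Each row carries the pixel's (row, col).
#'
#' @param viCube fused monthly [RasterCube-class] for the season.
#' @param climate [ClimateStack-class] on the fine grid.
#' @param cropMask boolean [RasterGrid-class].
#' @param year harvest year of the season.
#' @return data.frame with columns `row`, `col`, `year` and the 48 features.
#' @export
pixelFeatureTable <- function(viCube, climate, cropMask, year) {
  spec <- viCube@spec
  if (!sameSpec(climate@spec, spec) || !sameSpec(cropMask@spec, spec))
    stop("climate and crop mask must be on the VI cube's GridSpec")
  season <- seasonSpec(year)
  slots <- seasonSlots(season)
  vi <- cubeMatrix(viCube)                      # 8 x npix
  keep <- as.vector(cropMask@valid & !is.na(cropMask@values) &
                      cropMask@values != 0) &
    colSums(is.na(vi)) == 0L
  cl <- list()
  for (v in CLIMATE_VARS) for (s in 1:8) {
    g <- climateGrid(climate, slots$year[s], slots$month[s], v)
    col <- as.vector(g@values)
    keep <- keep & !is.na(col)
    cl[[paste(v, slots$label[s], sep = "_")]] <- col
  }
  if (!any(keep)) stop("no crop pixels with complete features")
  pix <- which(keep)
  out <- data.frame(row = ((pix - 1L) %% spec@nRows) + 1L,
                    col = ((pix - 1L) %/% spec@nRows) + 1L,
                    year = as.integer(year))
  for (s in 1:8) out[[paste0("VI_", slots$label[s])]] <- vi[s, pix]
  for (nm in names(cl)) out[[nm]] <- cl[[nm]][pix]
  out[, c("row", "col", "year", featureColumns())]
}

#' Truncate a feature matrix to the forward-month window
#'
#' Retains only feature columns whose month slot is at or before
#' `lastMonth` in season order; metadata and target columns are untouched.
#'
#' @param fm a feature matrix from [buildFeatureMatrix()] or
#'   [pixelFeatureTable()].
#' @param lastMonth final month to keep, one of [SEASON_MONTHS].
#' @return The truncated feature matrix.
#' @export
truncateToMonth <- function(fm, lastMonth) {
  keepFeat <- featureColumns(lastMonth)
  meta <- setdiff(names(fm), featureColumns())
  fm[, c(intersect(c("unit_id", "row", "col", "year"), meta), keepFeat,
         intersect("yield", meta))]
}
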