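# Orchestration of the three experiments: paired model comparison over the
# three indices, leave-one-year-out + relative-error banding, pixel-level
# mapping with county/site validation, and the forward-month timing curve.
# All experiments share one seed per run so comparisons are paired, and
# write a manifest (config, seed, package version) next to their outputs.

writeManifest <- function(outDir, config, seed, extra = list()) {
  if (is.null(outDir)) return(invisible(NULL))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  man <- c(list(
    package = "cropcast",
    version = as.character(utils::packageVersion("cropcast")),
    seed = seed,
    scene = list(nRows = config@fineSpec@nRows, nCols = config@fineSpec@nCols,
                 coarseFactor = config@coarseFactor, nYears = config@nYears,
                 firstYear = config@firstYear, nCounties = config@nCounties,
                 cloudFraction = config@cloudFraction,
                 noiseSd = config@noiseSd, sigmaY = config@sigmaY,
                 yieldVi = config@yieldVi, masterSeed = config@seed)),
    extra)
  yaml::write_yaml(man, file.path(outDir, "manifest.yaml"))
  invisible(NULL)
}

#' Paired comparison of indices and algorithms
#'
#' Builds reconstructed feature matrices for the three indices from one
#' synthetic scene (shared yields), then evaluates every (index, algorithm)
#' cell with [evaluateRandomSplit()] under one shared seed, so the
#' comparison is paired: identical splits and folds across cells.
#'
#' @param config a [SceneConfig-class].
#' @param seed experiment seed (split/folds/fits).
#' @param viNames indices to compare (default all three).
#' @param algorithms algorithms to compare (default both).
#' @param grids named list of hyperparameter grids per algorithm (defaults
#'   to [defaultGrid()]).
#' @param scene optionally a pre-built [synthScene()] result containing all
#'   `viNames` (avoids regeneration).
#' @param outDir optional output directory for the CSV and manifest.
#' @return data.frame with one row per cell: `vi`, `algorithm`, `r2`,
#'   `rmse`, `n_test`.
#' @export
runCompare <- function(config, seed = 1L,
                       viNames = c("NDVI", "NIRv", "kNDVI"),
                       algorithms = c("gbm", "lstm"), grids = list(),
                       scene = NULL, outDir = NULL) {
  if (is.null(scene)) scene <- synthScene(config, viNames = viNames)
  rows <- list()
  for (v in viNames) for (alg in algorithms) {
    res <- evaluateRandomSplit(scene$features[[v]], alg,
                               grid = grids[[alg]], seed = seed)
    rows[[paste(v, alg)]] <- data.frame(
      vi = v, algorithm = alg, r2 = reportR2(res$report),
      rmse = reportRMSE(res$report), n_test = res$report@n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(outDir)) {
    writeManifest(outDir, config, seed, list(experiment = "compare"))
    write.csv(out, file.path(outDir, "compare.csv"), row.names = FALSE)
  }
  out
}

#' Leave-one-year-out experiment with relative-error banding
#'
#' Builds (or reuses) the scene features for the config's index, runs
#' [leaveOneYearOut()] with the given model spec, and pools the
#' relative-error table with its +/-20\% bands.
#'
#' @param config a [SceneConfig-class].
#' @param spec [ModelSpec-class] to refit per held-out year.
#' @param scene optional pre-built [synthScene()] result.
#' @param outDir optional output directory.
#' @return list with `loyo` (a [LoyoResult-class]), `re` (the band table)
#'   and `summary` (per-year R2/RMSE data.frame).
#' @export
runLoyo <- function(config, spec = modelSpec("gbm"), scene = NULL,
                    outDir = NULL) {
  if (is.null(scene)) scene <- synthScene(config)
  fm <- scene$features[[config@yieldVi]]
  loyo <- leaveOneYearOut(fm, spec)
  re <- reByUnit(loyo)
  summary <- do.call(rbind, lapply(names(loyoReports(loyo)), function(y) {
    r <- loyoReports(loyo)[[y]]
    data.frame(year = as.integer(y), n = r@n, r2 = reportR2(r),
               rmse = reportRMSE(r))
  }))
  if (!is.null(outDir)) {
    writeManifest(outDir, config, spec@seed, list(experiment = "loyo"))
    write.csv(summary, file.path(outDir, "loyo_summary.csv"),
              row.names = FALSE)
    write.csv(re, file.path(outDir, "re_by_unit.csv"), row.names = FALSE)
  }
  list(loyo = loyo, re = re, summary = summary)
}

#' Pixel-level yield maps with county and site validation
#'
#' Trains one model on the county feature matrix, then for each requested
#' year builds the per-pixel feature table from the fused cubes, predicts a
#' yield map, and validates it against county statistics (map aggregated by
#' zonal mean) and site observations (map pixel containing the site).
#' Records are pooled across years into one county and one site report.
#'
#' @param config a [SceneConfig-class].
#' @param spec [ModelSpec-class] for the single trained model.
#' @param years years to map (default all).
#' @param scene optional pre-built [synthScene()] result with
#'   `keepCubes = TRUE`.
#' @param outDir optional output directory (maps written as ASCII grids).
#' @return list with `county`, `site` (pooled [EvalReport-class]s) and
#'   `maps` (named list of [RasterGrid-class]s).
#' @export
runMaps <- function(config, spec = modelSpec("gbm"), years = NULL,
                    scene = NULL, outDir = NULL) {
  if (is.null(scene))
    scene <- synthScene(config, years = years, keepCubes = TRUE)
  if (is.null(scene$cubes)) stop("scene must be built with keepCubes = TRUE")
  vi <- config@yieldVi
  fm <- scene$features[[vi]]
  fit <- trainModel(fm, spec)
  if (is.null(years)) years <- as.integer(names(scene$cubes[[vi]]))
  maps <- list()
  cRec <- list(); sRec <- list()
  for (yr in years) {
    pfm <- pixelFeatureTable(scene$cubes[[vi]][[as.character(yr)]],
                             scene$climate, scene$cropMask, yr)
    map <- yieldMap(fit, pfm, config@fineSpec)
    maps[[as.character(yr)]] <- map
    val <- validateMap(map, scene$counties, scene$cropMask, scene$yields,
                       scene$yields, yr)
    if (!is.null(val$county)) cRec[[as.character(yr)]] <- reportRecords(val$county)
    if (!is.null(val$site)) sRec[[as.character(yr)]] <- reportRecords(val$site)
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      writeRaster(map, file.path(outDir, sprintf("yield_map_%d.asc", yr)))
    }
  }
  pool <- function(recs) {
    if (!length(recs)) return(NULL)
    r <- do.call(rbind, recs)
    yieldMetrics(r$observed, r$predicted, unit_id = r$unit_id, year = r$year)
  }
  county <- pool(cRec); site <- pool(sRec)
  if (!is.null(outDir)) {
    writeManifest(outDir, config, spec@seed, list(experiment = "maps"))
    summ <- data.frame(
      level = c("county", "site"),
      r2 = c(if (is.null(county)) NA else reportR2(county),
             if (is.null(site)) NA else reportR2(site)),
      rmse = c(if (is.null(county)) NA else reportRMSE(county),
               if (is.null(site)) NA else reportRMSE(site)))
    write.csv(summ, file.path(outDir, "map_validation.csv"),
              row.names = FALSE)
  }
  list(county = county, site = site, maps = maps)
}

#' Forward-month timing experiment
#'
#' Delegates to [forwardMonthAnalysis()] on the scene's county features;
#' the May row coincides with the corresponding [runCompare()] cell at the
#' same seed.
#'
#' @param config a [SceneConfig-class].
#' @param algorithm `"gbm"` (alias `"lgbm"`) or `"lstm"`.
#' @param grid hyperparameter grid (default [defaultGrid()]).
#' @param seed experiment seed.
#' @param scene optional pre-built [synthScene()] result.
#' @param outDir optional output directory.
#' @return The month-performance data.frame of [forwardMonthAnalysis()].
#' @export
runTiming <- function(config, algorithm = "gbm", grid = NULL, seed = 1L,
                      scene = NULL, outDir = NULL) {
  if (is.null(scene)) scene <- synthScene(config)
  out <- forwardMonthAnalysis(scene$features[[config@yieldVi]], algorithm,
                              grid, seed)
  if (!is.null(outDir)) {
    writeManifest(outDir, config, seed, list(experiment = "timing"))
    write.csv(out, file.path(outDir, "timing.csv"), row.names = FALSE)
  }
  out
}
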