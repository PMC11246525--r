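# Yield regressors: 70/30 random split, ten-fold cross-validated
# hyperparameter selection, training and prediction for the gradient-boosted
# tree model (xgboost backend, leaf-wise histogram trees) and the in-package
# LSTM.

# evaluate expr under a given RNG seed without disturbing the caller's RNG
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a distinct 31-bit child seed from a parent seed and a stream label
childSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

featureColsOf <- function(fm) {
  cols <- intersect(featureColumns(), names(fm))
  if (!length(cols)) stop("no feature columns found in matrix")
  cols
}

#' Random 70/30 split of a feature matrix
#'
#' Splits rows into disjoint train/test sets with
#' `round(trainFraction * n)` training rows, reproducibly per seed.  By
#' default the split is by row (county-year); `groupBy` instead splits
#' whole counties or whole years, a leakage control for spatial or
#' temporal dependence (at the cost of a train size that only
#' approximates the requested fraction).
#'
#' @param fm feature matrix with a `yield` column and at least 10 rows.
#' @param trainFraction training fraction (default 0.7).
#' @param seed integer seed.
#' @param groupBy `NULL` (row-wise, default), `"unit"` or `"year"`.
#' @return list with elements `train` and `test`.
#' @export
randomSplit <- function(fm, trainFraction = 0.7, seed = 1L, groupBy = NULL) {
  n <- nrow(fm)
  if (n < 10L) stop("need at least 10 rows to split")
  if (is.null(groupBy)) {
    nTrain <- round(trainFraction * n)
    idx <- withSeed(childSeed(seed, "split"), sample.int(n, nTrain))
  } else {
    key <- switch(groupBy, unit = fm$unit_id, year = fm$year,
                  stop("groupBy must be NULL, 'unit' or 'year'"))
    groups <- unique(key)
    nG <- max(1L, round(trainFraction * length(groups)))
    pick <- withSeed(childSeed(seed, "split"), sample(groups, nG))
    idx <- which(key %in% pick)
  }
  list(train = fm[sort(idx), , drop = FALSE],
       test = fm[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

# near-equal disjoint fold assignment (sizes differ by <= 1)
foldAssignment <- function(n, nfolds, seed) {
  withSeed(childSeed(seed, "folds"),
           sample(rep_len(seq_len(nfolds), n)))
}

#' Hyperparameter grids
#'
#' Default search grids: for `"gbm"`, learning rate in {0.05, 0.1} crossed
#' with number of leaves in {15, 31} (at most 500 trees with early
#' stopping); for `"lstm"`, hidden size in {32, 64} (one recurrent layer,
#' at most 300 epochs, early-stopping patience 30, batch 32).
#'
#' @param algorithm `"gbm"` (alias `"lgbm"`) or `"lstm"`.
#' @return list of named hyperparameter lists.
#' @export
defaultGrid <- function(algorithm = c("gbm", "lstm", "lgbm")) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "lgbm") algorithm <- "gbm"
  if (algorithm == "gbm")
    do.call(Map, c(function(...) list(...),
                   expand.grid(learning_rate = c(0.05, 0.1),
                               num_leaves = c(15L, 31L)))) |>
      unname()
  else
    list(list(hidden = 32L), list(hidden = 64L))
}

#' Ten-fold cross-validated hyperparameter selection
#'
#' Partitions the rows into `nfolds` near-equal disjoint folds (sizes
#' differing by at most 1); for each grid entry the mean held-out RMSE over
#' folds is computed, and the entry with the lowest mean RMSE wins, ties
#' broken by grid order.
#'
#' @param fm feature matrix with `yield`, at least 20 rows.
#' @param algorithm `"gbm"` (alias `"lgbm"`) or `"lstm"`.
#' @param grid list of hyperparameter lists (default [defaultGrid()]).
#' @param seed integer seed.
#' @param nfolds number of folds (default 10).
#' @return The winning [ModelSpec-class]; the per-entry CV table is in
#'   `attr(, "cv_table")`.
#' @export
tenfoldCvSelect <- function(fm, algorithm = c("gbm", "lstm", "lgbm"),
                            grid = NULL, seed = 1L, nfolds = 10L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "lgbm") algorithm <- "gbm"
  if (is.null(grid)) grid <- defaultGrid(algorithm)
  if (!length(grid)) stop("empty hyperparameter grid")
  if (nrow(fm) < 20L) stop("need at least 20 rows for cross-validation")
  fold <- foldAssignment(nrow(fm), nfolds, seed)
  rmse <- numeric(length(grid))
  for (g in seq_along(grid)) {
    errs <- numeric(nfolds)
    for (k in seq_len(nfolds)) {
      tr <- fm[fold != k, , drop = FALSE]
      te <- fm[fold == k, , drop = FALSE]
      spec <- modelSpec(algorithm, grid[[g]], seed = childSeed(seed, "cv", g, k))
      fit <- trainModel(tr, spec)
      pred <- predictYield(fit, te)
      errs[k] <- sqrt(mean((pred - te$yield)^2))
    }
    rmse[g] <- mean(errs)
  }
  best <- which.min(rmse)                     # ties: first in grid order
  out <- modelSpec(algorithm, grid[[best]], seed = childSeed(seed, "fit"))
  attr(out, "cv_table") <- data.frame(entry = seq_along(grid),
                                      mean_rmse = rmse)
  out
}

gbmDefaults <- function(hyper) {
  utils::modifyList(list(learning_rate = 0.1, num_leaves = 31L,
                         n_estimators = 500L, early_stopping = TRUE,
                         min_data_in_leaf = 5L), hyper)
}

lstmDefaults <- function(hyper) {
  utils::modifyList(list(hidden = 32L, epochs = 300L, batch = 32L,
                         learning_rate = 0.01, patience = 30L,
                         weight_decay = 0.003, head = "last",
                         n_members = 3L), hyper)
}

#' Train a yield regressor
#'
#' For `"gbm"`: leaf-wise gradient-boosted regression trees on the flat
#' feature matrix, at most `n_estimators` trees with early stopping against
#' a held-out 10\% of the training rows.  For `"lstm"`: features are
#' reshaped into a sequence of month steps with 6 channels (VI + 5 climate
#' variables) in season order and fed to a single-layer LSTM with a linear
#' head, trained with Adam and early stopping on a held-out 10\% of the
#' training rows.  Features (and the target) are z-scored with training
#' statistics when `spec@standardize` is TRUE.
#'
#' @param fm feature matrix with a `yield` column and no missing values.
#' @param spec a [ModelSpec-class].
#' @return A [FittedModel-class].
#' @export
trainModel <- function(fm, spec) {
  cols <- featureColsOf(fm)
  X <- as.matrix(fm[, cols])
  y <- fm$yield
  if (anyNA(X) || anyNA(y) || !all(is.finite(X)) || !all(is.finite(y)))
    stop("feature matrix contains missing or non-finite values")
  if (spec@standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    yC <- mean(y); yS <- sd(y)
    if (!is.finite(yS) || yS == 0) yS <- 1
  } else {
    center <- setNames(rep(0, length(cols)), cols)
    scl <- setNames(rep(1, length(cols)), cols)
    yC <- 0; yS <- 1
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  ys <- (y - yC) / yS
  state <- if (spec@algorithm == "gbm") {
    hp <- gbmDefaults(spec@hyper)
    fitGbm(Xs, ys, hp, spec@seed)
  } else {
    hp <- lstmDefaults(spec@hyper)
    arr <- seqArray(Xs, cols)
    # a small committee of independently initialised trainings, averaged at
    # prediction time, stabilises the stochastic optimisation
    members <- lapply(seq_len(hp$n_members), function(k)
      lstmFit(arr, ys, hidden = hp$hidden, epochs = hp$epochs,
              batch = hp$batch, lr = hp$learning_rate,
              patience = hp$patience, weightDecay = hp$weight_decay,
              head = hp$head, seed = childSeed(spec@seed, "member", k)))
    list(type = "lstm", members = members)
  }
  new("FittedModel", spec = spec, schema = cols,
      center = setNames(as.numeric(center), cols),
      scale = setNames(as.numeric(scl), cols),
      yCenter = yC, yScale = yS, state = state)
}

# reshape a standardized flat matrix into an (n, steps, 6) array in season
# order; works for truncated schemas too
seqArray <- function(Xs, cols) {
  vars <- c("VI", CLIMATE_VARS)
  months <- intersect(SEASON_MONTHS,
                      unique(sub("^[A-Za-z]+_", "", cols)))
  arr <- array(0, dim = c(nrow(Xs), length(months), length(vars)))
  for (j in seq_along(vars)) for (s in seq_along(months))
    arr[, s, j] <- Xs[, paste(vars[j], months[s], sep = "_")]
  arr
}

fitGbm <- function(Xs, ys, hp, seed) {
  n <- nrow(Xs)
  params <- list(objective = "reg:squarederror", eta = hp$learning_rate,
                 max_depth = 0L, max_leaves = hp$num_leaves,
                 grow_policy = "lossguide", tree_method = "hist",
                 min_child_weight = hp$min_data_in_leaf, nthread = 1L)
  if (isTRUE(hp$early_stopping) && n >= 20L) {
    nVal <- max(2L, round(0.1 * n))
    vi <- withSeed(childSeed(seed, "gbm-es"), sample.int(n, nVal))
    dtrain <- xgboost::xgb.DMatrix(Xs[-vi, , drop = FALSE],
                                   label = ys[-vi], nthread = 1L)
    dval <- xgboost::xgb.DMatrix(Xs[vi, , drop = FALSE], label = ys[vi],
                                 nthread = 1L)
    probe <- withSeed(seed, xgboost::xgb.train(
      params, dtrain, nrounds = hp$n_estimators,
      evals = list(val = dval), early_stopping_rounds = 25L, verbose = 0))
    # refit on the full training set at the early-stopped round count
    nBest <- tryCatch(xgboost::xgb.attr(probe, "best_iteration"),
                      error = function(e) NULL)
    nBest <- suppressWarnings(as.integer(nBest))
    if (!length(nBest) || is.na(nBest)) nBest <- hp$n_estimators
    dfull <- xgboost::xgb.DMatrix(Xs, label = ys, nthread = 1L)
    fit <- withSeed(seed, xgboost::xgb.train(params, dfull,
                                             nrounds = max(nBest, 1L),
                                             verbose = 0))
  } else {
    dtrain <- xgboost::xgb.DMatrix(Xs, label = ys, nthread = 1L)
    fit <- withSeed(seed, xgboost::xgb.train(params, dtrain,
                                             nrounds = hp$n_estimators,
                                             verbose = 0))
  }
  list(type = "gbm", booster = fit)
}

#' Predict yields from a fitted model
#'
#' Applies the training-time standardization and back-transform; refuses a
#' matrix whose feature columns do not match the training schema exactly
#' (same names, same order).
#'
#' @param model a [FittedModel-class].
#' @param fm feature matrix (target column not required).
#' @return Numeric vector of predicted yields (kg/ha), one per row.
#' @export
predictYield <- function(model, fm) {
  cols <- intersect(featureColumns(), names(fm))
  if (!identical(cols, model@schema))
    stop("feature columns do not match the model's training schema")
  X <- as.matrix(fm[, cols])
  if (anyNA(X) || !all(is.finite(X)))
    stop("feature matrix contains missing or non-finite values")
  Xs <- sweep(sweep(X, 2L, model@center), 2L, model@scale, "/")
  ps <- if (model@state$type == "gbm")
    predict(model@state$booster, xgboost::xgb.DMatrix(Xs, nthread = 1L))
  else {
    arr <- seqArray(Xs, cols)
    rowMeans(vapply(model@state$members,
                    function(mem) lstmPredict(mem, arr),
                    numeric(nrow(Xs))))
  }
  as.numeric(ps) * model@yScale + model@yCenter
}

setMethod("predict", "FittedModel", function(object, newdata, ...)
  predictYield(object, newdata))
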