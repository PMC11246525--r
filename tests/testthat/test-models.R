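test_that("the 70/30 split is a reproducible partition", {
  fm <- linearFm(10)
  sp <- randomSplit(fm, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 7L)
  expect_equal(nrow(sp$test), 3L)
  sp2 <- randomSplit(fm, 0.7, seed = 3)
  expect_identical(sp$train$unit_id, sp2$train$unit_id)
  expect_length(intersect(sp$train$unit_id, sp$test$unit_id), 0)
  expect_setequal(c(sp$train$unit_id, sp$test$unit_id), fm$unit_id)
  expect_error(randomSplit(linearFm(8), 0.7, 1), "at least 10")
})

test_that("ten-fold assignments are near-equal disjoint partitions", {
  for (seed in c(1, 9)) {
    f <- cropcast:::foldAssignment(100, 10L, seed)
    expect_equal(as.vector(table(f)), rep(10L, 10))
    f2 <- cropcast:::foldAssignment(103, 10L, seed)
    expect_true(max(table(f2)) - min(table(f2)) <= 1)
    expect_length(f2, 103)
  }
})

test_that("cross-validation prefers the spec whose capacity matches the
           generative process", {
  # y = sign(x1) * sign(x2): two-leaf stumps are additive and cannot fit it,
  # four-leaf trees can
  fm <- linearFm(80, seed = 2)
  withr::with_seed(21, {
    fm$VI_Oct <- sample(c(-1, 1), 80, TRUE)
    fm$VI_Nov <- sample(c(-1, 1), 80, TRUE)
  })
  fm$yield <- 5000 + 800 * fm$VI_Oct * fm$VI_Nov
  for (cn in setdiff(featureColumns(), c("VI_Oct", "VI_Nov"))) fm[[cn]] <- 0
  grid <- list(list(num_leaves = 2L, learning_rate = 0.3),
               list(num_leaves = 4L, learning_rate = 0.3))
  spec <- tenfoldCvSelect(fm, "gbm", grid, seed = 3)
  expect_equal(spec@hyper$num_leaves, 4L)
  tab <- attr(spec, "cv_table")
  expect_lt(tab$mean_rmse[2], tab$mean_rmse[1] / 10)

  # degenerate grid of one entry is returned as-is
  one <- tenfoldCvSelect(fm, "gbm", grid[2], seed = 3)
  expect_equal(one@hyper$num_leaves, 4L)
  expect_error(tenfoldCvSelect(fm, "gbm", list(), 1), "empty")
  expect_error(tenfoldCvSelect(fm[1:10, ], "gbm", grid, 1), "at least 20")
})

test_that("both algorithms fit a constant target to within 1%", {
  fm <- linearFm(40, seed = 5)
  fm$yield <- rep(4200, 40)
  for (alg in c("gbm", "lstm")) {
    hyper <- if (alg == "lstm") list(hidden = 8L, epochs = 50L,
                                     n_members = 1L)
             else list()
    fit <- trainModel(fm, modelSpec(alg, hyper, seed = 2))
    pred <- predictYield(fit, fm)
    expect_lt(sqrt(mean((pred - 4200)^2)), 42)
  }
})

test_that("gradient boosting recovers a noiseless linear target in-sample", {
  fm <- linearFm(300, seed = 8, sigma = 0)
  fit <- trainModel(fm, modelSpec("gbm", list(early_stopping = FALSE),
                                  seed = 4))
  pred <- predictYield(fit, fm)
  r <- yieldMetrics(fm$yield, pred)
  expect_gte(reportR2(r), 0.99)
})

test_that("the LSTM recovers a noiseless linear target out of sample", {
  # enough rows that the 48-dimensional linear map is identifiable for a
  # nonparametric sequence model
  fm <- linearFm(2000, seed = 9, sigma = 0)
  sp <- randomSplit(fm, 0.7, seed = 1)
  fit <- trainModel(sp$train, modelSpec("lstm", list(n_members = 1L),
                                        seed = 4))
  pred <- predictYield(fit, sp$test)
  expect_gte(reportR2(yieldMetrics(sp$test$yield, pred)), 0.95)
  # near-zero residuals on training rows of the same noiseless problem
  ptr <- predictYield(fit, sp$train)
  expect_lt(sqrt(mean((ptr - sp$train$yield)^2)) / sd(sp$train$yield), 0.25)
})

test_that("prediction enforces the training schema", {
  fm <- linearFm(60, seed = 3, sigma = 100)
  fit <- trainModel(fm, modelSpec("gbm", seed = 1))
  expect_length(predictYield(fit, fm), 60)
  trunc <- truncateToMonth(fm, "Feb")
  fitT <- trainModel(trunc, modelSpec("gbm", seed = 1))
  expect_error(predictYield(fitT, fm), "schema")
  expect_error(predictYield(fit, trunc), "schema")
  bad <- fm; bad$VI_Apr[3] <- NA
  expect_error(predictYield(fit, bad), "missing")
  expect_error(trainModel(bad, modelSpec("gbm", seed = 1)), "missing")
})

test_that("LSTM backpropagation matches numerical gradients", {
  for (head in c("last", "mean")) {
    W <- cropcast:::lstmInit(2L, 3L, seed = 31)
    X <- array(withr::with_seed(5, rnorm(4 * 3 * 2)), dim = c(4, 3, 2))
    y <- withr::with_seed(6, rnorm(4))
    an <- cropcast:::lstmGrad(W, X, y, head = head)$grad
    lossAt <- function(Wmod)
      mean((cropcast:::lstmForward(Wmod, X, head = head)$yhat - y)^2)
    eps <- 1e-6
    for (nm in names(W)) {
      idx <- seq_len(min(5, length(W[[nm]])))
      for (i in idx) {
        Wp <- W; Wp[[nm]][i] <- Wp[[nm]][i] + eps
        Wm <- W; Wm[[nm]][i] <- Wm[[nm]][i] - eps
        num <- (lossAt(Wp) - lossAt(Wm)) / (2 * eps)
        expect_equal(as.numeric(an[[nm]][i]), num, tolerance = 1e-4)
      }
    }
  }
})

test_that("the lgbm alias and seed reproducibility hold", {
  fm <- linearFm(60, seed = 3, sigma = 100)
  s1 <- modelSpec("lgbm")
  expect_equal(s1@algorithm, "gbm")
  f1 <- trainModel(fm, modelSpec("gbm", seed = 7))
  f2 <- trainModel(fm, modelSpec("gbm", seed = 7))
  expect_equal(predictYield(f1, fm), predictYield(f2, fm))
  l1 <- trainModel(fm, modelSpec("lstm", list(hidden = 8L, epochs = 30L,
                                              n_members = 1L), seed = 7))
  l2 <- trainModel(fm, modelSpec("lstm", list(hidden = 8L, epochs = 30L,
                                              n_members = 1L), seed = 7))
  expect_identical(predictYield(l1, fm), predictYield(l2, fm))
})

test_that("grouped splits hold out whole counties or years", {
  fm <- linearFm(48, seed = 11, years = 2001:2004)
  fm$unit_id <- rep(1:12, each = 4)
  byYear <- randomSplit(fm, 0.7, seed = 2, groupBy = "year")
  expect_length(intersect(unique(byYear$train$year),
                          unique(byYear$test$year)), 0)
  byUnit <- randomSplit(fm, 0.7, seed = 2, groupBy = "unit")
  expect_length(intersect(unique(byUnit$train$unit_id),
                          unique(byUnit$test$unit_id)), 0)
  expect_equal(nrow(byUnit$train) + nrow(byUnit$test), 48L)
  expect_error(randomSplit(fm, 0.7, 1, groupBy = "county"), "groupBy")
})
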