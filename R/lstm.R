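# A small LSTM regressor for monthly feature sequences, written in
# vectorised base R: one recurrent layer, linear head, full backpropagation
# through time, Adam updates, early stopping on a held-out validation
# fraction.  Sequences here are short (at most 8 month steps, 6 channels),
# so dense matrix products over minibatches are entirely adequate.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstmInit <- function(C, H, seed) {
  withSeed(seed, {
    s <- 1 / sqrt(C + H)
    list(
      Wx = matrix(runif(C * 4 * H, -s, s), C, 4 * H),
      Wh = matrix(runif(H * 4 * H, -s, s), H, 4 * H),
      # forget-gate biases start at 1 so early training retains cell state
      b = c(rep(0, H), rep(1, H), rep(0, 2 * H)),
      Wy = matrix(runif(H, -s, s), H, 1),
      by = 0
    )
  })
}

# forward pass; returns predictions and (optionally) the per-step caches
# needed for backpropagation
lstmForward <- function(W, X, cache = FALSE, head = "last") {
  n <- dim(X)[1]; T <- dim(X)[2]; H <- nrow(W$Wy)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  hSum <- matrix(0, n, H)
  caches <- if (cache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    xt <- X[, t, , drop = FALSE]
    dim(xt) <- c(n, dim(X)[3])
    z <- xt %*% W$Wx + h %*% W$Wh + matrix(W$b, n, 4 * H, byrow = TRUE)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cPrev <- cc
    cc <- f * cPrev + i * g
    tc <- tanh(cc)
    hPrev <- h
    h <- o * tc
    hSum <- hSum + h
    if (cache)
      caches[[t]] <- list(x = xt, hPrev = hPrev, cPrev = cPrev, i = i, f = f,
                          g = g, o = o, tc = tc)
  }
  hOut <- if (head == "mean") hSum / T else h
  yhat <- as.vector(hOut %*% W$Wy + W$by)
  list(yhat = yhat, hOut = hOut, caches = caches)
}

# mean-squared-error loss gradient via BPTT
lstmGrad <- function(W, X, y, head = "last") {
  n <- dim(X)[1]; T <- dim(X)[2]; H <- nrow(W$Wy)
  fw <- lstmForward(W, X, cache = TRUE, head = head)
  dy <- matrix(2 * (fw$yhat - y) / n, n, 1)
  gW <- list(Wx = 0 * W$Wx, Wh = 0 * W$Wh, b = 0 * W$b,
             Wy = crossprod(fw$hOut, dy), by = sum(dy))
  dyW <- dy %*% t(W$Wy)
  # with the mean-pooling head every step receives dyW / T directly
  dh <- if (head == "mean") dyW / T else dyW
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(T))) {
    cs <- fw$caches[[t]]
    do <- dh * cs$tc
    dc <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    df <- dc * cs$cPrev
    dg <- dc * cs$i
    dcPrev <- dc * cs$f
    dz <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                dg * (1 - cs$g^2),
                do * cs$o * (1 - cs$o))
    gW$Wx <- gW$Wx + crossprod(cs$x, dz)
    gW$Wh <- gW$Wh + crossprod(cs$hPrev, dz)
    gW$b <- gW$b + colSums(dz)
    dh <- dz %*% t(W$Wh)
    if (head == "mean" && t > 1L) dh <- dh + dyW / T
    dc <- dcPrev
  }
  list(grad = gW, loss = mean((fw$yhat - y)^2))
}

adamStep <- function(W, g, mState, vState, step, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(W)) {
    mState[[nm]] <- beta1 * mState[[nm]] + (1 - beta1) * g[[nm]]
    vState[[nm]] <- beta2 * vState[[nm]] + (1 - beta2) * g[[nm]]^2
    mHat <- mState[[nm]] / (1 - beta1^step)
    vHat <- vState[[nm]] / (1 - beta2^step)
    # decoupled (AdamW-style) weight decay; biases are not decayed
    dec <- if (nm %in% c("b", "by")) 0 else weightDecay
    W[[nm]] <- W[[nm]] - lr * (mHat / (sqrt(vHat) + eps) + dec * W[[nm]])
  }
  list(W = W, m = mState, v = vState)
}

# Train the LSTM on an (n, T, C) array against a numeric target (both
# already standardized by the caller).  Returns the fitted state.
lstmFit <- function(X, y, hidden = 32L, epochs = 200L, batch = 32L,
                    lr = 0.01, patience = 20L, weightDecay = 0,
                    head = "last", valFraction = 0.1, seed = 1L) {
  n <- dim(X)[1]; C <- dim(X)[3]
  W <- lstmInit(C, hidden, childSeed(seed, "init"))
  nVal <- if (n >= 20L) max(2L, round(valFraction * n)) else 0L
  vi <- if (nVal > 0L) withSeed(childSeed(seed, "val"), sample.int(n, nVal))
        else integer()
  ti <- setdiff(seq_len(n), vi)
  Xv <- X[vi, , , drop = FALSE]; yv <- y[vi]
  Xt <- X[ti, , , drop = FALSE]; yt <- y[ti]
  m <- lapply(W, function(w) 0 * w)
  v <- lapply(W, function(w) 0 * w)
  best <- W; bestLoss <- Inf; wait <- 0L; step <- 0L
  plateau <- 0L; lrCur <- lr
  history <- numeric(0)
  orders <- withSeed(childSeed(seed, "shuffle"),
                     lapply(seq_len(epochs), function(e) sample(length(ti))))
  for (e in seq_len(epochs)) {
    ord <- orders[[e]]
    for (bStart in seq(1L, length(ti), by = batch)) {
      rows <- ord[bStart:min(bStart + batch - 1L, length(ti))]
      gb <- lstmGrad(W, Xt[rows, , , drop = FALSE], yt[rows], head)
      step <- step + 1L
      upd <- adamStep(W, gb$grad, m, v, step, lrCur, weightDecay)
      W <- upd$W; m <- upd$m; v <- upd$v
    }
    monLoss <- if (nVal > 0L)
      mean((lstmForward(W, Xv, head = head)$yhat - yv)^2)
    else mean((lstmForward(W, Xt, head = head)$yhat - yt)^2)
    history <- c(history, monLoss)
    if (monLoss < bestLoss - 1e-7) {
      bestLoss <- monLoss; best <- W; wait <- 0L; plateau <- 0L
    } else {
      wait <- wait + 1L
      plateau <- plateau + 1L
      if (wait >= patience) break
      # halve the learning rate when the validation loss stalls
      if (plateau >= 8L && lrCur > 1e-3) {
        lrCur <- lrCur / 2
        plateau <- 0L
      }
    }
  }
  list(type = "lstm", weights = best, head = head, val_loss = bestLoss,
       epochs_run = length(history), history = history)
}

lstmPredict <- function(state, X)
  lstmForward(state$weights, X, head = state$head)$yhat
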