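# Gap-free monthly VI reconstruction: monthly maximum-value compositing,
# temporal interpolation, Savitzky-Golay smoothing and fine/coarse fusion.

#' Monthly maximum-value composite over one season
#'
#' Reduces all valid observations of each pixel within each calendar month
#' slot (October through May) to their maximum, the standard maximum-value
#' compositing that suppresses residual cloud contamination.  A pixel with no
#' valid observation in a month is invalid in that slot.
#'
#' @param cube observation [RasterCube-class].
#' @param season a [SeasonSpec-class].
#' @return A [RasterCube-class] with exactly 8 layers, time-stamped at each
#'   slot's mid-month.
#' @export
monthlyMaxComposite <- function(cube, season) {
  slots <- seasonSlots(season)
  key <- format(cube@timestamps, "%Y-%m")
  slotKey <- sprintf("%d-%02d", slots$year, slots$month)
  if (!any(key %in% slotKey))
    stop("cube timestamps lie entirely outside the season span")
  m <- cubeMatrix(cube)
  out <- matrix(NA_real_, 8L, ncol(m))
  for (s in 1:8) {
    rows <- which(key == slotKey[s])
    if (length(rows)) {
      block <- m[rows, , drop = FALSE]
      mx <- suppressWarnings(apply(block, 2L, max, na.rm = TRUE))
      mx[!is.finite(mx)] <- NA_real_
      out[s, ] <- mx
    }
  }
  cubeFromMatrix(out, cube@spec, seasonSlotDates(season))
}

# Vectorised gap fill of a (T x N) matrix along rows: interior NA runs are
# linearly interpolated in slot index; leading/trailing NAs take the nearest
# valid value.  Columns with no valid entry stay all-NA.
fillSeriesMatrix <- function(m) {
  T <- nrow(m); N <- ncol(m)
  if (T == 0L || N == 0L) return(m)
  obs <- !is.na(m)
  idx <- matrix(seq_len(T), T, N)
  last <- idx; last[!obs] <- 0L
  nxt <- idx; nxt[!obs] <- T + 1L
  if (T > 1L) for (t in 2:T) last[t, ] <- pmax(last[t, ], last[t - 1L, ])
  if (T > 1L) for (t in (T - 1L):1L) nxt[t, ] <- pmin(nxt[t, ], nxt[t + 1L, ])
  colBase <- (seq_len(N) - 1L) * T
  out <- m
  for (t in seq_len(T)) {
    miss <- which(!obs[t, ])
    if (!length(miss)) next
    li <- last[t, miss]; ni <- nxt[t, miss]
    both <- li > 0L & ni <= T
    lead <- li == 0L & ni <= T
    trail <- li > 0L & ni > T
    if (any(both)) {
      j <- miss[both]
      lv <- m[colBase[j] + last[t, j]]
      nv <- m[colBase[j] + nxt[t, j]]
      w <- (t - last[t, j]) / (nxt[t, j] - last[t, j])
      out[t, j] <- lv + (nv - lv) * w
    }
    if (any(lead)) {
      j <- miss[lead]
      out[t, j] <- m[colBase[j] + nxt[t, j]]
    }
    if (any(trail)) {
      j <- miss[trail]
      out[t, j] <- m[colBase[j] + last[t, j]]
    }
  }
  out
}

#' Temporal interpolation of gaps in a cube
#'
#' Fills each pixel's missing layers by linear interpolation in layer index
#' between the nearest valid neighbors; leading/trailing gaps take the
#' nearest valid value.  Originally valid values are unchanged.  Pixels with
#' zero valid layers stay invalid throughout; their count is attached as
#' attribute `n_empty_pixels` on the returned cube's `@layers`-independent
#' metadata (see Details).
#'
#' @details The number of pixels that could not be filled is returned in
#'   `attr(result, "n_empty_pixels")` (stored on the cube's `layers` list is
#'   not possible for S4, so it is recorded via [emptyPixels()]).
#'
#' @param cube a [RasterCube-class].
#' @return A gap-free [RasterCube-class] (except all-missing pixels).
#' @export
temporalInterpolate <- function(cube) {
  if (nLayers(cube) == 0L) stop("empty cube")
  m <- cubeMatrix(cube)
  filled <- fillSeriesMatrix(m)
  out <- cubeFromMatrix(filled, cube@spec, cube@timestamps)
  attr(out, "n_empty_pixels") <- sum(colSums(!is.na(filled)) == 0L)
  out
}

#' Count of pixels left unfilled by the last interpolation/fusion
#' @param cube a cube returned by [temporalInterpolate()] or [fuseCubes()].
#' @return Integer (0 when the attribute is absent).
#' @export
emptyPixels <- function(cube) {
  n <- attr(cube, "n_empty_pixels")
  if (is.null(n)) 0L else as.integer(n)
}

# The (T x T) Savitzky-Golay smoothing operator for a series of length T:
# interior rows carry the central least-squares weights; the first/last
# h = (window-1)/2 rows fit the polynomial to the first/last full window and
# evaluate it at the edge positions, so polynomials of degree <= polyorder
# are reproduced exactly everywhere.
sgOperator <- function(T, params) {
  w <- params@window; p <- params@polyorder
  if (w > T) stop("SG window longer than the series")
  h <- (w - 1L) %/% 2L
  S <- matrix(0, T, T)
  powers <- 0:p
  A <- outer(seq_len(w), powers, "^")     # design over window positions 1..w
  H <- solve(crossprod(A), t(A))           # (p+1) x w least-squares solve
  evalAt <- function(x) as.vector(outer(x, powers, "^") %*% H)
  center <- evalAt(h + 1)
  for (t in seq_len(T)) {
    if (t <= h) S[t, 1:w] <- evalAt(t)
    else if (t > T - h) S[t, (T - w + 1):T] <- evalAt(w - (T - t))
    else S[t, (t - h):(t + h)] <- center
  }
  S
}

#' Savitzky-Golay smoothing of a cube's per-pixel series
#'
#' Convolves each pixel's time series with least-squares Savitzky-Golay
#' weights.  Edges are handled by fitting the polynomial to the first/last
#' full window and evaluating it at the edge positions, so any series that
#' is itself a polynomial of degree at most `polyorder` passes through
#' unchanged at every position.
#'
#' @param cube a gap-free [RasterCube-class] (run [temporalInterpolate()]
#'   first); pixels that are entirely invalid are passed through.
#' @param params an [SGParams-class].
#' @return A smoothed [RasterCube-class].
#' @export
sgSmooth <- function(cube, params = sgParams()) {
  T <- nLayers(cube)
  if (params@window > T) stop("SG window longer than the series")
  m <- cubeMatrix(cube)
  nValid <- colSums(!is.na(m))
  if (any(nValid > 0L & nValid < T))
    stop("cube has per-pixel gaps; run temporalInterpolate() first")
  S <- sgOperator(T, params)
  sm <- S %*% m                            # all-NA pixels stay all-NA
  cubeFromMatrix(sm, cube@spec, cube@timestamps)
}

#' Fuse fine-sensor composites with a smoothed coarse-sensor cube
#'
#' Per slot, the coarse cube is bilinearly resampled to the fine grid; each
#' output pixel takes the fine value where the fine sensor is valid, else
#' the resampled coarse value where that is valid; remaining holes are
#' filled by [temporalInterpolate()] and the final series is Savitzky-Golay
#' smoothed.  The result is gap-free wherever at least one source slot was
#' valid; pixels with no valid source anywhere are excluded and counted
#' (see [emptyPixels()]).
#'
#' No inter-sensor bias correction is applied: gaps take the resampled
#' coarse value as-is, which is an accuracy limitation wherever the two
#' sensors disagree systematically.
#'
#' @param fineMonthly monthly composite [RasterCube-class] on the fine grid.
#' @param coarseMonthly temporally interpolated, smoothed monthly
#'   [RasterCube-class] on the coarse grid, with the same 8 slots.
#' @param sg [SGParams-class] for the final smoothing pass.
#' @param smooth apply the final smoothing (set FALSE to inspect the
#'   pre-smoothing gap-filled cube).
#' @return A [RasterCube-class] on the fine grid.
#' @export
fuseCubes <- function(fineMonthly, coarseMonthly, sg = sgParams(),
                      smooth = TRUE) {
  if (nLayers(fineMonthly) != nLayers(coarseMonthly) ||
      !all(format(fineMonthly@timestamps, "%Y-%m") ==
           format(coarseMonthly@timestamps, "%Y-%m")))
    stop("fine and coarse cubes must share the same month slots")
  fm <- cubeMatrix(fineMonthly)
  cm <- t(vapply(seq_len(nLayers(coarseMonthly)), function(i) {
    as.vector(resampleBilinear(coarseMonthly@layers[[i]],
                               fineMonthly@spec)@values)
  }, numeric(fineMonthly@spec@nRows * fineMonthly@spec@nCols)))
  combined <- ifelse(is.na(fm), cm, fm)
  filled <- fillSeriesMatrix(combined)
  nEmpty <- sum(colSums(!is.na(filled)) == 0L)
  out <- cubeFromMatrix(filled, fineMonthly@spec, fineMonthly@timestamps)
  if (smooth) out <- sgSmooth(out, sg)
  attr(out, "n_empty_pixels") <- nEmpty
  out
}

#' Full single-season reconstruction from observation cubes
#'
#' The standard processing order.  Fine sensor: (already cloud-masked) VI
#' observations are monthly maximum composited.  Coarse sensor: VI
#' observations are temporally interpolated, monthly maximum composited and
#' Savitzky-Golay smoothed.  The two monthly cubes are then fused with
#' [fuseCubes()].
#'
#' @param fineVi VI observation [RasterCube-class] on the fine grid
#'   (validity encodes cloud masking).
#' @param coarseVi VI observation [RasterCube-class] on the coarse grid.
#' @param season a [SeasonSpec-class].
#' @param sg [SGParams-class] shared by the coarse and final smoothing pass.
#' @param smooth apply the final smoothing pass (default TRUE).
#' @return A gap-free monthly [RasterCube-class] on the fine grid.
#' @export
reconstructSeason <- function(fineVi, coarseVi, season, sg = sgParams(),
                              smooth = TRUE) {
  fineM <- monthlyMaxComposite(fineVi, season)
  coarseI <- temporalInterpolate(coarseVi)
  coarseM <- monthlyMaxComposite(coarseI, season)
  coarseM <- temporalInterpolate(coarseM)
  coarseS <- sgSmooth(coarseM, sg)
  fuseCubes(fineM, coarseS, sg, smooth = smooth)
}
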