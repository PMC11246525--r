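# Vegetation indices computed from red / near-infrared surface reflectance.
#
#   NDVI  = (NIR - RED) / (NIR + RED)      clipped to [-1, 1]
#   NIRv  = (NDVI - 0.08) * NIR            0.08 is a fixed constant of the formula
#   kNDVI = tanh(NDVI^2)                   in [0, tanh(1)]

checkReflectanceRange <- function(grid, what) {
  v <- grid@values[grid@valid]
  n <- sum(v < 0 | v > 1)
  if (n > 0 && isTRUE(getOption("cropcast.verbose", FALSE)))
    message(n, " ", what, " reflectance values outside [0, 1] accepted")
  invisible(n)
}

#' NDVI from red and NIR reflectance
#'
#' Computes (NIR - RED) / (NIR + RED) wherever both inputs are valid and the
#' denominator is nonzero, then clips to [-1, 1].  Cells with a zero
#' denominator or an invalid input are invalid.  Reflectance slightly outside
#' [0, 1] (common in real surface-reflectance products) is accepted.
#'
#' @param red,nir [RasterGrid-class]es of reflectance sharing one spec.
#' @return A [RasterGrid-class] of NDVI.
#' @export
computeNDVI <- function(red, nir) {
  if (!sameSpec(red@spec, nir@spec)) stop("red and nir must share a GridSpec")
  checkReflectanceRange(red, "red")
  checkReflectanceRange(nir, "nir")
  den <- nir@values + red@values
  ok <- red@valid & nir@valid & !is.na(den) & den != 0
  v <- (nir@values - red@values) / den
  v <- pmin(pmax(v, -1), 1)
  v[!ok] <- NA_real_
  rasterGrid(v, red@spec, ok)
}

#' NIRv from NDVI and NIR reflectance
#'
#' Computes (NDVI - 0.08) * NIR where both inputs are valid.  The 0.08
#' offset is a fixed constant of the index; the clipped NDVI is used.
#'
#' @param ndvi,nir [RasterGrid-class]es sharing one spec.
#' @return A [RasterGrid-class] of NIRv.
#' @export
computeNIRv <- function(ndvi, nir) {
  if (!sameSpec(ndvi@spec, nir@spec)) stop("ndvi and nir must share a GridSpec")
  ok <- ndvi@valid & nir@valid
  v <- (ndvi@values - 0.08) * nir@values
  v[!ok] <- NA_real_
  rasterGrid(v, ndvi@spec, ok)
}

#' kNDVI from NDVI
#'
#' Computes tanh(NDVI^2), the kernelized NDVI with a fixed length scale; the
#' output lies in [0, tanh(1)] and validity is inherited from the input.
#'
#' @param ndvi a [RasterGrid-class] with valid cells in [-1, 1].
#' @return A [RasterGrid-class] of kNDVI.
#' @export
computeKNDVI <- function(ndvi) {
  v <- tanh(ndvi@values^2)
  v[!ndvi@valid] <- NA_real_
  rasterGrid(v, ndvi@spec, ndvi@valid)
}

#' Per-date vegetation index over band cubes
#'
#' Applies the chosen index to each timestamp of a pair of red/NIR
#' reflectance cubes.  NIRv and kNDVI are derived from the NDVI of the same
#' timestamp.  A cell invalid at date t is invalid in the output at date t
#' only.
#'
#' @param redCube,nirCube [RasterCube-class]s sharing spec and timestamps.
#' @param viName one of `"NDVI"`, `"NIRv"`, `"kNDVI"`.
#' @return A [RasterCube-class] of the index.
#' @export
viCube <- function(redCube, nirCube, viName = c("NDVI", "NIRv", "kNDVI")) {
  viName <- match.arg(viName)
  if (!sameSpec(redCube@spec, nirCube@spec) ||
      !identical(redCube@timestamps, nirCube@timestamps))
    stop("band cubes must share spec and timestamps")
  layers <- lapply(seq_len(nLayers(redCube)), function(i) {
    ndvi <- computeNDVI(redCube@layers[[i]], nirCube@layers[[i]])
    switch(viName,
           NDVI = ndvi,
           NIRv = computeNIRv(ndvi, nirCube@layers[[i]]),
           kNDVI = computeKNDVI(ndvi))
  })
  rasterCube(layers, redCube@timestamps)
}
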