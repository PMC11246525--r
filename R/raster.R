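# Raster I/O, resampling and masking primitives.
#
# On-disk format: ESRI ASCII Grid (.asc) -- a plain-text header
# (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by the
# value matrix, top row first -- with an optional .prj sidecar holding the
# CRS tag.  The format carries square pixels only; that is all the package
# ever writes.

#' Read a single-band raster from an ESRI ASCII Grid file
#'
#' The declared `NODATA_value` (and any non-finite cell) maps to
#' `valid = FALSE`.  A sidecar `<path minus .asc>.prj`, when present, is read
#' as the CRS tag.
#'
#' @param path path to a `.asc` file.
#' @return A [RasterGrid-class].
#' @seealso [writeRaster()]
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  lines <- readLines(path, n = 8L, warn = FALSE)
  hdr <- list()
  nHdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
        grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nHdr <- nHdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("unreadable ASCII grid header in ", path)
  if (!("xllcorner" %in% names(hdr) || "xllcenter" %in% names(hdr)))
    stop("unreadable georeference (no xllcorner/xllcenter) in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  vals <- scan(path, what = double(), skip = nHdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cells, found ", length(vals), " in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  valid <- is.finite(m)
  if (!is.null(hdr$nodata_value))
    valid <- valid & (m != hdr$nodata_value)
  prj <- sub("\\.[^.]+$", ".prj", path)
  crs <- if (file.exists(prj)) readLines(prj, n = 1L, warn = FALSE)
         else "unspecified"
  spec <- gridSpec(nr, nc, originX = xll, originY = yll + nr * cs,
                   pixelWidth = cs, pixelHeight = cs, crs = crs)
  rasterGrid(m, spec, valid)
}

#' Write a RasterGrid to an ESRI ASCII Grid file
#'
#' Invalid cells are written as the declared nodata sentinel.  The CRS tag is
#' written to a `.prj` sidecar.  Requires square pixels (the only kind the
#' package produces); round-trips with [readRaster()] exactly for finite
#' values.
#'
#' @param grid a [RasterGrid-class].
#' @param path output path (conventionally `.asc`); overwritten if present.
#' @param nodata nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
writeRaster <- function(grid, path, nodata = -9999) {
  spec <- grid@spec
  if (spec@pixelWidth != spec@pixelHeight)
    stop("ASCII grid output requires square pixels")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  m <- grid@values
  m[!grid@valid] <- nodata
  hdr <- c(sprintf("ncols %d", spec@nCols),
           sprintf("nrows %d", spec@nRows),
           sprintf("xllcorner %.10g", spec@originX),
           sprintf("yllcorner %.10g", spec@originY - spec@nRows * spec@pixelHeight),
           sprintf("cellsize %.10g", spec@pixelWidth),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(spec@crs, sub("\\.[^.]+$", ".prj", path))
  invisible(path)
}

#' Write / read a RasterCube as a directory of date-stamped grids
#'
#' Layout: one `YYYY-MM-DD.asc` per layer plus a `manifest.csv` listing
#' timestamps and file names.
#'
#' @param cube a [RasterCube-class].
#' @param dir directory (created if missing).
#' @return `dir` (write) or a [RasterCube-class] (read).
#' @export
writeCube <- function(cube, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s.asc", format(cube@timestamps, "%Y-%m-%d"))
  for (i in seq_along(files))
    writeRaster(cube@layers[[i]], file.path(dir, files[i]))
  write.csv(data.frame(timestamp = format(cube@timestamps, "%Y-%m-%d"),
                       file = files),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCube
#' @export
readCube <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  man <- read.csv(mf, stringsAsFactors = FALSE)
  layers <- lapply(file.path(dir, man$file), readRaster)
  rasterCube(layers, as.Date(man$timestamp))
}

#' Bilinear resampling onto a target grid
#'
#' Each target pixel center is interpolated from the 4 surrounding source
#' pixel centers with bilinear weights.  A target cell is invalid when any
#' contributing source cell (weight > 0) is invalid, or when the target
#' center falls outside the hull of source pixel centers.  Validity is thus
#' propagated conservatively; gap repair is the reconstruction stage's job.
#'
#' @param src a [RasterGrid-class].
#' @param target a [GridSpec-class] with the same CRS tag and overlapping
#'   extent.
#' @return A [RasterGrid-class] on `target`.
#' @export
resampleBilinear <- function(src, target) {
  ss <- src@spec
  if (ss@crs != target@crs) stop("CRS mismatch between source and target")
  if (sameSpec(ss, target)) return(src)
  # continuous source index of target centers (u = c means "at center of col c")
  u <- (pixelCenterX(target, seq_len(target@nCols)) - ss@originX) /
    ss@pixelWidth + 0.5
  v <- (ss@originY - pixelCenterY(target, seq_len(target@nRows))) /
    ss@pixelHeight + 0.5
  inX <- u >= 1 & u <= ss@nCols
  inY <- v >= 1 & v <= ss@nRows
  if (!any(inX) || !any(inY)) stop("disjoint extents: no target center falls inside the source")
  c0 <- pmin(pmax(floor(u), 1L), max(ss@nCols - 1L, 1L))
  r0 <- pmin(pmax(floor(v), 1L), max(ss@nRows - 1L, 1L))
  fx <- u - c0
  fy <- v - r0
  c1 <- pmin(c0 + 1L, ss@nCols)
  r1 <- pmin(r0 + 1L, ss@nRows)
  V <- src@values
  A <- src@valid
  v00 <- V[r0, c0, drop = FALSE]; v01 <- V[r0, c1, drop = FALSE]
  v10 <- V[r1, c0, drop = FALSE]; v11 <- V[r1, c1, drop = FALSE]
  a00 <- A[r0, c0, drop = FALSE]; a01 <- A[r0, c1, drop = FALSE]
  a10 <- A[r1, c0, drop = FALSE]; a11 <- A[r1, c1, drop = FALSE]
  WY <- matrix(fy, target@nRows, target@nCols)
  WX <- matrix(fx, target@nRows, target@nCols, byrow = TRUE)
  w00 <- (1 - WY) * (1 - WX); w01 <- (1 - WY) * WX
  w10 <- WY * (1 - WX);       w11 <- WY * WX
  z <- function(m) { m[is.na(m)] <- 0; m }
  vals <- w00 * z(v00) + w01 * z(v01) + w10 * z(v10) + w11 * z(v11)
  ok <- (w00 == 0 | a00) & (w01 == 0 | a01) & (w10 == 0 | a10) & (w11 == 0 | a11)
  ok <- ok & matrix(inY, target@nRows, target@nCols) &
    matrix(inX, target@nRows, target@nCols, byrow = TRUE)
  vals[!ok] <- NA_real_
  rasterGrid(vals, target, ok)
}

#' Mask a grid by a boolean raster
#'
#' Output validity is `grid valid AND mask valid AND mask value != 0`;
#' values are unchanged where kept.
#'
#' @param grid,mask [RasterGrid-class]es sharing one spec; mask values are
#'   interpreted as boolean (nonzero = keep).
#' @return A [RasterGrid-class].
#' @export
maskWhere <- function(grid, mask) {
  if (!sameSpec(grid@spec, mask@spec))
    stop("grid and mask must share the same GridSpec")
  keep <- grid@valid & mask@valid & (!is.na(mask@values) & mask@values != 0)
  vals <- grid@values
  vals[!keep] <- NA_real_
  rasterGrid(vals, grid@spec, keep)
}
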