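#' Construct a GridRaster
#'
#' @param values numeric matrix, row 1 at the top (north).
#' @param cellSizeKm cell edge length in km.
#' @param originXY map coordinates (km) of the lower-left grid corner.
#' @param nodataValue sentinel marking missing cells.
#' @return A \linkS4class{GridRaster}.
#' @examples
#' r <- GridRaster(matrix(1:12, 3, 4))
#' dim(r)
#' @export
GridRaster <- function(values, cellSizeKm = 1, originXY = c(0, 0),
                       nodataValue = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("GridRaster", values = values, cellSizeKm = as.numeric(cellSizeKm),
      originXY = as.numeric(originXY), nodataValue = as.numeric(nodataValue))
}

#' @describeIn GridRaster grid dimensions (rows, cols).
#' @param x a GridRaster.
#' @export
setMethod("dim", "GridRaster", function(x) dim(x@values))

#' Raster accessors
#'
#' \code{rasterValues} returns the value matrix, \code{cellSize} the cell
#' edge in km, \code{rasterOrigin} the lower-left corner, \code{nodataValue}
#' the missing-data sentinel and \code{nodataMask} a logical matrix of
#' missing cells.
#'
#' @param x a \linkS4class{GridRaster}.
#' @return See individual descriptions.
#' @name raster-accessors
NULL

#' @rdname raster-accessors
#' @export
rasterValues <- function(x) x@values

#' @rdname raster-accessors
#' @export
cellSize <- function(x) x@cellSizeKm

#' @rdname raster-accessors
#' @export
rasterOrigin <- function(x) x@originXY

#' @rdname raster-accessors
#' @export
nodataValue <- function(x) x@nodataValue

#' @rdname raster-accessors
#' @export
nodataMask <- function(x) x@values == x@nodataValue

setMethod("show", "GridRaster", function(object) {
  d <- dim(object@values)
  nd <- sum(object@values == object@nodataValue)
  live <- object@values[object@values != object@nodataValue]
  cat("GridRaster: ", d[1], " x ", d[2], " cells, ",
      format(object@cellSizeKm), " km resolution\n", sep = "")
  cat("  origin (lower-left): (", object@originXY[1], ", ",
      object@originXY[2], ") km\n", sep = "")
  if (length(live))
    cat("  value range: [", format(min(live)), ", ", format(max(live)),
        "], nodata cells: ", nd, "\n", sep = "")
  else cat("  all cells nodata\n")
})

## shared geometry check used by every layer-combining operation
stopIfGeometryMismatch <- function(a, b, what = "rasters") {
  if (!identical(dim(a@values), dim(b@values)) ||
      !isTRUE(all.equal(a@cellSizeKm, b@cellSizeKm)) ||
      !isTRUE(all.equal(a@originXY, b@originXY)))
    stop(what, " do not share grid geometry (dimensions, cell size, origin)")
  invisible(TRUE)
}

#' Convert cell indices to map coordinates and back
#'
#' Cells are addressed by 1-based (row, col) with row 1 at the top (north),
#' the storage convention of ESRI ASCII grids.  \code{cellToXY} returns the
#' planar map coordinates (km) of the cell centre; \code{xyToCell} is its
#' inverse.  On a grid with origin (0, 0) and 1-km cells, the top-left cell
#' of a 10-row grid has centre y = 9.5.
#'
#' @param r a \linkS4class{GridRaster}.
#' @param row,col cell indices (vectors of equal length).
#' @param x,y map coordinates in km.
#' @return \code{cellToXY}: a 2-column matrix of x, y; \code{xyToCell}: a
#'   2-column integer matrix of row, col.
#' @examples
#' r <- GridRaster(matrix(0, 10, 10))
#' cellToXY(r, 1, 1)        # (0.5, 9.5)
#' xyToCell(r, 0.5, 9.5)    # row 1, col 1
#' @export
cellToXY <- function(r, row, col) {
  d <- dim(r@values)
  if (any(row < 1L | row > d[1] | col < 1L | col > d[2]))
    stop("cell index out of bounds")
  cbind(x = r@originXY[1] + (col - 0.5) * r@cellSizeKm,
        y = r@originXY[2] + (d[1] - row + 0.5) * r@cellSizeKm)
}

#' @rdname cellToXY
#' @export
xyToCell <- function(r, x, y) {
  d <- dim(r@values)
  col <- floor((x - r@originXY[1]) / r@cellSizeKm) + 1L
  row <- d[1] - floor((y - r@originXY[2]) / r@cellSizeKm)
  if (any(row < 1L | row > d[1] | col < 1L | col > d[2]))
    stop("map coordinates outside raster extent")
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read and write rasters as ESRI ASCII grids
#'
#' The package's raster interchange format is the plain-text ESRI ASCII grid
#' (header of ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value followed
#' by rows from north to south).  Values are written at full double
#' precision, so a write/read round trip is bit-exact.  Coordinates in the
#' file are kilometres, matching the package's planar convention.
#'
#' @param path file path.
#' @param format currently only \code{"ascii"}.
#' @param r a \linkS4class{GridRaster}.
#' @return \code{readRaster}: a GridRaster; \code{writeRaster}: the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' writeRaster(GridRaster(matrix(1:9, 3, 3)), f)
#' readRaster(f)
#' @export
readRaster <- function(path, format = c("ascii")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2L)
      stop("malformed ASCII grid header line in ", path, ": ", lines[i])
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header of ", path, " is missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != hdr$nrows * hdr$ncols)
    stop("ASCII grid body of ", path, " has ", length(body),
         " values; header promises ", hdr$nrows * hdr$ncols)
  vals <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  GridRaster(vals, cellSizeKm = hdr$cellsize,
             originXY = c(hdr$xllcorner, hdr$yllcorner),
             nodataValue = nodata)
}

#' @rdname readRaster
#' @export
writeRaster <- function(r, path, format = c("ascii")) {
  format <- match.arg(format)
  stopifnot(is(r, "GridRaster"))
  validObject(r)
  d <- dim(r@values)
  num <- function(x) formatC(x, format = "g", digits = 17)
  hdr <- c(paste("ncols", d[2]), paste("nrows", d[1]),
           paste("xllcorner", num(r@originXY[1])),
           paste("yllcorner", num(r@originXY[2])),
           paste("cellsize", num(r@cellSizeKm)),
           paste("NODATA_value", num(r@nodataValue)))
  rows <- apply(r@values, 1L, function(v) paste(num(v), collapse = " "))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write raster to ", path,
                                           ": ", conditionMessage(e)),
                  warning = function(w) stop("cannot write raster to ", path,
                                             ": ", conditionMessage(w)))
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}
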