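## Synthetic landscapes with the structure the simulator assumes —
## mountain ranges, plains, river corridors, desert patches, water and
## glacier barriers — so the full pipeline runs and is testable with no
## external data.  All generators are deterministic per seed.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}

#' Synthetic digital elevation model
#'
#' A smooth base elevation plus Gaussian ridge lines (randomly placed and
#' oriented mountain ranges) plus seeded white noise.  Ridge cross-sections
#' are Gaussian with the given width, so one ridge of height h raises the
#' crest by about h above base.
#'
#' @param nRows,nCols grid dimensions.
#' @param cellSizeKm cell size in km.
#' @param seed RNG seed.
#' @param nRanges number of mountain ridges (>= 0).
#' @param rangeHeightM ridge crest height above base (m).
#' @param rangeWidthKm ridge half-width (Gaussian sigma, km).
#' @param baseM base elevation (m).
#' @param noiseSdM white-noise standard deviation (m).
#' @return Elevation \linkS4class{GridRaster} (m).
#' @export
makeDem <- function(nRows, nCols, cellSizeKm = 1, seed = 1, nRanges = 2,
                    rangeHeightM = 2000, rangeWidthKm = 5, baseM = 100,
                    noiseSdM = 10) {
  withSeed(seed, {
    z <- matrix(baseM, nRows, nCols)
    xs <- (col(z) - 0.5) * cellSizeKm
    ys <- (nRows - row(z) + 0.5) * cellSizeKm
    for (i in seq_len(nRanges)) {
      ## a ridge is a line through a random point at a random angle
      px <- runif(1, 0, nCols * cellSizeKm)
      py <- runif(1, 0, nRows * cellSizeKm)
      th <- runif(1, 0, pi)
      dist <- abs(-(xs - px) * sin(th) + (ys - py) * cos(th))
      z <- z + rangeHeightM * exp(-0.5 * (dist / rangeWidthKm)^2)
    }
    if (noiseSdM > 0)
      z <- z + matrix(rnorm(nRows * nCols, 0, noiseSdM), nRows, nCols)
    GridRaster(z, cellSizeKm = cellSizeKm)
  })
}

#' Synthetic annual precipitation
#'
#' A smooth north-south gradient with seeded smooth noise, affinely scaled
#' so that approximately \code{desertFraction} of cells fall strictly below
#' the 250 mm/yr desert threshold (quantile scaling, so the fraction is
#' accurate up to ties).
#'
#' @param dem elevation \linkS4class{GridRaster} defining the grid.
#' @param desertFraction target fraction of desert cells in [0, 1].
#' @param seed RNG seed.
#' @param wetMm,dryMm precipitation (mm/yr) at the wet and dry ends before
#'   scaling.
#' @return Precipitation \linkS4class{GridRaster} (mm/yr).
#' @export
makePrecip <- function(dem, desertFraction = 0, seed = 1, wetMm = 800,
                       dryMm = 120) {
  d <- dim(dem@values)
  withSeed(seed, {
    lat <- (row(dem@values) - 1) / max(d[1] - 1, 1)   # 0 north .. 1 south
    p <- wetMm + (dryMm - wetMm) * lat
    p <- p + 50 * sin(2 * pi * (col(dem@values) / d[2]) * runif(1, 1, 3))
    if (desertFraction <= 0) {
      p <- pmax(p, 260)  # keep everything safely above the threshold
    } else if (desertFraction >= 1) {
      p <- pmin(p, 240)
    } else {
      q <- stats::quantile(p, desertFraction, names = FALSE)
      p <- p - q + 250  # cells below the desertFraction quantile are desert
    }
    GridRaster(p, cellSizeKm = dem@cellSizeKm, originXY = dem@originXY)
  })
}

#' Synthetic rivers by steepest descent
#'
#' Traces polylines downhill from random high cells: from each source the
#' path repeatedly moves to the lowest of the 8 neighbours until it reaches
#' the grid edge or a local minimum.  Elevations along each course are
#' non-increasing.  Discharges are assigned in the order given.
#'
#' @param dem elevation \linkS4class{GridRaster}.
#' @param dischargesM3s vector of discharges (m^3/s), one river each.
#' @param seed RNG seed.
#' @param sourceQuantile elevation quantile above which sources are drawn.
#' @return List of \code{\link{riverSegment}} objects.
#' @export
makeRivers <- function(dem, dischargesM3s, seed = 1, sourceQuantile = 0.9) {
  n <- length(dischargesM3s)
  if (n == 0L) return(list())
  v <- dem@values
  hi <- which(v >= stats::quantile(v, sourceQuantile))
  if (length(hi) < n)
    stop("fewer candidate source cells than rivers requested")
  nr <- nrow(v); nc <- ncol(v)
  withSeed(seed, {
    src <- sample(hi, n)
    lapply(seq_len(n), function(i) {
      r <- ((src[i] - 1L) %% nr) + 1L
      cc <- ((src[i] - 1L) %/% nr) + 1L
      rows <- r; cols <- cc
      prevR <- 0L; prevC <- 0L
      repeat {
        rr <- r + HEADING_DR; ccx <- cc + HEADING_DC
        ok <- rr >= 1L & rr <= nr & ccx >= 1L & ccx <= nc
        if (!any(ok)) break
        e <- v[cbind(rr[ok], ccx[ok])]
        j <- which.min(e)
        if (e[j] > v[r, cc]) break           # local minimum
        nxR <- rr[ok][j]; nxC <- ccx[ok][j]
        if (nxR == prevR && nxC == prevC) break  # flat ping-pong
        prevR <- r; prevC <- cc
        r <- nxR; cc <- nxC
        rows <- c(rows, r); cols <- c(cols, cc)
        if (r == 1L || r == nr || cc == 1L || cc == nc) break
        if (length(rows) > nr * nc) break    # safety
      }
      if (length(rows) < 2L) { # degenerate source on an edge minimum
        rows <- c(rows, min(rows + 1L, nr)); cols <- c(cols, cols[1])
      }
      tmpl <- dem
      xy <- cellToXY(tmpl, rows, cols)
      riverSegment(xy, dischargesM3s[i])
    })
  })
}

#' Synthetic glacier mask
#'
#' Marks the top \code{latFraction} of grid rows as glaciated, mimicking a
#' northern continental ice sheet margin.
#'
#' @param dem elevation \linkS4class{GridRaster}.
#' @param latFraction fraction of rows (from the north edge) under ice.
#' @return Logical matrix.
#' @export
makeGlacierMask <- function(dem, latFraction = 0) {
  d <- dim(dem@values)
  mask <- matrix(FALSE, d[1], d[2])
  k <- floor(latFraction * d[1])
  if (k > 0) mask[seq_len(k), ] <- TRUE
  mask
}

#' Uniform plain with a low-cost corridor
#'
#' The canonical corridor-emergence fixture: a uniform plain of cost
#' \code{offCorridorCost} crossed west-to-east by a one-cell-wide corridor
#' of cost \code{corridorCost} along the middle row.  No barriers.
#'
#' @param lengthCells grid edge length (the grid is square).
#' @param corridorCost cost on the corridor (default 1).
#' @param offCorridorCost cost elsewhere (default 1.74).
#' @return A \linkS4class{CostSurface}.
#' @export
makeCorridorWorld <- function(lengthCells, corridorCost = 1,
                              offCorridorCost = 1.74) {
  if (lengthCells < 3) stop("corridor world needs at least 3x3 cells")
  if (corridorCost >= offCorridorCost)
    stop("'corridorCost' must be below 'offCorridorCost'")
  v <- matrix(offCorridorCost, lengthCells, lengthCells)
  v[ceiling(lengthCells / 2), ] <- corridorCost
  CostSurface(GridRaster(v), matrix(FALSE, lengthCells, lengthCells))
}

#' Uniform open plain
#'
#' A flat, barrier-free cost surface of constant cost — the calibration
#' fixture for mean steps per walk.
#'
#' @param nRows,nCols grid dimensions.
#' @param cost constant cell cost.
#' @return A \linkS4class{CostSurface}.
#' @export
makeUniformPlain <- function(nRows, nCols = nRows, cost = 1) {
  CostSurface(GridRaster(matrix(cost, nRows, nCols)),
              matrix(FALSE, nRows, nCols))
}

#' Generate a full synthetic landscape stack
#'
#' Convenience wrapper producing every layer
#' \code{\link{buildCostSurface}} consumes, from one seed.
#'
#' @param nRows,nCols grid dimensions.
#' @param cellSizeKm cell size (km).
#' @param seed RNG seed.
#' @param nRanges mountain ridges.
#' @param rangeHeightM ridge height (m).
#' @param noiseSdM DEM noise sd (m).
#' @param riverDischargesM3s river discharges (m^3/s).
#' @param desertFraction fraction of desert cells.
#' @param glacierLatFraction fraction of northern rows glaciated.
#' @return List with \code{dem}, \code{precip}, \code{rivers},
#'   \code{glacierMask}, \code{waterMask}.
#' @export
makeLandscape <- function(nRows, nCols = nRows, cellSizeKm = 1, seed = 1,
                          nRanges = 2, rangeHeightM = 2000, noiseSdM = 10,
                          riverDischargesM3s = c(500, 5000),
                          desertFraction = 0.1, glacierLatFraction = 0.1) {
  dem <- makeDem(nRows, nCols, cellSizeKm, seed = seed, nRanges = nRanges,
                 rangeHeightM = rangeHeightM, noiseSdM = noiseSdM)
  list(dem = dem,
       precip = makePrecip(dem, desertFraction, seed = seed + 1L),
       rivers = makeRivers(dem, riverDischargesM3s, seed = seed + 2L),
       glacierMask = makeGlacierMask(dem, glacierLatFraction),
       waterMask = matrix(FALSE, nRows, nCols))
}
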