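#' Construct a CostSurface
#'
#' @param cost \linkS4class{GridRaster} of positive traversal costs.
#' @param barrier \linkS4class{GridRaster} of 0/1 (or a logical matrix,
#'   which is wrapped using the geometry of \code{cost}).
#' @return A \linkS4class{CostSurface}.
#' @export
CostSurface <- function(cost, barrier) {
  if (is.matrix(barrier))
    barrier <- GridRaster(barrier * 1, cellSizeKm = cost@cellSizeKm,
                          originXY = cost@originXY)
  new("CostSurface", cost = cost, barrier = barrier)
}

#' @rdname raster-accessors
#' @export
costLayer <- function(x) x@cost

#' @rdname raster-accessors
#' @export
barrierLayer <- function(x) x@barrier

#' @rdname raster-accessors
#' @export
barrierMask <- function(x) x@barrier@values == 1

setMethod("show", "CostSurface", function(object) {
  d <- dim(object@cost@values)
  nb <- sum(object@barrier@values == 1)
  open <- object@cost@values[object@barrier@values == 0]
  cat("CostSurface: ", d[1], " x ", d[2], " cells, ",
      format(object@cost@cellSizeKm), " km resolution\n", sep = "")
  cat("  barriers: ", nb, " cells (", round(100 * nb / prod(d), 1),
      "%)\n", sep = "")
  if (length(open))
    cat("  open-cell cost range: [", format(min(open)), ", ",
        format(max(open)), "]\n", sep = "")
})

#' Terrain slope from a DEM (Horn's method)
#'
#' Computes per-cell slope in degrees from the 3x3 neighbourhood using
#' Horn's third-order finite difference, the method of standard GIS slope
#' tools.  Grid edges are handled by edge replication; a nodata neighbour is
#' replaced by the centre cell's elevation (a documented fill rule that
#' leaves a flat contribution), and nodata centre cells stay nodata.
#'
#' @param dem \linkS4class{GridRaster} of elevations in metres.
#' @return \linkS4class{GridRaster} of slopes in degrees (>= 0).
#' @export
computeSlope <- function(dem) {
  v <- dem@values
  nd <- dem@nodataValue
  isND <- v == nd
  if (all(isND)) stop("cannot compute slope: DEM is entirely nodata")
  nr <- nrow(v); nc <- ncol(v)
  ## pad by edge replication, then substitute nodata with the centre value
  pr <- c(1L, seq_len(nr), nr)
  pc <- c(1L, seq_len(nc), nc)
  p <- v[pr, pc]
  pna <- isND[pr, pc]
  shift <- function(dr, dc) {
    m <- p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
    mna <- pna[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
    m[mna] <- v[mna]  # nodata neighbour -> centre elevation (flat fill)
    m
  }
  cellM <- dem@cellSizeKm * 1000
  dzdx <- ((shift(-1L, 1L) + 2 * shift(0L, 1L) + shift(1L, 1L)) -
           (shift(-1L, -1L) + 2 * shift(0L, -1L) + shift(1L, -1L))) /
          (8 * cellM)
  dzdy <- ((shift(1L, -1L) + 2 * shift(1L, 0L) + shift(1L, 1L)) -
           (shift(-1L, -1L) + 2 * shift(-1L, 0L) + shift(-1L, 1L))) /
          (8 * cellM)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[isND] <- nd
  GridRaster(slope, cellSizeKm = dem@cellSizeKm, originXY = dem@originXY,
             nodataValue = nd)
}

## Llobera & Sluckin's quartic metabolic cost of walking as a function of
## the terrain gradient m:  E(m) = 2.635 + 17.37 m + 42.37 m^2
##                                 - 21.43 m^3 + 14.93 m^4
llobera_sluckin_E <- function(m) {
  2.635 + 17.37 * m + 42.37 * m^2 - 21.43 * m^3 + 14.93 * m^4
}

## Gradient-convention scale g (m = g * tan(slope)) is calibrated once so
## that cost(15 deg)/cost(0 deg) equals the desert/river penalty anchor
## 1.74, and cached per anchor value.
.walkerCal <- new.env(parent = emptyenv())

#' Calibrated gradient scale of the walker cost function
#'
#' Solves for the scale \code{g} in \code{m = g * tan(slope)} such that
#' \code{walkerCost(15) / walkerCost(0)} equals \code{ratio15} (default
#' 1.74, the cost step the desert and river-crossing penalties are pegged
#' to).  The value is found by \code{uniroot} at ~1e-12 tolerance and
#' cached.
#'
#' @param ratio15 target cost ratio between 15 and 0 degrees.
#' @return The scale \code{g} (a single number).
#' @export
walkerGradientScale <- function(ratio15 = 1.74) {
  key <- format(ratio15, digits = 15)
  if (!is.null(.walkerCal[[key]])) return(.walkerCal[[key]])
  E0 <- llobera_sluckin_E(0)
  f <- function(g) llobera_sluckin_E(g * tanpi(15 / 180)) / E0 - ratio15
  g <- uniroot(f, c(1e-8, 10), tol = 1e-12)$root
  .walkerCal[[key]] <- g
  g
}

#' Slope-dependent walker traversal cost
#'
#' Per-km traversal cost of walking terrain of the given slope, from
#' Llobera and Sluckin's quartic energetic cost of walking, normalized so
#' flat ground costs exactly 1 and calibrated (see
#' \code{\link{walkerGradientScale}}) so a 15-degree slope costs 1.74 times
#' flat ground.  Strictly increasing over the 0-45 degree range of use.
#'
#' @param slopeDeg slope in degrees (vectorized); must satisfy
#'   \code{abs(slopeDeg) < 90}.
#' @param ratio15 calibration anchor, the cost ratio at 15 vs 0 degrees.
#' @return Numeric vector of dimensionless costs; \code{walkerCost(0) == 1}.
#' @examples
#' walkerCost(c(0, 15, 30))
#' @export
walkerCost <- function(slopeDeg, ratio15 = 1.74) {
  if (any(!is.finite(slopeDeg)) || any(abs(slopeDeg) >= 90))
    stop("'slopeDeg' must be finite with absolute value < 90")
  g <- walkerGradientScale(ratio15)
  llobera_sluckin_E(g * tanpi(slopeDeg / 180)) / llobera_sluckin_E(0)
}

#' Multiply cost in desert cells
#'
#' Cells whose annual precipitation is strictly below \code{thresholdMm}
#' are deserts; their traversal cost is multiplied by \code{factor}
#' (default 1.74, a 74% increase — the cost step from flat ground to a
#' 15-degree slope).  Cells at exactly the threshold are not penalized.
#' Nodata in either layer is passed through untouched.
#'
#' @param cost \linkS4class{GridRaster} of traversal costs.
#' @param precip \linkS4class{GridRaster} of annual precipitation (mm/yr),
#'   same geometry.
#' @param thresholdMm desert threshold (default 250 mm/yr).
#' @param factor multiplicative penalty (default 1.74).
#' @return \linkS4class{GridRaster} of penalized costs.
#' @export
applyDesertPenalty <- function(cost, precip, thresholdMm = 250,
                               factor = 1.74) {
  stopIfGeometryMismatch(cost, precip, "cost and precipitation layers")
  v <- cost@values
  keep <- v != cost@nodataValue & precip@values != precip@nodataValue
  desert <- keep & precip@values < thresholdMm
  v[desert] <- v[desert] * factor
  GridRaster(v, cellSizeKm = cost@cellSizeKm, originXY = cost@originXY,
             nodataValue = cost@nodataValue)
}

#' Multiply cost in crossable-river cells
#'
#' @param cost \linkS4class{GridRaster} of traversal costs.
#' @param crossable logical matrix (or 0/1 GridRaster) of cells touched by
#'   a crossable (sub-km wide) river.
#' @param factor multiplicative penalty (default 1.74).
#' @return \linkS4class{GridRaster} of penalized costs.
#' @export
applyCrossablePenalty <- function(cost, crossable, factor = 1.74) {
  if (is(crossable, "GridRaster")) {
    stopIfGeometryMismatch(cost, crossable, "cost and river layers")
    crossable <- crossable@values == 1
  }
  if (!identical(dim(crossable), dim(cost@values)))
    stop("cost and river layers do not share grid dimensions")
  v <- cost@values
  hit <- crossable & v != cost@nodataValue
  v[hit] <- v[hit] * factor
  GridRaster(v, cellSizeKm = cost@cellSizeKm, originXY = cost@originXY,
             nodataValue = cost@nodataValue)
}

#' River width from discharge (hydraulic geometry)
#'
#' Downstream hydraulic-geometry scaling \eqn{w = a Q^b} converting a
#' long-term mean discharge to a bankfull channel width.  Defaults a = 7.2,
#' b = 0.5 follow standard width-discharge scaling; with them a river needs
#' roughly 19,290 m^3/s to reach the 1-km width that makes it a barrier.
#'
#' @param q a \code{\link{riverSegment}} or a nonnegative discharge
#'   (m^3/s, vectorized).
#' @param a,b hydraulic-geometry coefficients.
#' @return Width in metres.
#' @examples
#' riverWidthM(10000)   # 720 m: wide but crossable
#' @export
riverWidthM <- function(q, a = 7.2, b = 0.5) {
  if (inherits(q, "riverSegment")) q <- q$dischargeM3s
  if (any(!is.finite(q)) || any(q < 0))
    stop("discharge must be nonnegative")
  a * q^b
}

## Exact grid traversal (Amanatides & Woo): all cells whose interior a
## segment passes through, in continuous grid coordinates where cell
## (row, col) spans [row-1, row] x [col-1, col] (row axis points south).
segmentCells <- function(r0, c0, r1, c1, nRows, nCols) {
  cells <- matrix(0L, 0L, 2L)
  add <- function(rr, cc) {
    if (rr >= 1L && rr <= nRows && cc >= 1L && cc <= nCols)
      cells <<- rbind(cells, c(rr, cc))
  }
  dr <- r1 - r0; dc <- c1 - c0
  row <- floor(r0) + 1L; col <- floor(c0) + 1L
  add(row, col)
  stepR <- sign(dr); stepC <- sign(dc)
  tMaxR <- if (dr > 0) (row - r0) / dr else if (dr < 0) (row - 1L - r0) / dr else Inf
  tMaxC <- if (dc > 0) (col - c0) / dc else if (dc < 0) (col - 1L - c0) / dc else Inf
  tDeltaR <- if (dr != 0) abs(1 / dr) else Inf
  tDeltaC <- if (dc != 0) abs(1 / dc) else Inf
  while (TRUE) {
    if (tMaxR < tMaxC) {
      if (tMaxR > 1) break
      row <- row + stepR
      tMaxR <- tMaxR + tDeltaR
    } else {
      if (tMaxC > 1) break
      col <- col + stepC
      tMaxC <- tMaxC + tDeltaC
    }
    add(row, col)
  }
  cells
}

#' Rasterize rivers into barrier and crossable masks
#'
#' Every cell whose interior a river polyline passes through is marked: in
#' the barrier mask if the river's hydraulic-geometry width is at least
#' \code{barrierWidthM} (default 1000 m — a river wider than a cell cannot
#' be crossed), otherwise in the crossable mask.  The masks are disjoint;
#' where a wide and a narrow river overlap, the barrier wins.
#'
#' @param rivers list of \code{\link{riverSegment}} objects.
#' @param template \linkS4class{GridRaster} defining the grid.
#' @param a,b hydraulic-geometry coefficients (see \code{\link{riverWidthM}}).
#' @param barrierWidthM width (m) at and above which a river is a barrier.
#' @return List with logical matrices \code{barrier} and \code{crossable}.
#' @export
rasterizeRivers <- function(rivers, template, a = 7.2, b = 0.5,
                            barrierWidthM = 1000) {
  d <- dim(template@values)
  barrier <- matrix(FALSE, d[1], d[2])
  crossable <- matrix(FALSE, d[1], d[2])
  for (rv in rivers) {
    wide <- riverWidthM(rv$dischargeM3s, a, b) >= barrierWidthM
    ## map xy -> continuous grid coords (row axis from the top edge)
    gc <- (rv$coords[, "x"] - template@originXY[1]) / template@cellSizeKm
    gr <- d[1] - (rv$coords[, "y"] - template@originXY[2]) / template@cellSizeKm
    for (i in seq_len(nrow(rv$coords) - 1L)) {
      cells <- segmentCells(gr[i], gc[i], gr[i + 1L], gc[i + 1L], d[1], d[2])
      if (nrow(cells)) {
        idx <- cbind(cells[, 1], cells[, 2])
        if (wide) barrier[idx] <- TRUE else crossable[idx] <- TRUE
      }
    }
  }
  crossable[barrier] <- FALSE
  list(barrier = barrier, crossable = crossable)
}

#' Flood-fill a paleolake up to a water level
#'
#' Emulates QGIS-style lake flooding: the set of cells 4-connected to the
#' seed through cells with elevation at or below \code{waterLevelM}.
#' 4-connectivity is the standard hydrological convention — water cannot
#' leak diagonally between two touching land cells.  A seed above the water
#' level yields an empty mask with a warning.
#'
#' @param dem \linkS4class{GridRaster} of elevations (m).
#' @param waterLevelM water surface elevation (m).
#' @param seed integer length-2 (row, col) of a cell inside the lake.
#' @return Logical matrix: TRUE on flooded cells.
#' @export
floodFillLake <- function(dem, waterLevelM, seed) {
  v <- dem@values
  nr <- nrow(v); nc <- ncol(v)
  sr <- as.integer(seed[1]); sc <- as.integer(seed[2])
  if (sr < 1L || sr > nr || sc < 1L || sc > nc)
    stop("flood seed out of bounds")
  mask <- matrix(FALSE, nr, nc)
  wet <- v != dem@nodataValue & v <= waterLevelM
  if (!wet[sr, sc]) {
    warning("flood seed lies above the water level; returning empty mask")
    return(mask)
  }
  ## iterative BFS on a preallocated stack (no recursion: grids can be large)
  stackR <- integer(nr * nc); stackC <- integer(nr * nc)
  stackR[1L] <- sr; stackC[1L] <- sc
  top <- 1L
  mask[sr, sc] <- TRUE
  while (top > 0L) {
    r <- stackR[top]; cc <- stackC[top]; top <- top - 1L
    for (k in 1:4) {
      nr2 <- r + c(-1L, 1L, 0L, 0L)[k]
      nc2 <- cc + c(0L, 0L, -1L, 1L)[k]
      if (nr2 >= 1L && nr2 <= nr && nc2 >= 1L && nc2 <= nc &&
          wet[nr2, nc2] && !mask[nr2, nc2]) {
        mask[nr2, nc2] <- TRUE
        top <- top + 1L
        stackR[top] <- nr2; stackC[top] <- nc2
      }
    }
  }
  mask
}

#' Cost-surface construction settings
#'
#' Collects the thresholds and factors of \code{\link{buildCostSurface}}.
#' \code{lakeLevels} is a list of \code{list(levelM = , seedXY = c(x, y))}
#' entries, one per paleolake to flood (the seed is a map coordinate inside
#' the lake); it is the in-code form of a reconstruction's lake-level table.
#'
#' @param desertThresholdMm annual precipitation (mm/yr) below which a cell
#'   is desert (strict comparison; default 250).
#' @param desertFactor multiplicative desert penalty (default 1.74).
#' @param riverCrossFactor multiplicative penalty for crossing a sub-km
#'   river (default 1.74).
#' @param widthA,widthB hydraulic-geometry coefficients.
#' @param barrierWidthM river width (m) making a river a barrier.
#' @param walkerRatio15 walker-cost calibration anchor.
#' @param lakeLevels paleolake flooding spec (see above).
#' @return A list of class \code{costConfig}.
#' @export
costConfig <- function(desertThresholdMm = 250, desertFactor = 1.74,
                       riverCrossFactor = 1.74, widthA = 7.2, widthB = 0.5,
                       barrierWidthM = 1000, walkerRatio15 = 1.74,
                       lakeLevels = list()) {
  structure(list(desertThresholdMm = desertThresholdMm,
                 desertFactor = desertFactor,
                 riverCrossFactor = riverCrossFactor,
                 widthA = widthA, widthB = widthB,
                 barrierWidthM = barrierWidthM,
                 walkerRatio15 = walkerRatio15,
                 lakeLevels = lakeLevels),
            class = "costConfig")
}

#' Build a traversal-cost surface from landscape layers
#'
#' The slope-based walker cost is the base map; penalties multiply it and
#' barriers override everything.  Per cell:
#' \enumerate{
#'   \item base cost = \code{\link{walkerCost}} of the Horn slope of the DEM;
#'   \item cells with precipitation strictly below the desert threshold are
#'     multiplied by the desert factor (default 1.74);
#'   \item cells crossed by a river narrower than 1 km are multiplied by the
#'     river-crossing factor (default 1.74); the two penalties compound
#'     multiplicatively on a desert cell with a river;
#'   \item barrier = ocean/lake mask, glacier mask, rivers at least 1 km
#'     wide, flood-filled paleolakes, and nodata in any input layer.
#' }
#' The construction is deterministic: identical inputs give a bit-identical
#' surface.
#'
#' @param dem elevation \linkS4class{GridRaster} (m).
#' @param precip annual-precipitation \linkS4class{GridRaster} (mm/yr), or
#'   NULL for no desert anywhere.
#' @param glacierMask,waterMask logical matrices (or 0/1 GridRasters) of
#'   glacier and modern lake/ocean cells, or NULL.
#' @param rivers list of \code{\link{riverSegment}} objects.
#' @param config a \code{\link{costConfig}}.
#' @return A \linkS4class{CostSurface}.
#' @export
buildCostSurface <- function(dem, precip = NULL, glacierMask = NULL,
                             waterMask = NULL, rivers = list(),
                             config = costConfig()) {
  asMask <- function(m, what) {
    if (is.null(m)) return(matrix(FALSE, nrow(dem@values), ncol(dem@values)))
    if (is(m, "GridRaster")) {
      stopIfGeometryMismatch(dem, m, paste("DEM and", what))
      return(m@values == 1)
    }
    if (!identical(dim(m), dim(dem@values)))
      stop("DEM and ", what, " do not share grid dimensions")
    m
  }
  glacier <- asMask(glacierMask, "glacier mask")
  water <- asMask(waterMask, "water mask")

  slope <- computeSlope(dem)
  nd <- dem@nodataValue
  noData <- dem@values == nd
  costV <- matrix(nd, nrow(dem@values), ncol(dem@values))
  costV[!noData] <- walkerCost(slope@values[!noData],
                               ratio15 = config$walkerRatio15)
  cost <- GridRaster(costV, cellSizeKm = dem@cellSizeKm,
                     originXY = dem@originXY, nodataValue = nd)

  if (!is.null(precip)) {
    stopIfGeometryMismatch(dem, precip, "DEM and precipitation layers")
    cost <- applyDesertPenalty(cost, precip,
                               thresholdMm = config$desertThresholdMm,
                               factor = config$desertFactor)
    noData <- noData | precip@values == precip@nodataValue
  }

  rmask <- rasterizeRivers(rivers, dem, a = config$widthA, b = config$widthB,
                           barrierWidthM = config$barrierWidthM)
  cost <- applyCrossablePenalty(cost, rmask$crossable,
                                factor = config$riverCrossFactor)

  flooded <- matrix(FALSE, nrow(dem@values), ncol(dem@values))
  for (lk in config$lakeLevels) {
    seedRC <- if (!is.null(lk$seedXY))
      xyToCell(dem, lk$seedXY[1], lk$seedXY[2])[1, ]
    else as.integer(lk$seedRC)
    flooded <- flooded | floodFillLake(dem, lk$levelM, seedRC)
  }

  barrier <- glacier | water | rmask$barrier | flooded | noData
  cv <- cost@values
  cv[barrier] <- nd  # barrier cells carry no usable cost
  CostSurface(GridRaster(cv, cellSizeKm = dem@cellSizeKm,
                         originXY = dem@originXY, nodataValue = nd),
              barrier)
}
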