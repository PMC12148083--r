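#' @import methods
NULL

#' GridRaster: a uniform-cell gridded field
#'
#' The carrier for every gridded layer in the package: elevation (m), annual
#' precipitation (mm/yr), traversal cost, boolean masks and occupancy counts.
#' Values are stored as a numeric matrix with row 1 at the top (north), the
#' storage order of ESRI ASCII grids.  Map coordinates are planar, in
#' kilometres, with y increasing northward; \code{originXY} is the map
#' position of the lower-left corner of the grid.
#'
#' Cells equal to \code{nodataValue} are missing; every other value must be
#' finite.
#'
#' @slot values numeric matrix (nrow x ncol), row 1 = north.
#' @slot cellSizeKm positive number, cell edge length in km (nominally 1).
#' @slot originXY numeric length-2, map x/y of the lower-left grid corner.
#' @slot nodataValue numeric sentinel marking missing cells.
#'
#' @aliases GridRaster-class
#' @exportClass GridRaster
setClass("GridRaster",
  representation(
    values = "matrix",
    cellSizeKm = "numeric",
    originXY = "numeric",
    nodataValue = "numeric"
  ),
  prototype(
    cellSizeKm = 1,
    originXY = c(0, 0),
    nodataValue = -9999
  )
)

setValidity("GridRaster", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L)
    msg <- c(msg, "raster must have at least one row and one column")
  if (length(object@cellSizeKm) != 1L || !is.finite(object@cellSizeKm) ||
      object@cellSizeKm <= 0)
    msg <- c(msg, "'cellSizeKm' must be a single positive number")
  if (length(object@originXY) != 2L || any(!is.finite(object@originXY)))
    msg <- c(msg, "'originXY' must be two finite numbers")
  if (length(object@nodataValue) != 1L || !is.finite(object@nodataValue))
    msg <- c(msg, "'nodataValue' must be a single finite number")
  if (is.numeric(v) && length(object@nodataValue) == 1L) {
    live <- v[!is.na(v) & v != object@nodataValue]
    if (any(!is.finite(live)))
      msg <- c(msg, "non-nodata values must all be finite")
    if (anyNA(v))
      msg <- c(msg, "use the nodata sentinel, not NA, for missing cells")
  }
  if (length(msg)) msg else TRUE
})

#' CostSurface: traversal cost plus barrier mask
#'
#' The agent's only knowledge of the world: a dimensionless per-cell
#' traversal cost (slope-based walker cost times any desert / river-crossing
#' penalty) and a boolean barrier layer (ocean, lakes, glaciers, rivers wider
#' than one cell, nodata).  Cost is positive and finite on every non-barrier
#' cell; barrier cells are never read as movement candidates.
#'
#' @slot cost \linkS4class{GridRaster} of positive traversal costs.
#' @slot barrier \linkS4class{GridRaster} holding 0/1 (1 = impassable).
#'
#' @aliases CostSurface-class
#' @exportClass CostSurface
setClass("CostSurface",
  representation(cost = "GridRaster", barrier = "GridRaster")
)

setValidity("CostSurface", function(object) {
  msg <- character()
  cv <- object@cost@values
  bv <- object@barrier@values
  if (!identical(dim(cv), dim(bv)))
    msg <- c(msg, "cost and barrier layers must share grid dimensions")
  if (!isTRUE(all.equal(object@cost@cellSizeKm, object@barrier@cellSizeKm)))
    msg <- c(msg, "cost and barrier layers must share cell size")
  if (!all(bv %in% c(0, 1)))
    msg <- c(msg, "barrier values must be 0 or 1")
  if (identical(dim(cv), dim(bv))) {
    open <- bv == 0
    if (any(!is.finite(cv[open])) || any(cv[open] <= 0))
      msg <- c(msg, "cost must be positive and finite on all non-barrier cells")
  }
  if (length(msg)) msg else TRUE
})

#' LevyParams: parameters of the truncated power-law walk
#'
#' Bout lengths follow the truncated discrete power law
#' \eqn{P(l) \propto l^{-\mu}} on \eqn{l \in [l_{min}, l_{max}]}.  The
#' occupancy memory marks a cell "recently occupied" if it was visited within
#' the last \code{memoryHorizon} steps; an agent finding at least
#' \code{newTerritoryMinUnvisited} of its 8 neighbours not recently occupied
#' is in new territory and doubles its current bout length (capped at
#' \code{lMax * doublingFactor}).
#'
#' The default exponent \code{mu} is a calibrated constant chosen so the mean
#' realized steps per walk on an open uniform plain is about 2.075 (see the
#' package vignette); all fields are ordinary knobs.
#'
#' @slot mu power-law exponent, > 1.
#' @slot lMin,lMax integer truncation bounds of the bout length, lMin <= lMax.
#' @slot memoryHorizon steps within which a visited cell counts as recent.
#' @slot newTerritoryMinUnvisited neighbours (of 8) that must be unvisited to
#'   trigger doubling; 1..8, default 5 ("most" of the neighbourhood).
#' @slot doublingFactor multiplier applied to the bout length in new
#'   territory (default 2).
#'
#' @aliases LevyParams-class
#' @exportClass LevyParams
setClass("LevyParams",
  representation(
    mu = "numeric",
    lMin = "integer",
    lMax = "integer",
    memoryHorizon = "integer",
    newTerritoryMinUnvisited = "integer",
    doublingFactor = "integer"
  )
)

setValidity("LevyParams", function(object) {
  msg <- character()
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu <= 1)
    msg <- c(msg, "'mu' must be a single number > 1")
  if (object@lMin < 1L) msg <- c(msg, "'lMin' must be >= 1")
  if (object@lMax < object@lMin) msg <- c(msg, "'lMax' must be >= 'lMin'")
  if (object@memoryHorizon < 1L) msg <- c(msg, "'memoryHorizon' must be >= 1")
  if (object@newTerritoryMinUnvisited < 1L ||
      object@newTerritoryMinUnvisited > 8L)
    msg <- c(msg, "'newTerritoryMinUnvisited' must be in 1..8")
  if (object@doublingFactor < 1L)
    msg <- c(msg, "'doublingFactor' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Trajectory: the ordered step record of one simulation run
#'
#' One row per recorded position: the initial placement (walk index 0) and
#' every step taken.  Consecutive positions are 8-adjacent and never on a
#' barrier cell.  Rows and columns are 1-based matrix indices into the cost
#' surface the run was executed on; the grid geometry is carried along so
#' steps can be mapped to planar km coordinates.
#'
#' @slot steps integer matrix with columns \code{walk}, \code{row},
#'   \code{col}; first row is the start position with walk 0.
#' @slot cellSizeKm,originXY,nRows,nCols grid geometry of the underlying
#'   cost surface.
#' @slot seed integer seed the run was executed with.
#' @slot scenario character scenario identifier.
#' @slot trapped logical; TRUE if the agent ran out of moves before
#'   completing its scheduled walks.
#' @slot nWalks number of Lévy walks scheduled.
#'
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    steps = "matrix",
    cellSizeKm = "numeric",
    originXY = "numeric",
    nRows = "integer",
    nCols = "integer",
    seed = "integer",
    scenario = "character",
    trapped = "logical",
    nWalks = "integer"
  ),
  prototype(scenario = "unnamed", trapped = FALSE)
)

setValidity("Trajectory", function(object) {
  msg <- character()
  s <- object@steps
  if (ncol(s) != 3L || !identical(colnames(s), c("walk", "row", "col")))
    msg <- c(msg, "'steps' must have columns walk, row, col")
  if (nrow(s) < 1L) msg <- c(msg, "a trajectory records at least the start")
  if (nrow(s) >= 1L) {
    if (any(s[, "row"] < 1L) || any(s[, "row"] > object@nRows) ||
        any(s[, "col"] < 1L) || any(s[, "col"] > object@nCols))
      msg <- c(msg, "step coordinates out of grid bounds")
    if (nrow(s) >= 2L) {
      dr <- abs(diff(s[, "row"])); dc <- abs(diff(s[, "col"]))
      if (any(pmax(dr, dc) != 1L))
        msg <- c(msg, "consecutive steps must be 8-adjacent")
    }
  }
  if (length(msg)) msg else TRUE
})
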