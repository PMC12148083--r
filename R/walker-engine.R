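#' Construct LevyParams
#'
#' Defaults are the package's shipped calibration: \code{mu} is chosen so
#' the mean realized steps per walk on an open uniform plain is about 2.075
#' (see the vignette and \code{scripts/calibrate_levy.R}); the memory
#' horizon and new-territory threshold are model constants, all exposed as
#' knobs.
#'
#' @param mu power-law exponent (> 1).
#' @param lMin,lMax truncation bounds of the drawn bout length.
#' @param memoryHorizon steps within which a visited cell is "recent".
#' @param newTerritoryMinUnvisited unvisited neighbours (of 8) required to
#'   double the bout length.
#' @param doublingFactor bout-length multiplier in new territory.
#' @return A \linkS4class{LevyParams}.
#' @export
LevyParams <- function(mu = PALEOWALK_DEFAULT_MU, lMin = 1, lMax = 100,
                       memoryHorizon = 10000,
                       newTerritoryMinUnvisited = 5, doublingFactor = 2) {
  new("LevyParams", mu = as.numeric(mu), lMin = as.integer(lMin),
      lMax = as.integer(lMax), memoryHorizon = as.integer(memoryHorizon),
      newTerritoryMinUnvisited = as.integer(newTerritoryMinUnvisited),
      doublingFactor = as.integer(doublingFactor))
}

setMethod("show", "LevyParams", function(object) {
  cat("LevyParams: P(l) ~ l^-", format(object@mu), " on [",
      object@lMin, ", ", object@lMax, "]\n", sep = "")
  cat("  memory horizon ", object@memoryHorizon, " steps; doubling x",
      object@doublingFactor, " when >= ", object@newTerritoryMinUnvisited,
      "/8 neighbours unvisited\n", sep = "")
})

#' Truncated power-law mass function
#'
#' The normalized probabilities \eqn{P(l) = l^{-\mu} / \sum_{k} k^{-\mu}}
#' on the support \code{lMin..lMax}; the distribution
#' \code{\link{drawLevyLength}} samples from.
#'
#' @param p a \linkS4class{LevyParams}.
#' @return Numeric vector of probabilities over \code{p@lMin : p@lMax}.
#' @export
levyMassFunction <- function(p) {
  l <- seq(p@lMin, p@lMax)
  w <- l^(-p@mu)
  w / sum(w)
}

#' Draw a Lévy bout length by inverse CDF
#'
#' Maps a uniform deviate to the truncated discrete power law
#' \eqn{P(l) \propto l^{-\mu}} on \code{lMin..lMax}: \code{u = 0} gives
#' \code{lMin}, and the map is nondecreasing in \code{u}.
#'
#' @param u uniform deviates in [0, 1) (vectorized).
#' @param p a \linkS4class{LevyParams}.
#' @return Integer bout lengths.
#' @export
drawLevyLength <- function(u, p) {
  if (any(u < 0 | u >= 1)) stop("'u' must lie in [0, 1)")
  pm <- levyMassFunction(p)
  cdf <- cumsum(pm)
  cdf[length(cdf)] <- 1  # guard rounding so u -> lMax stays in support
  p@lMin + findInterval(u, cdf, left.open = FALSE)
}

## 8 headings, index 1..8 = bearings 0 (N), 45 (NE), ..., 315 (NW).
## Row offsets: north = up = decreasing row.
HEADING_DR <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
HEADING_DC <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Bearings of the 8 grid headings
#'
#' @param h heading index 1..8.
#' @return Bearing in degrees clockwise from north (0, 45, ..., 315).
#' @export
headingBearing <- function(h) (h - 1L) * 45

## internal: mutable run state (environment, not S4, for speed)
newAgentState <- function(row, col, nRows, nCols) {
  s <- new.env(parent = emptyenv())
  s$row <- row; s$col <- col
  s$heading <- NA_integer_
  s$nRows <- nRows; s$nCols <- nCols
  s$lastVisit <- matrix(0L, nRows, nCols)  # 0 = never visited
  s$globalStep <- 0L
  s$lastVisit[row, col] <- 1L  # the start cell counts as visited
  s
}

## internal: neighbour scan shared by the 360-degree and cone choices.
## headings: candidate heading indices; returns the chosen heading or NA.
pickMinCostHeading <- function(s, costV, barrierV, headings, memoryHorizon) {
  nr <- s$nRows; nc <- s$nCols
  rows <- s$row + HEADING_DR[headings]
  cols <- s$col + HEADING_DC[headings]
  ok <- rows >= 1L & rows <= nr & cols >= 1L & cols <= nc
  if (!any(ok)) return(NA_integer_)
  headings <- headings[ok]; rows <- rows[ok]; cols <- cols[ok]
  idx <- (cols - 1L) * nr + rows
  open <- !barrierV[idx]
  if (!any(open)) return(NA_integer_)
  headings <- headings[open]; idx <- idx[open]
  lv <- s$lastVisit[idx]
  recent <- lv > 0L & (s$globalStep + 1L - lv) < memoryHorizon
  if (any(!recent)) {          # memory filter; dropped if it empties the set
    headings <- headings[!recent]; idx <- idx[!recent]
  }
  cost <- costV[idx]
  best <- which(cost == min(cost))
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  headings[best]
}

#' Choose a heading by scanning all eight neighbours
#'
#' The agent assesses its 8 adjacent cells in a full 360-degree radius and
#' faces the lowest-cost one that is in bounds, not a barrier, and not
#' recently occupied (visited within the memory horizon).  Exact cost ties
#' are broken uniformly at random from the run RNG.  If every open
#' neighbour is recent, the memory filter is dropped; \code{NA} is returned
#' only when all 8 neighbours are barriers or out of bounds (a trapped
#' agent).
#'
#' @param s agent state (internal environment; see \code{\link{runScenario}}).
#' @param cs \linkS4class{CostSurface}.
#' @param p \linkS4class{LevyParams}.
#' @return Heading index 1..8, or NA if trapped.
#' @keywords internal
chooseHeading360 <- function(s, cs, p) {
  pickMinCostHeading(s, cs@cost@values, cs@barrier@values == 1, 1:8,
                     p@memoryHorizon)
}

#' Neighbours inside the forward cone
#'
#' During a Lévy bout the agent only considers cells within a 100-degree
#' cone about its heading — never the cells behind itself.  On the 45-degree
#' neighbour spacing that is exactly the three cells at relative bearings
#' -45, 0 and +45 degrees (fewer at grid edges).
#'
#' @param heading heading index 1..8.
#' @param row,col agent position.
#' @param nRows,nCols grid dimensions.
#' @return Integer matrix with columns \code{heading}, \code{row},
#'   \code{col}, one row per in-bounds cone cell.
#' @export
coneNeighbors <- function(heading, row, col, nRows, nCols) {
  hs <- ((heading - 1L + c(-1L, 0L, 1L)) %% 8L) + 1L
  rows <- row + HEADING_DR[hs]
  cols <- col + HEADING_DC[hs]
  ok <- rows >= 1L & rows <= nRows & cols >= 1L & cols <= nCols
  cbind(heading = hs[ok], row = rows[ok], col = cols[ok])
}

#' Is the agent in new territory?
#'
#' TRUE when at least \code{newTerritoryMinUnvisited} of the agent's
#' in-bounds 8 neighbours have not been recently occupied — the trigger for
#' colonization-style bout doubling.
#'
#' @param s agent state.
#' @param p \linkS4class{LevyParams}.
#' @return Logical.
#' @keywords internal
isNewTerritory <- function(s, p) {
  rows <- s$row + HEADING_DR
  cols <- s$col + HEADING_DC
  ok <- rows >= 1L & rows <= s$nRows & cols >= 1L & cols <= s$nCols
  idx <- (cols[ok] - 1L) * s$nRows + rows[ok]
  lv <- s$lastVisit[idx]
  unvisited <- !(lv > 0L & (s$globalStep + 1L - lv) < p@memoryHorizon)
  sum(unvisited) >= p@newTerritoryMinUnvisited
}

#' Execute one Lévy walk
#'
#' One bout of the agent loop: face the lowest-cost non-recent neighbour
#' (360-degree scan), draw a bout length from the truncated power law,
#' double it if in new territory (capped at \code{lMax * doublingFactor}),
#' then step up to that many times, each step moving to the lowest-cost
#' non-recent cell inside the 100-degree forward cone and turning the
#' heading to the direction moved.  The bout ends early if the cone holds
#' no open cell.
#'
#' @param s agent state.
#' @param cs \linkS4class{CostSurface}.
#' @param p \linkS4class{LevyParams}.
#' @return Integer matrix with columns \code{row}, \code{col} of the cells
#'   visited, with attribute \code{trapped} = TRUE if no 360-degree
#'   candidate existed.
#' @keywords internal
doLevyWalk <- function(s, cs, p) {
  ## the scenario loop caches these in the state to avoid per-walk
  ## re-extraction over the whole grid
  costV <- if (!is.null(s$costV)) s$costV else cs@cost@values
  barrierV <- if (!is.null(s$barrierV)) s$barrierV else cs@barrier@values == 1
  h <- pickMinCostHeading(s, costV, barrierV, 1:8, p@memoryHorizon)
  if (is.na(h)) {
    out <- matrix(0L, 0L, 2L, dimnames = list(NULL, c("row", "col")))
    attr(out, "trapped") <- TRUE
    return(out)
  }
  s$heading <- h
  u <- runif(1)
  l <- if (!is.null(s$levyCdf)) p@lMin + findInterval(u, s$levyCdf)
       else drawLevyLength(u, p)
  if (isNewTerritory(s, p))
    l <- min(l * p@doublingFactor, p@lMax * p@doublingFactor)
  visited <- matrix(0L, l, 2L, dimnames = list(NULL, c("row", "col")))
  n <- 0L
  for (i in seq_len(l)) {
    h2 <- pickMinCostHeading(s, costV, barrierV,
                             ((s$heading - 1L + c(-1L, 0L, 1L)) %% 8L) + 1L,
                             p@memoryHorizon)
    if (is.na(h2)) break  # dead-end cone: the bout ends early
    s$row <- s$row + HEADING_DR[h2]
    s$col <- s$col + HEADING_DC[h2]
    s$heading <- h2
    s$globalStep <- s$globalStep + 1L
    s$lastVisit[s$row, s$col] <- s$globalStep + 1L
    n <- n + 1L
    visited[n, 1L] <- s$row; visited[n, 2L] <- s$col
  }
  out <- visited[seq_len(n), , drop = FALSE]
  attr(out, "trapped") <- FALSE
  out
}

#' Run a full simulation scenario
#'
#' Places one agent on a uniformly random non-barrier cell of the start
#' region and executes \code{nWalks} Lévy walks, recording every step.  A
#' single seeded RNG drives all stochastic choices in a fixed order (start
#' cell, then per walk: heading tie-breaks, the bout-length deviate, step
#' tie-breaks), so identical inputs and seed give a bit-identical
#' trajectory.  A permanently trapped agent truncates the run (flagged, not
#' an error).
#'
#' @param cs \linkS4class{CostSurface}.
#' @param startRegion where the agent may start: a 2-column x/y matrix of
#'   polygon vertices (map km), a logical matrix of allowed cells, or NULL
#'   for the whole grid.
#' @param nWalks number of Lévy walks (default 400000, the full study
#'   scale; tests use far fewer).
#' @param seed integer RNG seed.
#' @param levy \linkS4class{LevyParams}.
#' @param scenario scenario id stored in the trajectory metadata.
#' @return A \linkS4class{Trajectory}.
#' @examples
#' cs <- makeCorridorWorld(30)
#' tr <- runScenario(cs, nWalks = 50, seed = 1)
#' tr
#' @export
runScenario <- function(cs, startRegion = NULL, nWalks = 400000, seed = 1,
                        levy = LevyParams(), scenario = "unnamed") {
  validObject(cs); validObject(levy)
  if (nWalks < 0) stop("'nWalks' must be nonnegative")
  nr <- nrow(cs@cost@values); nc <- ncol(cs@cost@values)
  open <- cs@barrier@values == 0
  allowed <- if (is.null(startRegion)) {
    open
  } else if (is.matrix(startRegion) && is.logical(startRegion)) {
    if (!identical(dim(startRegion), dim(open)))
      stop("start-region mask does not match the grid")
    startRegion & open
  } else {
    ctr <- cellToXY(cs@cost, rep(seq_len(nr), nc),
                    rep(seq_len(nc), each = nr))
    inside <- matrix(pointsInPolygon(startRegion, ctr), nr, nc)
    inside & open
  }
  startIdx <- which(allowed)
  if (!length(startIdx))
    stop("start region contains no non-barrier cell")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  pick <- startIdx[sample.int(length(startIdx), 1L)]
  row0 <- ((pick - 1L) %% nr) + 1L
  col0 <- ((pick - 1L) %/% nr) + 1L
  s <- newAgentState(row0, col0, nr, nc)
  s$costV <- cs@cost@values
  s$barrierV <- !open
  cdf <- cumsum(levyMassFunction(levy))
  cdf[length(cdf)] <- 1
  s$levyCdf <- cdf

  cap <- 1024L
  walkV <- integer(cap); rowV <- integer(cap); colV <- integer(cap)
  walkV[1L] <- 0L; rowV[1L] <- row0; colV[1L] <- col0
  n <- 1L
  trapped <- FALSE
  for (w in seq_len(nWalks)) {
    cells <- doLevyWalk(s, cs, levy)
    if (attr(cells, "trapped")) { trapped <- TRUE; break }
    k <- nrow(cells)
    if (k) {
      while (n + k > cap) {
        cap <- cap * 2L
        walkV <- c(walkV, integer(cap - length(walkV)))
        rowV <- c(rowV, integer(cap - length(rowV)))
        colV <- c(colV, integer(cap - length(colV)))
      }
      walkV[(n + 1L):(n + k)] <- w
      rowV[(n + 1L):(n + k)] <- cells[, 1L]
      colV[(n + 1L):(n + k)] <- cells[, 2L]
      n <- n + k
    }
  }
  steps <- cbind(walk = walkV[seq_len(n)], row = rowV[seq_len(n)],
                 col = colV[seq_len(n)])
  new("Trajectory", steps = steps, cellSizeKm = cs@cost@cellSizeKm,
      originXY = cs@cost@originXY, nRows = nr, nCols = nc,
      seed = as.integer(seed), scenario = scenario, trapped = trapped,
      nWalks = as.integer(nWalks))
}

#' @describeIn runScenario number of steps taken (excluding the start).
#' @param tr a \linkS4class{Trajectory}.
#' @export
nSteps <- function(tr) nrow(tr@steps) - 1L

#' Trajectory step table
#'
#' @param x a \linkS4class{Trajectory}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with walk, step, row, col, x, y (map km of cell
#'   centres); step 0 is the start position.
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  tmpl <- GridRaster(matrix(0, x@nRows, x@nCols), cellSizeKm = x@cellSizeKm,
                     originXY = x@originXY)
  xy <- cellToXY(tmpl, x@steps[, "row"], x@steps[, "col"])
  data.frame(walk = x@steps[, "walk"],
             step = seq_len(nrow(x@steps)) - 1L,
             row = x@steps[, "row"], col = x@steps[, "col"],
             x = xy[, 1], y = xy[, 2])
}

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: ", nrow(object@steps) - 1L, " steps over ",
      max(object@steps[, "walk"]), " walks (of ", object@nWalks,
      " scheduled)\n", sep = "")
  cat("  scenario '", object@scenario, "', seed ", object@seed,
      if (object@trapped) ", agent trapped" else "", "\n", sep = "")
})

#' Write / read a trajectory as CSV
#'
#' The on-disk schema is one row per recorded position: run_id, walk,
#' step, row, col, x, y.
#'
#' @param tr a \linkS4class{Trajectory}.
#' @param path file path.
#' @param runId identifier written to the run_id column.
#' @return \code{writeTrajectoryCSV}: the path, invisibly;
#'   \code{readTrajectoryCSV}: a data.frame.
#' @export
writeTrajectoryCSV <- function(tr, path, runId = tr@scenario) {
  df <- cbind(run_id = runId, as.data.frame(tr))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Rebuild a Trajectory from a step table
#'
#' Inverse of \code{\link{writeTrajectoryCSV}} for analysis of stored runs:
#' the grid geometry comes from \code{template}.
#'
#' @param df data.frame with columns walk, row, col (one run).
#' @param template \linkS4class{GridRaster} of the grid the run used.
#' @param seed,scenario metadata to record.
#' @return A \linkS4class{Trajectory}.
#' @export
trajectoryFromDataFrame <- function(df, template, seed = 0L,
                                    scenario = "restored") {
  d <- dim(template@values)
  new("Trajectory",
      steps = cbind(walk = as.integer(df$walk), row = as.integer(df$row),
                    col = as.integer(df$col)),
      cellSizeKm = template@cellSizeKm, originXY = template@originXY,
      nRows = d[1], nCols = d[2], seed = as.integer(seed),
      scenario = scenario, trapped = FALSE,
      nWalks = max(as.integer(df$walk)))
}
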