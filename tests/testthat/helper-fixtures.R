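## Shared fixture builders.  Everything is generated in code; no files.

flatDem <- function(nr = 5, nc = 5, elev = 100, cellSizeKm = 1) {
  GridRaster(matrix(elev, nr, nc), cellSizeKm = cellSizeKm)
}

wetPrecip <- function(dem, mm = 400) {
  GridRaster(matrix(mm, nrow(rasterValues(dem)), ncol(rasterValues(dem))),
             cellSizeKm = cellSize(dem), originXY = rasterOrigin(dem))
}

## brute-force connected component at or below a water level (oracle for
## floodFillLake): grow the seed set until fixed point, 4-connectivity
floodOracle <- function(demValues, level, seed, nodata = -9999) {
  nr <- nrow(demValues); nc <- ncol(demValues)
  wet <- demValues != nodata & demValues <= level
  mask <- matrix(FALSE, nr, nc)
  if (!wet[seed[1], seed[2]]) return(mask)
  mask[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- mask
    grown[-1, ] <- grown[-1, ] | mask[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | mask[-1, ]
    grown[, -1] <- grown[, -1] | mask[, -nc]
    grown[, -nc] <- grown[, -nc] | mask[, -1]
    grown <- grown & wet
    if (identical(grown, mask)) return(mask)
    mask <- grown
  }
}

## brute-force straight-segment scan (oracle for straightSegments):
## for every start position, extend while the step direction repeats
segmentsOracle <- function(steps, minLen = 5, cellSizeKm = 1) {
  n <- nrow(steps)
  out <- data.frame(start_index = integer(), length_steps = integer())
  if (n < 2) return(out)
  dr <- diff(steps[, "row"]); dc <- diff(steps[, "col"])
  i <- 1L
  while (i <= length(dr)) {
    j <- i
    while (j + 1L <= length(dr) && dr[j + 1L] == dr[i] && dc[j + 1L] == dc[i])
      j <- j + 1L
    if (j - i + 1L >= minLen)
      out <- rbind(out, data.frame(start_index = i, length_steps = j - i + 1L))
    i <- j + 1L
  }
  out
}

## brute-force per-cell test of whether a segment's interior crosses a cell
## (oracle for rasterizeRivers): sample the segment very densely
riverCellsOracle <- function(coords, template) {
  d <- dim(rasterValues(template))
  hit <- matrix(FALSE, d[1], d[2])
  org <- rasterOrigin(template); csz <- cellSize(template)
  for (i in seq_len(nrow(coords) - 1L)) {
    p0 <- coords[i, ]; p1 <- coords[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / csz * 2000)))
    xs <- p0[1] + ts * (p1[1] - p0[1]); ys <- p0[2] + ts * (p1[2] - p0[2])
    cc <- floor((xs - org[1]) / csz) + 1L
    rr <- d[1] - floor((ys - org[2]) / csz)
    ok <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2]
    hit[cbind(rr[ok], cc[ok])] <- TRUE
  }
  hit
}
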