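## build a Trajectory by hand from a path of (row, col) cells
trajFromPath <- function(path, nRows = 100, nCols = 100, walk = NULL) {
  steps <- cbind(walk = c(0L, if (is.null(walk)) seq_len(nrow(path) - 1L)
                          else walk),
                 row = as.integer(path[, 1]), col = as.integer(path[, 2]))
  new("Trajectory", steps = steps, cellSizeKm = 1, originXY = c(0, 0),
      nRows = as.integer(nRows), nCols = as.integer(nCols), seed = 0L,
      scenario = "handmade", trapped = FALSE,
      nWalks = as.integer(nrow(path) - 1L))
}

## an eastward path along one row
eastPath <- function(row, colFrom, colTo) {
  cbind(row, colFrom:colTo)
}

test_that("success classification hits the buffer boundary exactly", {
  ## sites at x=600.5 on the path's row; path cells y at row 50
  tr <- trajFromPath(eastPath(50, 1, 100), 100, 1000)
  y <- 100 - 50 + 0.5  # path y
  sites <- cbind(x = 600.5, y = y)
  ## endpoint x = 99.5 -> distance 501: failure by 1 km
  r1 <- classifySuccess(tr, targetSpec(sites, bufferKm = 500))
  expect_false(r1$success)
  expect_equal(r1$endpoint_distance_to_buffer_km, 1)
  expect_equal(r1$min_distance_to_buffer_km, 1)
  ## buffer 502: success; first step inside is the one at distance <= 502
  r2 <- classifySuccess(tr, targetSpec(sites, bufferKm = 502))
  expect_true(r2$success)
  expect_equal(r2$min_distance_to_buffer_km, 0)
  expect_equal(r2$n_steps_to_target, 98)  # x=98.5, 600.5-98.5=502
  ## start inside the buffer -> success at step 0
  r3 <- classifySuccess(tr, targetSpec(cbind(x = 1, y = y), bufferKm = 500))
  expect_equal(r3$n_steps_to_target, 0)
  ## failed path ending 1200 km away -> 700 km to the buffer edge
  r4 <- classifySuccess(tr, targetSpec(cbind(x = 1299.5, y = y), 500))
  expect_equal(r4$endpoint_distance_to_buffer_km, 700)
})

test_that("success is invariant to truncation after the first in-buffer step", {
  tr <- trajFromPath(eastPath(50, 1, 100), 100, 1000)
  y <- 50.5
  tgt <- targetSpec(cbind(x = 60.5, y = y), bufferKm = 10)
  full <- classifySuccess(tr, tgt)
  cut <- trajFromPath(eastPath(50, 1, 60), 100, 1000)
  expect_equal(classifySuccess(cut, tgt)$n_steps_to_target,
               full$n_steps_to_target)
  expect_true(full$success)
})

test_that("straight segments: worked examples", {
  ## 6 east steps then a turn north-east
  path <- rbind(eastPath(10, 1, 7), c(9, 8))
  seg <- straightSegments(trajFromPath(path))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_index, 1)
  expect_equal(seg$length_steps, 6)
  expect_equal(seg$bearing_deg, 90)       # due east
  expect_equal(seg$net_distance_km, 6)
  ## strictly alternating E / NE steps -> nothing
  zig <- matrix(c(10, 1), 1, 2)
  for (i in 1:10) {
    last <- zig[nrow(zig), ]
    zig <- rbind(zig, if (i %% 2) c(last[1], last[2] + 1)
                      else c(last[1] - 1, last[2] + 1))
  }
  expect_equal(nrow(straightSegments(trajFromPath(zig, 50, 50))), 0)
  ## short trajectory -> empty, not an error
  expect_equal(nrow(straightSegments(trajFromPath(eastPath(5, 1, 3), 10, 10))),
               0)
})

test_that("straight segments match the brute-force oracle and are maximal", {
  set.seed(303)
  for (rep in 1:8) {
    ## random 8-adjacent walk of 2000 steps on a big grid
    n <- 2000
    dr <- sample(-1:1, n, replace = TRUE, prob = c(.2, .35, .45))
    dc <- sample(-1:1, n, replace = TRUE, prob = c(.2, .3, .5))
    keep <- !(dr == 0 & dc == 0)
    path <- cbind(3000 + cumsum(c(0, dr[keep])),
                  3000 + cumsum(c(0, dc[keep])))
    tr <- trajFromPath(path, 6000, 6000)
    seg <- straightSegments(tr)
    oracle <- segmentsOracle(tr@steps)
    expect_equal(seg$start_index, oracle$start_index)
    expect_equal(seg$length_steps, oracle$length_steps)
    ## maximality: the step before and after each run differs in direction
    d <- cbind(diff(tr@steps[, "row"]), diff(tr@steps[, "col"]))
    for (k in seq_len(nrow(seg))) {
      i0 <- seg$start_index[k]; i1 <- i0 + seg$length_steps[k] - 1L
      if (i0 > 1) expect_false(all(d[i0 - 1, ] == d[i0, ]))
      if (i1 < nrow(d)) expect_false(all(d[i1 + 1, ] == d[i1, ]))
    }
  }
})

test_that("occupancy frequency counts revisits and conserves totals", {
  tmpl <- GridRaster(matrix(0, 20, 20))
  ## one run visiting cell (5,5) three times
  path <- rbind(c(5, 5), c(5, 6), c(5, 5), c(6, 6), c(5, 5))
  tr <- trajFromPath(path, 20, 20)
  f1 <- occupancyFrequency(list(tr), tmpl)
  expect_equal(rasterValues(f1)[5, 5], 3)
  ## two identical runs -> same frequencies as one
  f2 <- occupancyFrequency(list(tr, tr), tmpl)
  expect_identical(rasterValues(f2), rasterValues(f1))
  ## conservation: sum(freq) * n_runs = total recorded positions
  set.seed(9)
  trs <- lapply(1:3, function(s)
    runScenario(makeUniformPlain(20), nWalks = 100, seed = s))
  f <- occupancyFrequency(trs, tmpl)
  expect_equal(sum(rasterValues(f)) * 3,
               sum(vapply(trs, function(t) nrow(t@steps), 0)))
})

test_that("redundancy zones threshold on visited-cell statistics", {
  tmpl <- GridRaster(matrix(0, 5, 5))
  ## constant nonzero frequency: sd 0, all visited cells within 1 sd
  f <- GridRaster(matrix(c(rep(0, 20), rep(2, 5)), 5, 5))
  m <- redundancyZones(f)
  expect_equal(sum(m), 5)
  expect_false(any(redundancyZones(f, "above_1sd")))
  ## an outlier at mean + 2 sd is excluded / included by rule
  vals <- c(10, 10, 10, 10, 12, 12, 12, 12, 25)
  fv <- matrix(0, 5, 5)
  fv[cbind(rep(1:3, 3), rep(1:3, each = 3))] <- vals
  f2 <- GridRaster(fv)
  mu <- mean(vals); sd1 <- sd(vals)
  hi <- fv > mu + sd1 & fv > 0
  expect_identical(redundancyZones(f2, "above_1sd"), hi)
  expect_identical(redundancyZones(f2, "within_1sd"),
                   fv > 0 & abs(fv - mu) <= sd1)
  ## all-zero map -> empty mask
  expect_false(any(redundancyZones(GridRaster(matrix(0, 5, 5)))))
})

test_that("arrival-time conversion is exact and linear", {
  expect_equal(arrivalYears(0, 500), 0)
  expect_equal(arrivalYears(923439, 579.0), 1594.886, tolerance = 5e-7)
  expect_equal(arrivalYears(1103612, 579.0), 1906.066, tolerance = 5e-7)
  expect_equal(arrivalYears(1105725, 696.5), 1587.545, tolerance = 5e-7)
  ## linear in steps, inverse in rate
  set.seed(4)
  n <- sample(1e6, 20); a <- runif(20, 300, 900)
  expect_equal(arrivalYears(2 * n, a), 2 * arrivalYears(n, a))
  expect_equal(arrivalYears(n, 2 * a), arrivalYears(n, a) / 2)
  ## cell size scales the distance walked
  expect_equal(arrivalYears(1000, 500, cellSizeKm = 2),
               2 * arrivalYears(1000, 500))
  expect_error(arrivalYears(10, 0), "positive")
  expect_error(arrivalYears(-1, 500), "nonnegative")
})

test_that("routeMetrics bundles classification, segments and timing", {
  tr <- trajFromPath(eastPath(50, 1, 100), 100, 1000)
  tgt <- targetSpec(cbind(x = 90.5, y = 50.5), bufferKm = 10)
  m <- routeMetrics(tr, tgt, annualKm = 579)
  expect_true(m$success)
  expect_equal(m$n_straight_segments, 1)
  expect_equal(m$est_years, arrivalYears(m$n_steps_to_target, 579))
  seg <- attr(m, "segments")
  expect_equal(seg$length_steps, 99)
})
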