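#' Define an experiment plan
#'
#' A plan is a table of scenarios, each run \code{nReplicates} times with
#' replicate seeds \code{baseSeed + 0 .. nReplicates - 1} (deterministic
#' and recorded in the manifest).  The study design this mirrors — a set of
#' climate-stage cost surfaces crossed with two start regions, five
#' replicates each — is expressed as one row per scenario.
#'
#' @param scenarios data.frame with columns \code{id} (unique character),
#'   \code{costPath}, \code{barrierPath} (ASCII-grid raster paths),
#'   \code{startRegionPath} (GeoJSON polygon path, or NA for the whole
#'   grid), and optionally \code{annualKm}.
#' @param nReplicates replicates per scenario (>= 1, default 5).
#' @param baseSeed first replicate seed.
#' @param nWalks Lévy walks per run.
#' @param levy \linkS4class{LevyParams}.
#' @return A list of class \code{experimentPlan}.
#' @export
experimentPlan <- function(scenarios, nReplicates = 5, baseSeed = 1,
                           nWalks = 400000, levy = LevyParams()) {
  if (anyDuplicated(scenarios$id)) stop("scenario ids must be unique")
  if (nReplicates < 1) stop("'nReplicates' must be >= 1")
  structure(list(scenarios = scenarios, nReplicates = nReplicates,
                 baseSeed = as.integer(baseSeed), nWalks = as.integer(nWalks),
                 levy = levy),
            class = "experimentPlan")
}

#' Run an experiment plan
#'
#' Executes every scenario x replicate with \code{\link{runScenario}},
#' analyses each trajectory against the target sites, and writes per-run
#' trajectory CSVs, a per-run metrics CSV, an aggregate summary and a JSON
#' manifest (seeds, file md5 hashes, settings) sufficient to reproduce
#' every output.  Missing inputs fail before any simulation; a trapped run
#' is recorded in its metrics row, not fatal.
#'
#' @param plan an \code{\link{experimentPlan}}.
#' @param sites x/y matrix of target sites (map km).
#' @param outDir output directory (created if needed).
#' @param bufferKm success-buffer radius (km).
#' @return Invisibly, the per-run metrics data.frame.
#' @export
runExperiment <- function(plan, sites, outDir, bufferKm = 500) {
  sc <- plan$scenarios
  paths <- c(sc$costPath, sc$barrierPath,
             sc$startRegionPath[!is.na(sc$startRegionPath)])
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tgt <- targetSpec(sites, bufferKm)

  rows <- list()
  manifest <- list(baseSeed = plan$baseSeed, nWalks = plan$nWalks,
                   bufferKm = bufferKm,
                   levy = list(mu = plan$levy@mu, lMin = plan$levy@lMin,
                               lMax = plan$levy@lMax,
                               memoryHorizon = plan$levy@memoryHorizon,
                               newTerritoryMinUnvisited =
                                 plan$levy@newTerritoryMinUnvisited,
                               doublingFactor = plan$levy@doublingFactor),
                   inputs = as.list(tools::md5sum(unique(paths))),
                   runs = list())
  for (i in seq_len(nrow(sc))) {
    cs <- CostSurface(readRaster(sc$costPath[i]),
                      readRaster(sc$barrierPath[i]))
    region <- if (is.na(sc$startRegionPath[i])) NULL
              else readPolygonGeoJSON(sc$startRegionPath[i])
    annualKm <- if ("annualKm" %in% names(sc)) sc$annualKm[i] else NA
    for (rep in seq_len(plan$nReplicates)) {
      seed <- plan$baseSeed + rep - 1L
      runId <- paste0(sc$id[i], "_rep", rep)
      tr <- runScenario(cs, startRegion = region, nWalks = plan$nWalks,
                        seed = seed, levy = plan$levy, scenario = runId)
      trajPath <- file.path(outDir, paste0("traj_", runId, ".csv"))
      writeTrajectoryCSV(tr, trajPath, runId = runId)
      m <- routeMetrics(tr, tgt, annualKm = annualKm)
      rows[[runId]] <- cbind(run_id = runId, scenario = sc$id[i],
                             replicate = rep, seed = seed,
                             n_steps = nSteps(tr), trapped = tr@trapped, m)
      manifest$runs[[runId]] <- list(scenario = sc$id[i], replicate = rep,
                                     seed = seed,
                                     trajectory = basename(trajPath))
    }
  }
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  summary <- data.frame(
    n_runs = nrow(metrics),
    n_success = sum(metrics$success),
    median_endpoint_distance_km =
      stats::median(metrics$endpoint_distance_to_buffer_km),
    mean_steps = mean(metrics$n_steps)
  )
  utils::write.csv(summary, file.path(outDir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}
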