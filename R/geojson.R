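## Minimal GeoJSON support for the vector inputs the simulator needs:
## polygons (start regions), points (target sites) and river polylines
## carrying a discharge_m3s property.  Coordinates are planar km, matching
## the raster convention; no CRS handling is attempted.

#' River segment
#'
#' A polyline in map coordinates with a long-term mean discharge, the input
#' to hydraulic-geometry width estimation and river rasterization.
#'
#' @param coords numeric matrix with >= 2 rows and columns x, y (km).
#' @param dischargeM3s nonnegative long-term mean discharge (m^3/s).
#' @return An object of class \code{riverSegment} (a list with elements
#'   \code{coords} and \code{dischargeM3s}).
#' @export
riverSegment <- function(coords, dischargeM3s) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L || ncol(coords) != 2L)
    stop("a river polyline needs at least 2 vertices with x and y")
  if (!is.finite(dischargeM3s) || dischargeM3s < 0)
    stop("'dischargeM3s' must be a nonnegative number")
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, dischargeM3s = as.numeric(dischargeM3s)),
            class = "riverSegment")
}

#' @export
print.riverSegment <- function(x, ...) {
  cat("riverSegment:", nrow(x$coords), "vertices, discharge",
      x$dischargeM3s, "m^3/s\n")
  invisible(x)
}

#' Read and write the package's GeoJSON inputs
#'
#' \code{readSitesGeoJSON} reads Point features into an x/y matrix;
#' \code{readPolygonGeoJSON} reads the first Polygon feature's outer ring;
#' \code{readRiversGeoJSON} reads LineString features with a
#' \code{discharge_m3s} property into \code{\link{riverSegment}} objects.
#' The writers emit the matching FeatureCollections.
#'
#' @param path file path to a GeoJSON FeatureCollection.
#' @return See individual descriptions.
#' @name geojson-io
NULL

geojsonFeatures <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection: ", path)
  g$features
}

#' @rdname geojson-io
#' @export
readSitesGeoJSON <- function(path) {
  feats <- geojsonFeatures(path)
  pts <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Point")) return(NULL)
    as.numeric(unlist(f$geometry$coordinates))
  })
  pts <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
  if (is.null(pts)) stop("no Point features in ", path)
  colnames(pts) <- c("x", "y")
  pts
}

#' @rdname geojson-io
#' @export
readPolygonGeoJSON <- function(path) {
  feats <- geojsonFeatures(path)
  for (f in feats) {
    if (identical(f$geometry$type, "Polygon")) {
      ring <- f$geometry$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
      colnames(m) <- c("x", "y")
      return(m)
    }
  }
  stop("no Polygon feature in ", path)
}

#' @rdname geojson-io
#' @export
readRiversGeoJSON <- function(path) {
  feats <- geojsonFeatures(path)
  out <- list()
  for (f in feats) {
    if (!identical(f$geometry$type, "LineString")) next
    m <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(p) as.numeric(unlist(p))))
    q <- f$properties$discharge_m3s
    if (is.null(q)) stop("LineString feature lacks a discharge_m3s property")
    out[[length(out) + 1L]] <- riverSegment(m, as.numeric(q))
  }
  out
}

#' @rdname geojson-io
#' @param sites x/y matrix of site points.
#' @export
writeSitesGeoJSON <- function(sites, path) {
  sites <- as.matrix(sites)
  feats <- lapply(seq_len(nrow(sites)), function(i) list(
    type = "Feature", properties = list(id = i),
    geometry = list(type = "Point", coordinates = as.numeric(sites[i, ]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geojson-io
#' @param poly x/y matrix of polygon ring vertices (closed or open).
#' @export
writePolygonGeoJSON <- function(poly, path) {
  poly <- as.matrix(poly)
  if (any(poly[1, ] != poly[nrow(poly), ]))
    poly <- rbind(poly, poly[1, ])
  ring <- lapply(seq_len(nrow(poly)), function(i) as.numeric(poly[i, ]))
  feats <- list(list(type = "Feature", properties = list(),
                     geometry = list(type = "Polygon",
                                     coordinates = list(ring))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geojson-io
#' @param rivers list of \code{\link{riverSegment}}.
#' @export
writeRiversGeoJSON <- function(rivers, path) {
  feats <- lapply(rivers, function(rv) list(
    type = "Feature",
    properties = list(discharge_m3s = rv$dischargeM3s),
    geometry = list(
      type = "LineString",
      coordinates = lapply(seq_len(nrow(rv$coords)),
                           function(i) as.numeric(rv$coords[i, ])))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Which points fall inside a polygon
#'
#' Thin wrapper around \code{mgcv::in.out}; boundary behaviour follows that
#' routine.
#'
#' @param poly x/y matrix of ring vertices.
#' @param pts x/y matrix of query points.
#' @return Logical vector, one element per query point.
#' @export
pointsInPolygon <- function(poly, pts) {
  poly <- as.matrix(poly)
  if (any(poly[1, ] != poly[nrow(poly), ]))
    poly <- rbind(poly, poly[1, ])
  mgcv::in.out(poly, as.matrix(pts))
}
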