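#' Zone ids used throughout the package
#'
#' The six release/recruitment zone labels in their canonical order.
#' @format Character vector of length 6.
#' @export
ZONE_IDS <- c("RC_A", "RC_B", "RC_C", "RC_D", "RC_E", "RC_F")

#' Depth strata for the trap-haul abundance model
#'
#' Bathymetric strata with edges 0, 50, 100, 150, 200 m. Binning is half-open
#' `[lower, upper)` so the strata partition `[0, 200)` without overlap.
#' @keywords internal
DEPTH_EDGES <- c(0, 50, 100, 150, 200)

#' Labelled zone polygons around an island
#'
#' A set of labelled polygons (`RC_A` ... `RC_F`) that serve both as larval
#' release areas and as recruitment targets, plus an optional island (land)
#' polygon. Polygons are closed rings of `(lon, lat)` vertices; ids must be
#' unique and zones must not overlap except along shared boundaries.
#'
#' @param zones A named list; each element a list/data.frame with numeric
#'   `lon` and `lat` vertex vectors (closed automatically if the first and
#'   last vertices differ). Names are the zone ids.
#' @param island Optional land polygon in the same format.
#' @return An object of class `zone_set`.
#' @seealso [synthetic_zoneset()] for the built-in annular-sector geometry.
#' @export
zone_set <- function(zones, island = NULL) {
  if (is.null(names(zones)) || anyDuplicated(names(zones)))
    stop("zones must be a named list with unique ids")
  close_ring <- function(p) {
    lon <- as.numeric(p$lon); lat <- as.numeric(p$lat)
    if (length(lon) != length(lat) || length(lon) < 3L)
      stop("each polygon needs matching lon/lat vectors of length >= 3")
    if (lon[1] != lon[length(lon)] || lat[1] != lat[length(lat)]) {
      lon <- c(lon, lon[1]); lat <- c(lat, lat[1])
    }
    list(lon = lon, lat = lat)
  }
  zs <- lapply(zones, close_ring)
  structure(
    list(zones = zs, ids = names(zs),
         island = if (is.null(island)) NULL else close_ring(island)),
    class = "zone_set"
  )
}

#' @export
print.zone_set <- function(x, ...) {
  cat("<zone_set> with", length(x$zones), "zones:",
      paste(x$ids, collapse = ", "), "\n")
  if (!is.null(x$island)) cat("  island polygon:",
                              length(x$island$lon) - 1L, "vertices\n")
  invisible(x)
}

#' Locate points within zones
#'
#' Returns the id of the zone containing each point, or `NA` for points
#' outside every zone. Points on a shared boundary resolve deterministically
#' to the zone with the lowest id (zones are probed in id order and boundary
#' hits count as containment).
#'
#' @param zones A [zone_set].
#' @param lon,lat Numeric vectors of point coordinates (degrees).
#' @return Character vector of zone ids (`NA` = outside all zones).
#' @export
locate_zone <- function(zones, lon, lat) {
  stopifnot(inherits(zones, "zone_set"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(as.numeric(lon), n)
  lat <- rep_len(as.numeric(lat), n)
  out <- rep(NA_character_, n)
  todo <- seq_len(n)
  for (id in sort(zones$ids)) {
    if (length(todo) == 0L) break
    poly <- zones$zones[[id]]
    hit <- sp::point.in.polygon(lon[todo], lat[todo], poly$lon, poly$lat) > 0
    out[todo[hit]] <- id
    todo <- todo[!hit]
  }
  out
}

#' Assign depths to bathymetric strata
#'
#' Half-open binning `[lower, upper)` over the edges 0, 50, 100, 150, 200 m.
#' Depths of 200 m or more fall outside every stratum and return `NA`.
#'
#' @param depth Non-negative depths in metres.
#' @param edges Strictly increasing bin edges (m); default the four strata
#'   used by the abundance model.
#' @return Factor of stratum labels (`"0-50"`, `"50-100"`, ...), `NA` beyond
#'   the last edge.
#' @export
depth_stratum <- function(depth, edges = DEPTH_EDGES) {
  depth <- as.numeric(depth)
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  labs <- paste0(edges[-length(edges)], "-", edges[-1])
  i <- findInterval(depth, edges, rightmost.closed = FALSE)
  i[i == length(edges)] <- NA  # at or beyond the last edge
  i[i == 0] <- NA
  factor(labs[i], levels = labs)
}

#' Synthetic annular-sector zone geometry
#'
#' Builds six equal-angle annular sectors around a circular island, labelled
#' `RC_A` ... `RC_F` clockwise from north, standing in for unpublished real
#' zone polygons. The ring spans `island_radius` to
#' `island_radius + ring_width` kilometres from the island centre; sectors
#' share radial edges, so together with the lowest-id boundary tie-break
#' [locate_zone()] partitions the ring.
#'
#' @param center `c(lon, lat)` of the island centre (degrees).
#' @param island_radius Island radius in km (also the inner ring radius).
#' @param ring_width Ring width in km.
#' @param n_arc Vertices per arc (controls how finely circles are
#'   polygonized).
#' @return A [zone_set] whose island polygon is the circular island.
#' @examples
#' zs <- synthetic_zoneset(center = c(-78.85, -33.65))
#' locate_zone(zs, -78.85, -33.55)  # due north of the island -> "RC_A"
#' @export
synthetic_zoneset <- function(center = c(-78.85, -33.65), island_radius = 5,
                              ring_width = 14, n_arc = 36) {
  stopifnot(island_radius > 0, ring_width > 0)
  km_lat <- 1 / 111.195
  km_lon <- km_lat / cos(center[2] * pi / 180)
  ring <- function(r, bearings) {
    th <- bearings * pi / 180  # clockwise from north
    list(lon = center[1] + r * sin(th) * km_lon,
         lat = center[2] + r * cos(th) * km_lat)
  }
  r_in <- island_radius
  r_out <- island_radius + ring_width
  zones <- list()
  for (s in seq_len(6)) {
    b0 <- (s - 1) * 60
    bearings <- seq(b0, b0 + 60, length.out = n_arc)
    inner <- ring(r_in, rev(bearings))
    outer <- ring(r_out, bearings)
    zones[[ZONE_IDS[s]]] <- list(lon = c(outer$lon, inner$lon),
                                 lat = c(outer$lat, inner$lat))
  }
  full <- ring(r_in, seq(0, 360, length.out = 6 * n_arc))
  zone_set(zones, island = full)
}

#' Read zone polygons from GeoJSON
#'
#' Expects a FeatureCollection with one Polygon feature per zone and a
#' property `id` naming it; an optional feature with `id = "island"` becomes
#' the land polygon.
#'
#' @param path Path to a GeoJSON file.
#' @return A [zone_set].
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  zones <- list()
  island <- NULL
  for (ft in gj$features) {
    id <- ft$properties$id
    if (is.null(id)) stop("every feature needs an 'id' property")
    ring <- ft$geometry$coordinates[[1]]
    lon <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
    lat <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
    poly <- list(lon = lon, lat = lat)
    if (identical(id, "island")) island <- poly else zones[[id]] <- poly
  }
  zone_set(zones, island = island)
}

#' Write zone polygons to GeoJSON
#'
#' @param zones A [zone_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  stopifnot(inherits(zones, "zone_set"))
  feat <- function(id, poly) {
    list(type = "Feature", properties = list(id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(Map(c, poly$lon, poly$lat))))
  }
  features <- Map(feat, zones$ids, zones$zones)
  names(features) <- NULL
  if (!is.null(zones$island))
    features <- c(features, list(feat("island", zones$island)))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Internal: area of the zone-union bounding box and a point-in-union test,
# used by release sampling.
zone_bbox <- function(zones) {
  lon <- unlist(lapply(zones$zones, `[[`, "lon"))
  lat <- unlist(lapply(zones$zones, `[[`, "lat"))
  c(lon_min = min(lon), lon_max = max(lon),
    lat_min = min(lat), lat_max = max(lat))
}
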