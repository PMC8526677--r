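#' Generate a stylised study domain with a coastline barrier
#'
#' Builds a rectangular ocean domain bounded on the west by a piecewise-linear
#' synthetic coastline, split into six named fishing zones. The geometry is
#' topological rather than cartographic: what matters downstream is that a
#' physical barrier (land) interrupts spatial correlation and that effort is
#' organised into zones, not the exact shape of any real shoreline.
#'
#' Coastal zones (`SAB`, `MAB`, `NEC`) occupy the western strip in three
#' latitude bands; offshore zones (`SAR`, `TUS`, `NED`) mirror them to the
#' east. Zones tile the boundary rectangle without overlap; the land barrier
#' lies inside the coastal zones and generated fishing positions always avoid
#' it.
#'
#' @param seed integer seed controlling the coastline jitter.
#' @return an object of class `domain_spec`: a list with `boundary` (polygon,
#'   degrees), `barriers` (list of polygons), `zones` (named list of
#'   polygons), `zone_groups` (named character, coastal/offshore), and
#'   `planar_scale` (km-per-degree factors about the mid-latitude).
#' @export
gen_domain <- function(seed = 1L) {
  lon_w <- -80; lon_e <- -64; lat_s <- 30; lat_n <- 42
  boundary <- cbind(lon = c(lon_w, lon_e, lon_e, lon_w),
                    lat = c(lat_s, lat_s, lat_n, lat_n))
  coast <- with_seed(seed, {
    lat <- seq(lat_s, lat_n, by = 0.5)
    lon <- -78.4 + 0.7 * sin(2 * pi * (lat - lat_s) / 16) +
      runif(length(lat), -0.35, 0.35)
    cbind(lon = pmin(pmax(lon, -79.6), -77.0), lat = lat)
  })
  # land polygon: coastline closed back along the western edge
  barrier <- rbind(coast, c(lon_w, lat_n), c(lon_w, lat_s))
  colnames(barrier) <- c("lon", "lat")
  lon_split <- -71
  band <- function(x0, x1, y0, y1) cbind(lon = c(x0, x1, x1, x0),
                                         lat = c(y0, y0, y1, y1))
  zones <- list(
    SAB = band(lon_w, lon_split, 30, 34),
    MAB = band(lon_w, lon_split, 34, 38),
    NEC = band(lon_w, lon_split, 38, 42),
    SAR = band(lon_split, lon_e, 30, 34),
    TUS = band(lon_split, lon_e, 34, 38),
    NED = band(lon_split, lon_e, 38, 42))
  mid_lat <- (lat_s + lat_n) / 2
  structure(list(
    boundary = boundary,
    barriers = list(coast = barrier),
    coastline = coast,
    zones = zones,
    zone_groups = c(SAB = "coastal", MAB = "coastal", NEC = "coastal",
                    SAR = "offshore", TUS = "offshore", NED = "offshore"),
    planar_scale = c(km_per_deg_lon = 111.32 * cos(mid_lat * pi / 180),
                     km_per_deg_lat = 111.32),
    origin = c(lon = lon_w, lat = lat_s),
    seed = as.integer(seed)),
    class = "domain_spec")
}

#' Project geographic degrees to planar kilometres
#'
#' Equirectangular projection about the domain mid-latitude. All meshing,
#' range parameters and distance rules operate in this planar metric.
#'
#' @param domain a `domain_spec`.
#' @param lon,lat coordinates in degrees.
#' @return two-column matrix `x`, `y` in km relative to the domain origin.
#' @export
to_planar <- function(domain, lon, lat) {
  cbind(x = (lon - domain$origin["lon"]) * domain$planar_scale["km_per_deg_lon"],
        y = (lat - domain$origin["lat"]) * domain$planar_scale["km_per_deg_lat"])
}

#' @rdname to_planar
#' @param x,y planar coordinates in km.
#' @export
from_planar <- function(domain, x, y) {
  cbind(lon = x / domain$planar_scale["km_per_deg_lon"] + domain$origin["lon"],
        lat = y / domain$planar_scale["km_per_deg_lat"] + domain$origin["lat"])
}

# polygon in planar km for a degree-space polygon
poly_planar <- function(domain, poly) {
  to_planar(domain, poly[, 1], poly[, 2])
}

#' Locate positions in fishing zones
#'
#' @param domain a `domain_spec`.
#' @param lon,lat positions in degrees.
#' @return character vector of zone codes (`NA` for positions outside every
#'   zone).
#' @export
zone_of <- function(domain, lon, lat) {
  out <- rep(NA_character_, length(lon))
  for (z in names(domain$zones)) {
    hit <- is.na(out) & point_in_poly(domain$zones[[z]], lon, lat)
    out[hit] <- z
  }
  out
}

# TRUE for positions on land (inside any barrier polygon)
in_barrier <- function(domain, lon, lat) {
  hit <- rep(FALSE, length(lon))
  for (b in domain$barriers) hit <- hit | point_in_poly(b, lon, lat)
  hit
}

#' Write a domain to GeoJSON
#'
#' Serialises boundary, barriers and zones as a GeoJSON FeatureCollection of
#' polygons (degrees).
#'
#' @param domain a `domain_spec`.
#' @param path output file path.
#' @export
write_domain_geojson <- function(domain, path) {
  ring <- function(poly) {
    poly <- as.matrix(poly)
    if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
    lapply(seq_len(nrow(poly)), function(i) unname(poly[i, ]))
  }
  feat <- function(name, kind, poly) {
    list(type = "Feature",
         properties = list(name = name, kind = kind),
         geometry = list(type = "Polygon", coordinates = list(ring(poly))))
  }
  features <- c(list(feat("boundary", "boundary", domain$boundary)),
                lapply(names(domain$barriers), function(b)
                  feat(b, "barrier", domain$barriers[[b]])),
                lapply(names(domain$zones), function(z)
                  feat(z, "zone", domain$zones[[z]])))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
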