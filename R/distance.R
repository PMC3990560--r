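#' Great-circle distance between coordinates
#'
#' Haversine great-circle distance on a sphere of radius `radius_km`
#' (default 6371 km, the mean Earth radius). Vectorized over coordinate
#' pairs; symmetric; 0 for identical points.
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees; latitudes in \[-90, 90\],
#'   longitudes in \[-180, 180\].
#' @param radius_km Sphere radius in km.
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 180)  # antipodal: pi * 6371 ~ 20015 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  check_number(lat1, "lat1", -90, 90); check_number(lat2, "lat2", -90, 90)
  check_number(lon1, "lon1", -180, 180); check_number(lon2, "lon2", -180, 180)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Combined geographic/elevation "total distance" between sites
#'
#' Ecological similarity between forest sites decays with both horizontal
#' separation and elevation difference (a 1-km climb changes climate about
#' as much as a several-hundred-km poleward journey). The two are combined
#' into a single proximity measure by equating 1 m of altitude with 1 km of
#' horizontal distance: `total = sqrt(geo_km^2 + elev_m^2)`. The mixed
#' units mean `total` is a unitless "distance unit", not a physical
#' distance; 1000 such units is the default neighborhood cutoff in
#' [intercompare()].
#'
#' @param lat1,lon1,elev1 Focal coordinates (decimal degrees) and elevation
#'   (m).
#' @param lat2,lon2,elev2 Candidate coordinates and elevation.
#' @param radius_km Earth radius passed to [haversine_km()].
#' @param missing_elevation `"error"` (default) or `"zero"`: how to treat
#'   missing elevations (`"zero"` sets the elevation term to 0 with a
#'   warning).
#' @return A tibble with columns `geo_km`, `elev_m`, `total`, one row per
#'   input pair.
#' @examples
#' total_distance(0, 0, 0, 0, 3 / 111.19, 4)$total  # ~ 5 (3-4-5 triangle)
#' @export
total_distance <- function(lat1, lon1, elev1, lat2, lon2, elev2,
                           radius_km = 6371,
                           missing_elevation = c("error", "zero")) {
  missing_elevation <- match.arg(missing_elevation)
  elev_diff <- abs(elev2 - elev1)
  if (any(is.na(elev_diff))) {
    if (missing_elevation == "error") {
      abort("missing elevation; set missing_elevation = \"zero\" to ignore",
            class = "standcompare_validation_error")
    }
    warn("missing elevation treated as zero elevation difference")
    elev_diff[is.na(elev_diff)] <- 0
  }
  geo <- haversine_km(lat1, lon1, lat2, lon2, radius_km)
  tibble::tibble(geo_km = geo, elev_m = elev_diff,
                 total = sqrt(geo^2 + elev_diff^2))
}

#' Pairwise total distances between site tables
#'
#' @param sites_a A site table (`site_id`, `latitude`, `longitude`,
#'   `elevation_m`).
#' @param sites_b Optional second site table; defaults to `sites_a`
#'   (all pairs within one table).
#' @inheritParams total_distance
#' @return A long tibble: `site_a`, `site_b`, `geo_km`, `elev_m`, `total`.
#' @export
site_distances <- function(sites_a, sites_b = NULL, radius_km = 6371,
                           missing_elevation = c("error", "zero")) {
  sites_b <- sites_b %||% sites_a
  grid <- tidyr::expand_grid(a = seq_len(nrow(sites_a)),
                             b = seq_len(nrow(sites_b)))
  d <- total_distance(sites_a$latitude[grid$a], sites_a$longitude[grid$a],
                      sites_a$elevation_m[grid$a],
                      sites_b$latitude[grid$b], sites_b$longitude[grid$b],
                      sites_b$elevation_m[grid$b],
                      radius_km, missing_elevation)
  dplyr::bind_cols(tibble::tibble(site_a = sites_a$site_id[grid$a],
                                  site_b = sites_b$site_id[grid$b]), d)
}
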