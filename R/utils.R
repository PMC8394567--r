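#' @importFrom stats dnorm sd
#' @importFrom utils head tail
#' @importFrom data.table := as.data.table setorder .N
NULL

.datatable.aware <- TRUE

# Mean Earth radius (IUGG), km. Sub-metre bias at deer-migration scales.
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points, km
#'
#' Haversine formula on a sphere of radius 6371.0088 km. Vectorised over
#' all four coordinate arguments (recycled as usual).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in kilometres.
#' @export
#' @examples
#' haversine_km(40, -111, 40.5, -111) # ~55.6 km due north
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  phi1 <- lat1 * rad
  phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Planar km offsets -> degrees around a base latitude. Adequate for the
# tens-of-km extents simulated here; not valid near the poles/antimeridian.
km_to_lat_deg <- function(north_km) north_km / 111.32
km_to_lon_deg <- function(east_km, at_lat) east_km / (111.32 * cos(at_lat * pi / 180))

# Migratory-year helpers: year `label` runs label-07-01 .. (label+1)-06-30.
migratory_year_start <- function(year_label) as.Date(sprintf("%d-07-01", year_label))
migratory_year_end   <- function(year_label) as.Date(sprintf("%d-06-30", year_label + 1))

# Which migratory year a calendar date belongs to (its July-1 start year).
migratory_year_of <- function(date) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  ifelse(m >= 7L, y, y - 1L)
}

# Days since July 1 of the trajectory's migratory year (July 1 -> 0).
days_since_july1 <- function(date, year_label) {
  as.integer(date - migratory_year_start(year_label))
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the classification pipeline with the
#' published defaults.
#'
#' @param min_segment_days Minimum segment length h in observed days
#'   (default 14): the minimum stay for a location to count as a range;
#'   shorter pauses are stopovers by construction.
#' @param buffer_days Days of data kept before/after the migratory year so
#'   that year-edge movements segment correctly (default 14).
#' @param max_breaks Cap on the number of breakpoints considered; the
#'   effective cap is `min(max_breaks, floor(n/h) - 1)` (default 20).
#' @param overlap_threshold Segments whose NSD density overlap exceeds this
#'   fraction are the same range (default 0.05).
#' @param gradual_nsd_km2 NSD level a gradual mover must sustain, km^2
#'   (default 25, i.e. displacement > 5 km; cf. a typical mule-deer home
#'   range of ~25 km^2).
#' @param gradual_run_days Length of the sustained run, consecutive observed
#'   days (default 14).
#' @param rss_floor Floor on the residual sum of squares inside the BIC to
#'   avoid log(0) on exactly constant series; `NULL` means `n * 1e-12`.
#' @return A list of class `migr_config`.
#' @export
migr_config <- function(min_segment_days = 14L,
                        buffer_days = 14L,
                        max_breaks = 20L,
                        overlap_threshold = 0.05,
                        gradual_nsd_km2 = 25,
                        gradual_run_days = 14L,
                        rss_floor = NULL) {
  stopifnot(min_segment_days >= 2, buffer_days >= 0, max_breaks >= 0,
            overlap_threshold >= 0, overlap_threshold < 1,
            gradual_nsd_km2 > 0, gradual_run_days >= 1)
  structure(list(
    min_segment_days = as.integer(min_segment_days),
    buffer_days = as.integer(buffer_days),
    max_breaks = as.integer(max_breaks),
    overlap_threshold = overlap_threshold,
    gradual_nsd_km2 = gradual_nsd_km2,
    gradual_run_days = as.integer(gradual_run_days),
    rss_floor = rss_floor
  ), class = "migr_config")
}

#' The seven migratory-strategy categories
#' @export
STRATEGY_LEVELS <- c("dual_range_migrant", "multi_range_migrant", "commuter",
                     "poly_migrant", "disperser", "resident", "gradual_mover")
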