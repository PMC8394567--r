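# Timing, duration and distance descriptors for classified trajectories.
# Departure/return dates are breakdates: the first day of the segment that
# follows a range shift.

#' Trip lengths
#'
#' Per-trip length is return date minus departure date in days; the
#' combined length is their sum. Incomplete trips are excluded and counted.
#'
#' @param trips Trips from [extract_trips()].
#' @return List with `per_trip` (integer days), `combined` and
#'   `n_incomplete`.
#' @export
trip_lengths <- function(trips) {
  complete <- Filter(function(t) isTRUE(t$complete), trips)
  per <- vapply(complete, function(t)
    as.integer(t$inbound_date - t$outbound_date), integer(1))
  list(per_trip = per, combined = sum(per),
       n_incomplete = length(trips) - length(complete))
}

#' Distances between ranges
#'
#' Each range's centroid is the day-weighted mean of the daily locations
#' over all its segments (each observed day contributes one location);
#' distances are great-circle km from the summer-range centroid. Centroids
#' are preferred over sqrt(NSD) plateau levels because they are robust to
#' within-range drift.
#'
#' @param labeling A `range_labeling` with segment dates.
#' @param daily Daily-location table for the same animal covering the
#'   segment dates.
#' @return List with `per_range` (data.frame: range_id, distance_km over
#'   non-summer ranges), `mean_km`, `max_km` (NA when only one range).
#' @export
range_distances <- function(labeling, daily) {
  s <- labeling$segments
  stopifnot("start_date" %in% names(s))
  cent <- lapply(sort(unique(s$range_id)), function(rid) {
    rows <- s[s$range_id == rid, , drop = FALSE]
    in_range <- rep(FALSE, nrow(daily))
    for (i in seq_len(nrow(rows)))
      in_range <- in_range | (daily$date >= rows$start_date[i] &
                              daily$date <= rows$end_date[i])
    d <- daily[in_range, , drop = FALSE]
    c(rid = rid, lat = mean(d$lat), lon = mean(d$lon))
  })
  cent <- as.data.frame(do.call(rbind, cent))
  summer <- cent[cent$rid == 1, , drop = FALSE]
  others <- cent[cent$rid != 1, , drop = FALSE]
  if (nrow(others) == 0L) {
    return(list(per_range = data.frame(range_id = integer(), distance_km = numeric()),
                mean_km = NA_real_, max_km = NA_real_))
  }
  dist <- haversine_km(summer$lat, summer$lon, others$lat, others$lon)
  list(per_range = data.frame(range_id = as.integer(others$rid), distance_km = dist),
       mean_km = mean(dist), max_km = max(dist))
}

#' Typical migratory timing
#'
#' For single-trip trajectories: TRUE when the outbound movement falls in
#' September--December and the inbound movement in April--June, the
#' windows in which a typical temperate-montane migrant is expected to
#' leave for and return from its winter range.
#'
#' @param trip A single complete trip.
#' @return Logical scalar.
#' @export
typical_timing <- function(trip) {
  stopifnot(isTRUE(trip$complete))
  out_m <- as.integer(format(trip$outbound_date, "%m"))
  in_m <- as.integer(format(trip$inbound_date, "%m"))
  out_m %in% 9:12 && in_m %in% 4:6
}

#' Mean daily displacement over the core year
#'
#' @param series An `nsd_series`.
#' @return Mean of sqrt(NSD) over core days, km.
#' @export
mean_displacement <- function(series) {
  core <- series[series$in_core, , drop = FALSE]
  if (nrow(core) == 0L) return(NA_real_)
  mean(core$displacement_km)
}

#' All metrics for one classified trajectory
#'
#' @param labeling A `range_labeling`.
#' @param trips Trips from [extract_trips()].
#' @param series The `nsd_series`.
#' @param daily Daily locations for the animal.
#' @return One-row data.frame of the metric columns used in the
#'   per-trajectory output table.
#' @export
trajectory_metrics <- function(labeling, trips, series, daily) {
  tl <- trip_lengths(trips)
  complete <- Filter(function(t) isTRUE(t$complete), trips)
  rd <- range_distances(labeling, daily)
  data.frame(
    departure_date = if (length(complete)) complete[[1]]$outbound_date else as.Date(NA),
    return_date = if (length(complete))
      complete[[length(complete)]]$inbound_date else as.Date(NA),
    trip_length_days = if (length(tl$per_trip) == 1L) tl$per_trip else NA_integer_,
    combined_trip_length_days = tl$combined,
    n_trip_ranges = if (length(complete))
      length(unique(unlist(lapply(complete, function(t) t$visited)))) else 0L,
    mean_range_distance_km = rd$mean_km,
    max_range_distance_km = rd$max_km,
    typical_timing = if (length(complete) == 1L) typical_timing(complete[[1]]) else NA,
    mean_displacement_km = mean_displacement(series)
  )
}
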