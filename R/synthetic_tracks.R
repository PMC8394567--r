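# Synthetic GPS-fix generator with known ground truth, emulating annual
# large-herbivore trajectories: residency in discrete ranges 10--35 km
# apart, range shifts lasting days, stays of weeks to months, and
# within-range scatter far smaller than between-range separation. All
# seven strategy archetypes have templates whose timing and distances echo
# published cohort means (departure ~Nov 9, return ~Apr 26, dual-range
# separation ~25 km, trip length ~168 days).

#' Template trajectory specification for a strategy
#'
#' Returns a parameterised `trajectory_spec` realising one strategy:
#' \itemize{
#' \item resident: one range all year;
#' \item gradual_mover: one nominal range whose centre drifts linearly
#'   12 km over the year (no discrete shift);
#' \item dual_range_migrant: ranges A, B 25 km apart, away Nov 9--Apr 26;
#' \item multi_range_migrant: A -> B (20 km) -> C (35 km) -> A;
#' \item commuter: two round trips A -> B -> A, B 12 km away;
#' \item poly_migrant: A -> B (15 km) -> A -> C (18 km) -> A;
#' \item disperser: A -> B -> C with no return.
#' }
#'
#' @param category One of [STRATEGY_LEVELS].
#' @param seed Integer seed stored in the spec; simulation is fully
#'   reproducible from it.
#' @param year_label Migratory-year start year (default 2016).
#' @param within_range_sd_km Isotropic per-fix position noise, km
#'   (default 0.5 — a realistic within-home-range daily scatter).
#' @param fixes_per_day Fixes per day, evenly spaced (default 4).
#' @param transit_days Duration of each range shift, days (default 5).
#' @param base_location Named lat/lon of range A (default Utah highlands).
#' @param animal_id Identifier; default derived from category and seed.
#' @return A `trajectory_spec` list.
#' @export
template_spec <- function(category, seed = 1L, year_label = 2016L,
                          within_range_sd_km = 0.5, fixes_per_day = 4L,
                          transit_days = 5L,
                          base_location = c(lat = 40.5, lon = -111.5),
                          animal_id = NULL) {
  category <- match.arg(category, STRATEGY_LEVELS)
  n_days <- as.integer(migratory_year_end(year_label) -
                       migratory_year_start(year_label)) + 1L
  tpl <- switch(category,
    resident            = list(ranges = 1L, departures = integer(0),
                               offsets = list(c(0, 0)), drift = 0),
    gradual_mover       = list(ranges = 1L, departures = integer(0),
                               offsets = list(c(0, 0)), drift = 12),
    dual_range_migrant  = list(ranges = c(1L, 2L, 1L), departures = c(132L, 300L),
                               offsets = list(c(0, 0), c(25, 25) / sqrt(2)), drift = 0),
    multi_range_migrant = list(ranges = c(1L, 2L, 3L, 1L),
                               departures = c(121L, 201L, 291L),
                               offsets = list(c(0, 0), c(20, 0), c(30, 18)), drift = 0),
    commuter            = list(ranges = c(1L, 2L, 1L, 2L, 1L),
                               departures = c(61L, 141L, 211L, 291L),
                               offsets = list(c(0, 0), c(12, 0)), drift = 0),
    poly_migrant        = list(ranges = c(1L, 2L, 1L, 3L, 1L),
                               departures = c(61L, 141L, 211L, 291L),
                               offsets = list(c(0, 0), c(15, 0), c(0, 18)), drift = 0),
    disperser           = list(ranges = c(1L, 2L, 3L),
                               departures = c(121L, 221L),
                               offsets = list(c(0, 0), c(15, 0), c(15, 13)), drift = 0)
  )
  itin <- build_itinerary(tpl$ranges, tpl$departures, transit_days, n_days)
  structure(list(
    category = category,
    base_location = base_location,
    range_offsets = tpl$offsets,
    itinerary = itin,
    drift_km = tpl$drift,
    transit_days = as.integer(transit_days),
    within_range_sd_km = within_range_sd_km,
    fixes_per_day = as.integer(fixes_per_day),
    stopovers = NULL,
    missing_day_rate = 0,
    ar1_coef = 0,
    year_label = as.integer(year_label),
    n_days = n_days,
    seed = as.integer(seed),
    animal_id = if (is.null(animal_id)) sprintf("%s_s%03d", category, seed) else animal_id
  ), class = "trajectory_spec")
}

# Stays from a range sequence and the first day of each transit.
build_itinerary <- function(ranges, departures, transit_days, n_days) {
  stopifnot(length(departures) == length(ranges) - 1L)
  start <- 1L
  rows <- list()
  for (k in seq_along(ranges)) {
    end <- if (k <= length(departures)) departures[k] - 1L else n_days
    stopifnot(end - start + 1L >= 14L) # every stay must be a detectable range
    rows[[k]] <- data.frame(range = ranges[k], start_day = start, end_day = end)
    start <- end + transit_days + 1L
  }
  do.call(rbind, rows)
}

#' Insert a stopover into a trajectory spec
#'
#' Interrupts the `which`-th migration with a pause of `duration` days
#' (default 10, below the minimum segment length) at fraction `frac` of
#' the straight line between the two ranges, with the spec's usual
#' `transit_days` of travel on each side — i.e. the stopover enters the
#' itinerary as a short stay, the same grammar as a range but too brief to
#' qualify as one. Used to probe whether such pauses are detected as
#' ranges; note that the changepoint model may pad a sub-minimum pause
#' with adjacent travel/plateau days into a full-length segment, so
#' immunity is not guaranteed (see the methods vignette).
#'
#' @param spec A `trajectory_spec` with at least one transit.
#' @param which Index of the transit to interrupt (default 1, the first
#'   outbound movement).
#' @param duration Stopover length in days (default 10).
#' @param frac Position along the transit line (default 0.5).
#' @return The modified spec; stays after the stopover shift later by
#'   `duration + transit_days`.
#' @export
with_stopover <- function(spec, which = 1L, duration = 10L, frac = 0.5) {
  it <- spec$itinerary
  stopifnot(which >= 1L, which <= nrow(it) - 1L)
  from <- spec$range_offsets[[it$range[which]]]
  to <- spec$range_offsets[[it$range[which + 1L]]]
  pos <- from + frac * (to - from)
  td <- spec$transit_days
  t0 <- it$end_day[which] + td + 1L
  stop_df <- data.frame(east_km = pos[1], north_km = pos[2],
                        start_day = t0, end_day = t0 + duration - 1L)
  # later stays move back: the gap is now transit + pause + transit
  shift <- duration + td
  later <- seq(which + 1L, nrow(it))
  it$start_day[later] <- it$start_day[later] + shift
  it$end_day[later] <- it$end_day[later] + shift
  it$end_day[nrow(it)] <- min(it$end_day[nrow(it)], spec$n_days)
  spec$itinerary <- it
  spec$stopovers <- rbind(spec$stopovers, stop_df)
  spec
}

# Deterministic centre (east, north km) for day t of the core year;
# t outside [1, n_days] clamps to the nearest core day.
center_for_day <- function(spec, t) {
  tc <- min(max(t, 1L), spec$n_days)
  it <- spec$itinerary
  off <- NULL
  row <- which(tc >= it$start_day & tc <= it$end_day)
  if (length(row) == 1L) {
    off <- spec$range_offsets[[it$range[row]]]
  } else {
    # in transit between stay k and k+1: linear interpolation
    k <- max(which(it$end_day < tc))
    from <- spec$range_offsets[[it$range[k]]]
    to <- spec$range_offsets[[it$range[k + 1L]]]
    f <- (tc - it$end_day[k]) / (it$start_day[k + 1L] - it$end_day[k])
    off <- from + f * (to - from)
  }
  if (!is.null(spec$stopovers)) {
    hit <- which(tc >= spec$stopovers$start_day & tc <= spec$stopovers$end_day)
    if (length(hit))
      off <- c(spec$stopovers$east_km[hit[1]], spec$stopovers$north_km[hit[1]])
  }
  if (spec$drift_km > 0) {
    f <- (tc - 1) / (spec$n_days - 1)
    off <- off + c(spec$drift_km * f, 0)
  }
  off
}

#' Simulate GPS fixes from a trajectory spec
#'
#' Each day's position is the deterministic centre plus isotropic Gaussian
#' noise (sd `within_range_sd_km`); the day's fixes scatter independently
#' around that position with the same sd, evenly spaced in time. During
#' transit the centre interpolates linearly between range centres. km
#' offsets become degrees via 1 deg lat = 111.32 km and 1 deg lon =
#' 111.32 cos(lat) km. Simulation covers the core year plus
#' `sim_buffer_days` on each side (centre clamped to the year's ends) so
#' the analysis buffers are populated. Fully reproducible from the spec
#' seed.
#'
#' @param spec A `trajectory_spec`.
#' @param sim_buffer_days Extra days simulated on each side (default 21).
#' @return List with `fixes` (fix table) and `truth` (list: animal_id,
#'   true_category, true_shift_dates — first day of each transit whose
#'   endpoints differ —, true_range_of_day data.frame with NA during
#'   transit, spec).
#' @export
simulate_fixes <- function(spec, sim_buffer_days = 21L) {
  stopifnot(inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  ystart <- migratory_year_start(spec$year_label)
  days <- seq(1L - sim_buffer_days, spec$n_days + sim_buffer_days)
  centers <- t(vapply(days, function(t) center_for_day(spec, t), numeric(2)))
  if (spec$ar1_coef > 0) {
    # AR(1) daily wander of the centre, stationary sd = within_range_sd_km
    phi <- spec$ar1_coef
    innov_sd <- spec$within_range_sd_km * sqrt(1 - phi^2)
    e <- matrix(0, nrow = length(days), ncol = 2)
    e[1, ] <- stats::rnorm(2, 0, spec$within_range_sd_km)
    for (i in 2:length(days))
      e[i, ] <- phi * e[i - 1, ] + stats::rnorm(2, 0, innov_sd)
    centers <- centers + e
  }
  keep <- rep(TRUE, length(days))
  if (spec$missing_day_rate > 0)
    keep <- stats::runif(length(days)) >= spec$missing_day_rate

  # the day's position wanders around the centre, and each fix scatters
  # independently around the day's position, both with the same sd
  day_e <- centers[, 1] + stats::rnorm(length(days), 0, spec$within_range_sd_km)
  day_n <- centers[, 2] + stats::rnorm(length(days), 0, spec$within_range_sd_km)
  f <- spec$fixes_per_day
  hours <- seq(0, 24 - 24 / f, by = 24 / f)
  n_total <- sum(keep) * f
  east <- rep(day_e[keep], each = f) + stats::rnorm(n_total, 0, spec$within_range_sd_km)
  north <- rep(day_n[keep], each = f) + stats::rnorm(n_total, 0, spec$within_range_sd_km)
  dates <- rep(ystart + (days[keep] - 1L), each = f)
  ts <- as.POSIXct(dates, tz = "UTC") + rep(hours, sum(keep)) * 3600

  lat0 <- spec$base_location[["lat"]]
  fixes <- data.frame(
    animal_id = spec$animal_id,
    timestamp = ts,
    lat = lat0 + km_to_lat_deg(north),
    lon = spec$base_location[["lon"]] + km_to_lon_deg(east, lat0)
  )

  it <- spec$itinerary
  shift_days <- integer(0)
  if (nrow(it) >= 2L) {
    moved <- it$range[-1] != it$range[-nrow(it)]
    shift_days <- (it$end_day[-nrow(it)] + 1L)[moved]
  }
  range_of_day <- rep(NA_integer_, spec$n_days)
  for (i in seq_len(nrow(it)))
    range_of_day[it$start_day[i]:it$end_day[i]] <- it$range[i]

  truth <- list(
    animal_id = spec$animal_id,
    true_category = spec$category,
    true_shift_dates = ystart + shift_days - 1L,
    true_range_of_day = data.frame(date = ystart + seq_len(spec$n_days) - 1L,
                                   range = range_of_day),
    spec = spec
  )
  list(fixes = fixes, truth = truth)
}

#' Simulate a labelled cohort
#'
#' One single-year animal per replicate per category, with unique ids and
#' per-animal ground truth.
#'
#' @param n_per_category Either a single count applied to all seven
#'   categories or a named vector of counts.
#' @param base_seed Seed base; animal i of the cohort uses `base_seed * 1000 + i`.
#' @param ... Passed to [template_spec()] (e.g. `within_range_sd_km`).
#' @return List with `fixes` (one fix table), `truth` (data.frame:
#'   animal_id, year_label, true_category) and `details` (per-animal truth
#'   lists keyed by animal_id).
#' @export
simulate_cohort <- function(n_per_category = 5L, base_seed = 1L, ...) {
  counts <- if (length(n_per_category) == 1L && is.null(names(n_per_category)))
    stats::setNames(rep(as.integer(n_per_category), 7), STRATEGY_LEVELS)
  else {
    cc <- stats::setNames(rep(0L, 7), STRATEGY_LEVELS)
    cc[names(n_per_category)] <- as.integer(n_per_category)
    cc
  }
  fixes <- list()
  truth_rows <- list()
  details <- list()
  i <- 0L
  for (cat_name in STRATEGY_LEVELS) {
    for (rep_k in seq_len(counts[[cat_name]])) {
      i <- i + 1L
      id <- sprintf("%s_%02d", cat_name, rep_k)
      spec <- template_spec(cat_name, seed = base_seed * 1000L + i,
                            animal_id = id, ...)
      sim <- simulate_fixes(spec)
      fixes[[i]] <- sim$fixes
      truth_rows[[i]] <- data.frame(animal_id = id, year_label = spec$year_label,
                                    true_category = cat_name)
      details[[id]] <- sim$truth
    }
  }
  list(
    fixes = if (length(fixes)) do.call(rbind, fixes) else
      data.frame(animal_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                 lat = numeric(), lon = numeric()),
    truth = if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(animal_id = character(), year_label = integer(),
                 true_category = character()),
    details = details
  )
}

#' Simulate one animal over several consecutive migratory years
#'
#' Years are chained: each year's summer range sits where the previous
#' year ended (so a disperser's new range becomes next year's summer
#' range), keeping the multi-year track spatially continuous. Only the
#' first year gets a leading simulation buffer and only the last a
#' trailing one; in between, each year's analysis buffer is served by its
#' neighbour's fixes.
#'
#' @param categories Character vector: the true strategy of each
#'   consecutive year.
#' @param seed Integer seed.
#' @param animal_id Identifier.
#' @param first_year_label Migratory-year start of the first year.
#' @param ... Passed to [template_spec()].
#' @return List with `fixes` and `truth` (data.frame: animal_id,
#'   year_label, true_category).
#' @export
simulate_animal_years <- function(categories, seed = 1L, animal_id = "multi01",
                                  first_year_label = 2015L, ...) {
  base <- c(lat = 40.5, lon = -111.5)
  fixes <- list()
  truth <- list()
  for (j in seq_along(categories)) {
    yl <- first_year_label + j - 1L
    spec <- template_spec(categories[j], seed = seed + 131L * j,
                          year_label = yl, base_location = base,
                          animal_id = animal_id, ...)
    sim <- simulate_fixes(spec, sim_buffer_days = 21L)
    # keep simulated buffers only on the outer ends; inner years abut
    dts <- as.Date(sim$fixes$timestamp, tz = "UTC")
    keep <- rep(TRUE, nrow(sim$fixes))
    if (j > 1L) keep <- keep & dts >= migratory_year_start(yl)
    if (j < length(categories)) keep <- keep & dts <= migratory_year_end(yl)
    sim$fixes <- sim$fixes[keep, , drop = FALSE]
    fixes[[j]] <- sim$fixes
    truth[[j]] <- data.frame(animal_id = animal_id, year_label = yl,
                             true_category = categories[j])
    # chain: next year's base = centre occupied on the last core day
    end_off <- center_for_day(spec, spec$n_days)
    base <- c(lat = base[["lat"]] + km_to_lat_deg(end_off[2]),
              lon = base[["lon"]] + km_to_lon_deg(end_off[1], base[["lat"]]))
  }
  list(fixes = do.call(rbind, fixes), truth = do.call(rbind, truth))
}
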