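# Shared fixture builders and independent oracles.

# Daily-location table from parallel vectors.
make_daily <- function(dates, lat, lon, animal_id = "a1", n_fixes = 1L) {
  data.frame(animal_id = animal_id, date = as.Date(dates),
             lat = lat, lon = lon, n_fixes = n_fixes)
}

# Full-coverage daily table for one migratory year (plus optional buffers),
# at a fixed point unless lat/lon functions of day index are given.
make_year_daily <- function(year_label = 2016L, animal_id = "a1",
                            lat = 40, lon = -111,
                            pre_days = 0L, post_days = 0L) {
  d0 <- migrclass:::migratory_year_start(year_label)
  d1 <- migrclass:::migratory_year_end(year_label)
  dates <- seq(d0 - pre_days, d1 + post_days, by = "day")
  make_daily(dates, rep_len(lat, length(dates)), rep_len(lon, length(dates)),
             animal_id)
}

# Bare nsd_series from a vector of NSD values (km^2), all in core.
make_series <- function(nsd, year_label = 2016L, animal_id = "a1",
                        start = migrclass:::migratory_year_start(year_label),
                        in_core = TRUE) {
  nsd <- pmax(nsd, 0)
  dates <- seq(as.Date(start), by = "day", length.out = length(nsd))
  structure(
    data.frame(date = dates, lat = NA_real_, lon = NA_real_,
               displacement_km = sqrt(nsd), nsd_km2 = nsd,
               in_core = rep_len(in_core, length(nsd))),
    animal_id = animal_id, year_label = year_label,
    reference = c(lat = NA_real_, lon = NA_real_),
    class = c("nsd_series", "data.frame"))
}

# Hand-built range labeling from a vector of per-segment range ids and
# segment start dates; used to exercise the classifier directly.
make_labeling <- function(range_ids, start = as.Date("2016-07-01"),
                          seg_len = 30L) {
  k <- length(range_ids)
  starts <- start + (seq_len(k) - 1L) * seg_len
  segments <- data.frame(
    start = as.integer((seq_len(k) - 1L) * seg_len + 1L),
    end = as.integer(seq_len(k) * seg_len),
    range_id = range_ids,
    n_days = seg_len,
    mean_nsd = NA_real_,
    start_date = starts,
    end_date = starts + seg_len - 1L
  )
  if (k >= 2) {
    shifts <- data.frame(date = segments$start_date[-1],
                         index = segments$start[-1],
                         from_range = range_ids[-k], to_range = range_ids[-1])
    shifts <- shifts[shifts$from_range != shifts$to_range, , drop = FALSE]
  } else {
    shifts <- data.frame(date = as.Date(character()), index = integer(),
                         from_range = integer(), to_range = integer())
  }
  structure(list(segments = segments, n_ranges = length(unique(range_ids)),
                 shifts = shifts, summer_range_id = 1L,
                 animal_id = "a1", year_label = 2016L),
            class = "range_labeling")
}

# --- independent oracles --------------------------------------------------

# Direct RSS of a constant fit (no prefix sums).
direct_rss <- function(x) sum((x - mean(x))^2)

# Exhaustive minimum-RSS search over all feasible placements of exactly m
# breakpoints with minimum segment length h. Lexicographically earliest
# breakpoint vector on ties. Vectorised over candidate placements.
brute_force_breaks <- function(values, m, h) {
  n <- length(values)
  stopifnot((m + 1) * h <= n)
  if (m == 0) return(list(breakpoints = integer(0), rss = direct_rss(values)))
  s1 <- c(0, cumsum(values))
  s2 <- c(0, cumsum(values^2))
  cost <- function(i, j) (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / (j - i + 1)
  cand <- utils::combn(seq(h, n - h), m)
  if (m > 1) # enforce the minimum gap h between successive breakpoints
    cand <- cand[, apply(cand, 2, function(b) all(diff(b) >= h)), drop = FALSE]
  bounds <- rbind(0L, cand, n) # segment ends are cand; starts are prev + 1
  rss <- rep(0, ncol(cand))
  for (k in seq_len(m + 1)) {
    rss <- rss + cost(bounds[k, ] + 1L, bounds[k + 1L, ])
  }
  best <- which.min(rss) # combn columns are lexicographic -> earliest on ties
  list(breakpoints = as.integer(cand[, best]), rss = rss[best])
}

# Haversine oracle, written independently of the package (law of cosines
# variant on the same sphere radius).
oracle_distance_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  d <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  6371.0088 * acos(pmin(pmax(d, -1), 1))
}

# Write a fix CSV to a temp file.
write_fix_csv <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
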