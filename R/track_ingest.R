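# Ingest raw GPS fixes, reduce to daily locations, cut into buffered
# migratory years (July 1 -- June 30) and compute daily net squared
# displacement (NSD) series.

#' Read a GPS fix table from delimited text
#'
#' Reads CSV (or TSV, autodetected from the `.tsv`/`.txt` extension) collar
#' data into a standardised fix table. Rows with unparseable timestamps or
#' out-of-range coordinates are skipped with a warning and counted in the
#' `n_rejected` attribute; a missing mapped column is a configuration error.
#'
#' @param path Path to the delimited file. Must have a header row.
#' @param dialect Named character vector mapping the standard names
#'   `animal_id`, `timestamp`, `lat`, `lon` to the file's column names.
#' @return A `data.frame` with columns `animal_id` (character), `timestamp`
#'   (POSIXct, UTC), `lat`, `lon`, sorted by (animal_id, timestamp), with
#'   attribute `n_rejected`.
#' @export
read_gps_table <- function(path,
                           dialect = c(animal_id = "animal_id",
                                       timestamp = "timestamp",
                                       lat = "lat", lon = "lon")) {
  if (!file.exists(path)) stop("file not found: ", path)
  needed <- c("animal_id", "timestamp", "lat", "lon")
  if (!all(needed %in% names(dialect)))
    stop("dialect must map all of: ", paste(needed, collapse = ", "))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", strip.white = TRUE)
  missing_cols <- setdiff(unname(dialect[needed]), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- data.frame(animal_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                      lat = numeric(), lon = numeric())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  fx <- data.frame(
    animal_id = raw[[dialect[["animal_id"]]]],
    timestamp = parse_utc_timestamp(raw[[dialect[["timestamp"]]]]),
    lat = suppressWarnings(as.numeric(raw[[dialect[["lat"]]]])),
    lon = suppressWarnings(as.numeric(raw[[dialect[["lon"]]]])),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(fx$timestamp) & is.finite(fx$lat) & is.finite(fx$lon) &
    fx$lat >= -90 & fx$lat <= 90 & fx$lon >= -180 & fx$lon <= 180 &
    nzchar(fx$animal_id)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L)
    warning(n_rejected, " row(s) rejected while reading ", path,
            " (bad timestamp or coordinates)", call. = FALSE)
  fx <- fx[ok, , drop = FALSE]
  fx <- fx[order(fx$animal_id, fx$timestamp), , drop = FALSE]
  rownames(fx) <- NULL
  attr(fx, "n_rejected") <- n_rejected
  fx
}

# ISO-8601-ish timestamps to POSIXct UTC; several common layouts accepted.
# Parsed per element (a single corrupt row must not poison the column).
parse_utc_timestamp <- function(x) {
  x <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y-%m-%d", "%Y/%m/%d %H:%M:%OS")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

#' Average fixes to one location per animal per day
#'
#' Reduces a fix table to one record per (animal, UTC calendar day): the
#' arithmetic mean of that day's latitudes and longitudes, with the number
#' of contributing fixes. Averaging in degrees is accurate at the
#' tens-of-km extents of ungulate tracks (do not use across the
#' antimeridian).
#'
#' @param fixes A fix table as returned by [read_gps_table()].
#' @return A `data.frame` with columns `animal_id`, `date` (Date, UTC),
#'   `lat`, `lon`, `n_fixes`, sorted by (animal_id, date).
#' @export
average_daily <- function(fixes) {
  if (nrow(fixes) == 0L) {
    return(data.frame(animal_id = character(), date = as.Date(character()),
                      lat = numeric(), lon = numeric(), n_fixes = integer()))
  }
  dt <- data.table::as.data.table(fixes)
  dt[, date := as.Date(timestamp, tz = "UTC")]
  out <- dt[, .(lat = mean(lat), lon = mean(lon), n_fixes = .N),
            by = .(animal_id, date)]
  data.table::setorder(out, animal_id, date)
  as.data.frame(out)
}

#' Split daily locations into buffered migratory years
#'
#' Cuts an animal's daily-location table into annual tracks running July 1
#' to June 30, each carrying up to `buffer_days` of extra locations on both
#' sides. A year is complete when July 1 has a location, at least 95% of
#' core days are present, and no gap exceeds 7 consecutive days; incomplete
#' years are still returned (flagged) so callers can report them.
#'
#' @param daily Daily-location table from [average_daily()] (one or more
#'   animals).
#' @param buffer_days Buffer length on each side, days (default 14).
#' @return A list of `annual_track` objects, each a list with elements
#'   `animal_id`, `year_label`, `core`, `buffer_pre`, `buffer_post`,
#'   `complete`.
#' @export
split_migratory_years <- function(daily, buffer_days = 14L) {
  if (nrow(daily) == 0L) return(list())
  out <- list()
  for (id in unique(daily$animal_id)) {
    d <- daily[daily$animal_id == id, , drop = FALSE]
    d <- d[order(d$date), , drop = FALSE]
    if (anyDuplicated(d$date)) stop("duplicate dates for animal ", id)
    labels <- sort(unique(migratory_year_of(d$date)))
    for (yl in labels) {
      ystart <- migratory_year_start(yl)
      yend <- migratory_year_end(yl)
      core <- d[d$date >= ystart & d$date <= yend, , drop = FALSE]
      if (nrow(core) == 0L) next
      pre <- d[d$date >= ystart - buffer_days & d$date < ystart, , drop = FALSE]
      post <- d[d$date > yend & d$date <= yend + buffer_days, , drop = FALSE]
      n_core_days <- as.integer(yend - ystart) + 1L
      has_july1 <- ystart %in% core$date
      coverage <- nrow(core) / n_core_days
      max_gap <- if (nrow(core) >= 2L) max(as.integer(diff(core$date))) - 1L else
        n_core_days - nrow(core)
      # gaps at the ends of the core window count too
      edge_gap <- max(as.integer(core$date[1L] - ystart),
                      as.integer(yend - core$date[nrow(core)]))
      max_gap <- max(max_gap, edge_gap)
      complete <- has_july1 && coverage >= 0.95 && max_gap <= 7L
      out[[length(out) + 1L]] <- structure(list(
        animal_id = id, year_label = yl,
        core = core, buffer_pre = pre, buffer_post = post,
        complete = complete
      ), class = "annual_track")
    }
  }
  out
}

#' Compute the daily net squared displacement series for one annual track
#'
#' The reference point is the July 1 daily location (the start of the
#' migratory year). Each day's displacement is the great-circle distance
#' (km) from the reference; NSD is its square (km^2). Buffer days are
#' included in the series and flagged `in_core = FALSE`.
#'
#' @param track An `annual_track` with `complete = TRUE`.
#' @return An `nsd_series`: a `data.frame` with columns `date`, `lat`,
#'   `lon`, `displacement_km`, `nsd_km2`, `in_core`, and attributes
#'   `animal_id`, `year_label`, `reference` (named lat/lon vector).
#' @export
compute_nsd <- function(track) {
  stopifnot(inherits(track, "annual_track"))
  if (!isTRUE(track$complete))
    stop("compute_nsd requires a complete annual track (animal ",
         track$animal_id, ", year ", track$year_label, ")")
  ystart <- migratory_year_start(track$year_label)
  ref_row <- track$core[track$core$date == ystart, , drop = FALSE]
  if (nrow(ref_row) != 1L) stop("July 1 location missing; track should be incomplete")
  all_days <- rbind(track$buffer_pre, track$core, track$buffer_post)
  disp <- haversine_km(ref_row$lat, ref_row$lon, all_days$lat, all_days$lon)
  disp[all_days$date == ystart] <- 0
  ser <- data.frame(
    date = all_days$date, lat = all_days$lat, lon = all_days$lon,
    displacement_km = disp, nsd_km2 = disp^2,
    in_core = all_days$date >= ystart & all_days$date <= migratory_year_end(track$year_label)
  )
  structure(ser,
            animal_id = track$animal_id,
            year_label = track$year_label,
            reference = c(lat = ref_row$lat, lon = ref_row$lon),
            class = c("nsd_series", "data.frame"))
}

#' @export
print.annual_track <- function(x, ...) {
  cat(sprintf("<annual_track> %s, migratory year %d-%d, %d core days, complete=%s\n",
              x$animal_id, x$year_label, x$year_label + 1L, nrow(x$core),
              x$complete))
  invisible(x)
}

#' @export
print.nsd_series <- function(x, ...) {
  cat(sprintf("<nsd_series> %s year %d: %d days (%d core), max displacement %.2f km\n",
              attr(x, "animal_id"), attr(x, "year_label"), nrow(x),
              sum(x$in_core), sqrt(max(x$nsd_km2))))
  invisible(x)
}
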