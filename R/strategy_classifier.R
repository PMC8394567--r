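# The seven-category decision tree. Round trips away from the summer range
# (the range occupied on July 1, always range 1) drive the first split:
#   one round trip  -> dual-range migrant (one other range visited)
#                      or multi-range migrant (several)
#   several trips   -> commuter (always the same range) or poly-migrant
#   no round trip   -> disperser (left, never returned), else
#                      gradual mover (sustained displacement beyond
#                      home-range scale) or resident.

#' Extract round trips from a range labeling
#'
#' Scans the range shifts in time order. A shift leaving range 1 opens a
#' trip (an outbound movement); a shift back to range 1 closes it (the
#' inbound movement); ranges visited while away are recorded in order.
#' Shifts between two non-summer ranges neither open nor close trips. A
#' trailing open trip is returned with `complete = FALSE`.
#'
#' @param labeling A `range_labeling`.
#' @return List of trips; each has `outbound_date`, `inbound_date` (NA if
#'   incomplete), `visited` (distinct non-summer range ids, in order),
#'   `complete`.
#' @export
extract_trips <- function(labeling) {
  shifts <- labeling$shifts
  trips <- list()
  open <- NULL
  for (i in seq_len(nrow(shifts))) {
    from <- shifts$from_range[i]
    to <- shifts$to_range[i]
    if (is.null(open)) {
      if (from == 1L && to != 1L) {
        open <- list(outbound_date = shifts$date[i], inbound_date = as.Date(NA),
                     visited = to, complete = FALSE)
      }
      # a shift not touching range 1 before any trip cannot occur when the
      # first segment is the summer range; ignore defensively
    } else {
      if (to == 1L) {
        open$inbound_date <- shifts$date[i]
        open$complete <- TRUE
        trips[[length(trips) + 1L]] <- open
        open <- NULL
      } else {
        open$visited <- unique(c(open$visited, to))
      }
    }
  }
  if (!is.null(open)) trips[[length(trips) + 1L]] <- open
  trips
}

#' Sustained-displacement test for gradual movers
#'
#' TRUE when the core-year series contains a run of at least
#' `gradual_run_days` consecutive observed calendar days with NSD above
#' `gradual_nsd_km2` (default 25 km^2, i.e. displacement beyond the ~5 km
#' radius of a typical home range). A missing calendar day breaks a run.
#'
#' @param series An `nsd_series`.
#' @param config A [migr_config()].
#' @return Logical scalar.
#' @export
gradual_mover_test <- function(series, config = migr_config()) {
  core <- series[series$in_core, , drop = FALSE]
  if (nrow(core) == 0L) return(FALSE)
  above <- core$nsd_km2 > config$gradual_nsd_km2
  gap_ok <- c(TRUE, diff(core$date) == 1)
  run <- 0L
  best <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i] && (run == 0L || gap_ok[i])) run + 1L else as.integer(above[i])
    if (run > best) best <- run
  }
  best >= config$gradual_run_days
}

#' Classify one annual trajectory into a migration strategy
#'
#' Applies the decision tree to the trips extracted from a range labeling.
#' Every input maps to exactly one of the seven categories. A trajectory
#' with completed round trips plus a trailing open outbound is classified
#' from its completed trips and flagged `incomplete_final_trip`.
#'
#' @param labeling A `range_labeling`.
#' @param trips Trips from [extract_trips()]; recomputed when `NULL`.
#' @param series The core `nsd_series` (used only for the gradual-mover
#'   test when no shifts exist).
#' @param config A [migr_config()].
#' @return A `strategy_label`: list with `category`, `n_round_trips`,
#'   `n_ranges_total`, `flags` (character vector, possibly empty).
#' @export
classify_trajectory <- function(labeling, trips = NULL, series = NULL,
                                config = migr_config()) {
  if (is.null(trips)) trips <- extract_trips(labeling)
  complete <- Filter(function(t) isTRUE(t$complete), trips)
  n_trips <- length(complete)
  flags <- character(0)
  if (length(trips) > n_trips && n_trips >= 1L) flags <- "incomplete_final_trip"

  category <- if (n_trips == 1L) {
    if (length(complete[[1]]$visited) == 1L) "dual_range_migrant" else "multi_range_migrant"
  } else if (n_trips >= 2L) {
    sets <- lapply(complete, function(t) sort(t$visited))
    same_single <- length(sets[[1]]) == 1L &&
      all(vapply(sets, function(s) identical(s, sets[[1]]), logical(1)))
    if (same_single) "commuter" else "poly_migrant"
  } else if (nrow(labeling$shifts) >= 1L) {
    "disperser"
  } else if (!is.null(series) && gradual_mover_test(series, config)) {
    "gradual_mover"
  } else {
    "resident"
  }

  structure(list(
    category = category,
    n_round_trips = n_trips,
    n_ranges_total = labeling$n_ranges,
    flags = flags
  ), class = "strategy_label")
}

#' @export
print.strategy_label <- function(x, ...) {
  cat(sprintf("<strategy_label> %s (%d round trip(s), %d range(s)%s)\n",
              x$category, x$n_round_trips, x$n_ranges_total,
              if (length(x$flags)) paste0("; flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}
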