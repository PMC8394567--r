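# Piecewise-constant segmentation of an NSD series: exact minimum-RSS
# breakpoint placement by dynamic programming under a minimum segment
# length h, with the number of breakpoints selected by minimum BIC.
#
# Indexing is over observed days: missing days are skipped, h counts
# observed days, and no values are imputed.

#' Constant-fit cost lookup for a series
#'
#' Precomputes prefix sums so the residual sum of squares of a constant fit
#' on `values[i..j]` is available in O(1) for any window of length >= h.
#'
#' @param values Numeric vector, length n >= h.
#' @param h Minimum window length (observed days).
#' @return A list with n, h and `cost(i, j)` (vectorised over `j`).
#' @export
nsd_cost_table <- function(values, h) {
  n <- length(values)
  if (n < h) stop("series length ", n, " shorter than minimum segment length ", h)
  s1 <- c(0, cumsum(values))
  s2 <- c(0, cumsum(values^2))
  cost <- function(i, j) {
    len <- j - i + 1
    rss <- (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / len
    pmax(rss, 0) # guard tiny negative round-off
  }
  list(n = n, h = h, cost = cost)
}

# Suffix dynamic program: G[k, i] = minimum RSS of covering values[i..n]
# with exactly k segments, each >= h long. Forward reconstruction from G
# picks the smallest feasible split at every tie, which yields the
# lexicographically earliest breakpoint vector.
dp_suffix_table <- function(ct, k_max) {
  n <- ct$n; h <- ct$h; cost <- ct$cost
  G <- matrix(NA_real_, nrow = k_max, ncol = n)
  for (i in 1:(n - h + 1)) G[1, i] <- cost(i, n)
  if (k_max >= 2) {
    for (k in 2:k_max) {
      i_hi <- n - k * h + 1
      if (i_hi < 1) break
      for (i in 1:i_hi) {
        j <- (i + h - 1):(n - (k - 1) * h)
        G[k, i] <- min(cost(i, j) + G[k - 1, j + 1])
      }
    }
  }
  G
}

dp_reconstruct <- function(ct, G, m) {
  n <- ct$n; h <- ct$h; cost <- ct$cost
  if (m == 0) return(integer(0))
  breaks <- integer(m)
  i <- 1L
  for (k in (m + 1):2) {
    j <- (i + h - 1):(n - (k - 1) * h)
    tot <- cost(i, j) + G[k - 1, j + 1]
    jstar <- j[which.min(tot)]
    breaks[m + 2L - k] <- jstar
    i <- jstar + 1L
  }
  breaks
}

#' Optimal placement of exactly m breakpoints
#'
#' Global minimum-RSS segmentation of a series into m+1 constant-mean
#' segments of at least h observed days each, by exact dynamic programming
#' (all feasible placements are considered). Ties are broken toward the
#' lexicographically earliest breakpoint vector.
#'
#' @param values Numeric vector.
#' @param m Number of breakpoints; `(m + 1) * h <= length(values)` required.
#' @param h Minimum segment length.
#' @return List with `breakpoints` (last index of each segment but the
#'   final one) and `rss`.
#' @export
best_breaks_for_m <- function(values, m, h) {
  ct <- nsd_cost_table(values, h)
  if ((m + 1) * h > ct$n)
    stop("infeasible: ", m, " breakpoints with h = ", h, " need n >= ",
         (m + 1) * h, ", have ", ct$n)
  if (m == 0) return(list(breakpoints = integer(0), rss = ct$cost(1, ct$n)))
  G <- dp_suffix_table(ct, m + 1)
  list(breakpoints = dp_reconstruct(ct, G, m), rss = G[m + 1, 1])
}

#' Segment an NSD series, selecting the breakpoint count by BIC
#'
#' Runs the exact dynamic program for every breakpoint count m = 0..m_max
#' and keeps the one minimising
#' `BIC(m) = n log(max(RSS_m, rss_floor) / n) + (2m + 2) log(n)`,
#' i.e. a Gaussian changepoint model with m breakpoint positions, m + 1
#' segment means and one variance. Ties go to the smaller m. Series
#' shorter than 2h cannot be split and come back as a single segment.
#'
#' Segmentation runs over the full buffered series; use
#' [clip_segments_to_core()] before range labelling.
#'
#' @param series An `nsd_series` (or a bare numeric vector of NSD values).
#' @param config A [migr_config()].
#' @return An `nsd_segmentation`: list with `m`, `breakpoints` (observed-day
#'   indices), `segments` (data.frame: start, end, n_days, mean_nsd, plus
#'   start_date/end_date when dates are known), `rss`, `bic`, `n`, `h`.
#' @export
select_segmentation <- function(series, config = migr_config()) {
  if (inherits(series, "nsd_series")) {
    values <- series$nsd_km2
    dates <- series$date
  } else {
    values <- as.numeric(series)
    dates <- NULL
  }
  h <- config$min_segment_days
  n <- length(values)
  rss_floor <- if (is.null(config$rss_floor)) n * 1e-12 else config$rss_floor

  if (n < 2 * h) {
    rss <- if (n > 1) sum((values - mean(values))^2) else 0
    return(new_segmentation(values, dates, integer(0), rss,
                            bic_value(n, rss, 0L, rss_floor), h, series))
  }
  ct <- nsd_cost_table(values, h)
  m_max <- min(config$max_breaks, n %/% h - 1L)
  G <- dp_suffix_table(ct, m_max + 1L)
  rss_by_m <- G[, 1]
  bic_by_m <- vapply(0:m_max, function(m) bic_value(n, rss_by_m[m + 1], m, rss_floor),
                     numeric(1))
  m_best <- which.min(bic_by_m) - 1L # first minimum = smallest m on ties
  breaks <- dp_reconstruct(ct, G, m_best)
  new_segmentation(values, dates, breaks, rss_by_m[m_best + 1],
                   bic_by_m[m_best + 1], h, series)
}

bic_value <- function(n, rss, m, rss_floor) {
  n * log(max(rss, rss_floor) / n) + (2 * m + 2) * log(n)
}

new_segmentation <- function(values, dates, breaks, rss, bic, h, series) {
  n <- length(values)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  seg <- data.frame(
    start = starts, end = ends, n_days = ends - starts + 1L,
    mean_nsd = vapply(seq_along(starts),
                      function(k) mean(values[starts[k]:ends[k]]), numeric(1))
  )
  if (!is.null(dates)) {
    seg$start_date <- dates[starts]
    seg$end_date <- dates[ends]
  }
  structure(list(
    m = length(breaks), breakpoints = breaks, segments = seg,
    rss = rss, bic = bic, n = n, h = h,
    values = values, dates = dates,
    animal_id = attr(series, "animal_id"),
    year_label = attr(series, "year_label")
  ), class = "nsd_segmentation")
}

#' Clip a segmentation to the core migratory year
#'
#' The series is segmented with its 14-day buffers attached so that
#' movements at the year edges are modelled; classification then operates
#' on the core year only. Segments lying wholly inside a buffer are
#' dropped; segments straddling a boundary are trimmed to the core.
#'
#' @param seg An `nsd_segmentation` built from a full `nsd_series`.
#' @param series The `nsd_series` it was built from (provides `in_core`).
#' @return The segmentation with `segments`, `breakpoints`, `m` restricted
#'   to the core year.
#' @export
clip_segments_to_core <- function(seg, series) {
  stopifnot(inherits(seg, "nsd_segmentation"), inherits(series, "nsd_series"))
  core_idx <- which(series$in_core)
  lo <- min(core_idx); hi <- max(core_idx)
  keep <- seg$segments$end >= lo & seg$segments$start <= hi
  s <- seg$segments[keep, , drop = FALSE]
  s$start <- pmax(s$start, lo)
  s$end <- pmin(s$end, hi)
  s$n_days <- s$end - s$start + 1L
  s$mean_nsd <- vapply(seq_len(nrow(s)),
                       function(k) mean(seg$values[s$start[k]:s$end[k]]), numeric(1))
  if (!is.null(seg$dates)) {
    s$start_date <- seg$dates[s$start]
    s$end_date <- seg$dates[s$end]
  }
  rownames(s) <- NULL
  seg$segments <- s
  seg$breakpoints <- s$end[-nrow(s)]
  seg$m <- nrow(s) - 1L
  seg
}

#' @export
print.nsd_segmentation <- function(x, ...) {
  cat(sprintf("<nsd_segmentation> n = %d observed days, h = %d, m = %d breakpoint(s), RSS = %.4g, BIC = %.2f\n",
              x$n, x$h, x$m, x$rss, x$bic))
  print(x$segments, ...)
  invisible(x)
}

#' Export a segmentation as JSON
#'
#' @param seg An `nsd_segmentation` with dates.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
segmentation_to_json <- function(seg, path = NULL) {
  obj <- list(
    animal_id = seg$animal_id, year_label = seg$year_label,
    # a breakdate is the first day of the segment that follows the break
    breakdates = if (!is.null(seg$dates) && seg$m > 0)
      format(seg$dates[seg$breakpoints + 1L]) else character(0),
    segment_means_km2 = seg$segments$mean_nsd,
    m = seg$m, rss = seg$rss, bic = seg$bic
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
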