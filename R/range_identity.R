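# Decide which NSD segments represent the same geographic range. A change
# in mean NSD can mark a range shift but also mere range expansion or a
# return to an earlier range, so segments are compared by the overlap of
# their NSD value distributions: overlap > 5% = same range. Breakpoints
# between adjacent same-range segments are discarded; the survivors are
# range shifts.

#' Overlap coefficient of two samples
#'
#' eta = integral of min(f_a, f_b), where f_a, f_b are Gaussian kernel
#' density estimates of the two samples evaluated on a shared grid.
#' Bandwidths follow Silverman's rule per sample with a floor of
#' `max(0.01 * pooled sd, 1e-6)` so near-constant resident segments never
#' degenerate; the grid has 1024 points spanning the pooled range plus 3
#' bandwidths on each side; integration is trapezoidal. eta = 1 for
#' identical distributions, 0 for disjoint ones.
#'
#' @param a,b Numeric samples (NSD values of two segments).
#' @return A fraction in [0, 1].
#' @export
#' @examples
#' set.seed(1)
#' overlap_coefficient(rnorm(500), rnorm(500, 4)) # nearly disjoint
overlap_coefficient <- function(a, b) {
  a <- as.numeric(a[is.finite(a)])
  b <- as.numeric(b[is.finite(b)])
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  pooled_sd <- stats::sd(c(a, b))
  if (!is.finite(pooled_sd)) pooled_sd <- 0
  bw_floor <- max(0.01 * pooled_sd, 1e-6)
  bw_a <- max(silverman_bw(a), bw_floor)
  bw_b <- max(silverman_bw(b), bw_floor)
  bw_max <- max(bw_a, bw_b)
  lo <- min(a, b) - 3 * bw_max
  hi <- max(a, b) + 3 * bw_max
  grid <- seq(lo, hi, length.out = 1024L)
  fa <- kde_on_grid(a, bw_a, grid)
  fb <- kde_on_grid(b, bw_b, grid)
  eta <- trapz(grid, pmin(fa, fb))
  min(max(eta, 0), 1)
}

# Silverman's rule of thumb; 0 when the sample has no usable spread
# (caller applies the floor).
silverman_bw <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  sdx <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  s <- min(sdx, iqr)
  if (!is.finite(s) || s <= 0) s <- max(sdx, iqr)
  if (!is.finite(s) || s <= 0) return(0)
  0.9 * s * n^(-1 / 5)
}

# Gaussian KDE of `x` with bandwidth `bw` on `grid`, chunked so large
# samples (10^4+) do not allocate a giant outer-product matrix at once.
kde_on_grid <- function(x, bw, grid, chunk = 2048L) {
  acc <- numeric(length(grid))
  n <- length(x)
  for (s in seq(1L, n, by = chunk)) {
    xi <- x[s:min(s + chunk - 1L, n)]
    acc <- acc + rowSums(outer(grid, xi, function(g, v) stats::dnorm(g, v, bw)))
  }
  acc / n
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Assign segments to ranges by NSD distribution overlap
#'
#' Two-stage procedure on the raw daily NSD values of the segments.
#'
#' Stage 1 repeatedly merges \emph{adjacent} segments whose value
#' distributions overlap by more than the threshold (highest-overlap pair
#' first, pooling their values and recomputing), discarding the breakpoint
#' between them: a breakpoint whose flanking segments look alike marked a
#' range expansion or a pause in a gradual drift, not a shift. Pooling
#' also absorbs segments that the changepoint model dedicates to a transit
#' window into the neighbouring range.
#'
#' Stage 2 computes the overlap between every pair of surviving merged
#' segments and closes the same-range relation transitively (connected
#' components), so a migrant's two visits to its summer range resolve to a
#' single range and round trips become detectable. Should closure ever
#' label two adjacent segments as the same range, they are merged and the
#' procedure restarts.
#'
#' Ranges are numbered by order of first appearance, so the range occupied
#' on July 1 (the summer range) is always range 1; the boundaries between
#' the final segments are the range shifts.
#'
#' @param seg An `nsd_segmentation`, already clipped to the core year via
#'   [clip_segments_to_core()] when buffers were used.
#' @param series The `nsd_series` the segmentation refers to.
#' @param threshold Overlap above which two segments share a range
#'   (default 0.05).
#' @return A `range_labeling`: list with `segments` (data.frame: start,
#'   end, start_date, end_date, n_days, range_id, mean_nsd), `n_ranges`,
#'   `shifts` (data.frame: date, index, from_range, to_range),
#'   `summer_range_id`, `overlap_matrix` (all-pairs, final segments).
#' @export
build_range_labeling <- function(seg, series, threshold = 0.05) {
  stopifnot(inherits(seg, "nsd_segmentation"))
  s <- seg$segments
  bounds <- cbind(s$start, s$end)

  repeat {
    # stage 1: iterated adjacent merging on pooled values
    repeat {
      k <- nrow(bounds)
      if (k < 2L) break
      eta_adj <- vapply(seq_len(k - 1L), function(i)
        overlap_coefficient(seg_values(seg, bounds, i),
                            seg_values(seg, bounds, i + 1L)), numeric(1))
      if (max(eta_adj) <= threshold) break
      i <- which.max(eta_adj)
      bounds <- merge_rows(bounds, i)
    }

    # stage 2: all-pairs identity with transitive closure
    k <- nrow(bounds)
    eta <- diag(1, k)
    if (k >= 2L) {
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        eta[i, j] <- eta[j, i] <- overlap_coefficient(
          seg_values(seg, bounds, i), seg_values(seg, bounds, j))
      }
    }
    comp <- connected_components(eta > threshold)
    range_id <- match(comp, unique(comp))
    adj_same <- which(diff(range_id) == 0)
    if (!length(adj_same)) break
    bounds <- merge_rows(bounds, adj_same[1]) # conservative: drop that break too
  }

  merged <- data.frame(start = bounds[, 1], end = bounds[, 2],
                       range_id = range_id)
  merged$n_days <- merged$end - merged$start + 1L
  merged$mean_nsd <- vapply(seq_len(nrow(merged)), function(i)
    mean(seg$values[merged$start[i]:merged$end[i]]), numeric(1))
  if (!is.null(seg$dates)) {
    merged$start_date <- seg$dates[merged$start]
    merged$end_date <- seg$dates[merged$end]
  }

  nseg <- nrow(merged)
  if (nseg >= 2) {
    shifts <- data.frame(
      date = if (!is.null(seg$dates)) seg$dates[merged$start[-1]] else
        as.Date(NA) + seq_len(nseg - 1) * 0,
      index = merged$start[-1],
      from_range = merged$range_id[-nseg],
      to_range = merged$range_id[-1]
    )
  } else {
    shifts <- data.frame(date = as.Date(character()), index = integer(),
                         from_range = integer(), to_range = integer())
  }

  structure(list(
    segments = merged,
    n_ranges = length(unique(merged$range_id)),
    shifts = shifts,
    summer_range_id = 1L,
    overlap_matrix = eta,
    animal_id = seg$animal_id,
    year_label = seg$year_label
  ), class = "range_labeling")
}

# Raw NSD values of working segment i (rows of a start/end bounds matrix).
seg_values <- function(seg, bounds, i) seg$values[bounds[i, 1]:bounds[i, 2]]

# Merge working segment i with i + 1.
merge_rows <- function(bounds, i) {
  bounds[i, 2] <- bounds[i + 1L, 2]
  bounds[-(i + 1L), , drop = FALSE]
}

# Connected components of an undirected adjacency matrix; returns the
# component index of each node (components in order of their lowest node).
connected_components <- function(adj) {
  k <- nrow(adj)
  comp <- rep(NA_integer_, k)
  cur <- 0L
  for (seed in seq_len(k)) {
    if (!is.na(comp[seed])) next
    cur <- cur + 1L
    frontier <- seed
    comp[seed] <- cur
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & is.na(comp))
      comp[nb] <- cur
      frontier <- c(frontier[-1], nb)
    }
  }
  comp
}

#' @export
print.range_labeling <- function(x, ...) {
  cat(sprintf("<range_labeling> %d segment(s), %d range(s), %d shift(s)\n",
              nrow(x$segments), x$n_ranges, nrow(x$shifts)))
  print(x$segments, ...)
  if (nrow(x$shifts)) {
    cat("shifts:\n")
    print(x$shifts, ...)
  }
  invisible(x)
}

#' Export a range labeling as JSON
#' @param labeling A `range_labeling`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
range_labeling_to_json <- function(labeling, path = NULL) {
  s <- labeling$segments
  obj <- list(
    animal_id = labeling$animal_id, year_label = labeling$year_label,
    segments = lapply(seq_len(nrow(s)), function(i) list(
      start = if ("start_date" %in% names(s)) format(s$start_date[i]) else s$start[i],
      end = if ("end_date" %in% names(s)) format(s$end_date[i]) else s$end[i],
      range_id = s$range_id[i]
    )),
    shifts = lapply(seq_len(nrow(labeling$shifts)), function(i) list(
      date = format(labeling$shifts$date[i]),
      from = labeling$shifts$from_range[i],
      to = labeling$shifts$to_range[i]
    ))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
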