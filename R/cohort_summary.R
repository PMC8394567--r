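# Cohort-level aggregation: category percentages, per-category metric
# means +/- SE, strategies-per-animal tables and the year-to-year
# transition matrix.

#' Summarise classified trajectories by category
#'
#' Counts and percentages per category, plus mean +/- SE (sd/sqrt(n),
#' n - 1 denominator sd) for every numeric metric column present. Date
#' metrics are averaged as days since July 1 of each trajectory's
#' migratory year and rendered back as month-day strings, avoiding
#' calendar-wrap artifacts.
#'
#' @param results Per-trajectory table from [classify_tracks()].
#' @return A `category_summary`: list with `categories` (category, n,
#'   percent) and `metrics` (category, metric, mean, se, n, long form).
#' @export
summarize_cohort <- function(results) {
  if (nrow(results) == 0L)
    return(structure(list(categories = data.frame(), metrics = data.frame()),
                     class = "category_summary"))
  n_total <- nrow(results)
  cats <- data.frame(category = STRATEGY_LEVELS)
  cats$n <- vapply(cats$category, function(cc) sum(results$category == cc), integer(1))
  cats$percent <- 100 * cats$n / n_total

  num_metrics <- c("trip_length_days", "combined_trip_length_days",
                   "n_trip_ranges", "mean_range_distance_km",
                   "max_range_distance_km", "mean_displacement_km")
  num_metrics <- intersect(num_metrics, names(results))
  date_metrics <- intersect(c("departure_date", "return_date"), names(results))

  mrows <- list()
  for (cc in STRATEGY_LEVELS) {
    sub <- results[results$category == cc, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (mname in num_metrics) {
      x <- sub[[mname]]
      x <- x[is.finite(x)]
      if (!length(x)) next
      mrows[[length(mrows) + 1L]] <- data.frame(
        category = cc, metric = mname, mean = mean(x),
        se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
        n = length(x), display = NA_character_)
    }
    for (mname in date_metrics) {
      dts <- as.Date(sub[[mname]]) # tolerate character dates from CSV
      ok <- !is.na(dts)
      if (!any(ok)) next
      doy <- days_since_july1(dts[ok], sub$year_label[ok])
      m <- mean(doy)
      mrows[[length(mrows) + 1L]] <- data.frame(
        category = cc, metric = mname, mean = m,
        se = if (sum(ok) > 1) stats::sd(doy) / sqrt(sum(ok)) else NA_real_,
        n = sum(ok),
        display = format(migratory_year_start(2001L) + round(m), "%b %d"))
    }
  }
  structure(list(categories = cats,
                 metrics = if (length(mrows)) do.call(rbind, mrows) else data.frame(),
                 n_total = n_total),
            class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat(sprintf("<category_summary> %d trajectories\n", x$n_total))
  print(x$categories, row.names = FALSE, ...)
  invisible(x)
}

# Maximal runs of consecutive migratory years per animal.
consecutive_runs <- function(results) {
  out <- list()
  for (id in unique(results$animal_id)) {
    yrs <- sort(results$year_label[results$animal_id == id])
    grp <- cumsum(c(1L, diff(yrs) != 1L))
    for (g in unique(grp))
      out[[length(out) + 1L]] <- list(animal_id = id, years = yrs[grp == g])
  }
  out
}

#' Strategies-per-animal table
#'
#' For animals monitored 2+ consecutive migratory years, tabulates how many
#' distinct strategies each used, stratified by the number of consecutive
#' years monitored. A gap year breaks a run; each maximal run of >= 2
#' years contributes one entry. Single-year animals are excluded.
#'
#' @param results Per-trajectory table from [classify_tracks()].
#' @return data.frame: years_monitored, n, then percentage columns
#'   `pct_1_strategy` ... up to the largest strategy count observed.
#' @export
strategy_switching <- function(results) {
  runs <- Filter(function(r) length(r$years) >= 2L, consecutive_runs(results))
  if (!length(runs))
    return(data.frame(years_monitored = integer(), n = integer()))
  per_run <- do.call(rbind, lapply(runs, function(r) {
    labs <- results$category[results$animal_id == r$animal_id &
                             results$year_label %in% r$years]
    data.frame(years_monitored = length(r$years),
               n_strategies = length(unique(labs)))
  }))
  strata <- sort(unique(per_run$years_monitored))
  max_s <- max(per_run$n_strategies)
  out <- data.frame(years_monitored = strata)
  out$n <- vapply(strata, function(y) sum(per_run$years_monitored == y), integer(1))
  for (s in seq_len(max_s)) {
    out[[sprintf("pct_%d_strategy", s)]] <- vapply(strata, function(y) {
      sub <- per_run[per_run$years_monitored == y, ]
      100 * sum(sub$n_strategies == s) / nrow(sub)
    }, numeric(1))
  }
  out
}

#' Year-to-year strategy transition matrix
#'
#' Counts every (category in year t -> category in year t + 1) pair over
#' consecutive migratory years within each animal (a gap year breaks the
#' pairing). Columns are the year-t category; percentages are conditioned
#' per column. The overall switch percentage is 100 x off-diagonal pairs /
#' all pairs.
#'
#' @param results Per-trajectory table from [classify_tracks()].
#' @return A `transition_matrix`: list with `counts` (7x7, rows = next
#'   year), `percent` (column-conditional, NA columns with no outgoing
#'   pairs), `n_pairs`, `switch_percent`.
#' @export
transition_matrix <- function(results) {
  counts <- matrix(0L, 7, 7, dimnames = list(to = STRATEGY_LEVELS,
                                             from = STRATEGY_LEVELS))
  for (r in consecutive_runs(results)) {
    if (length(r$years) < 2L) next
    sub <- results[results$animal_id == r$animal_id &
                   results$year_label %in% r$years, , drop = FALSE]
    sub <- sub[order(sub$year_label), , drop = FALSE]
    for (i in seq_len(nrow(sub) - 1L)) {
      counts[sub$category[i + 1L], sub$category[i]] <-
        counts[sub$category[i + 1L], sub$category[i]] + 1L
    }
  }
  n_pairs <- sum(counts)
  col_tot <- colSums(counts)
  percent <- sweep(counts, 2, ifelse(col_tot > 0, col_tot, NA), "/") * 100
  switch_percent <- if (n_pairs > 0) 100 * (n_pairs - sum(diag(counts))) / n_pairs
                    else NA_real_
  structure(list(counts = counts, percent = percent, n_pairs = n_pairs,
                 switch_percent = switch_percent),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d consecutive-year pairs, %.1f%% switched\n",
              x$n_pairs, x$switch_percent))
  print(round(x$percent, 1), ...)
  invisible(x)
}
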