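test_that("template specs realise their category's definition", {
  for (cat_name in STRATEGY_LEVELS) {
    spec <- template_spec(cat_name, seed = 1)
    it <- spec$itinerary
    # stays ordered, non-overlapping, each >= 14 days, covering the year
    expect_true(all(it$end_day >= it$start_day))
    expect_true(all(it$end_day - it$start_day + 1L >= 14L))
    if (nrow(it) > 1) {
      expect_true(all(it$start_day[-1] > it$end_day[-nrow(it)]))
      expect_true(all(it$start_day[-1] - it$end_day[-nrow(it)] - 1L ==
                        spec$transit_days))
    }
    expect_equal(it$start_day[1], 1L)
    expect_equal(it$end_day[nrow(it)], spec$n_days)
    # distinct range offsets pairwise >= 10 km apart
    offs <- spec$range_offsets
    if (length(offs) > 1) {
      for (i in 1:(length(offs) - 1)) for (j in (i + 1):length(offs)) {
        expect_gte(sqrt(sum((offs[[i]] - offs[[j]])^2)), 10)
      }
    }
  }

  # category-specific structure
  expect_equal(nrow(template_spec("resident")$itinerary), 1L)
  dual <- template_spec("dual_range_migrant")$itinerary
  expect_equal(dual$range, c(1L, 2L, 1L))
  expect_gt(dual$end_day[2] - dual$start_day[2] + 1L, 150) # long away-stay
  disp <- template_spec("disperser")$itinerary
  expect_true(disp$range[nrow(disp)] != 1L) # ends off the summer range
  expect_gte(length(unique(disp$range)), 2L)
  expect_error(template_spec("nomad"), "arg")
})

test_that("simulate_fixes is reproducible and respects the noise model", {
  spec <- template_spec("dual_range_migrant", seed = 9)
  a <- simulate_fixes(spec)
  b <- simulate_fixes(spec)
  expect_identical(a$fixes, b$fixes) # bit-identical from the same seed

  # resident, sd 0.5: >= 99% of daily means within 2 km of the centre
  rspec <- template_spec("resident", seed = 10)
  daily <- average_daily(simulate_fixes(rspec)$fixes)
  dist <- haversine_km(rspec$base_location[["lat"]], rspec$base_location[["lon"]],
                       daily$lat, daily$lon)
  expect_gte(mean(dist <= 2), 0.99)

  # dual-range, 25 km separation: away-plateau mean NSD within 5% of 625
  dspec <- template_spec("dual_range_migrant", seed = 11)
  sim <- simulate_fixes(dspec)
  tracks <- split_migratory_years(average_daily(sim$fixes))
  ser <- compute_nsd(Filter(function(t) t$complete, tracks)[[1]])
  away <- ser$date >= as.Date("2016-11-20") & ser$date <= as.Date("2017-04-10")
  expect_equal(mean(ser$nsd_km2[away]), 625, tolerance = 0.05)

  # ground truth: shift dates at the first transit day
  expect_equal(sim$truth$true_shift_dates,
               as.Date(c("2016-11-09", "2017-04-26")))
  expect_equal(sim$truth$true_category, "dual_range_migrant")
  # range-of-day map is NA exactly during transit
  rod <- sim$truth$true_range_of_day
  expect_equal(sum(is.na(rod$range)), 2L * dspec$transit_days)
})

test_that("missing-day injection and AR(1) options behave", {
  spec <- template_spec("resident", seed = 12)
  spec$missing_day_rate <- 0.2
  sim <- simulate_fixes(spec)
  days <- unique(as.Date(sim$fixes$timestamp, tz = "UTC"))
  expect_lt(length(days), 407) # some days dropped
  expect_gt(length(days), 250)

  # AR(1) centre wander raises the lag-1 autocorrelation of daily latitude
  # well above the independent-noise baseline (the two white-noise layers
  # dilute it below the raw coefficient)
  spec_iid <- template_spec("resident", seed = 13)
  spec_ar <- template_spec("resident", seed = 13)
  spec_ar$ar1_coef <- 0.6
  acf1 <- function(s) {
    d <- average_daily(simulate_fixes(s)$fixes)
    stats::acf(d$lat, plot = FALSE)$acf[2]
  }
  expect_lt(acf1(spec_iid), 0.12)
  expect_gt(acf1(spec_ar), acf1(spec_iid) + 0.1)
})

test_that("simulate_cohort bookkeeping and multi-year truth", {
  expect_equal(nrow(simulate_cohort(0)$truth), 0L)

  cohort <- simulate_cohort(2, base_seed = 3)
  expect_equal(nrow(cohort$truth), 14L)
  expect_equal(as.vector(table(cohort$truth$true_category)[STRATEGY_LEVELS]),
               rep(2L, 7))
  expect_equal(anyDuplicated(cohort$truth$animal_id), 0L)
  expect_setequal(unique(cohort$fixes$animal_id), cohort$truth$animal_id)

  # named counts
  small <- simulate_cohort(c(resident = 1L, disperser = 2L), base_seed = 4)
  expect_equal(sort(small$truth$true_category),
               c("disperser", "disperser", "resident"))

  # multi-year animal: the truth labels line up with the requested years
  my <- simulate_animal_years(c("resident", "dual_range_migrant", "resident"),
                              seed = 5, animal_id = "m1")
  expect_equal(my$truth$year_label, 2015:2017)
  expect_equal(my$truth$true_category,
               c("resident", "dual_range_migrant", "resident"))
  # fixes cover all three years contiguously
  days <- as.Date(my$fixes$timestamp, tz = "UTC")
  expect_lte(min(days), as.Date("2015-07-01"))
  expect_gte(max(days), as.Date("2018-06-30"))
})

test_that("with_stopover inserts a short pause without changing the year span", {
  spec <- template_spec("dual_range_migrant", seed = 6)
  sp <- with_stopover(spec, duration = 10L)
  expect_equal(nrow(sp$stopovers), 1L)
  expect_equal(sp$stopovers$end_day - sp$stopovers$start_day + 1L, 10L)
  expect_equal(sp$itinerary$end_day[nrow(sp$itinerary)], spec$n_days)
  # stopover sits between the two ranges
  expect_true(sp$stopovers$east_km > 0 &&
                sp$stopovers$east_km < spec$range_offsets[[2]][1])
})
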