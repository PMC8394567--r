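test_that("read_gps_table parses, rejects and sorts", {
  hdr <- "animal_id,timestamp,lat,lon"
  # header-only -> empty, no warnings
  expect_no_warning(fx0 <- read_gps_table(write_fix_csv(hdr)))
  expect_equal(nrow(fx0), 0L)
  expect_equal(attr(fx0, "n_rejected"), 0L)

  # single record
  fx1 <- read_gps_table(write_fix_csv(c(hdr, "d1,2016-01-01T00:00Z,40.0,-111.0")))
  expect_equal(nrow(fx1), 1L)
  expect_equal(fx1$lat, 40.0)
  expect_s3_class(fx1$timestamp, "POSIXct")
  expect_equal(format(fx1$timestamp, "%Y-%m-%d %H:%M", tz = "UTC"), "2016-01-01 00:00")

  # 3 animals x 10 fixes with 2 corrupt rows -> 28 fixes, 2 counted
  rows <- unlist(lapply(c("a", "b", "c"), function(id)
    sprintf("%s,2016-01-%02dT06:00Z,40.%d,-111.0", id, 1:10, 1:10)))
  rows[4] <- "a,not-a-time,40.0,-111.0"
  rows[15] <- "b,2016-01-05T06:00Z,991.0,-111.0"
  expect_warning(fx <- read_gps_table(write_fix_csv(c(hdr, rows))), "2 row")
  expect_equal(nrow(fx), 28L)
  expect_equal(attr(fx, "n_rejected"), 2L)
  expect_false(is.unsorted(fx$timestamp[fx$animal_id == "a"]))

  # missing mapped column is a configuration error, not a row problem
  expect_error(read_gps_table(write_fix_csv("id,timestamp,lat,lon")),
               "absent")

  # TSV dialect with custom column names
  tsv <- write_fix_csv(c("tag\twhen\ty\tx", "d9\t2016-03-01 12:00\t41.5\t-110.25"),
                       ext = ".tsv")
  fxt <- read_gps_table(tsv, dialect = c(animal_id = "tag", timestamp = "when",
                                         lat = "y", lon = "x"))
  expect_equal(fxt$lon, -110.25)
})

test_that("average_daily averages per UTC day and is idempotent", {
  # one fix per day: identity
  fx <- data.frame(animal_id = "a1",
                   timestamp = as.POSIXct(c("2016-07-01 06:00", "2016-07-02 06:00"),
                                          tz = "UTC"),
                   lat = c(40, 40.5), lon = c(-111, -111.5))
  d <- average_daily(fx)
  expect_equal(d$lat, c(40, 40.5))
  expect_equal(d$n_fixes, c(1L, 1L))

  # two fixes on one day: arithmetic mean
  fx2 <- data.frame(animal_id = "a1",
                    timestamp = as.POSIXct(c("2016-07-01 00:00", "2016-07-01 12:00"),
                                           tz = "UTC"),
                    lat = c(40.0, 40.2), lon = c(-111.0, -111.2))
  d2 <- average_daily(fx2)
  expect_equal(d2$lat, 40.1)
  expect_equal(d2$lon, -111.1)
  expect_equal(d2$n_fixes, 2L)

  # 48 jittered fixes around a centre: equals the directly computed mean
  set.seed(7)
  lat <- 40 + rnorm(48, 0, 0.01)
  lon <- -111 + rnorm(48, 0, 0.01)
  fx48 <- data.frame(animal_id = "a1",
                     timestamp = as.POSIXct("2016-07-01", tz = "UTC") +
                       seq(0, by = 1800, length.out = 48),
                     lat = lat, lon = lon)
  d48 <- average_daily(fx48)
  expect_equal(d48$lat, mean(lat), tolerance = 1e-12)
  expect_equal(d48$lon, mean(lon), tolerance = 1e-12)
  expect_equal(d48$n_fixes, 48L)

  # idempotence: averaging the daily table (viewed as fixes) changes nothing
  again <- average_daily(data.frame(animal_id = d48$animal_id,
                                    timestamp = as.POSIXct(d48$date, tz = "UTC"),
                                    lat = d48$lat, lon = d48$lon))
  expect_equal(again[c("animal_id", "date", "lat", "lon")],
               d48[c("animal_id", "date", "lat", "lon")])

  expect_equal(nrow(average_daily(fx[0, ])), 0L)
})

test_that("split_migratory_years labels years, buffers and completeness", {
  # full coverage 2016-07-01..2017-06-30 -> one complete year
  tr <- split_migratory_years(make_year_daily(2016L))
  expect_length(tr, 1L)
  expect_true(tr[[1]]$complete)
  expect_equal(tr[[1]]$year_label, 2016L)
  expect_equal(nrow(tr[[1]]$core), 365L)

  # half-year only -> incomplete
  half <- make_daily(seq(as.Date("2016-07-01"), as.Date("2016-12-31"), "day"),
                     40, -111)
  tr2 <- split_migratory_years(half)
  expect_length(tr2, 1L)
  expect_false(tr2[[1]]$complete)

  # 2016-06-17 .. 2018-07-14: two complete years with full 14-day buffers
  # (plus flagged partial years at the ends)
  full <- make_daily(seq(as.Date("2016-06-17"), as.Date("2018-07-14"), "day"),
                     40, -111)
  tr3 <- split_migratory_years(full)
  complete <- Filter(function(t) t$complete, tr3)
  expect_length(complete, 2L)
  expect_equal(vapply(complete, function(t) t$year_label, integer(1)),
               c(2016L, 2017L))
  expect_equal(vapply(complete, function(t) nrow(t$buffer_pre), integer(1)),
               c(14L, 14L))
  expect_equal(vapply(complete, function(t) nrow(t$buffer_post), integer(1)),
               c(14L, 14L))

  # an 8-day gap breaks completeness even with 97% coverage
  gappy <- make_year_daily(2016L)
  gap <- seq(as.Date("2016-09-01"), by = "day", length.out = 8)
  tr4 <- split_migratory_years(gappy[!gappy$date %in% gap, ])
  expect_false(tr4[[1]]$complete)

  # missing July 1 breaks completeness
  tr5 <- split_migratory_years(gappy[gappy$date != as.Date("2016-07-01"), ])
  expect_false(tr5[[1]]$complete)

  # splitting then concatenating core days reproduces the covered input
  cores <- do.call(rbind, lapply(tr3, function(t) t$core))
  cores <- cores[order(cores$date), ]
  covered <- full[full$date >= as.Date("2015-07-01") &
                  full$date <= as.Date("2019-06-30"), ]
  expect_equal(sort(cores$date), sort(covered$date))
})

test_that("compute_nsd matches a haversine oracle", {
  # stationary: all zeros
  tr <- split_migratory_years(make_year_daily(2016L))[[1]]
  ser <- compute_nsd(tr)
  expect_true(all(ser$nsd_km2 == 0))

  # a day 3.000 km due north of the reference -> 9.000 km^2
  d <- make_year_daily(2016L)
  north3 <- 40 + 3 / (6371.0088 * pi / 180) # 3 km of arc due north
  d$lat[d$date == as.Date("2016-10-01")] <- north3
  ser2 <- compute_nsd(split_migratory_years(d)[[1]])
  expect_equal(ser2$nsd_km2[ser2$date == as.Date("2016-10-01")], 9,
               tolerance = 1e-6)
  expect_equal(ser2$nsd_km2[ser2$date == as.Date("2016-07-01")], 0)

  # every day's displacement equals the independent great-circle oracle
  set.seed(11)
  d3 <- make_year_daily(2016L)
  d3$lat <- d3$lat + rnorm(nrow(d3), 0, 0.05)
  d3$lon <- d3$lon + rnorm(nrow(d3), 0, 0.05)
  ser3 <- compute_nsd(split_migratory_years(d3)[[1]])
  ref <- attr(ser3, "reference")
  # law-of-cosines oracle loses precision near zero distance: absolute
  # agreement to 0.1 m is the meaningful bound
  expect_lt(max(abs(ser3$displacement_km -
                      oracle_distance_km(ref[["lat"]], ref[["lon"]],
                                         ser3$lat, ser3$lon))), 1e-4)
  expect_equal(ser3$displacement_km, sqrt(ser3$nsd_km2))

  # invariance: relabelling the animal leaves the NSD values unchanged
  d4 <- d3
  d4$animal_id <- "zz"
  ser4 <- compute_nsd(split_migratory_years(d4)[[1]])
  expect_equal(ser4$nsd_km2, ser3$nsd_km2)

  # incomplete track is refused
  half <- split_migratory_years(make_daily(
    seq(as.Date("2016-07-01"), as.Date("2016-12-31"), "day"), 40, -111))[[1]]
  expect_error(compute_nsd(half), "complete")
})
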