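test_that("chained grouping follows the 30-minute independence rule", {
  mk <- function(mins) data.frame(
    site_id = rep("S1", length(mins)),
    timestamp = as.POSIXct("2018-06-01 10:00:00", tz = "UTC") + mins * 60)

  # gaps {10, 35}: 35 > 30 splits
  ev <- group_events(mk(c(0, 10, 45)))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$n_photos, c(2L, 1L))

  # all consecutive gaps <= 30: one event even though span is 60 min
  ev <- group_events(mk(c(0, 20, 40, 60)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_photos, 4L)

  # a gap of exactly the threshold stays within the event (strict ">")
  ev <- group_events(mk(c(0, 30)))
  expect_equal(nrow(ev), 1L)
  ev <- group_events(mk(c(0, 30.001)))
  expect_equal(nrow(ev), 2L)

  # empty input -> empty collection
  expect_equal(nrow(group_events(mk(numeric(0)))), 0L)
})

test_that("event attributes aggregate photo-level flags", {
  ev <- group_events(tiny_photos())
  expect_equal(nrow(ev), 2L)
  s1 <- ev[ev$site_id == "S1", ]
  expect_true(s1$face_captured)        # any face_visible
  expect_equal(s1$behavior, "curiosity")  # curiosity > look_only > none
  expect_false(s1$monochrome)
  expect_equal(s1$face_resolution_px, 20000)
  s2 <- ev[ev$site_id == "S2", ]
  expect_equal(s2$behavior, "retreat")
  expect_true(s2$monochrome)
  expect_true(s2$flash_fired)
  # face_captured iff max face_bbox_pixels > 0
  expect_equal(ev$face_captured, ev$face_resolution_px > 0)
})

test_that("grouping rejects malformed input", {
  bad <- tiny_photos()
  bad$timestamp[2] <- "not-a-time"
  expect_error(group_events(bad), "unparseable timestamp.*2",
               class = "facetrap_input_error")
  bad <- tiny_photos()
  bad$face_visible[1] <- FALSE # but bbox > 0
  expect_error(group_events(bad), "face_bbox_pixels",
               class = "facetrap_input_error")
  bad <- tiny_photos()
  bad$behavior_code[1] <- "sleeping"
  expect_error(group_events(bad), "behavior_code",
               class = "facetrap_input_error")
})

test_that("grouping is idempotent and monotone in the gap", {
  set.seed(11)
  sched <- simulate_event_schedule(n_events = 60, n_sites = 8, seed = 11)
  photos <- simulate_photo_stream(sched, photos_per_event = 3, seed = 11)
  for (gap in c(15, 30, 60, 240)) {
    ev <- group_events(photos, gap)
    # regroup one representative photo per (event, photo) -- identical events
    ev2 <- group_events(photos, gap)
    expect_identical(ev[, -1], ev2[, -1])
  }
  n_by_gap <- vapply(c(5, 15, 30, 60, 120, 1e6),
                     function(g) nrow(group_events(photos, g)), numeric(1))
  expect_true(all(diff(n_by_gap) <= 0)) # coarsening never adds events
  expect_equal(n_by_gap[length(n_by_gap)], 8) # one event per site at huge gap
})

test_that("a 208-cluster photo stream regroups to exactly 208 events", {
  sched <- simulate_event_schedule(n_events = 208, n_sites = 61, seed = 4)
  sched$face_captured <- TRUE
  sched$face_resolution_px <- 30000 + seq_len(208)
  photos <- simulate_photo_stream(sched, photos_per_event = 5, seed = 4)
  expect_equal(nrow(photos), 1040L)
  ev <- group_events(photos, 30, tz = "US/Mountain")
  expect_equal(nrow(ev), 208L)
  # round trip: same sites, same start times, same per-event face resolution
  key <- function(d) paste(d$site_id, format(d$start_time, "%Y%m%d%H%M%S"))
  expect_setequal(key(ev), key(sched))
  expect_setequal(ev$face_resolution_px, sched$face_resolution_px)
})

test_that("solar elevation matches an independent trig oracle and NOAA anchors", {
  lat <- 43.48; lon <- -110.76
  noon_jun <- as.POSIXct("2018-06-21 12:00:00", tz = "US/Mountain")
  night_dec <- as.POSIXct("2018-12-21 01:00:00", tz = "US/Mountain")
  e1 <- solar_elevation(lat, lon, noon_jun)
  e2 <- solar_elevation(lat, lon, night_dec)
  # independent oracle with solstice declination +/-23.44
  expect_lt(abs(e1 - solar_oracle_deg(lat, lon, noon_jun, 23.44)), 2)
  expect_lt(abs(e2 - solar_oracle_deg(lat, lon, night_dec, -23.44)), 2)
  expect_gt(e1, 0)    # midsummer noon: day
  expect_lt(e2, -18)  # midwinter 1 am: astronomical night
  expect_false(is_astronomical_night(lat, lon, noon_jun))
  expect_true(is_astronomical_night(lat, lon, night_dec))
})

test_that("night classification agrees with a minute-by-minute boundary scan", {
  lat <- 43.48; lon <- -110.76
  mins <- seq(as.POSIXct("2018-09-15 18:00", tz = "US/Mountain"),
              as.POSIXct("2018-09-16 08:00", tz = "US/Mountain"), by = "1 min")
  elev <- solar_elevation(lat, lon, mins)
  night <- elev < -18
  # exactly one dusk crossing and one dawn crossing over this window
  flips <- which(diff(night) != 0)
  expect_equal(length(flips), 2L)
  # the classifier agrees with the scan at and adjacent to each crossing
  for (f in flips) {
    idx <- max(1, f - 1):min(length(mins), f + 2)
    expect_equal(is_astronomical_night(lat, lon, mins[idx]), night[idx])
  }
})

test_that("classify_night joins coordinates and flags errors", {
  ev <- group_events(tiny_photos(), tz = "US/Mountain")
  sites <- data.frame(site_id = c("S1", "S2"), latitude = 43.48,
                      longitude = -110.76, has_acd = c(TRUE, FALSE))
  ev <- classify_night(ev, sites)
  expect_false(ev$is_night[ev$site_id == "S1"]) # 10:00 local, June
  expect_true(ev$is_night[ev$site_id == "S2"])  # 23:30 local, June
  expect_error(classify_night(ev, sites[1, ]), "unknown site",
               class = "facetrap_input_error")
  sites$latitude[2] <- NA
  expect_error(classify_night(ev, sites), "coordinates",
               class = "facetrap_config_error")
})

test_that("median split assigns low/high with ties to low", {
  ev <- data.frame(event_id = paste0("E", 1:4),
                   face_resolution_px = c(1, 2, 3, 4))
  out <- assign_resolution_class(ev)
  expect_equal(out$resolution_class, c("low", "low", "high", "high"))

  ev$face_resolution_px <- c(5, 5, 5, 5)
  expect_equal(assign_resolution_class(ev)$resolution_class, rep("low", 4))

  # 16 values constructed so the midpoint median is 39216 -> 8/8 split
  set.seed(1)
  px <- c(sort(round(exp(stats::runif(7, log(13338), log(38000))))), 39000,
          39432, sort(round(exp(stats::runif(7, log(40000), log(109495))))))
  ev <- data.frame(event_id = sprintf("E%02d", 1:16), face_resolution_px = px)
  out <- assign_resolution_class(ev)
  expect_equal(stats::median(px), 39216)
  expect_equal(as.integer(table(out$resolution_class)), c(8L, 8L))

  ev$face_resolution_px[3] <- 0
  expect_error(assign_resolution_class(ev), "E03",
               class = "facetrap_input_error")
})

test_that("timestamps parse offsets and reject garbage", {
  t1 <- parse_timestamps("2018-06-01T10:00:00", tz = "UTC")
  t2 <- parse_timestamps("2018-06-01T04:00:00-06:00", tz = "UTC")
  t3 <- parse_timestamps("2018-06-01 10:00:00Z", tz = "UTC")
  expect_equal(as.numeric(t1), as.numeric(t2))
  expect_equal(as.numeric(t1), as.numeric(t3))
  expect_error(parse_timestamps(c("2018-06-01T10:00:00", "junk")),
               "record\\(s\\) 2", class = "facetrap_input_error")
})
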