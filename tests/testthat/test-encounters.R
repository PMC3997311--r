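test_that("season assignment follows the study calendar exactly", {
  expect_equal(assign_season(as.Date("2009-03-15")), "FallWinter")
  expect_equal(assign_season(as.Date("2009-03-16")), "Excluded")
  expect_equal(assign_season(as.Date("2009-04-20")), "Excluded")
  expect_equal(assign_season(as.Date("2009-05-31")), "Excluded")
  expect_equal(assign_season(as.Date("2009-06-01")), "Summer")
  expect_equal(assign_season(as.Date("2009-09-30")), "Summer")
  expect_equal(assign_season(as.Date("2008-10-01")), "FallWinter")
  expect_equal(assign_season(as.Date("2009-01-15")), "FallWinter")
})

test_that("detection events split on gaps of at least 15 minutes", {
  t0 <- as.POSIXct("2009-01-01 12:00:00", tz = "UTC")
  expect_equal(nrow(group_detections(t0 + c(0, 10 * 60))), 1)
  expect_equal(nrow(group_detections(t0 + c(0, 16 * 60))), 2)
  expect_equal(nrow(group_detections(t0 + c(0, 15 * 60))), 2)
  expect_equal(nrow(group_detections(as.POSIXct(character(),
                                                tz = "UTC"))), 0)
  # unsorted input, mixed gaps: 3 bursts
  ts <- t0 + c(40 * 60, 0, 5 * 60, 41 * 60, 90 * 60)
  ev <- group_detections(ts)
  expect_equal(nrow(ev), 3)
  expect_equal(sum(ev$n_images), 5)
})

test_that("proximity counts equal a brute-force distance scan", {
  set.seed(15)
  for (k in 1:10) {
    tel <- data.frame(
      animal_id = "A", sex = "F",
      date = as.Date("2008-10-01") + sample(0:364, 200, replace = TRUE),
      x = runif(200, 0, 5000), y = runif(200, 0, 5000))
    cx <- runif(1, 0, 5000); cy <- runif(1, 0, 5000)
    r <- sample(c(250, 500), 1)
    win <- sort(as.Date("2008-10-01") + sample(0:364, 2))
    expect_identical(
      count_relocations_within(tel, cx, cy, r, window = win),
      brute_count_within(tel, cx, cy, r, window = win))
    expect_identical(
      count_relocations_within(tel, cx, cy, r, season = "FallWinter"),
      brute_count_within(tel, cx, cy, r, season = "FallWinter"))
  }
  expect_warning(
    count_relocations_within(tel, 0, 0, 500, min_spacing = 800),
    "half the minimum")
})

test_that("availability combines the 90% isopleth with window overlap", {
  set.seed(44)
  pts <- matrix(rnorm(2 * 200, sd = 500), ncol = 2)
  sel <- select_bandwidth(pts, animal_id = "F01", period = "FallWinter")
  hr <- list(F01 = list(FallWinter = list(
    ud = sel$ud, isos = isopleths(sel$ud, 1:95, fragments = FALSE),
    multiplier = sel$multiplier, n = 200)))
  tracking <- data.frame(animal_id = "F01", sex = "F",
                         start = as.Date("2008-10-01"),
                         end = as.Date("2009-09-30"))
  cams <- data.frame(camera_id = c("IN", "OUT", "SPRING"),
                     x = c(0, 50000, 0), y = c(0, 50000, 0),
                     start = as.Date(c("2008-11-01", "2008-11-01",
                                       "2009-04-01")),
                     end = as.Date(c("2008-12-06", "2008-12-06",
                                     "2009-05-15")))
  av <- available_pairs(tracking, cams, homeranges = hr,
                        seasons = "FallWinter")
  expect_equal(av$camera_id, "IN")        # outside isopleth + spring-only drop
  expect_equal(av$exposure_days, 36)      # full deployment, no excluded days

  # availability is monotone in the tracking window
  tracking2 <- tracking
  tracking2$start <- tracking$start + 40  # shrink: may drop pairs
  av2 <- available_pairs(tracking2, cams, homeranges = hr,
                         seasons = "FallWinter")
  expect_true(all(paste(av2$animal_id, av2$camera_id) %in%
                    paste(av$animal_id, av$camera_id)))
  # zero-length deployments are dropped with a warning
  cams$end[1] <- cams$start[1] - 1
  expect_warning(available_pairs(tracking, cams, homeranges = hr,
                                 seasons = "FallWinter"), "empty deployment")
})

test_that("encounter tables satisfy their invariants and conserve events", {
  study <- tiny_study(seed = 7)
  hr <- estimate_homeranges(study$telemetry)
  enc <- suppressWarnings(build_encounter_table(
    study$telemetry, study$cameras, study$detections, homeranges = hr,
    analysis = "homerange"))
  expect_gt(nrow(enc), 10)
  expect_silent(validate_encounters(enc, "homerange"))
  expect_true(all(enc$ud > 0))
  expect_true(all(enc$isopleth_pct >= 1 & enc$isopleth_pct <= 90,
                  na.rm = TRUE))
  expect_identical(enc$core, enc$isopleth_pct <= 50)
  expect_identical(enc$detected, as.integer(enc$photo_count > 0))

  encp <- suppressWarnings(build_encounter_table(
    study$telemetry, study$cameras, study$detections,
    analysis = "proximity"))
  expect_true(all(encp$n_locs_250 <= encp$n_locs_500))
  # event conservation: grouped events inside available windows + dropped
  # images account for every detection image
  expect_lte(attr(encp, "n_dropped_images"), nrow(study$detections))
  expect_gte(sum(encp$photo_count), 0)
  if (nrow(study$detections) > 0 && attr(encp, "n_dropped_images") == 0)
    expect_gte(sum(encp$photo_count), 1)

  # NLocs recount against brute force on a sample of records
  set.seed(3)
  cams <- study$cameras
  rows <- sample(nrow(encp), min(25, nrow(encp)))
  for (i in rows) {
    tel <- study$telemetry[study$telemetry$animal_id ==
                             encp$animal_id[i], ]
    ci <- match(encp$camera_id[i], cams$camera_id)
    ov <- c(max(cams$start[ci], min(tel$date)),
            min(cams$end[ci], max(tel$date)))
    expect_identical(encp$n_locs_500[i],
                     brute_count_within(tel, cams$x[ci], cams$y[ci], 500,
                                        window = ov,
                                        season = encp$season[i]))
  }
  expect_error(build_encounter_table(study$telemetry, study$cameras,
                                     study$detections,
                                     analysis = "homerange"),
               "requires estimated home ranges")
})
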